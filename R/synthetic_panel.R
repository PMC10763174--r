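#' Describe how a synthetic panel rates one item
#'
#' Three archetypes cover the empirical patterns multi-round appropriateness
#' panels exhibit: `consensus` (ratings clustered around a target location),
#' `polarized` (two camps at opposite poles) and `uniform` (no structure).
#'
#' @param kind `"consensus"`, `"polarized"` or `"uniform"`.
#' @param location Target score in `[1, 9]` (consensus only).
#' @param dispersion Spread (standard deviation of the latent bell) around
#'   `location`; `0` gives a degenerate all-identical panel.
#' @param poles Length-2 integer pair of pole scores (polarized only).
#' @param mix Fraction of the panel at the first pole (polarized only).
#' @return A list of class `"item_archetype"`.
#' @export
#' @examples
#' item_archetype("consensus", location = 2, dispersion = 1)
#' item_archetype("polarized", poles = c(1, 9), mix = 0.5)
item_archetype <- function(kind = c("consensus", "polarized", "uniform"),
                           location = NULL, dispersion = NULL,
                           poles = c(1L, 9L), mix = 0.5) {
  kind <- match.arg(kind)
  if (kind == "consensus") {
    if (is.null(location) || location < 1 || location > 9) {
      abort_config("a consensus archetype needs `location` in [1, 9]")
    }
    if (is.null(dispersion) || dispersion < 0) {
      abort_config("a consensus archetype needs `dispersion` >= 0")
    }
  }
  if (kind == "polarized") {
    if (length(poles) != 2 || any(poles < 1 | poles > 9)) {
      abort_config("`poles` must be two scores in [1, 9]")
    }
    if (mix < 0 || mix > 1) abort_config("`mix` must be in [0, 1]")
  }
  structure(list(kind = kind, location = location, dispersion = dispersion,
                 poles = as.integer(poles), mix = mix),
            class = "item_archetype")
}

# the band (or disagreement state) the archetype is built to represent;
# used as ground truth in recovery experiments
archetype_truth <- function(a) {
  if (a$kind == "consensus") {
    cls <- classify(a$location, 0)
    list(agreement = "agreement", band = cls$band)
  } else {
    list(agreement = "disagreement", band = NA_character_)
  }
}

# one panel's integer ratings for one item. `pole_assignment = "fixed"`
# allocates exactly round(mix * n) panellists to the first pole so a
# polarized item is polarized in every realization; "random" draws camp
# membership per panellist (Bernoulli), under which a nominal 50/50 split
# of 24 raters fails to straddle the scale in ~6% of draws.
draw_ratings <- function(n, archetype, pole_assignment = "fixed") {
  switch(
    archetype$kind,
    consensus = {
      x <- round(rnorm(n, archetype$location, archetype$dispersion))
      as.integer(pmin(9, pmax(1, x)))
    },
    polarized = {
      k <- if (pole_assignment == "fixed") {
        round(archetype$mix * n)
      } else {
        rbinom(1, n, archetype$mix)
      }
      sample(c(rep(archetype$poles[1], k), rep(archetype$poles[2], n - k)))
    },
    uniform = sample(1:9, n, replace = TRUE)
  )
}

#' Configuration of a synthetic two-round panel study
#'
#' Defaults emulate the design shape of the motivating opioid-indicator
#' study: 24 panellists rate 20 items in round 1; attrition leaves an
#' expected 19 of them to rate the same 20 items plus 13 reworded child
#' items in round 2; retained panellists tend to move toward the round-1
#' item median after seeing the feedback.
#'
#' @param n_panellists Round-1 panel size (default 24).
#' @param n_items Number of round-1 items (default 20).
#' @param n_modified Number of reworded child items added in round 2, one
#'   per parent taken from the first `n_modified` items (default 13).
#' @param attrition Per-panellist probability of dropping out between
#'   rounds; the default 5/24 gives an expected round-2 panel of 19.
#' @param feedback_shift Probability that a retained panellist moves their
#'   round-2 rating one scale step toward the round-1 item median (never
#'   past it). Default 0.5.
#' @param archetypes List of [item_archetype()]s, one per round-1 item.
#'   Default: 15 consensus items at location 2 and 5 at location 5, both
#'   with dispersion 1 — the 15 "inappropriate" / 5 "equivocal" split of
#'   the motivating study.
#' @param pole_assignment `"fixed"` (default) or `"random"`; see
#'   [item_archetype()].
#' @param skip_prob Probability a panellist skips an individual item
#'   (default 0: everyone rates everything).
#' @param seed Integer seed; identical configs with identical seeds yield
#'   byte-identical studies.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_panellists = 24, n_items = 20,
                              n_modified = 13, attrition = 5 / 24,
                              feedback_shift = 0.5, archetypes = NULL,
                              pole_assignment = c("fixed", "random"),
                              skip_prob = 0, seed = 1L) {
  pole_assignment <- match.arg(pole_assignment)
  for (p in c(attrition, feedback_shift, skip_prob)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      abort_config("probabilities must lie in [0, 1]")
    }
  }
  if (n_panellists < 1 || n_items < 1 || n_modified < 0 ||
      n_modified > n_items) {
    abort_config("counts must be positive and n_modified <= n_items")
  }
  if (is.null(archetypes)) {
    n_inapp <- min(15, n_items)
    archetypes <- c(
      replicate(n_inapp, item_archetype("consensus", 2, 1), simplify = FALSE),
      replicate(n_items - n_inapp, item_archetype("consensus", 5, 1),
                simplify = FALSE)
    )
  }
  if (length(archetypes) != n_items) {
    abort_config("`archetypes` must supply one archetype per item")
  }
  ok <- vapply(archetypes, inherits, logical(1), "item_archetype")
  if (!all(ok)) abort_config("`archetypes` must be item_archetype objects")
  structure(list(n_panellists = as.integer(n_panellists),
                 n_items = as.integer(n_items),
                 n_modified = as.integer(n_modified),
                 attrition = attrition, feedback_shift = feedback_shift,
                 archetypes = archetypes, pole_assignment = pole_assignment,
                 skip_prob = skip_prob, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Archetypes are given as a list of mappings with the fields of
#' [item_archetype()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `simulation_config` object.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(vals$archetypes)) {
    vals$archetypes <- lapply(vals$archetypes, function(a) {
      do.call(item_archetype, a)
    })
  }
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort_config(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(simulation_config, vals)
}

# sub-seed derivation: one deterministic stream per (item, round) plus a
# study-level stream, so adding items never perturbs existing items' draws
sub_seed <- function(seed, item_index, round) {
  (abs(seed) + 1000003 * item_index + 7919 * round) %% .Machine$integer.max
}

#' Simulate a two-round rating study
#'
#' Round-1 ratings are drawn per item archetype for the full panel. A
#' study-level attrition draw then removes each panellist independently
#' with probability `attrition`; the retained roster re-rates every
#' round-1 item and additionally rates the reworded child items. Round-2
#' ratings are fresh archetype draws, after which each rating moves one
#' scale step toward the (parent) item's round-1 median with probability
#' `feedback_shift`, never crossing it.
#'
#' @param config A [simulation_config()].
#' @return A [rating_study()] with rounds 1 and 2, lineage rows for the
#'   reworded items, and an `items` table carrying each item's archetype
#'   kind.
#' @export
#' @examples
#' study <- simulate_study(simulation_config(seed = 42))
#' study
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- sprintf("i%02d", seq_len(config$n_items))
  panellists <- sprintf("p%02d", seq_len(config$n_panellists))

  # study-level stream: attrition and per-record skips
  set.seed(config$seed %% .Machine$integer.max)
  retained <- panellists[runif(config$n_panellists) >= config$attrition]
  if (length(retained) == 0) retained <- panellists[1]  # a panel cannot vanish

  round1 <- list()
  medians <- numeric(config$n_items)
  for (j in seq_len(config$n_items)) {
    set.seed(sub_seed(config$seed, j, 1))
    r <- draw_ratings(config$n_panellists, config$archetypes[[j]],
                      config$pole_assignment)
    medians[j] <- median(as.numeric(r))
    round1[[j]] <- tibble::tibble(panellist_id = panellists, round = 1L,
                                  item_id = ids[j],
                                  dimension = "appropriateness", rating = r)
  }

  shift_toward <- function(r, target, p) {
    move <- runif(length(r)) < p & abs(r - target) >= 1
    as.integer(r + move * sign(target - r))
  }

  round2 <- list()
  n2 <- length(retained)
  for (j in seq_len(config$n_items)) {
    set.seed(sub_seed(config$seed, j, 2))
    r <- draw_ratings(n2, config$archetypes[[j]], config$pole_assignment)
    r <- shift_toward(r, medians[j], config$feedback_shift)
    round2[[j]] <- tibble::tibble(panellist_id = retained, round = 2L,
                                  item_id = ids[j],
                                  dimension = "appropriateness", rating = r)
  }

  mod_parents <- seq_len(config$n_modified)
  mod_ids <- sprintf("%sm", ids[mod_parents])
  for (k in seq_along(mod_parents)) {
    j <- mod_parents[k]
    set.seed(sub_seed(config$seed, config$n_items + k, 2))
    r <- draw_ratings(n2, config$archetypes[[j]], config$pole_assignment)
    r <- shift_toward(r, medians[j], config$feedback_shift)
    round2[[config$n_items + k]] <-
      tibble::tibble(panellist_id = retained, round = 2L,
                     item_id = mod_ids[k],
                     dimension = "appropriateness", rating = r)
  }

  records <- dplyr::bind_rows(c(round1, round2))
  if (config$skip_prob > 0) {
    set.seed(sub_seed(config$seed, 0, 3))
    keep <- runif(nrow(records)) >= config$skip_prob
    # never let an item lose its whole panel
    records <- records[keep | !duplicated(records$item_id), , drop = FALSE]
  }

  all_ids <- c(ids, mod_ids)
  items <- tibble::tibble(
    item_id = all_ids,
    archetype = vapply(c(seq_len(config$n_items), mod_parents),
                       function(j) config$archetypes[[j]]$kind, character(1))
  )
  lineage <- if (length(mod_ids)) {
    tibble::tibble(child_id = mod_ids, parent_id = ids[mod_parents],
                   relation = "modified")
  } else {
    NULL
  }
  rating_study(records, items = items, lineage = lineage)
}

#' Operating characteristics of the consensus criteria by simulation
#'
#' For each archetype x panel-size cell, repeatedly simulates a single-item
#' panel, runs the full summary + classification pipeline and tallies how
#' often the panel reaches agreement, how often the classification matches
#' the archetype's built-in truth (its band for consensus archetypes,
#' "disagreement" for polarized/uniform ones), and the mean disagreement
#' index. Common random numbers across panel sizes: cell seeds depend only
#' on the archetype index, the replicate and the seed, so accuracy
#' comparisons across `n` are positively correlated.
#'
#' @param archetypes List of [item_archetype()]s.
#' @param n_panellists Integer vector of panel sizes.
#' @param replicates Replicates per cell (>= 1).
#' @param config A [consensus_config()].
#' @param pole_assignment `"fixed"` or `"random"` pole allocation for
#'   polarized archetypes; see [simulation_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per cell: archetype descriptors, `n`,
#'   `replicates`, `p_agreement`, `accuracy`, `mean_di`, and Monte-Carlo
#'   standard errors `se_agreement`, `se_accuracy`.
#' @export
recovery_experiment <- function(archetypes, n_panellists = c(12, 24),
                                replicates = 200,
                                config = consensus_config(),
                                pole_assignment = "fixed", seed = 1L) {
  if (length(archetypes) == 0) abort_config("`archetypes` must be non-empty")
  if (replicates < 1) abort_config("`replicates` must be >= 1")
  grid <- expand.grid(a = seq_along(archetypes), n = n_panellists)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    a <- archetypes[[grid$a[g]]]
    n <- grid$n[g]
    truth <- archetype_truth(a)
    agree <- logical(replicates)
    correct <- logical(replicates)
    dis <- numeric(replicates)
    for (r in seq_len(replicates)) {
      set.seed((abs(seed) + 7907 * grid$a[g] + 17 * r) %% .Machine$integer.max)
      ratings <- draw_ratings(n, a, pole_assignment)
      s <- summarize_item(ratings, config)
      cls <- classify(s$median, s$di, config)
      agree[r] <- cls$agreement == "agreement"
      correct[r] <- if (truth$agreement == "agreement") {
        cls$agreement == "agreement" && cls$band == truth$band
      } else {
        cls$agreement == "disagreement"
      }
      dis[r] <- s$di
    }
    p_a <- mean(agree)
    p_c <- mean(correct)
    tibble::tibble(
      kind = a$kind,
      location = ifelse(is.null(a$location), NA_real_, a$location),
      dispersion = ifelse(is.null(a$dispersion), NA_real_, a$dispersion),
      n = n, replicates = replicates,
      p_agreement = p_a, accuracy = p_c, mean_di = mean(dis),
      se_agreement = sqrt(p_a * (1 - p_a) / replicates),
      se_accuracy = sqrt(p_c * (1 - p_c) / replicates)
    )
  })
  dplyr::bind_rows(rows)
}
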