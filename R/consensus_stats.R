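#' Percentile of a panel's ratings
#'
#' @param scores Integer ratings in `[1, 9]`.
#' @param q Fraction in (0, 1).
#' @param method Interpolation method; see [consensus_config()].
#' @return A single numeric value within `[min(scores), max(scores)]`.
#' @export
#' @examples
#' percentile_score(1:9, 0.30) # 3.4 under the default linear rule
percentile_score <- function(scores, q, method = c("linear", "nearest", "weibull")) {
  method <- match.arg(method)
  check_ratings(scores)
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort_domain("`q` must be a single fraction strictly inside (0, 1)")
  }
  type <- switch(method, linear = 7, nearest = 1, weibull = 6)
  unname(quantile(as.numeric(scores), probs = q, type = type, names = FALSE))
}

# shared rating validation; empty input is its own condition class because
# an empty panel is a data problem, not a domain error
check_ratings <- function(scores) {
  if (length(scores) == 0 || all(is.na(scores))) abort_empty_panel()
  if (anyNA(scores)) abort_validation("ratings contain missing values")
  if (!is.numeric(scores) || any(scores != as.integer(scores))) {
    abort_validation("ratings must be integers")
  }
  if (any(scores < 1 | scores > 9)) {
    abort_validation("ratings must lie in [1, 9]")
  }
  invisible(scores)
}

#' Disagreement index from a pair of percentiles
#'
#' The RAND/UCLA disagreement index compares the panel's interpercentile
#' range (IPR) with the interpercentile range adjusted for symmetry (IPRAS):
#' \deqn{IPR = P_{hi} - P_{lo}, \quad IPRCP = (P_{lo} + P_{hi})/2,}
#' \deqn{AI = |5 - IPRCP|, \quad IPRAS = 2.35 + 1.5 \, AI, \quad DI = IPR / IPRAS.}
#' A panel whose ratings straddle the whole scale symmetrically
#' (\eqn{P_{lo} = 1, P_{hi} = 9}) has \eqn{DI = 8 / 2.35 \approx 3.40}; a
#' degenerate panel (\eqn{P_{lo} = P_{hi}}) has \eqn{DI = 0}.
#'
#' @param p_low,p_high Percentile values with `1 <= p_low <= p_high <= 9`.
#'   Vectorised over pairs.
#' @param config A [consensus_config()] supplying the IPRAS constants.
#' @return A tibble with columns `ipr`, `iprcp`, `ai`, `ipras`, `di`.
#' @export
#' @examples
#' disagreement_index(1, 9)  # di = 8 / 2.35
#' disagreement_index(2, 3)  # di ~ 0.164
disagreement_index <- function(p_low, p_high, config = consensus_config()) {
  if (length(p_low) != length(p_high)) {
    abort_domain("`p_low` and `p_high` must have equal length")
  }
  if (any(p_low < 1 | p_high > 9)) {
    abort_domain("percentiles must lie on the 1-9 rating scale")
  }
  if (any(p_low > p_high)) {
    abort_domain("`p_low` must not exceed `p_high`")
  }
  ipr <- p_high - p_low
  iprcp <- (p_low + p_high) / 2
  ai <- abs(config$scale_mid - iprcp)
  ipras <- config$ipras_intercept + config$ipras_slope * ai
  tibble::tibble(ipr = ipr, iprcp = iprcp, ai = ai, ipras = ipras,
                 di = ipr / ipras)
}

#' Summarise one item's ratings
#'
#' Computes the full per-item statistics block: rating count, median,
#' low/high percentiles, the disagreement-index components and the
#' low/middle/high bin counts.
#'
#' @param ratings Integer ratings in `[1, 9]` for one item, round and
#'   rating dimension.
#' @param config A [consensus_config()].
#' @return A one-row tibble with columns `n`, `median`, `p_low`, `p_high`,
#'   `ipr`, `iprcp`, `ai`, `ipras`, `di`, `n_low`, `n_mid`, `n_high`.
#' @export
#' @examples
#' summarize_item(c(rep(2, 18), 3))
summarize_item <- function(ratings, config = consensus_config()) {
  check_ratings(ratings)
  p_low <- percentile_score(ratings, config$q_low, config$method)
  p_high <- percentile_score(ratings, config$q_high, config$method)
  bins <- bin_counts(ratings)
  dplyr::bind_cols(
    tibble::tibble(n = length(ratings),
                   median = median(as.numeric(ratings)),
                   p_low = p_low, p_high = p_high),
    disagreement_index(p_low, p_high, config),
    tibble::tibble(n_low = bins[[1]], n_mid = bins[[2]], n_high = bins[[3]])
  )
}

#' Summarise every item of a rating study
#'
#' Applies [summarize_item()] to each item x round combination of one
#' rating dimension.
#'
#' @param study A [rating_study()].
#' @param dimension Rating dimension to summarise
#'   (`"appropriateness"` or `"feasibility"`).
#' @param config A [consensus_config()].
#' @return A tibble with one row per item x round, keyed by `item_id`,
#'   `round` and `dimension`, followed by the [summarize_item()] columns.
#' @export
summarize_items <- function(study, dimension = "appropriateness",
                            config = consensus_config()) {
  stopifnot(inherits(study, "rating_study"))
  recs <- dplyr::filter(study$records, .data$dimension == !!dimension)
  if (nrow(recs) == 0) {
    abort_empty_panel(paste0("no ratings for dimension '", dimension, "'"))
  }
  recs |>
    dplyr::group_by(.data$item_id, .data$round, .data$dimension) |>
    dplyr::reframe(summarize_item(.data$rating, config)) |>
    dplyr::arrange(.data$item_id, .data$round)
}

#' Classify a panel's verdict from its median and disagreement index
#'
#' Agreement is declared when the disagreement index falls below the
#' threshold; given agreement, the median places the item in the
#' inappropriate (1-3), equivocal (4-6) or appropriate (7-9) band. Labels
#' follow the field's shorthand: `"A/IA"` for agreement on
#' inappropriateness, `"Neutral"` for agreement on equivocality, `"A/A"`
#' for agreement on appropriateness and `"Disagreement"` otherwise.
#'
#' @param median Panel median(s) on the 1-9 scale.
#' @param di Disagreement index value(s).
#' @param config A [consensus_config()] supplying threshold and band edges.
#' @return A tibble with columns `agreement` (`"agreement"`/
#'   `"disagreement"`), `band` (`"inappropriate"`/`"equivocal"`/
#'   `"appropriate"`) and `label`.
#' @export
#' @examples
#' classify(2, 0.203)  # agreement on inappropriateness, "A/IA"
#' classify(5, 3.40)   # disagreement
classify <- function(median, di, config = consensus_config()) {
  if (length(median) != length(di)) {
    abort_domain("`median` and `di` must have equal length")
  }
  if (any(di < 0)) abort_domain("`di` must be non-negative")
  agreement <- ifelse(di < config$di_threshold, "agreement", "disagreement")
  band <- dplyr::case_when(
    median < config$band_edges[1] ~ "inappropriate",
    median > config$band_edges[2] ~ "appropriate",
    TRUE ~ "equivocal"
  )
  label <- dplyr::case_when(
    agreement == "disagreement" ~ "Disagreement",
    band == "inappropriate" ~ "A/IA",
    band == "appropriate" ~ "A/A",
    TRUE ~ "Neutral"
  )
  tibble::tibble(agreement = agreement, band = band, label = label)
}

#' Expand a printed verdict label into agreement and band
#'
#' The inverse of the label composition in [classify()]: useful when working
#' from a published summary table that prints only the composite label
#' ("A/IA", "Neutral", "A/A", "Disagreement").
#'
#' @param label Character vector of verdict labels.
#' @return A tibble with columns `agreement`, `band` (band is `NA` for
#'   disagreement labels) and `label`.
#' @export
#' @examples
#' label_classification(c("A/IA", "Neutral"))
label_classification <- function(label) {
  known <- c("A/IA", "Neutral", "A/A", "Disagreement")
  bad <- setdiff(unique(label), known)
  if (length(bad)) {
    abort_domain(paste0("unknown verdict label(s): ",
                        paste(bad, collapse = ", ")))
  }
  tibble::tibble(
    agreement = ifelse(label == "Disagreement", "disagreement", "agreement"),
    band = dplyr::case_when(
      label == "A/IA" ~ "inappropriate",
      label == "Neutral" ~ "equivocal",
      label == "A/A" ~ "appropriate",
      TRUE ~ NA_character_
    ),
    label = label
  )
}

#' Attach classifications to an item-summary table
#'
#' @param summaries A tibble with `median` and `di` columns, e.g. from
#'   [summarize_items()] or a published summary table.
#' @param config A [consensus_config()].
#' @return `summaries` with `agreement`, `band` and `label` columns added
#'   (existing columns of those names are replaced).
#' @export
classify_summaries <- function(summaries, config = consensus_config()) {
  if (!all(c("median", "di") %in% names(summaries))) {
    abort_schema("`summaries` must have `median` and `di` columns")
  }
  cls <- classify(summaries$median, summaries$di, config)
  summaries |>
    dplyr::select(-dplyr::any_of(c("agreement", "band", "label"))) |>
    dplyr::bind_cols(cls)
}
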