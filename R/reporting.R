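# display helpers ---------------------------------------------------------

# scores shown as integers, or with one decimal when they are not whole
format_score <- function(x) {
  ifelse(x == round(x), format(round(x)), format(round(x, 1), nsmall = 1))
}

# DI shown to 3 decimals; round() is round-half-to-even, matching the
# customary presentation
format_di <- function(x) format(round(x, 3), nsmall = 3)

md_grid <- function(df) {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) format(col) else as.character(col)
  }), check.names = FALSE, stringsAsFactors = FALSE)
  widths <- pmax(nchar(names(df)),
                 vapply(df, function(c) max(nchar(c), 0L), integer(1)))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste0("| ", paste(mapply(pad, names(df), widths), collapse = " | "), " |")
  rule <- paste0("|", paste(vapply(widths, function(w)
    paste0(strrep("-", w + 2)), character(1)), collapse = "|"), "|")
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(mapply(pad, unlist(df[i, ]), widths), collapse = " | "), " |")
  }, character(1))
  paste(c(header, rule, body), collapse = "\n")
}

# one item-round's display cells from a summary + classification row
report_cells <- function(row) {
  tibble::tibble(
    summary = sprintf("%s (%s, %s)", format_score(row$median),
                      format_score(row$p_low), format_score(row$p_high)),
    n_low = row$n_low, n_mid = row$n_mid, n_high = row$n_high,
    verdict = sprintf("%s (%s)", row$label, format_di(row$di))
  )
}

#' Render the per-item consensus report
#'
#' Produces the customary wide table: one row per item, the two rounds side
#' by side, each showing `median (p_low, p_high)`, the 1-3 / 4-6 / 7-9
#' rating counts and the verdict label with the disagreement index to three
#' decimals. Reworded/split children sort directly under their parent and
#' carry a convergence marker when an agreed-equivocal comparison state
#' became agreed-inappropriate.
#'
#' @param classified A tibble with `item_id`, `round`, `median`, `p_low`,
#'   `p_high`, `n_low`, `n_mid`, `n_high`, `di`, `label` (and optionally
#'   `scenario`) — i.e. [classify_summaries()] output.
#' @param lineage Optional lineage tibble; used for ordering and the
#'   convergence marker.
#' @param rounds The two rounds to juxtapose (default `c(1, 2)`).
#' @return A tibble, one row per item, with display columns
#'   `r<k>_summary`, `r<k>_1_3`, `r<k>_4_6`, `r<k>_7_9`, `r<k>_verdict`
#'   for each round plus `item_id`, `relation` and `converged`.
#' @export
render_item_table <- function(classified, lineage = NULL, rounds = c(1, 2)) {
  tt <- transition_table(classified, lineage,
                         round_before = rounds[1], round_after = rounds[2])
  comp <- tt$comparisons
  # parent-then-children ordering
  ord <- order(match(comp$parent_id, unique(comp$parent_id)),
               comp$relation != "identical" & comp$relation != "dropped",
               comp$item_id)
  comp <- comp[ord, , drop = FALSE]

  one_round <- function(id, round) {
    row <- classified[classified$item_id == id & classified$round == round, ,
                      drop = FALSE]
    if (nrow(row) == 0) {
      tibble::tibble(summary = "", n_low = NA_integer_, n_mid = NA_integer_,
                     n_high = NA_integer_, verdict = "")
    } else {
      report_cells(row[1, ])
    }
  }
  blocks <- lapply(seq_len(nrow(comp)), function(i) {
    id <- comp$item_id[i]
    # identical items show both rounds; children show only the later round
    first <- if (comp$relation[i] %in% c("identical", "dropped")) {
      one_round(id, rounds[1])
    } else {
      one_round(comp$parent_id[i], rounds[2])
    }
    second <- if (comp$relation[i] == "dropped") {
      one_round(id, NA)
    } else {
      one_round(id, rounds[2])
    }
    names(first) <- paste0("r", rounds[1], "_", names(first))
    names(second) <- paste0("r", rounds[2], "_", names(second))
    dplyr::bind_cols(
      tibble::tibble(item_id = id, relation = comp$relation[i]),
      first, second,
      tibble::tibble(converged = isTRUE(comp$converged[i]))
    )
  })
  out <- dplyr::bind_rows(blocks)
  if ("scenario" %in% names(classified)) {
    sc <- dplyr::distinct(classified, .data$item_id, .data$scenario)
    out <- dplyr::left_join(out, sc, by = "item_id") |>
      dplyr::relocate("scenario", .after = "item_id")
  }
  out
}

#' Render the category cross-tabulation
#'
#' Spreads [category_crosstab()] output into the customary wide shape: one
#' row per category, one agreed-inappropriate count column per round.
#'
#' @param crosstab Output of [category_crosstab()].
#' @return A tibble `category_id`, `category_label`, `n_items`, then one
#'   `round<k>_aia` column per round.
#' @export
render_crosstab <- function(crosstab) {
  if (nrow(crosstab) == 0) {
    return(tibble::tibble(category_id = character(),
                          category_label = character(),
                          n_items = integer()))
  }
  crosstab |>
    dplyr::group_by(.data$category_id, .data$category_label) |>
    dplyr::mutate(n_items = max(.data$n_items)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "round", values_from = "n_aia",
                       names_prefix = "round", values_fill = 0L) |>
    dplyr::rename_with(~ paste0(.x, "_aia"), dplyr::starts_with("round"))
}

#' Write a report table to disk
#'
#' @param table A data frame (e.g. from [render_item_table()]).
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"md"` (a Markdown grid).
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, format = c("csv", "tsv", "md")) {
  format <- match.arg(format)
  switch(format,
         csv = readr::write_csv(table, path, progress = FALSE),
         tsv = readr::write_tsv(table, path, progress = FALSE),
         md = writeLines(md_grid(table), path))
  invisible(path)
}
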