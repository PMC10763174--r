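#' Bundled example: opioid prescribing-safety e-Delphi round summaries
#'
#' Published per-item consensus summaries from a two-round e-Delphi study
#' in which a UK expert panel (24 panellists in round 1, 19 in round 2)
#' rated the appropriateness of 20 opioid prescribing scenarios on the 1-9
#' scale; 11 scenarios were reworded and one was split in two for a second
#' rating within round 2, giving 13 child items. The raw individual
#' ratings were not released, so the table carries the *printed* per-item
#' statistics: median, 30th/70th percentiles, 1-3/4-6/7-9 rating counts,
#' disagreement index and verdict label. Printed percentiles are rounded,
#' which is why recomputing a DI from them does not reproduce the printed
#' DI (e.g. rows printing percentiles "(2, 2)" carry DI 0.203, not 0).
#'
#' @return `opioid_delphi_summaries()`: a tibble with one row per
#'   item x round (`item_id`, `scenario`, `round`, `median`, `p_low`,
#'   `p_high`, `n_low`, `n_mid`, `n_high`, `di`, `label`).
#' @export
#' @examples
#' s <- opioid_delphi_summaries()
#' table(classify_summaries(s)$label, s$round)
opioid_delphi_summaries <- function() {
  path <- system.file("extdata", "opioid_round_summaries.csv",
                      package = "randelphi", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::rename(p_low = "p30", p_high = "p70")
}

#' @rdname opioid_delphi_summaries
#' @return `opioid_delphi_lineage()`: the lineage tibble linking the 13
#'   round-2 child items to their parents.
#' @export
opioid_delphi_lineage <- function() {
  read_lineage(system.file("extdata", "opioid_item_lineage.csv",
                           package = "randelphi", mustWork = TRUE))
}

#' @rdname opioid_delphi_summaries
#' @return `opioid_delphi_categories()`: the prescribing-problem category
#'   of every item (children inherit their parent's category).
#' @export
opioid_delphi_categories <- function() {
  read_categories(system.file("extdata", "opioid_item_categories.csv",
                              package = "randelphi", mustWork = TRUE))
}
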