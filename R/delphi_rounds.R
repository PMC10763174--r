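#' Band transitions between rounds and across rewordings
#'
#' Pairs every item of the later round with its comparison state and counts
#' the appropriateness-band transitions. Items rated unchanged in both
#' rounds ("identical", the default for items without a lineage entry) are
#' compared against their own earlier-round classification. Reworded
#' (`modified`) and `split` items exist only in the later round, so they
#' are compared against their parent's classification *in that same later
#' round*: that is the within-round effect of the rewording, separate from
#' the between-round feedback effect.
#'
#' An item is flagged `converged` when an agreed-equivocal comparison state
#' becomes agreed-inappropriate.
#'
#' @param classified A tibble with columns `item_id`, `round`, `median`,
#'   `di`, `agreement`, `band` (e.g. from [classify_summaries()]).
#' @param lineage Optional lineage tibble `(child_id, parent_id, relation)`;
#'   items absent from it are treated as identical to themselves.
#' @param round_before,round_after The two rounds to compare (defaults 1, 2).
#' @return A list of class `"transition_table"` with
#'   `comparisons` (one row per later-round item: `item_id`, `parent_id`,
#'   `relation`, `band_before`, `band_after`, `di_before`, `di_after`,
#'   `agreement_before`, `agreement_after`, `converged`) and `counts`
#'   (band-before x band-after contingency matrix over resolvable pairs,
#'   plus items of the earlier round that were dropped without successor
#'   appearing with `NA` transition in `comparisons` only).
#' @export
transition_table <- function(classified, lineage = NULL,
                             round_before = 1, round_after = 2) {
  need <- c("item_id", "round", "di", "agreement", "band")
  if (!all(need %in% names(classified))) {
    abort_schema(paste0("`classified` must have columns: ",
                        paste(need, collapse = ", ")))
  }
  lineage <- validate_lineage(lineage, unique(classified$item_id))
  before <- dplyr::filter(classified, .data$round == round_before)
  after <- dplyr::filter(classified, .data$round == round_after)
  if (nrow(after) == 0) abort_empty_panel("no classifications in the later round")

  lookup <- function(tab, id) tab[tab$item_id == id, , drop = FALSE]

  rows <- lapply(seq_len(nrow(after)), function(i) {
    id <- after$item_id[i]
    lin <- lineage[lineage$child_id == id, , drop = FALSE]
    if (nrow(lin) && lin$relation != "identical") {
      parent <- lin$parent_id
      relation <- lin$relation
      # reworded/split: the comparison state is the parent in the same round
      ref <- lookup(after, parent)
      if (nrow(ref) == 0) ref <- lookup(before, parent)
    } else {
      parent <- id
      relation <- "identical"
      ref <- lookup(before, id)
    }
    if (nrow(ref) == 0) {
      if (relation == "identical") {
        # genuinely new item with no declared parent: not linkable
        abort_linkage(paste0("item '", id, "' in round ", round_after,
                             " has no round-", round_before,
                             " counterpart and no lineage entry"))
      }
      abort_linkage(paste0("parent '", parent, "' of item '", id,
                           "' has no classification to compare against"))
    }
    tibble::tibble(
      item_id = id, parent_id = parent, relation = relation,
      band_before = ref$band[1], band_after = after$band[i],
      di_before = ref$di[1], di_after = after$di[i],
      agreement_before = ref$agreement[1], agreement_after = after$agreement[i],
      converged = ref$agreement[1] == "agreement" &&
        after$agreement[i] == "agreement" &&
        ref$band[1] == "equivocal" && after$band[i] == "inappropriate"
    )
  })
  comparisons <- dplyr::bind_rows(rows)

  # earlier-round items that were dropped (no identical successor, no child)
  succeeded <- unique(c(
    comparisons$item_id[comparisons$relation == "identical"],
    comparisons$parent_id
  ))
  dropped <- setdiff(before$item_id, succeeded)
  if (length(dropped)) {
    comparisons <- dplyr::bind_rows(
      comparisons,
      dplyr::tibble(item_id = dropped, parent_id = dropped,
                    relation = "dropped",
                    band_before = before$band[match(dropped, before$item_id)],
                    band_after = NA_character_,
                    di_before = before$di[match(dropped, before$item_id)],
                    di_after = NA_real_,
                    agreement_before =
                      before$agreement[match(dropped, before$item_id)],
                    agreement_after = NA_character_, converged = NA)
    )
  }

  bands <- c("inappropriate", "equivocal", "appropriate")
  linked <- comparisons[!is.na(comparisons$band_after), , drop = FALSE]
  counts <- table(factor(linked$band_before, levels = bands),
                  factor(linked$band_after, levels = bands))
  names(dimnames(counts)) <- c("before", "after")

  structure(list(comparisons = comparisons, counts = unclass(counts)),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("<transition_table>\n")
  print(x$counts)
  nconv <- sum(x$comparisons$converged, na.rm = TRUE)
  cat(sprintf("  %d item(s) converged from agreed-equivocal to agreed-inappropriate\n",
              nconv))
  invisible(x)
}

#' Cross-tabulate agreed-inappropriate items by problem category
#'
#' Counts, per prescribing-problem category and per round, the items the
#' panel agreed were inappropriate (agreement with an inappropriate-band
#' median, the "A/IA" verdict).
#'
#' @param classified A tibble with columns `item_id`, `round`, `agreement`,
#'   `band`.
#' @param category_map A tibble `(item_id, category_id, category_label)`;
#'   every classified item must appear exactly once.
#' @return A tibble with one row per category x round: `category_id`,
#'   `category_label`, `n_items` (items of that category rated in that
#'   round) and `n_aia` (agreed-inappropriate count). Categories with no
#'   rated items in a round get a zero row only if they appear in
#'   `category_map` for rated items; wholly unrated categories are absent.
#' @export
category_crosstab <- function(classified, category_map) {
  need <- c("item_id", "round", "agreement", "band")
  if (!all(need %in% names(classified))) {
    abort_schema(paste0("`classified` must have columns: ",
                        paste(need, collapse = ", ")))
  }
  if (anyDuplicated(category_map$item_id)) {
    abort_validation("each item must have exactly one category")
  }
  unmapped <- setdiff(classified$item_id, category_map$item_id)
  if (length(unmapped)) {
    abort_mapping(paste0("item(s) missing from the category map: ",
                         paste(unmapped, collapse = ", ")))
  }
  classified |>
    dplyr::inner_join(category_map, by = "item_id") |>
    dplyr::group_by(.data$category_id, .data$category_label, .data$round) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      n_aia = sum(.data$agreement == "agreement" &
                    .data$band == "inappropriate"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category_id, .data$round)
}
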