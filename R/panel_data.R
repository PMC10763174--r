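#' Construct a multi-round rating study
#'
#' The central container: long-format rating records (one row per panellist
#' x item x round x dimension), an item table, an optional lineage table
#' linking later-round items to their parents, and the per-round panellist
#' roster derived from the records.
#'
#' @param records A data frame with columns `panellist_id`, `round`,
#'   `item_id`, `dimension`, `rating`. Ratings must be integers in `[1, 9]`
#'   and `(panellist_id, round, item_id, dimension)` must be unique.
#'   Missing ratings are simply absent rows; no imputation is performed.
#' @param items Optional data frame `(item_id, scenario, category_id)`
#'   describing the items; defaults to the distinct item ids in `records`.
#' @param lineage Optional data frame `(child_id, parent_id, relation)`
#'   with relation one of `"identical"`, `"modified"`, `"split"`.
#' @param allow_late_joiners If `FALSE` (default), a panellist first
#'   appearing after round 1 is a validation error.
#' @return An object of class `"rating_study"`: a list with elements
#'   `records`, `items`, `lineage`, `panellists` (tibble of
#'   `round`, `panellist_id`).
#' @export
#' @examples
#' recs <- data.frame(panellist_id = c("p1", "p2", "p3"), round = 1,
#'                    item_id = "A", dimension = "appropriateness",
#'                    rating = c(2, 2, 3))
#' rating_study(recs)
rating_study <- function(records, items = NULL, lineage = NULL,
                         allow_late_joiners = FALSE) {
  records <- tibble::as_tibble(records)
  required <- c("panellist_id", "round", "item_id", "dimension", "rating")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    abort_schema(paste0("records are missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) abort_empty_panel("a study needs at least one rating")
  records$panellist_id <- as.character(records$panellist_id)
  records$item_id <- as.character(records$item_id)
  records$dimension <- as.character(records$dimension)
  bad_dim <- setdiff(unique(records$dimension),
                     c("appropriateness", "feasibility"))
  if (length(bad_dim)) {
    abort_validation(paste0("unknown rating dimension(s): ",
                            paste(bad_dim, collapse = ", ")))
  }
  if (anyNA(records$round) || any(records$round != as.integer(records$round)) ||
      any(records$round < 1)) {
    abort_validation("`round` must be a positive integer")
  }
  records$round <- as.integer(records$round)

  bad <- which(is.na(records$rating) | records$rating != floor(records$rating) |
                 records$rating < 1 | records$rating > 9)
  if (length(bad)) {
    abort_validation(paste0(
      "rating out of range or non-integer in row(s): ",
      paste(utils::head(bad, 10), collapse = ", ")))
  }
  records$rating <- as.integer(records$rating)
  # canonical column order; drops any extraneous columns/attributes so a
  # study round-trips through write -> read unchanged
  records <- tibble::tibble(panellist_id = records$panellist_id,
                            round = records$round,
                            item_id = records$item_id,
                            dimension = records$dimension,
                            rating = records$rating)

  key <- paste(records$panellist_id, records$round, records$item_id,
               records$dimension, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(key %in% key[duplicated(key)])
    abort_validation(paste0(
      "duplicate (panellist, round, item, dimension) key in rows: ",
      paste(utils::head(d, 10), collapse = ", ")))
  }

  if (is.null(items)) {
    items <- tibble::tibble(item_id = sort(unique(records$item_id)))
  } else {
    items <- tibble::as_tibble(items)
    if (!"item_id" %in% names(items)) abort_schema("`items` needs an `item_id` column")
    items$item_id <- as.character(items$item_id)
    orphan <- setdiff(records$item_id, items$item_id)
    if (length(orphan)) {
      abort_validation(paste0("records reference unknown item(s): ",
                              paste(orphan, collapse = ", ")))
    }
  }

  lineage <- validate_lineage(lineage, items$item_id)

  panellists <- records |>
    dplyr::distinct(.data$round, .data$panellist_id) |>
    dplyr::arrange(.data$round, .data$panellist_id)
  if (!allow_late_joiners) {
    rounds <- sort(unique(panellists$round))
    for (i in seq_along(rounds)[-1]) {
      prev <- panellists$panellist_id[panellists$round == rounds[i - 1]]
      cur <- panellists$panellist_id[panellists$round == rounds[i]]
      late <- setdiff(cur, prev)
      if (length(late)) {
        abort_validation(paste0(
          "panellist(s) first appear in round ", rounds[i],
          " (late joiners are not allowed): ", paste(late, collapse = ", ")))
      }
    }
  }

  structure(list(records = records, items = items, lineage = lineage,
                 panellists = panellists),
            class = "rating_study")
}

validate_lineage <- function(lineage, known_items) {
  if (is.null(lineage)) {
    return(tibble::tibble(child_id = character(), parent_id = character(),
                          relation = character()))
  }
  lineage <- tibble::as_tibble(lineage)
  need <- c("child_id", "parent_id", "relation")
  if (!all(need %in% names(lineage))) {
    abort_schema("lineage needs columns child_id, parent_id, relation")
  }
  lineage <- dplyr::mutate(lineage, dplyr::across(dplyr::all_of(need), as.character))
  bad_rel <- setdiff(unique(lineage$relation), c("identical", "modified", "split"))
  if (length(bad_rel)) {
    abort_validation(paste0("unknown lineage relation(s): ",
                            paste(bad_rel, collapse = ", ")))
  }
  if (anyDuplicated(lineage$child_id)) {
    abort_validation("each child item must have exactly one parent")
  }
  self_loop <- lineage$child_id == lineage$parent_id & lineage$relation != "identical"
  if (any(self_loop)) {
    abort_validation("modified/split items cannot be their own parent")
  }
  # split implies >= 2 children sharing the parent
  sp <- lineage[lineage$relation == "split", ]
  if (nrow(sp)) {
    narrow <- table(sp$parent_id)
    if (any(narrow < 2)) {
      abort_validation("a 'split' parent must have at least two split children")
    }
  }
  # acyclicity: walking child -> parent must terminate
  parent_of <- setNames(lineage$parent_id, lineage$child_id)
  for (start in lineage$child_id) {
    seen <- character()
    node <- start
    while (node %in% names(parent_of) && parent_of[[node]] != node) {
      if (node %in% seen) abort_validation("lineage graph contains a cycle")
      seen <- c(seen, node)
      node <- parent_of[[node]]
    }
  }
  lineage
}

#' @export
print.rating_study <- function(x, ...) {
  cat("<rating_study>\n")
  per_round <- dplyr::count(x$panellists, .data$round)
  cat(sprintf("  %d ratings, %d items, %d round(s)\n",
              nrow(x$records), nrow(x$items), nrow(per_round)))
  for (i in seq_len(nrow(per_round))) {
    cat(sprintf("  round %d: %d panellists\n",
                per_round$round[i], per_round$n[i]))
  }
  if (nrow(x$lineage)) {
    cat(sprintf("  lineage: %d linked item(s)\n", nrow(x$lineage)))
  }
  invisible(x)
}

#' Read long-format ratings from a delimited text file
#'
#' CSV or TSV is auto-detected from the file extension. Column names can be
#' remapped through `schema`; a missing `dimension` column defaults every
#' row to `"appropriateness"`.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (`panellist_id`, `round`, `item_id`, `dimension`, `rating`) to
#'   the names used in the file, e.g. `c(rating = "score")`.
#' @param ... Passed on to [rating_study()] (e.g. `items`, `lineage`).
#' @return A [rating_study()].
#' @export
read_ratings <- function(path, schema = NULL, ...) {
  if (!file.exists(path)) abort_schema(paste0("ratings file not found: ", path))
  reader <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  canonical <- c("panellist_id", "round", "item_id", "dimension", "rating")
  lookup <- setNames(canonical, canonical)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), canonical)
    if (length(bad)) {
      abort_schema(paste0("schema maps unknown column(s): ",
                          paste(bad, collapse = ", ")))
    }
    lookup[names(schema)] <- unname(schema)
  }
  for (canon in setdiff(canonical, "dimension")) {
    if (!lookup[[canon]] %in% names(raw)) {
      abort_schema(paste0("required column '", lookup[[canon]],
                          "' (for ", canon, ") not found in ", path))
    }
  }
  recs <- tibble::tibble(
    panellist_id = raw[[lookup[["panellist_id"]]]],
    round = raw[[lookup[["round"]]]],
    item_id = raw[[lookup[["item_id"]]]],
    dimension = if (lookup[["dimension"]] %in% names(raw)) {
      raw[[lookup[["dimension"]]]]
    } else {
      "appropriateness"
    },
    rating = raw[[lookup[["rating"]]]]
  )
  rating_study(recs, ...)
}

#' Write a rating study's records to delimited text
#'
#' The inverse of [read_ratings()]: a study written and re-read yields
#' identical records.
#'
#' @param study A [rating_study()].
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(study, path) {
  stopifnot(inherits(study, "rating_study"))
  writer <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv
  } else {
    readr::write_csv
  }
  writer(study$records, path, progress = FALSE)
  invisible(path)
}

#' Read an item-lineage table
#'
#' @param path CSV with columns `child_id`, `parent_id`, `relation`.
#' @return A validated lineage tibble.
#' @export
read_lineage <- function(path) {
  if (!file.exists(path)) abort_schema(paste0("lineage file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_lineage(tab, unique(c(tab$child_id, tab$parent_id)))
}

#' Read an item-category map
#'
#' @param path CSV with columns `item_id`, `category_id`, `category_label`.
#' @return A tibble with one row per item.
#' @export
read_categories <- function(path) {
  if (!file.exists(path)) abort_schema(paste0("category file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("item_id", "category_id")
  if (!all(need %in% names(tab))) {
    abort_schema("category map needs columns item_id, category_id")
  }
  if (anyDuplicated(tab$item_id)) {
    abort_validation("each item must have exactly one category")
  }
  if (!"category_label" %in% names(tab)) tab$category_label <- tab$category_id
  tibble::as_tibble(tab)
}

#' Count ratings in the low, middle and high thirds of the scale
#'
#' @param ratings Integer ratings in `[1, 9]`.
#' @return A named integer vector `c("1-3", "4-6", "7-9")` summing to
#'   `length(ratings)`.
#' @export
#' @examples
#' bin_counts(c(rep(2, 23), 8)) # 23, 0, 1
bin_counts <- function(ratings) {
  check_ratings(ratings)
  c("1-3" = sum(ratings <= 3),
    "4-6" = sum(ratings >= 4 & ratings <= 6),
    "7-9" = sum(ratings >= 7))
}
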