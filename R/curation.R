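#' Label bioassay records as active or inactive
#'
#' Applies the high-throughput dose-response labeling rules to raw bioassay
#' records: a compound is *active* when its curve class is the full
#' high-efficacy inhibition code (default `-1.1`) **and** its efficacy is at
#' least `efficacy_min` percent of control; *inactive* when the curve class
#' is the inactivity code (default `4.0`). Every other curve class is
#' inconclusive and excluded. Structures are parsed and desalted on the way
#' in; unparsable rows, rows with a missing curve class, inorganic entries
#' and fragmented entries (two or more organic fragments) are removed with a
#' logged reason.
#'
#' The observed potency range of the actives is recorded as metadata (it is
#' not a filter; labeling is by curve class alone).
#'
#' @param records A data frame with columns `compound_id`, `smiles`,
#'   `curve_class`, `efficacy` and optionally `potency`.
#' @param efficacy_min Minimum percent-of-control efficacy for an active
#'   (default 80).
#' @param active_class,inactive_class Curve-class codes retained as active
#'   and inactive.
#' @return A tibble of labeled compounds (`label` is a factor
#'   `active`/`inactive`) carrying canonical desalted structures and a
#'   `source_record_ids` column. Removed rows, with reasons, are attached as
#'   attribute `"removed"`; per-reason counts as attribute `"curation_log"`.
#' @export
label_records <- function(records, efficacy_min = 80,
                          active_class = -1.1, inactive_class = 4.0) {
  needed <- c("compound_id", "smiles", "curve_class")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    cyp_abort(paste("records lack columns:", paste(missing_cols, collapse = ", ")),
              class = "cyp_curation_error")
  }
  if (!"efficacy" %in% names(records)) records$efficacy <- NA_real_
  x <- records |>
    parse_smiles() |>
    desalt()

  reason <- rep(NA_character_, nrow(x))
  reason[is.na(x$curve_class)] <- "missing curve class"
  reason[is.na(reason) & !is.na(x$parse_error)] <- "unparsable structure"
  reason[is.na(reason) & !is.na(x$desalt_error)] <- "inorganic"
  reason[is.na(reason) & x$n_organic_fragments > 1] <- "fragmented"

  is_active <- is.na(reason) & x$curve_class == active_class &
    !is.na(x$efficacy) & x$efficacy >= efficacy_min
  is_inactive <- is.na(reason) & x$curve_class == inactive_class
  reason[is.na(reason) & !is_active & !is_inactive] <- "inconclusive"

  keep <- is.na(reason)
  out <- x[keep, , drop = FALSE] |>
    dplyr::mutate(
      label = factor(ifelse(is_active[keep], "active", "inactive"),
                     levels = c("active", "inactive")),
      source_record_ids = as.character(.data$compound_id)
    )
  removed <- dplyr::mutate(x[!keep, , drop = FALSE], reason = reason[!keep])
  log <- dplyr::count(removed, .data$reason, name = "n")
  pot <- out$potency[out$label == "active"] %||% numeric(0)
  attr(out, "removed") <- removed
  attr(out, "curation_log") <- log
  attr(out, "potency_range") <- if (any(!is.na(pot))) range(pot, na.rm = TRUE) else NULL
  out
}

#' Resolve duplicate structures
#'
#' Duplicates are rows sharing a canonical desalted structure. Same-label
#' duplicates collapse to one entry (keeping the lexicographically smallest
#' source id and recording all contributing ids); duplicates carrying
#' conflicting labels are removed entirely.
#'
#' @param candidates Output of [label_records()] (needs `smiles_canonical`,
#'   `label`, `compound_id`).
#' @return A deduplicated tibble; one row per unique canonical structure.
#'   Structures dropped for label conflicts are attached as attribute
#'   `"conflicted"`.
#' @export
resolve_duplicates <- function(candidates) {
  stopifnot(all(c("smiles_canonical", "label", "compound_id") %in% names(candidates)))
  x <- as_tibble(candidates)
  grp <- dplyr::group_by(x, .data$smiles_canonical)
  n_labels <- dplyr::summarise(grp, nl = dplyr::n_distinct(.data$label))
  conflicted <- n_labels$smiles_canonical[n_labels$nl > 1]
  x <- x[!x$smiles_canonical %in% conflicted, , drop = FALSE]
  out <- x |>
    dplyr::group_by(.data$smiles_canonical) |>
    dplyr::arrange(.data$compound_id, .by_group = TRUE) |>
    dplyr::mutate(
      source_record_ids = paste(sort(unique(.data$compound_id)), collapse = ";")
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$compound_id)
  attr(out, "conflicted") <- conflicted
  out
}

#' Stratified train/validation split
#'
#' Splits a labeled dataset into training and validation subsets while
#' keeping the active:inactive ratio constant. Per class, rows are shuffled
#' under `seed` and the first `round_half_up(fraction_train * class size)`
#' go to training (remainders favour training). Fully reproducible: the same
#' seed yields the same membership.
#'
#' @param data A labeled tibble (any columns; `label` must have two levels
#'   present, each with at least 2 members).
#' @param fraction_train Fraction assigned to training (default 0.75); must
#'   leave a non-empty validation set.
#' @param seed Integer seed for the per-class shuffles.
#' @param label Column holding the class label.
#' @return `data` with a `split` column (`"train"`/`"validation"`); the seed
#'   and fraction are attached as attributes.
#' @export
stratified_split <- function(data, fraction_train = 0.75, seed = 1,
                             label = label) {
  lab <- as.character(dplyr::pull(data, {{ label }}))
  classes <- unique(lab)
  if (length(classes) < 2) split_error("both classes must be present to split")
  if (any(table(lab) < 2)) split_error("every class needs at least 2 members")
  if (fraction_train <= 0 || fraction_train >= 1) {
    split_error("fraction_train must lie strictly between 0 and 1")
  }
  n_train <- floor(fraction_train * table(lab) + 0.5) # round half up
  if (any(n_train == table(lab))) {
    split_error("fraction_train leaves an empty validation class")
  }
  split <- character(length(lab))
  set.seed(seed)
  for (cl in sort(classes)) {
    ix <- which(lab == cl)
    tr <- sample(ix, n_train[[cl]])
    split[tr] <- "train"
    split[setdiff(ix, tr)] <- "validation"
  }
  out <- dplyr::mutate(as_tibble(data), split = split)
  attr(out, "seed") <- seed
  attr(out, "fraction_train") <- fraction_train
  out
}

#' Curate a screening library
#'
#' Prepares a raw compound library for virtual screening: structures are
#' parsed and desalted; unparsable rows, inorganic entries and fragmented
#' entries (>= 2 organic fragments) are removed; duplicate canonical
#' structures collapse to the row with the smallest id; entries matching the
#' exclusion list are removed. Counts for every removal reason are logged.
#'
#' @param compounds A data frame with `compound_id` and `smiles` columns
#'   (other columns pass through).
#' @param exclusion Optional exclusion list: a data frame with a `smiles`
#'   and/or `compound_id` column. Matching is by canonical desalted
#'   structure or by id. Default `NULL` (empty list; the curated exclusion
#'   of e.g. pesticides and drugs is supplied by the user).
#' @return The curated tibble; removed rows with reasons as attribute
#'   `"removed"`, per-reason counts as attribute `"curation_log"`.
#' @export
curate_library <- function(compounds, exclusion = NULL) {
  x <- compounds |>
    parse_smiles() |>
    desalt()
  reason <- rep(NA_character_, nrow(x))
  reason[!is.na(x$parse_error)] <- "unparsable structure"
  reason[is.na(reason) & !is.na(x$desalt_error)] <- "inorganic"
  reason[is.na(reason) & x$n_organic_fragments > 1] <- "fragmented"

  ex <- canonical_exclusion(exclusion)
  excl_smiles <- ex$smiles; excl_ids <- ex$ids
  reason[is.na(reason) &
           (x$smiles_canonical %in% excl_smiles |
              as.character(x$compound_id) %in% excl_ids)] <- "exclusion list"

  # deterministic duplicate survivor: smallest id per canonical structure
  ord <- order(as.character(x$compound_id))
  dup <- rep(FALSE, nrow(x))
  seen <- new.env(parent = emptyenv())
  for (i in ord) {
    if (!is.na(reason[i])) next
    key <- x$smiles_canonical[i]
    if (is.na(key)) next
    if (!is.null(seen[[key]])) dup[i] <- TRUE else seen[[key]] <- TRUE
  }
  reason[dup] <- "duplicate structure"

  keep <- is.na(reason)
  out <- as_tibble(x[keep, , drop = FALSE])
  removed <- dplyr::mutate(x[!keep, , drop = FALSE], reason = reason[!keep])
  attr(out, "removed") <- removed
  attr(out, "curation_log") <- dplyr::count(removed, .data$reason, name = "n")
  out
}

# Canonical structures and ids named by an exclusion list (either or both of
# a `smiles` and a `compound_id` column may be present).
canonical_exclusion <- function(exclusion) {
  out <- list(smiles = character(0), ids = character(0))
  if (is.null(exclusion) || !nrow(exclusion)) return(out)
  if ("smiles" %in% names(exclusion)) {
    ex <- exclusion
    if (!"compound_id" %in% names(ex)) {
      ex$compound_id <- sprintf("excl%04d", seq_len(nrow(ex)))
    }
    ex <- ex |> parse_smiles() |> desalt()
    out$smiles <- ex$smiles_canonical[!is.na(ex$smiles_canonical)]
  }
  if ("compound_id" %in% names(exclusion)) {
    out$ids <- as.character(exclusion$compound_id)
  }
  out
}

#' Removed rows from a curation step
#'
#' @param x A tibble returned by [label_records()] or [curate_library()].
#' @return The tibble of removed rows with their `reason` column.
#' @export
removed_compounds <- function(x) attr(x, "removed") %||% tibble()

#' @rdname removed_compounds
#' @export
curation_log <- function(x) attr(x, "curation_log") %||% tibble()
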