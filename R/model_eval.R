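#' Confusion counts at a threshold
#'
#' Counts true/false positives and negatives for a vector of prediction
#' indices against known labels, using the inclusive `>=` threshold rule of
#' [classify_index()].
#'
#' @param truth Known labels: factor/character `"active"`/`"inactive"` or
#'   logical (TRUE = active).
#' @param index Numeric prediction indices, aligned with `truth`.
#' @param threshold Decision threshold (default 0.7).
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, index, threshold = 0.7) {
  if (!length(truth)) eval_error("empty input")
  if (length(truth) != length(index)) {
    eval_error("truth and index must have the same length")
  }
  pos <- if (is.logical(truth)) truth else as.character(truth) == "active"
  pred <- index >= threshold
  tibble(
    tp = sum(pos & pred), fp = sum(!pos & pred),
    tn = sum(!pos & !pred), fn = sum(pos & !pred)
  )
}

#' Screening performance metrics
#'
#' Standard confusion-matrix metrics for a virtual screen:
#' \deqn{SE = TP/(TP+FN), \quad SP = TN/(TN+FP)}
#' \deqn{EF = \frac{TP/(TP+FP)}{(TP+FN)/N}, \quad
#'       MCC = \frac{TP \cdot TN - FP \cdot FN}
#'                  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' The enrichment factor is precision over active prevalence: how many times
#' better the hit list is than picking at random. Metrics with a zero
#' denominator are reported as `NA` and named in the `undefined` column,
#' except MCC which is 0 by convention for degenerate margins.
#'
#' @param counts A one-row tibble/list with `tp`, `fp`, `tn`, `fn`
#'   (e.g. from [confusion_counts()]).
#' @return A one-row tibble with `se`, `sp`, `ef`, `mcc`, `n` and
#'   `undefined` (comma-separated names of undefined metrics, or `NA`).
#' @examples
#' screen_metrics(confusion_counts(c(TRUE, TRUE, FALSE, FALSE),
#'                                 c(0.9, 0.2, 0.1, 0.8)))
#' @export
screen_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (any(is.na(c(tp, fp, tn, fn))) || any(c(tp, fp, tn, fn) < 0)) {
    eval_error("counts must be non-negative numbers")
  }
  n <- tp + fp + tn + fn
  undef <- character(0)
  se <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "se"); NA_real_ }
  sp <- if (tn + fp > 0) tn / (tn + fp) else { undef <- c(undef, "sp"); NA_real_ }
  ef <- if (tp + fp > 0 && tp + fn > 0 && n > 0) {
    (tp / (tp + fp)) / ((tp + fn) / n)
  } else { undef <- c(undef, "ef"); NA_real_ }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  tibble(se = se, sp = sp, ef = ef, mcc = mcc, n = n,
         undefined = if (length(undef)) paste(undef, collapse = ",") else NA_character_)
}

#' Rank-based ROC AUC
#'
#' The area under the receiver operating characteristic curve computed as
#' the normalised Mann--Whitney statistic, with ties handled by midranks.
#' Invariant under any strictly monotone transform of the indices.
#'
#' @inheritParams confusion_counts
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(truth, index) {
  if (length(truth) != length(index)) {
    eval_error("truth and index must have the same length")
  }
  pos <- if (is.logical(truth)) truth else as.character(truth) == "active"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) eval_error("both classes must be present for AUC")
  r <- rank(index) # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams confusion_counts
#' @return A tibble of (`fpr`, `tpr`, `threshold`) points sweeping the
#'   observed index values.
#' @export
roc_points <- function(truth, index) {
  pos <- if (is.logical(truth)) truth else as.character(truth) == "active"
  th <- c(Inf, sort(unique(index), decreasing = TRUE))
  purrr::map_dfr(th, function(t) {
    pred <- index >= t
    tibble(threshold = t,
           tpr = sum(pos & pred) / sum(pos),
           fpr = sum(!pos & pred) / sum(!pos))
  })
}

#' Literature-consistency TP/FP ratio of a hit list
#'
#' Compares a screened hit list against published potency annotations. A hit
#' is *confirmed* (TP) when its annotated IC50 is at or below
#' `potency_cutoff` (censored annotations like `"<10"` count when the bound
#' implies it), or when a supplied in-house assay result confirms it;
#' *refuted* (FP) when the annotated IC50 exceeds the cutoff. Unannotated
#' hits are ignored. Alternatively, a pre-recorded per-compound call column
#' (`"confirmed"`/`"refuted"`) can be supplied for compilations whose
#' classification is given directly.
#'
#' @param hits A data frame of hits.
#' @param ic50 Column with literature IC50 annotations (numeric, or
#'   character possibly carrying `<`/`>` qualifiers; `NA`/`"new"` =
#'   unannotated).
#' @param call Optional column with recorded calls `"confirmed"`/`"refuted"`
#'   that override the numeric rule where present.
#' @param potency_cutoff IC50 cutoff in uM separating a confirmed inhibitor
#'   from a refuted one (default 20).
#' @param assay Optional data frame of in-house assay results with columns
#'   `compound_id` (or `name`) and `ic50`; results at or below the cutoff
#'   add confirmations for matching hits.
#' @return A one-row tibble with `tp`, `fp`, `ratio` and `n_annotated`.
#'   `ratio` is `Inf` (flagged in `undefined`) when there are no refuted
#'   hits, and `NA` when nothing is annotated.
#' @export
literature_consistency <- function(hits, ic50 = lit_ic50, call = NULL,
                                   potency_cutoff = 20, assay = NULL) {
  ann <- dplyr::pull(hits, {{ ic50 }})
  parsed <- parse_ic50_annotation(ann)
  status <- rep(NA_character_, nrow(hits))
  # numeric rule with censoring: "<x" confirms if x <= cutoff, ">x" refutes
  # if x >= cutoff
  ok <- !is.na(parsed$value)
  status[ok & parsed$qualifier == "<" & parsed$value <= potency_cutoff] <- "confirmed"
  status[ok & parsed$qualifier == ">" & parsed$value >= potency_cutoff] <- "refuted"
  exact <- ok & parsed$qualifier == "="
  status[exact] <- ifelse(parsed$value[exact] <= potency_cutoff,
                          "confirmed", "refuted")
  call_quo <- rlang::enquo(call)
  if (!rlang::quo_is_null(call_quo)) {
    recorded <- as.character(dplyr::pull(hits, !!call_quo))
    use <- !is.na(recorded) & recorded %in% c("confirmed", "refuted")
    status[use] <- recorded[use]
  }
  tp <- sum(status == "confirmed", na.rm = TRUE)
  fp <- sum(status == "refuted", na.rm = TRUE)
  if (!is.null(assay) && nrow(assay)) {
    conf <- sum(assay$ic50 <= potency_cutoff, na.rm = TRUE)
    tp <- tp + conf
    fp <- fp + sum(assay$ic50 > potency_cutoff, na.rm = TRUE)
  }
  n_ann <- tp + fp
  undefined <- NA_character_
  ratio <- if (n_ann == 0) { undefined <- "ratio"; NA_real_ }
           else if (fp == 0) { undefined <- "ratio"; Inf }
           else tp / fp
  tibble(tp = tp, fp = fp, ratio = ratio, n_annotated = n_ann,
         undefined = undefined)
}

# "14.51" -> (=, 14.51); ">100" -> (>, 100); "<10" -> (<, 10); "new"/"" -> NA
parse_ic50_annotation <- function(x) {
  x <- trimws(as.character(x))
  qual <- dplyr::case_when(
    startsWith(x, "<") ~ "<",
    startsWith(x, ">") ~ ">",
    TRUE ~ "="
  )
  num <- suppressWarnings(as.numeric(sub("^[<>=]+", "", x)))
  list(qualifier = qual, value = num)
}
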