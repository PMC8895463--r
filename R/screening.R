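#' Count Lipinski rule-of-five violations
#'
#' The four criteria predicting poor intestinal absorption: molecular weight
#' greater than 500 g/mol, logP greater than 5, more than 5 hydrogen-bond
#' donors, more than 10 hydrogen-bond acceptors. All comparisons are strict,
#' so MW = 500.0 or HBD = 5 is not a violation. In this pipeline compounds
#' *violating two or more* criteria are of special interest: they are
#' unlikely to be absorbed and so act locally on intestinal CYP3A4.
#'
#' @param data A data frame with descriptor columns.
#' @param mw,logp,hbd,hba Descriptor columns (unquoted; defaults `mw`,
#'   `logp`, `hbd`, `hba`).
#' @return `data` plus an integer `lro5_violations` column (0--4).
#' @examples
#' lro5_violations(tibble::tibble(mw = 552.5, logp = 6.1, hbd = 5, hba = 10))
#' @export
lro5_violations <- function(data, mw = mw, logp = logp, hbd = hbd, hba = hba) {
  vals <- list(
    mw = dplyr::pull(data, {{ mw }}),
    logp = dplyr::pull(data, {{ logp }}),
    hbd = dplyr::pull(data, {{ hbd }}),
    hba = dplyr::pull(data, {{ hba }})
  )
  for (f in names(vals)) if (anyNA(vals[[f]])) filter_error(f)
  v <- (vals$mw > 500) + (vals$logp > 5) + (vals$hbd > 5) + (vals$hba > 10)
  dplyr::mutate(as_tibble(data), lro5_violations = as.integer(v))
}

#' Filter hits to candidate intestine-local inhibitors
#'
#' Keeps hits violating two or more of the rule-of-five criteria -- the
#' compounds least likely to cross the intestinal epithelium, hence the best
#' candidates for local inhibition of intestinal CYP3A4.
#'
#' @param hits A data frame with an `lro5_violations` column (see
#'   [lro5_violations()]); rows are expected to be screen hits.
#' @param min_violations Minimum violation count (default 2).
#' @return The qualifying subset with `is_intestinal_candidate = TRUE`.
#' @export
intestinal_filter <- function(hits, min_violations = 2) {
  if (!"lro5_violations" %in% names(hits)) {
    filter_error("lro5_violations")
  }
  hits |>
    as_tibble() |>
    dplyr::filter(.data$lro5_violations >= min_violations) |>
    dplyr::mutate(is_intestinal_candidate = TRUE)
}

#' Run a virtual screen
#'
#' Orchestrates the full screening funnel over a compound library:
#' curation (desalting, inorganic/fragment/duplicate removal), fingerprints
#' with the model's configuration, prediction indices, the applicability
#' domain gate, the index threshold, exclusion-list removal, descriptors and
#' rule-of-five violation counts. Every curated library compound receives a
#' hit record; a *hit* is reliable (in-domain), at or above the threshold,
#' and not excluded. The report is sorted by descending index (ties by id)
#' and is fully deterministic given model, APD and configuration.
#'
#' Descriptor provenance: when the library supplies `mw`, `logp`, `hbd` and
#' `hba` columns those values are used (`descriptor_source = "supplied"`);
#' otherwise descriptors are computed from the structures.
#'
#' @param library A data frame with `compound_id` and `smiles` (optionally
#'   `name` and precomputed descriptor columns).
#' @param model A `cyp_classifier`.
#' @param apd A `cyp_apd` fitted with the same fingerprint configuration.
#' @param threshold Prediction-index hit threshold (inclusive; default 0.7).
#' @param exclusion Optional exclusion list (see [curate_library()]);
#'   excluded compounds are retained in the report with
#'   `exclusion_reason` filled and can never be hits.
#' @return A tibble of hit records with columns including `pred_index`,
#'   `nn_distance`, `reliable`, descriptor columns, `lro5_violations`,
#'   `is_hit` and `is_intestinal_candidate`; the screening funnel counts are
#'   attached as attribute `"funnel"`.
#' @export
run_screen <- function(library, model, apd, threshold = 0.7,
                       exclusion = NULL) {
  stopifnot(inherits(model, "cyp_classifier"), inherits(apd, "cyp_apd"))
  if (!is.null(apd$fp_config) &&
      !fp_config_equal(model$fp_config, apd$fp_config)) {
    screen_error("model and applicability domain use different fingerprint configurations")
  }
  n_input <- nrow(library)
  curated <- curate_library(library) # exclusions handled below, with reasons
  scored <- curated |>
    fingerprint_compounds(fp = fp_config(model$fp_config$type)) |>
    (\(d) predict_index(model, d))() |>
    (\(d) apd_in_domain(apd, d))()

  excl_reason <- rep(NA_character_, nrow(scored))
  if (!is.null(exclusion) && nrow(exclusion)) {
    ex <- canonical_exclusion(exclusion)
    excl_reason[scored$smiles_canonical %in% ex$smiles |
                  as.character(scored$compound_id) %in% ex$ids] <- "exclusion list"
  }

  supplied <- all(c("mw", "logp", "hbd", "hba") %in% names(library))
  if (!supplied) scored <- compute_descriptors(scored)
  scored <- scored |>
    dplyr::mutate(
      descriptor_source = if (supplied) "supplied" else "computed",
      exclusion_reason = excl_reason
    ) |>
    lro5_violations() |>
    dplyr::mutate(
      is_hit = .data$reliable & .data$pred_index >= threshold &
        is.na(.data$exclusion_reason),
      is_intestinal_candidate = .data$is_hit & .data$lro5_violations >= 2
    ) |>
    dplyr::arrange(dplyr::desc(.data$pred_index), .data$compound_id)

  funnel <- c(
    input = n_input,
    curated = nrow(scored),
    in_domain = sum(scored$reliable),
    above_threshold = sum(scored$reliable & scored$pred_index >= threshold),
    hits = sum(scored$is_hit),
    intestinal_candidates = sum(scored$is_intestinal_candidate)
  )
  attr(scored, "funnel") <- funnel
  attr(scored, "threshold") <- threshold
  class(scored) <- c("cyp_screen", class(scored))
  scored
}

#' Screening funnel counts
#'
#' @param x A screen report from [run_screen()].
#' @return Named integer vector: input, curated, in-domain, above-threshold,
#'   hits, intestinal candidates.
#' @export
screen_funnel <- function(x) attr(x, "funnel")

#' Funnel bar chart for a screen report
#'
#' @param object A screen report from [run_screen()].
#' @param ... Unused.
#' @export
autoplot.cyp_screen <- function(object, ...) plot_screen_funnel(object)

#' @rdname autoplot.cyp_screen
#' @param report A screen report from [run_screen()].
#' @export
plot_screen_funnel <- function(report) {
  f <- screen_funnel(report)
  if (is.null(f)) screen_error("no funnel attribute; was this made by run_screen()?")
  df <- tibble(stage = factor(names(f), levels = rev(names(f))),
               n = as.integer(f))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.15, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.12))) +
    ggplot2::labs(x = "compounds", y = NULL, title = "Virtual-screening funnel") +
    ggplot2::theme_minimal()
}
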