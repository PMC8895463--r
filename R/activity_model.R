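#' Train a fingerprint-based activity classifier
#'
#' Fits a binary classifier that maps molecular fingerprints to a
#' *prediction index* in `[0, 1]` (a probability-like score; higher means
#' more likely active). Class imbalance is handled by inverse-class-frequency
#' observation weights; the emitted index is then calibrated back to the
#' training prevalence by shifting the logit by `log(n_inactive/n_active)`,
#' so a high threshold keeps its conservative, high-specificity meaning on
#' imbalanced data. Training is deterministic for a fixed seed and dataset.
#'
#' Two engines are available:
#' \describe{
#'   \item{`"glmnet"` (default)}{elastic-net-regularised logistic regression
#'     on the fingerprint bits; the penalty is chosen by seeded
#'     cross-validation. Sparse, fast, and reproducible.}
#'   \item{`"nnet"`}{a single-hidden-layer feed-forward network
#'     (`hidden` units, sigmoid output) trained by BFGS with weight decay.
#'     Practical with compact fingerprint spaces (e.g. `"MACCS"`, 256 bits);
#'     on the 4096-bit hashed space its dense weight matrix makes training
#'     orders of magnitude slower than the default engine.}
#' }
#'
#' @param data A tibble with a `fingerprint` list-column (from
#'   [fingerprint_compounds()]) and a label column; typically the
#'   `split == "train"` rows of a [stratified_split()].
#' @param label Column holding the class label (factor or character with
#'   values `"active"`/`"inactive"`).
#' @param engine `"glmnet"` or `"nnet"`.
#' @param seed Integer seed controlling fold assignment / weight
#'   initialisation.
#' @param alpha Elastic-net mixing parameter (glmnet engine).
#' @param nfolds Cross-validation folds for the penalty choice (glmnet).
#' @param hidden Hidden-layer size (nnet engine).
#' @param epochs Maximum optimiser iterations (nnet engine); the training
#'   budget is capped in iterations, not wall-clock time, so results are
#'   hardware independent.
#' @param decay Weight decay (nnet engine).
#' @return A `cyp_classifier` object.
#' @seealso [predict_index()], [classify_index()]
#' @export
train_activity_model <- function(data, label = label,
                                 engine = c("glmnet", "nnet"),
                                 seed = 1, alpha = 0.5, nfolds = 5,
                                 hidden = 8, epochs = 200, decay = 0.1) {
  engine <- match.arg(engine)
  if (!"fingerprint" %in% names(data)) {
    train_error("data needs a 'fingerprint' list-column; run fingerprint_compounds() first")
  }
  fpc <- attr(data, "fp_config")
  if (is.null(fpc)) train_error("data carries no fingerprint configuration")
  lab <- as.character(dplyr::pull(data, {{ label }}))
  if (length(unique(lab)) < 2) {
    train_error("both classes must be present in the training set")
  }
  y <- factor(lab, levels = c("inactive", "active"))
  fps <- data$fingerprint
  X <- fp_matrix(fps, fpc$n_bits)
  n_by_class <- table(y)
  w <- as.numeric(1 / n_by_class[as.character(y)])
  w <- w / mean(w)

  set.seed(seed)
  if (engine == "glmnet") {
    fit <- glmnet::cv.glmnet(X, y, family = "binomial", weights = w,
                             alpha = alpha, nfolds = nfolds,
                             standardize = FALSE)
    meta <- list(lambda = fit$lambda.min, alpha = alpha, nfolds = nfolds,
                 cv_deviance = fit$cvm[fit$lambda == fit$lambda.min])
  } else {
    Xd <- as.matrix(X)
    fit <- nnet::nnet(Xd, as.numeric(y == "active"), size = hidden,
                      entropy = TRUE, weights = w, decay = decay,
                      maxit = epochs, MaxNWts = (ncol(Xd) + 2) * hidden + 1,
                      trace = FALSE)
    meta <- list(hidden = hidden, epochs = epochs, decay = decay,
                 final_loss = fit$value)
  }
  structure(
    list(
      engine = engine, fit = fit, fp_config = fpc, seed = seed,
      n_train = length(y), class_counts = as.list(as.integer(n_by_class)) |>
        setNames(names(n_by_class)),
      # inverse-frequency weighting fits a balanced-class posterior; shift
      # the logit back by the log weight ratio so the emitted index is
      # calibrated to the training prevalence (otherwise the rare class's
      # scores are inflated and a high threshold loses its meaning)
      prior_correction = log(n_by_class[["inactive"]] / n_by_class[["active"]]),
      meta = meta
    ),
    class = "cyp_classifier"
  )
}

#' @export
print.cyp_classifier <- function(x, ...) {
  cat("<CYP activity classifier>\n")
  cat("  engine:     ", x$engine, "\n")
  cat("  fingerprint:", x$fp_config$type, paste0("(", x$fp_config$n_bits, " bits)"), "\n")
  cat("  trained on: ", x$n_train, "compounds (",
      x$class_counts$active, "active /", x$class_counts$inactive, "inactive )\n")
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}

#' Predict the activity index for compounds
#'
#' A pure function of the trained weights and the fingerprint: repeated calls
#' on the same molecule return the same index. The fingerprint configuration
#' of `data` must match the one the model was trained with.
#'
#' @param model A `cyp_classifier`.
#' @param data A tibble with a `fingerprint` list-column.
#' @return `data` plus a `pred_index` column in `[0, 1]`.
#' @export
predict_index <- function(model, data) {
  stopifnot(inherits(model, "cyp_classifier"))
  if (!"fingerprint" %in% names(data)) {
    screen_error("data needs a 'fingerprint' list-column")
  }
  fpc <- attr(data, "fp_config")
  if (!is.null(fpc) && !fp_config_equal(fpc, model$fp_config)) {
    screen_error(sprintf(
      "fingerprint configuration mismatch: data has %s, model expects %s",
      fpc$type, model$fp_config$type
    ))
  }
  X <- fp_matrix(data$fingerprint, model$fp_config$n_bits)
  p <- if (model$engine == "glmnet") {
    as.numeric(predict(model$fit, X, s = "lambda.min", type = "response"))
  } else {
    as.numeric(predict(model$fit, as.matrix(X)))
  }
  corr <- model$prior_correction %||% 0
  p <- plogis(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) - corr)
  dplyr::mutate(as_tibble(data), pred_index = pmin(pmax(p, 0), 1))
}

#' Threshold a prediction index into active/inactive
#'
#' The call is *inclusive*: an index exactly at the threshold is active.
#' Hit sets therefore shrink monotonically as the threshold rises.
#'
#' @param index Numeric vector of prediction indices in `[0, 1]`.
#' @param threshold Decision threshold in (0, 1); default 0.7, chosen to
#'   trade sensitivity for high specificity in screening use.
#' @return A factor with levels `active`, `inactive`.
#' @examples
#' classify_index(c(0.93, 0.70, 0.69))
#' @export
classify_index <- function(index, threshold = 0.7) {
  if (threshold <= 0 || threshold >= 1) {
    cyp_abort("threshold must lie strictly between 0 and 1",
              class = "cyp_threshold_error")
  }
  factor(ifelse(index >= threshold, "active", "inactive"),
         levels = c("active", "inactive"))
}

#' @export
tidy.cyp_classifier <- function(x, ...) {
  if (x$engine == "glmnet") {
    co <- coef(x$fit, s = "lambda.min")
    ix <- which(co[, 1] != 0)
    tibble(
      term = rownames(co)[ix],
      estimate = as.numeric(co[ix, 1])
    )
  } else {
    tibble(term = names(x$fit$wts) %||% paste0("w", seq_along(x$fit$wts)),
           estimate = x$fit$wts)
  }
}

#' @export
glance.cyp_classifier <- function(x, ...) {
  tibble(
    engine = x$engine,
    fingerprint = x$fp_config$type,
    n_bits = x$fp_config$n_bits,
    n_train = x$n_train,
    n_active = x$class_counts$active,
    n_inactive = x$class_counts$inactive,
    seed = x$seed
  )
}
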