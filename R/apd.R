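#' Fit a Tanimoto-distance applicability domain
#'
#' The applicability domain (APD) bounds the region of chemical space in
#' which the classifier's predictions are considered reliable. All
#' `n(n-1)/2` pairwise Tanimoto distances among the training fingerprints
#' are enumerated; their grand mean is computed; then the mean `d` and
#' standard deviation `sigma` of the *below-average* subset (strictly below
#' the grand mean; when every distance equals the mean the whole set is used
#' and `sigma = 0`). The domain threshold is
#' \deqn{APD = d + Z \sigma}
#' A screening compound is in-domain when its nearest training neighbour is
#' at Tanimoto distance at most APD.
#'
#' @param data A tibble with a `fingerprint` list-column (training set), or
#'   a bare list of fingerprints.
#' @param z Multiplier `Z` for the dispersion term (default 0.5, the usual
#'   choice for this construction; record it with your results).
#' @param n_bits Fingerprint length; taken from the `fp_config` attribute
#'   when present.
#' @return A `cyp_apd` object with fields `mean_all`, `d_sub`, `sigma_sub`,
#'   `z`, `threshold`, `n` and the training fingerprints.
#' @examples
#' fps <- list(c(1, 2), c(1, 3), c(5, 6))
#' fit_apd(fps, z = 0.5, n_bits = 8)$threshold # 0.6667
#' @export
fit_apd <- function(data, z = 0.5, n_bits = NULL) {
  if (is.data.frame(data)) {
    if (!"fingerprint" %in% names(data)) apd_error("data needs a 'fingerprint' list-column")
    fps <- data$fingerprint
    fpc <- attr(data, "fp_config")
  } else {
    fps <- data
    fpc <- NULL
  }
  if (is.null(n_bits)) n_bits <- fpc$n_bits
  if (is.null(n_bits) || is.na(n_bits)) {
    n_bits <- max(c(0L, unlist(fps)), na.rm = TRUE) + 1L
  }
  n <- length(fps)
  if (n < 2) apd_error("at least 2 training fingerprints are required")
  D <- tanimoto_cross(fps, fps, n_bits)
  d_all <- D[upper.tri(D)] # the n(n-1)/2 unordered pairs
  mean_all <- mean(d_all)
  sub <- d_all[d_all < mean_all]
  if (!length(sub)) sub <- d_all # all-equal degenerate case
  d_sub <- mean(sub)
  sigma_sub <- stats::sd(sub)
  if (is.na(sigma_sub)) sigma_sub <- 0
  structure(
    list(
      fingerprints = fps, n = n, n_bits = n_bits, fp_config = fpc,
      mean_all = mean_all, d_sub = d_sub, sigma_sub = sigma_sub,
      z = z, threshold = d_sub + z * sigma_sub, n_pairs = length(d_all)
    ),
    class = "cyp_apd"
  )
}

#' @export
print.cyp_apd <- function(x, ...) {
  cat("<applicability domain>\n")
  cat(sprintf("  n = %d training fingerprints (%d pairs)\n", x$n, x$n_pairs))
  cat(sprintf("  mean pair distance = %.4f; below-mean subset: d = %.4f, sigma = %.4f\n",
              x$mean_all, x$d_sub, x$sigma_sub))
  cat(sprintf("  threshold = d + %.2f sigma = %.4f\n", x$z, x$threshold))
  invisible(x)
}

#' @export
glance.cyp_apd <- function(x, ...) {
  tibble(n = x$n, n_pairs = x$n_pairs, mean_all = x$mean_all,
         d_sub = x$d_sub, sigma_sub = x$sigma_sub, z = x$z,
         threshold = x$threshold)
}

#' Flag screening compounds inside/outside the applicability domain
#'
#' For every query fingerprint, finds the nearest-neighbour Tanimoto
#' distance to the APD's training set; a prediction is reliable when that
#' distance does not exceed the APD threshold. Decisions do not depend on
#' training-set order, and a compound present in the training set is always
#' in-domain (distance 0).
#'
#' @param apd A `cyp_apd` from [fit_apd()].
#' @param data A tibble with a `fingerprint` list-column.
#' @return `data` plus `nn_distance` and `reliable` columns.
#' @export
apd_in_domain <- function(apd, data) {
  stopifnot(inherits(apd, "cyp_apd"))
  if (!"fingerprint" %in% names(data)) apd_error("data needs a 'fingerprint' list-column")
  fpc <- attr(data, "fp_config")
  if (!is.null(fpc) && !is.null(apd$fp_config) &&
      !fp_config_equal(fpc, apd$fp_config)) {
    screen_error("fingerprint configuration mismatch between query set and APD")
  }
  D <- tanimoto_cross(data$fingerprint, apd$fingerprints, apd$n_bits)
  nn <- apply(D, 1, min)
  dplyr::mutate(as_tibble(data),
                nn_distance = as.numeric(nn),
                reliable = .data$nn_distance <= apd$threshold)
}

#' @describeIn fit_apd Histogram of the training pairwise distances with the
#'   domain threshold marked.
#' @param object A `cyp_apd`.
#' @param ... Unused.
#' @export
autoplot.cyp_apd <- function(object, ...) {
  D <- tanimoto_cross(object$fingerprints, object$fingerprints, object$n_bits)
  df <- tibble(distance = D[upper.tri(D)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "firebrick",
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = object$mean_all, colour = "steelblue",
                        linetype = 3) +
    ggplot2::labs(
      x = "pairwise Tanimoto distance", y = "pairs",
      title = "Applicability domain",
      subtitle = sprintf("threshold d + Z sigma = %.3f (Z = %.2f); mean = %.3f",
                         object$threshold, object$z, object$mean_all)
    ) +
    ggplot2::theme_minimal()
}
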