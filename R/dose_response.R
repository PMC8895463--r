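#' Percent-of-control enzyme activity from fluorescence deltas
#'
#' Activity is the fluorescence gain of a sample over the reaction window
#' relative to the vehicle-control gain:
#' `100 * (sample_t20 - sample_t0) / (control_t20 - control_t0)`.
#'
#' @param sample_t0,sample_t20 Sample fluorescence at reaction start and
#'   after the incubation window.
#' @param control_t0,control_t20 Vehicle-control fluorescence at the same
#'   time points. The control delta must be positive.
#' @return Numeric vector of percent-of-control activities.
#' @examples
#' percent_of_control(100, 600, 100, 1100) # 50
#' @export
percent_of_control <- function(sample_t0, sample_t20, control_t0, control_t20) {
  ctrl <- control_t20 - control_t0
  if (any(!is.finite(ctrl)) || any(ctrl <= 0)) {
    assay_error("control fluorescence delta must be positive")
  }
  100 * (sample_t20 - sample_t0) / ctrl
}

# four-parameter logistic in concentration space; decreasing for hill > 0
four_pl <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit an IC50 by four-parameter logistic regression
#'
#' Least-squares fit of the four-parameter logistic (4PL) inhibition model
#' in log concentration,
#' \deqn{y = bottom + \frac{top - bottom}{1 + (c / IC_{50})^{hill}}}
#' to percent-of-control activities. All replicate points are fitted (not
#' their means). IC50 is the concentration producing activity midway between
#' the fitted asymptotes. Asymptotes are free by default within
#' `0 <= bottom <= top <= 120`; `fix_asymptotes = TRUE` pins them to 100/0.
#'
#' Initialisation: asymptotes from the extreme-concentration means, IC50
#' from the interpolated 50%-of-span crossing, hill = 1. Non-convergence is
#' reported (`converged = FALSE` with a diagnostic), never a silent number;
#' a fit whose data never bracket the midpoint is flagged `extrapolated`.
#'
#' @param data A data frame of dose-response measurements.
#' @param conc,activity Columns holding concentration (uM, strictly
#'   positive) and percent-of-control activity.
#' @param fix_asymptotes Pin top/bottom to 100/0 instead of fitting them.
#' @return A `cyp_ic50_fit` with fields `ic50`, `hill`, `top`, `bottom`,
#'   `r_squared`, `converged`, `extrapolated`, `n`, `data` and (when
#'   converged) the underlying `nls` fit.
#' @export
fit_ic50 <- function(data, conc = concentration, activity = activity,
                     fix_asymptotes = FALSE) {
  x <- dplyr::pull(data, {{ conc }})
  y <- dplyr::pull(data, {{ activity }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0)) assay_error("concentrations must be strictly positive")
  if (length(unique(x)) < 4) {
    assay_error("at least 4 distinct concentrations are required")
  }
  df <- tibble(conc = x, activity = y)
  means <- df |>
    dplyr::group_by(.data$conc) |>
    dplyr::summarise(m = mean(.data$activity), .groups = "drop") |>
    dplyr::arrange(.data$conc)
  top0 <- mean(means$m[means$conc <= quantile(means$conc, 0.25)])
  bot0 <- mean(means$m[means$conc >= quantile(means$conc, 0.75)])
  if (!is.finite(top0)) top0 <- max(means$m)
  if (!is.finite(bot0)) bot0 <- min(means$m)
  mid <- (top0 + bot0) / 2
  # interpolated 50%-of-span crossing for the IC50 start value
  lower <- means$conc[means$m <= mid]
  upper <- means$conc[means$m >= mid]
  ic50_0 <- if (length(lower) && length(upper)) {
    sqrt(min(lower) * max(upper))
  } else {
    exp(mean(log(range(means$conc))))
  }
  extrapolated <- !(min(means$m) < 50 && max(means$m) > 50)

  result <- list(
    ic50 = NA_real_, hill = NA_real_, top = NA_real_, bottom = NA_real_,
    r_squared = NA_real_, converged = FALSE, extrapolated = extrapolated,
    n = nrow(df), data = df, fit = NULL, diagnostic = NA_character_,
    fixed_asymptotes = fix_asymptotes
  )

  if (fix_asymptotes) {
    par0 <- c(log_ic50 = log(ic50_0), hill = 1)
    lower <- c(log_ic50 = log(1e-6), hill = 0.05)
    upper <- c(log_ic50 = log(1e6), hill = 20)
    residual <- function(p) {
      df$activity - four_pl(df$conc, 100, 0, exp(p[["log_ic50"]]), p[["hill"]])
    }
  } else {
    par0 <- c(top = min(max(top0, 1), 120), bottom = max(min(bot0, 119), 0),
              log_ic50 = log(ic50_0), hill = 1)
    lower <- c(top = 0, bottom = 0, log_ic50 = log(1e-6), hill = 0.05)
    upper <- c(top = 120, bottom = 120, log_ic50 = log(1e6), hill = 20)
    residual <- function(p) {
      df$activity - four_pl(df$conc, p[["top"]], p[["bottom"]],
                            exp(p[["log_ic50"]]), p[["hill"]])
    }
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = residual, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    result$diagnostic <- conditionMessage(fit)
    return(structure(result, class = "cyp_ic50_fit"))
  }
  if (!fit$info %in% 1:4) { # Levenberg-Marquardt did not reach a solution
    result$diagnostic <- fit$message
    return(structure(result, class = "cyp_ic50_fit"))
  }
  cf <- fit$par
  top_hat <- if (fix_asymptotes) 100 else unname(cf[["top"]])
  bot_hat <- if (fix_asymptotes) 0 else unname(cf[["bottom"]])
  ic50_hat <- exp(unname(cf[["log_ic50"]]))
  hill_hat <- unname(cf[["hill"]])
  ss_res <- sum(residual(cf)^2)
  ss_tot <- sum((df$activity - mean(df$activity))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  # an IC50 pushed to the search bounds or a collapsed span is not a result
  degenerate <- ic50_hat <= 1.01e-6 || ic50_hat >= 0.99e6 ||
    (top_hat - bot_hat) < 5 || (!is.na(r2) && r2 < 0) ||
    top_hat > 140 || bot_hat < -20
  result$ic50 <- ic50_hat
  result$hill <- hill_hat
  result$top <- top_hat
  result$bottom <- bot_hat
  result$r_squared <- r2
  result$converged <- !degenerate
  result$fit <- fit
  if (degenerate) result$diagnostic <- "degenerate fit (no usable dose-response signal)"
  structure(result, class = "cyp_ic50_fit")
}

#' Fit IC50 curves for several compounds at once
#'
#' @param data Long-format measurements for several compounds.
#' @param compound Column identifying the compound.
#' @inheritParams fit_ic50
#' @return A tibble with one row per compound: unnested fit parameters plus
#'   a `fit` list-column of `cyp_ic50_fit` objects.
#' @export
fit_ic50_curves <- function(data, compound = compound,
                            conc = concentration, activity = activity,
                            fix_asymptotes = FALSE) {
  data |>
    dplyr::transmute(compound = {{ compound }}, conc = {{ conc }},
                     activity = {{ activity }}) |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_ic50(d, conc = conc, activity = activity,
                    fix_asymptotes = fix_asymptotes)
      g <- glance(f)
      g$fit <- list(f)
      g
    }) |>
    dplyr::ungroup()
}

#' @export
print.cyp_ic50_fit <- function(x, ...) {
  cat("<IC50 fit>\n")
  if (x$converged) {
    cat(sprintf("  IC50 = %.4g uM (hill %.3g, top %.1f, bottom %.1f)\n",
                x$ic50, x$hill, x$top, x$bottom))
    cat(sprintf("  R^2 = %.4f over %d points%s\n", x$r_squared, x$n,
                if (x$extrapolated) " [extrapolated]" else ""))
  } else {
    cat("  did not converge:", x$diagnostic, "\n")
  }
  invisible(x)
}

#' @export
tidy.cyp_ic50_fit <- function(x, ...) {
  tibble(
    term = c("ic50", "hill", "top", "bottom"),
    estimate = c(x$ic50, x$hill, x$top, x$bottom)
  )
}

#' @export
glance.cyp_ic50_fit <- function(x, ...) {
  tibble(
    ic50 = x$ic50, hill = x$hill, top = x$top, bottom = x$bottom,
    r_squared = x$r_squared, converged = x$converged,
    extrapolated = x$extrapolated, n = x$n
  )
}

#' @export
autoplot.cyp_ic50_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$activity)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "activity (% of control)",
                  title = "Dose-response") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(conc = exp(seq(log(min(df$conc)), log(max(df$conc)),
                                  length.out = 200)))
    grid$activity <- four_pl(grid$conc, object$top, object$bottom,
                             object$ic50, object$hill)
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$ic50, linetype = 2,
                          colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf("IC50 = %.3g uM, R^2 = %.3f",
                                       object$ic50, object$r_squared))
  }
  p
}
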