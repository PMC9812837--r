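#' Predicted trend with pointwise confidence band
#'
#' Mean response and Wald confidence limits along a grid of years,
#' conditional on the estimated breakpoint for segmented fits. Binomial
#' intervals are computed on the logit scale and mapped through the inverse
#' logit, so they respect `[0, 1]`.
#'
#' @param fit A `trend_fit` object.
#' @param x_new Years at which to predict; default 200 points spanning the
#'   observed range.
#' @param level Confidence level (default the fit's `ci_level`).
#' @return Tibble with `year`, `estimate`, `conf.low`, `conf.high`; carries
#'   an `extrapolated` flag column when any `x_new` lies more than 50 years
#'   outside the observed range (with a warning).
#' @export
predict_trend <- function(fit, x_new = NULL, level = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  if (!isTRUE(fit$converged)) {
    warn("predicting from a non-converged fit")
  }
  level <- level %||% fit$ci_level
  xr <- range(fit$data$year)
  x_new <- x_new %||% seq(xr[1], xr[2], length.out = 200)
  extr <- x_new < xr[1] - 50 | x_new > xr[2] + 50
  if (any(extr)) {
    warn("predictions requested far outside the observed year range")
  }
  t_new <- x_new - fit$year_origin
  psi_t <- if (!is.na(fit$psi)) fit$psi - fit$year_origin else NULL
  X <- trend_design(t_new, fit$form, psi = psi_t)
  # drop derived rows (year_right) from the coefficient vector
  est <- fit$coefficients$estimate[match(colnames(X), fit$coefficients$term)]
  eta <- drop(X %*% est)
  se <- sqrt(pmax(rowSums((X %*% fit$vcov) * X), 0))
  q <- if (fit$family == "gaussian") {
    qt(1 - (1 - level) / 2, df = fit$n - fit$np)
  } else {
    qnorm(1 - (1 - level) / 2)
  }
  lo <- eta - q * se
  hi <- eta + q * se
  if (fit$family == "binomial") {
    eta <- plogis(eta); lo <- plogis(lo); hi <- plogis(hi)
  }
  out <- tibble::tibble(year = x_new, estimate = eta,
                        conf.low = lo, conf.high = hi)
  if (any(extr)) out$extrapolated <- extr
  out
}

#' Plot a fitted range trend over its data
#'
#' Observed points, fitted mean curve, and pointwise confidence ribbon.
#' Segmented fits mark the estimated breakpoint year with a dashed line.
#'
#' @param object A `trend_fit`.
#' @param level Confidence level for the ribbon.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, level = NULL, ...) {
  pred <- predict_trend(object, level = level)
  ylab <- if (object$family == "binomial") "Occupancy probability" else
    "Distance from range center (km)"
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate),
                       color = "steelblue", linewidth = 0.9) +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$year, y = .data$y),
                        alpha = 0.6) +
    ggplot2::labs(x = "Year", y = ylab,
                  title = sprintf("%s trend (%s family)", object$form,
                                  object$family)) +
    ggplot2::theme_minimal()
  if (!is.na(object$psi)) {
    p <- p + ggplot2::geom_vline(xintercept = object$psi, linetype = "dashed",
                                 color = "grey40")
  }
  p
}

#' Plot an AICc comparison table
#'
#' Akaike weights by model, annotated with delta-AICc.
#'
#' @param object A `comparison_tbl` from [akaike_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comparison_tbl
#' @export
autoplot.comparison_tbl <- function(object, ...) {
  df <- dplyr::mutate(object,
                      model = factor(.data$model,
                                     levels = rev(.data$model)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("Δ %.2f",
                                                    .data$delta_aicc)),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
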