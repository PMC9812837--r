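#' Tidy a fitted range-trend model
#'
#' One row per mean-structure parameter, in the layout of a published
#' parameter table: intercept, pre-breakpoint slope (`year`), quadratic
#' term, hinge slope change (`hinge`), derived post-breakpoint slope
#' (`year_right`), and the breakpoint year as its own row for segmented
#' fits.
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  out <- x$coefficients
  if (!is.na(x$psi)) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(term = "breakpoint_year", estimate = x$psi,
                     std.error = x$psi_se, conf.low = x$psi_conf.low,
                     conf.high = x$psi_conf.high))
  }
  out
}

#' One-row summary of a fitted range-trend model
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return Tibble with `form`, `family`, `nll`, `np`, `k`, `aicc`, `n`,
#'   `sigma`, `psi`, `converged`, `n_iter`.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    form = x$form, family = x$family, nll = x$nll, np = x$np, k = x$k_aicc,
    aicc = tryCatch(aicc(x$nll, x$k_aicc, x$n), error = function(e) NA_real_),
    n = x$n, sigma = x$sigma,
    psi = x$psi, converged = x$converged, n_iter = x$n_iter
  )
}
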