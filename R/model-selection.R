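#' Second-order (small-sample) Akaike information criterion
#'
#' `AICc = 2*NLL + 2k + 2k(k+1)/(n - k - 1)`, where `NLL` is the negative
#' log-likelihood at the maximum-likelihood estimates and `k` the effective
#' parameter count (for Gaussian models the residual variance counts toward
#' `k`; binomial-logit models carry no dispersion parameter).
#'
#' @param nll Negative log-likelihood (note: half of the deviance-scale
#'   "-2LL").
#' @param k Effective parameter count.
#' @param n Observation count; must exceed `k + 1`.
#' @return AICc value(s); vectorized.
#' @examples
#' aicc(128.68, 4, 30) # 266.96
#' @export
aicc <- function(nll, k, n) {
  if (any(n <= k + 1)) {
    abort("AICc undefined: need n > k + 1", class = "rangemargins_small_n")
  }
  2 * nll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Parameter-counting convention for the candidate model suite
#'
#' `np` counts mean-structure parameters including the breakpoint year
#' (constant 1; linear 2; quadratic 3; left-horizontal 3; two-slope 4);
#' the AICc count `k` adds 1 for the Gaussian residual variance and equals
#' `np` for the binomial family.
#'
#' @param form Model form (see [fit_trend()]); vectorized.
#' @param family `"gaussian"` or `"binomial"`; vectorized.
#' @return Tibble with columns `form`, `family`, `np`, `k`.
#' @export
effective_k <- function(form, family = "gaussian") {
  res <- purrr::map2(form, family, function(f, fam) {
    f <- match.arg(f, trend_forms)
    fam <- match.arg(fam, c("gaussian", "binomial"))
    ks <- effective_k_scalar(f, fam)
    tibble::tibble(form = f, family = fam, np = ks[["np"]], k = ks[["k"]])
  })
  dplyr::bind_rows(res)
}

#' Akaike weights from a vector of AICc values
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AICc_i - min(AICc)`. Invariant to adding a constant to all
#' values.
#'
#' @param ic Numeric vector of information-criterion values.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' akaike_weights(c(100, 102))
#' @export
akaike_weights <- function(ic) {
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank a suite of fitted trend models by AICc
#'
#' Builds the model-comparison table: AICc, difference from the best model,
#' Akaike weights, negative log-likelihood, and parameter counts, sorted by
#' AICc (ties broken by `np`). Non-converged fits are retained as rows but
#' excluded from the weight normalization. The `support` flag marks models
#' within 2 AICc units of the best (conventionally "substantial support");
#' it is an annotation, not a decision rule.
#'
#' @param fits A (possibly named) list of `trend_fit` objects fitted to the
#'   same data (same `n`, same response values).
#' @param labels Optional row labels; defaults to list names or the model
#'   forms.
#' @return A tibble of class `comparison_tbl` with columns `model`, `aicc`,
#'   `delta_aicc`, `weight`, `nll`, `np`, `k`, `converged`, `support`.
#' @export
akaike_table <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 2)
  ns <- vapply(fits, function(f) f$n, 0L)
  fams <- vapply(fits, function(f) f$family, "")
  if (length(unique(ns)) != 1 || length(unique(fams)) != 1) {
    abort("models are not comparable: differing n or family",
          class = "rangemargins_incomparable")
  }
  ysig <- vapply(fits, function(f) sum(f$data$y) + sum(f$data$y^2), 0)
  if (max(abs(ysig - ysig[1])) > 1e-8 * (1 + abs(ysig[1]))) {
    abort("models are not comparable: fitted to different responses",
          class = "rangemargins_incomparable")
  }
  if (is.null(labels)) {
    nm <- names(fits)
    labels <- if (!is.null(nm) && all(nzchar(nm))) nm else
      vapply(fits, function(f) f$form, "")
  }
  tab <- tibble::tibble(
    model = unname(labels),
    aicc = unname(vapply(fits, function(f) aicc(f$nll, f$k_aicc, f$n), 0)),
    nll = unname(vapply(fits, function(f) f$nll, 0)),
    np = unname(vapply(fits, function(f) f$np, 0L)),
    k = unname(vapply(fits, function(f) f$k_aicc, 0L)),
    converged = unname(vapply(fits, function(f) isTRUE(f$converged), TRUE))
  )
  conv <- tab$converged
  best <- min(tab$aicc[conv])
  tab$delta_aicc <- tab$aicc - best
  tab$weight <- NA_real_
  tab$weight[conv] <- akaike_weights(tab$aicc[conv])
  tab$support <- conv & tab$delta_aicc <= 2
  tab <- dplyr::arrange(tab, .data$aicc, .data$np)
  tab <- dplyr::select(tab, "model", "aicc", "delta_aicc", "weight",
                       "nll", "np", "k", "converged", "support")
  class(tab) <- c("comparison_tbl", class(tab))
  tab
}

#' Fit the full candidate suite and rank it
#'
#' Convenience wrapper: fits all five forms (or a subset) with [fit_trend()]
#' and returns the [akaike_table()] ranking. Individual fits are attached as
#' the `"fits"` attribute.
#'
#' @inheritParams fit_trend
#' @param forms Model forms to include (default all five).
#' @return A `comparison_tbl`; `attr(, "fits")` holds the `trend_fit`s.
#' @export
compare_trends <- function(data, forms = trend_forms, family = NULL,
                           response = NULL, control = seg_control(),
                           ci_level = 0.95) {
  forms <- match.arg(forms, trend_forms, several.ok = TRUE)
  fits <- list()
  for (f in forms) {
    fits[[f]] <- tryCatch(
      fit_trend(data, f, family = family, response = response,
                control = control, ci_level = ci_level),
      rangemargins_boundary_error = function(e) NULL
    )
    if (is.null(fits[[f]])) {
      warn(sprintf("form '%s' failed (boundary breakpoint); dropped", f))
      fits[[f]] <- NULL
    }
  }
  tab <- akaike_table(fits)
  attr(tab, "fits") <- fits
  tab
}
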