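trend_forms <- c("constant", "linear", "quadratic",
                 "left_horizontal", "two_slope")

#' Control parameters for breakpoint estimation
#'
#' @param tol Convergence tolerance on the breakpoint update, in years.
#' @param max_iter Maximum linearization iterations.
#' @param n_grid Number of interior quantile candidates used to initialize
#'   (and profile) the breakpoint.
#' @param damp Step-halving factor applied to oversized breakpoint updates.
#' @param polish Run a bounded one-dimensional profile optimization around
#'   the linearization solution so the returned breakpoint is the
#'   conditional-ML optimum (default TRUE).
#' @return A list of class `seg_control`.
#' @export
seg_control <- function(tol = 1e-8, max_iter = 100L, n_grid = 10L,
                        damp = 0.5, polish = TRUE) {
  stopifnot(tol > 0, max_iter >= 1, n_grid >= 2, damp > 0, damp < 1)
  structure(list(tol = tol, max_iter = max_iter, n_grid = as.integer(n_grid),
                 damp = damp, polish = polish), class = "seg_control")
}

# ---- internal helpers ------------------------------------------------------

# Exact Gaussian negative log-likelihood at the MLE, all constants included.
gaussian_nll <- function(rss, n) {
  if (rss <= 0) return(-Inf)  # degenerate perfect fit
  (n / 2) * (log(2 * pi) + log(rss / n) + 1)
}

binomial_nll <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

# Design matrix for a fixed form (and, for segmented forms, fixed psi),
# on the internally shifted time scale t.
trend_design <- function(t, form, psi = NULL) {
  switch(form,
    constant = cbind(`(Intercept)` = rep(1, length(t))),
    linear = cbind(`(Intercept)` = 1, year = t),
    quadratic = cbind(`(Intercept)` = 1, year = t, `year^2` = t^2),
    left_horizontal = cbind(`(Intercept)` = 1, hinge = pmax(t - psi, 0)),
    two_slope = cbind(`(Intercept)` = 1, year = t, hinge = pmax(t - psi, 0)),
    abort(paste0("unknown model form '", form, "'"),
          class = "rangemargins_config_error")
  )
}

# Maximum-likelihood fit of y on a fixed design. Returns coefficients,
# covariance, nll, sigma (Gaussian), convergence flag.
ml_fit <- function(X, y, family) {
  n <- length(y)
  if (family == "gaussian") {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      abort("rank-deficient design (too few distinct years for this form)",
            class = "rangemargins_rank_error")
    }
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    sigma2_hat <- rss / (n - ncol(X))          # unbiased, for Wald SEs
    XtXinv <- matrix(NA_real_, ncol(X), ncol(X))
    XtXinv[qx$pivot, qx$pivot] <- chol2inv(qr.R(qx))
    dimnames(XtXinv) <- list(colnames(X), colnames(X))
    list(coef = fit$coefficients,
         vcov = XtXinv * sigma2_hat,
         nll = gaussian_nll(rss, n),
         rss = rss, sigma = sqrt(rss / n),
         fitted = drop(X %*% fit$coefficients),
         converged = TRUE, degenerate = rss <= 1e-12)
  } else {
    fit <- suppressWarnings(
      glm.fit(X, y, family = binomial("logit"),
              control = list(epsilon = 1e-10, maxit = 100))
    )
    eta <- drop(X %*% fit$coefficients)
    # |eta| this large at a data point means probabilities pinned at 0/1,
    # the IRLS footprint of (quasi-)complete separation
    sep <- !fit$converged || max(abs(eta)) > 15
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XtWX <- crossprod(X * sqrt(w))
    vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
      matrix(NA_real_, ncol(X), ncol(X))
    })
    dimnames(vc) <- list(colnames(X), colnames(X))
    list(coef = fit$coefficients, vcov = vc,
         nll = binomial_nll(y, p), rss = NA_real_, sigma = NA_real_,
         fitted = p, converged = !sep, degenerate = FALSE)
  }
}

effective_k_scalar <- function(form, family) {
  np <- switch(form, constant = 1L, linear = 2L, quadratic = 3L,
               left_horizontal = 3L, two_slope = 4L)
  k <- if (family == "gaussian") np + 1L else np
  c(np = np, k = k)
}

infer_response <- function(data, response) {
  if (!is.null(response)) return(response)
  if ("distance" %in% names(data)) return("distance")
  if ("detected" %in% names(data)) return("detected")
  abort("cannot infer the response column; pass `response`",
        class = "rangemargins_config_error")
}

new_trend_fit <- function(...) {
  structure(list(...), class = "trend_fit")
}

# ---- main fitting entry ----------------------------------------------------

#' Fit a candidate range-trend model
#'
#' Fits one of the five candidate forms describing how a range statistic
#' changes with survey year:
#' \describe{
#'   \item{constant}{no temporal change (intercept only);}
#'   \item{linear}{monotone change at a constant rate;}
#'   \item{quadratic}{smooth non-monotone change;}
#'   \item{left_horizontal}{stasis followed by linear change after an
#'     estimated breakpoint year (pre-breakpoint slope fixed at zero);}
#'   \item{two_slope}{two linear phases joined at an estimated breakpoint.}
#' }
#' The Gaussian family models margin distances (identity link); the binomial
#' family models presence-absence (logit link). Breakpoints are estimated by
#' iterative linearization with a hinge term (see [fit_segmented()]).
#'
#' @param data Tibble with a numeric `year` column and the response column.
#' @param form One of `"constant"`, `"linear"`, `"quadratic"`,
#'   `"left_horizontal"`, `"two_slope"`.
#' @param family `"gaussian"` or `"binomial"`; inferred from the response
#'   (0/1 values imply binomial) when omitted.
#' @param response Response column name; defaults to `distance` or
#'   `detected`, whichever is present.
#' @param year_origin Year subtracted from `year` before fitting, for
#'   conditioning and interpretable intercepts. Defaults to `min(year)` for
#'   all forms except `quadratic`, which is fitted on raw years.
#'   Breakpoints are always reported on the original year scale.
#' @param psi0 Starting breakpoint for segmented forms: `"auto"` (profile
#'   grid scan) or a numeric year.
#' @param control A [seg_control()] list.
#' @param ci_level Confidence level for Wald intervals (default 0.95;
#'   t quantiles for Gaussian, normal for binomial).
#' @return A `trend_fit` object with [tidy()], [glance()], [predict_trend()]
#'   and [autoplot()] methods.
#' @examples
#' d <- tibble::tibble(year = rep(c(1985, 2003, 2013, 2019, 2021), 2),
#'                     distance = 160 + 5 * pmax(rep(c(1985, 2003, 2013,
#'                       2019, 2021), 2) - 2006, 0))
#' fit_trend(d, "left_horizontal")
#' @export
fit_trend <- function(data, form = trend_forms, family = NULL,
                      response = NULL, year_origin = NULL, psi0 = "auto",
                      control = seg_control(), ci_level = 0.95) {
  form <- match.arg(form, trend_forms)
  response <- infer_response(data, response)
  if (!"year" %in% names(data)) {
    abort("`data` must contain a numeric `year` column",
          class = "rangemargins_data_error")
  }
  x <- as.numeric(data[["year"]])
  y <- as.numeric(data[[response]])
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(y)
  if (is.null(family)) {
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }
  family <- match.arg(family, c("gaussian", "binomial"))
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    abort("binomial responses must be 0/1", class = "rangemargins_data_error")
  }
  ks <- effective_k_scalar(form, family)
  if (n < ks[["np"]] + 1) {
    abort(sprintf("n = %d too small for form '%s' (need n >= np + 1 = %d)",
                  n, form, ks[["np"]] + 1),
          class = "rangemargins_insufficient_data")
  }
  # Quadratic Gaussian fits default to raw years (the conventional reporting
  # scale for distance-vs-year curvature); everything else is shifted to
  # min(year) for conditioning and interpretable intercepts.
  origin <- year_origin %||%
    if (form == "quadratic" && (is.null(family) || family == "gaussian")) 0
    else min(x)
  if (form %in% c("left_horizontal", "two_slope")) {
    return(fit_segmented_engine(x, y, family, form, origin, psi0, control,
                                ci_level, response))
  }
  t <- x - origin
  X <- trend_design(t, form)
  fit <- ml_fit(X, y, family)
  build_trend_fit(fit, x, y, t, origin, form, family, response, ci_level,
                  psi = NULL, psi_se = NA_real_, n_iter = 0L,
                  converged = fit$converged)
}

# Assemble the trend_fit object from a converged ml_fit.
build_trend_fit <- function(fit, x, y, t, origin, form, family, response,
                            ci_level, psi, psi_se, n_iter, converged) {
  n <- length(y)
  ks <- effective_k_scalar(form, family)
  df <- n - ks[["np"]]
  q <- if (family == "gaussian") qt(1 - (1 - ci_level) / 2, df) else
    qnorm(1 - (1 - ci_level) / 2)
  est <- fit$coef
  se <- sqrt(pmax(diag(fit$vcov), 0))
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    conf.low = unname(est - q * se), conf.high = unname(est + q * se)
  )
  # derived right slope ("Year 2") for segmented forms
  if (form == "left_horizontal") {
    g <- coefs[coefs$term == "hinge", ]
    coefs <- dplyr::bind_rows(
      coefs,
      tibble::tibble(term = "year_right", estimate = g$estimate,
                     std.error = g$std.error, conf.low = g$conf.low,
                     conf.high = g$conf.high))
  } else if (form == "two_slope") {
    i1 <- which(names(est) == "year"); i2 <- which(names(est) == "hinge")
    b2 <- est[[i1]] + est[[i2]]
    v2 <- fit$vcov[i1, i1] + fit$vcov[i2, i2] + 2 * fit$vcov[i1, i2]
    se2 <- sqrt(max(v2, 0))
    coefs <- dplyr::bind_rows(
      coefs,
      tibble::tibble(term = "year_right", estimate = b2, std.error = se2,
                     conf.low = b2 - q * se2, conf.high = b2 + q * se2))
  }
  psi_ci <- if (!is.null(psi)) c(psi - q * psi_se, psi + q * psi_se) else
    c(NA_real_, NA_real_)
  new_trend_fit(
    form = form, family = family, response = response,
    coefficients = coefs, vcov = fit$vcov,
    psi = psi %||% NA_real_, psi_se = psi_se,
    psi_conf.low = psi_ci[1], psi_conf.high = psi_ci[2],
    sigma = fit$sigma, nll = fit$nll, rss = fit$rss,
    n = n, np = ks[["np"]], k_aicc = ks[["k"]],
    converged = converged, degenerate = isTRUE(fit$degenerate),
    n_iter = n_iter, year_origin = origin, ci_level = ci_level,
    data = tibble::tibble(year = x, y = y)
  )
}

#' Fit an intercept-only, linear, or quadratic trend
#'
#' Thin wrapper around [fit_trend()] restricted to the three no-breakpoint
#' baseline forms.
#'
#' @inheritParams fit_trend
#' @param form `"constant"`, `"linear"`, or `"quadratic"`.
#' @return A `trend_fit` object.
#' @export
fit_baseline <- function(data, form = c("constant", "linear", "quadratic"),
                         family = NULL, response = NULL, year_origin = NULL,
                         ci_level = 0.95) {
  form <- match.arg(form)
  fit_trend(data, form, family = family, response = response,
            year_origin = year_origin, ci_level = ci_level)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s / %s, n = %d\n", x$form, x$family, x$n))
  if (!is.na(x$psi)) {
    cat(sprintf("  breakpoint year: %.2f (SE %.3f, %g%% CI %.1f-%.1f)\n",
                x$psi, x$psi_se, 100 * x$ci_level,
                x$psi_conf.low, x$psi_conf.high))
  }
  cat(sprintf("  NLL = %.4f, np = %d, k(AICc) = %d, converged: %s\n",
              x$nll, x$np, x$k_aicc, x$converged))
  print(x$coefficients)
  invisible(x)
}
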