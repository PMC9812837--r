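# Breakpoint ("segmented") trend fitting.
#
# Mean structure: beta0 [+ beta1 * t] + gamma * (t - psi)_+ ,
# with beta1 absent (fixed at 0) in the left-horizontal form. The breakpoint
# psi is estimated by iterative linearization: the design is augmented with
# U = (t - psi)_+ and V = -1[t > psi]; at each step the working estimate is
# updated by psi <- psi + coef(V) / coef(U) (a Newton-type step in psi),
# damped when oversized and clamped to the admissible interior. The
# iteration is started from the best point of a profile-likelihood grid
# scan and, on convergence, a bounded one-dimensional profile optimization
# within the bracketing distinct-year interval certifies the optimum.
# SE(psi) comes from the delta-method ratio SE(coef(V)) / |coef(U)| at the
# solution.

psi_bounds <- function(t) {
  u <- sort(unique(t))
  if (length(u) < 2) {
    abort("segmented fitting needs at least two distinct years",
          class = "rangemargins_insufficient_data")
  }
  eps <- min(diff(u)) / 2
  c(lo = min(u) + eps, hi = max(u) - eps)
}

# Exact conditional ML at fixed psi; +Inf when the conditional design is
# singular (psi leaves too few distinct years on one side).
profile_nll_at <- function(psi, t, y, family, form) {
  X <- trend_design(t, form, psi = psi)
  out <- tryCatch(ml_fit(X, y, family)$nll, error = function(e) Inf)
  if (!is.finite(out)) out else out
}

#' Profile negative log-likelihood over candidate breakpoints
#'
#' For each candidate breakpoint the remaining coefficients are re-estimated
#' by exact conditional maximum likelihood and the negative log-likelihood
#' recorded. This is both the initializer and the independent audit for
#' [fit_segmented()]: the free fit's NLL must not exceed the profile
#' minimum.
#'
#' @inheritParams fit_trend
#' @param psi_grid Numeric vector of candidate breakpoint years (original
#'   year scale).
#' @param left_constrained If TRUE profile the left-horizontal form,
#'   otherwise the two-slope form.
#' @return Tibble with columns `psi`, `nll`, sorted as given.
#' @export
profile_psi <- function(data, psi_grid, family = NULL, response = NULL,
                        left_constrained = FALSE) {
  if (length(psi_grid) == 0) {
    abort("`psi_grid` is empty", class = "rangemargins_config_error")
  }
  response <- infer_response(data, response)
  x <- as.numeric(data[["year"]]); y <- as.numeric(data[[response]])
  if (is.null(family)) {
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }
  family <- match.arg(family, c("gaussian", "binomial"))
  form <- if (left_constrained) "left_horizontal" else "two_slope"
  origin <- min(x)
  t <- x - origin
  b <- psi_bounds(t)
  nll <- vapply(psi_grid - origin, function(p) {
    if (p <= min(t) || p >= max(t)) return(Inf)
    profile_nll_at(p, t, y, family, form)
  }, 0)
  tibble::tibble(psi = psi_grid, nll = nll)
}

#' Fit a one-breakpoint segmented trend
#'
#' Estimates the hinge model `beta0 [+ beta1*year] + gamma*(year - psi)_+`
#' (binomial: on the logit scale) with the breakpoint year `psi` treated as
#' a free parameter. See the package vignette for the estimation scheme.
#' Reported slopes are the pre-breakpoint slope (`year`, zero and omitted in
#' the left-constrained form) and the derived post-breakpoint slope
#' (`year_right` = `year` + `hinge`).
#'
#' @inheritParams fit_trend
#' @param left_constrained If TRUE the pre-breakpoint slope is fixed at
#'   zero (the "left-horizontal" stasis-then-expansion form).
#' @return A `trend_fit` object; `$psi`, `$psi_se` and the CI columns carry
#'   the breakpoint inference.
#' @export
fit_segmented <- function(data, left_constrained = FALSE, family = NULL,
                          response = NULL, psi0 = "auto",
                          control = seg_control(), ci_level = 0.95) {
  form <- if (left_constrained) "left_horizontal" else "two_slope"
  fit_trend(data, form, family = family, response = response,
            psi0 = psi0, control = control, ci_level = ci_level)
}

fit_segmented_engine <- function(x, y, family, form, origin, psi0, control,
                                 ci_level, response) {
  t <- x - origin
  n <- length(y)
  u <- sort(unique(t))
  min_distinct <- if (form == "two_slope") 4L else 3L
  if (length(u) < min_distinct) {
    abort(sprintf("form '%s' needs at least %d distinct years",
                  form, min_distinct),
          class = "rangemargins_insufficient_data")
  }
  b <- psi_bounds(t)
  lo <- b[["lo"]]; hi <- b[["hi"]]

  prof <- function(p) profile_nll_at(p, t, y, family, form)

  # --- initialization: interior-quantile profile scan ---
  if (identical(psi0, "auto")) {
    grid <- unique(pmin(pmax(
      quantile(t, probs = seq_len(control$n_grid) / (control$n_grid + 1),
               type = 7, names = FALSE), lo), hi))
    gvals <- vapply(grid, prof, 0)
    psi <- grid[which.min(gvals)]
  } else {
    psi <- min(max(as.numeric(psi0) - origin, lo), hi)
  }

  # --- iterative linearization with U/V augmentation ---
  max_step <- (hi - lo) / 4
  converged <- FALSE
  boundary_hits <- 0L
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    U <- pmax(t - psi, 0)
    V <- -as.numeric(t > psi)
    X <- trend_design(t, form, psi = psi)
    Xa <- cbind(X, V = V)
    af <- tryCatch(ml_fit(Xa, y, family), error = function(e) NULL)
    if (is.null(af) || anyNA(af$coef)) break
    gU <- af$coef[["hinge"]]
    bV <- af$coef[["V"]]
    if (!is.finite(gU) || abs(gU) < 1e-12) break
    step <- bV / gU
    while (abs(step) > max_step) step <- step * control$damp
    psi_new <- min(max(psi + step, lo), hi)
    if (psi_new %in% c(lo, hi)) boundary_hits <- boundary_hits + 1L else
      boundary_hits <- 0L
    delta <- abs(psi_new - psi)
    psi <- psi_new
    if (delta < control$tol) { converged <- TRUE; break }
    if (boundary_hits >= 3L) break
  }

  # --- profile polish: certify the conditional-ML optimum ---
  if (isTRUE(control$polish)) {
    ints <- unique(pmin(pmax(u, lo), hi))
    brackets <- cbind(ints[-length(ints)], ints[-1])
    cand_psi <- psi
    cand_val <- prof(psi)
    scan_all <- nrow(brackets) <= 24
    for (i in seq_len(nrow(brackets))) {
      bl <- brackets[i, 1]; bh <- brackets[i, 2]
      if (bh - bl < 1e-10) next
      if (!scan_all && !(psi >= bl - 1e-9 && psi <= bh + 1e-9)) next
      op <- optimize(prof, lower = bl, upper = bh, tol = 1e-10)
      if (op$objective < cand_val - 1e-12) {
        cand_val <- op$objective; cand_psi <- op$minimum
      }
      # interval endpoints are kinks; check them too
      for (pp in c(bl, bh)) {
        vv <- prof(pp)
        if (vv < cand_val - 1e-12) { cand_val <- vv; cand_psi <- pp }
      }
    }
    if (cand_val < prof(psi) - 1e-12) psi <- cand_psi
    converged <- converged || is.finite(cand_val)
  }

  if (psi <= lo + 1e-9 || psi >= hi - 1e-9) {
    side <- if (psi <= lo + 1e-9) "lower (early-year)" else "upper (late-year)"
    abort(sprintf(
      "breakpoint driven to the %s boundary of the admissible range",
      side), class = "rangemargins_boundary_error")
  }

  # --- final conditional fit and delta-method SE(psi) ---
  X <- trend_design(t, form, psi = psi)
  fit <- ml_fit(X, y, family)
  V <- -as.numeric(t > psi)
  af <- tryCatch(ml_fit(cbind(X, V = V), y, family),
                 error = function(e) NULL)
  gU <- if (!is.null(af)) af$coef[["hinge"]] else NA_real_
  psi_se <- if (!is.null(af) && is.finite(gU) && abs(gU) > 1e-12 &&
                is.finite(af$vcov["V", "V"])) {
    sqrt(af$vcov["V", "V"]) / abs(gU)
  } else NA_real_

  # Coefficient uncertainty is taken from the V-augmented working model:
  # the extra breakpoint column propagates the uncertainty in psi into the
  # slope SEs (the conditional fit at fixed psi would understate them).
  if (!is.null(af) && !anyNA(af$vcov[colnames(X), colnames(X)])) {
    fit$vcov <- af$vcov[colnames(X), colnames(X)]
  }

  build_trend_fit(fit, x, y, t, origin, form, family, response, ci_level,
                  psi = psi + origin, psi_se = psi_se, n_iter = iter,
                  converged = converged && fit$converged)
}
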