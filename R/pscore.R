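#' Pseudo-score test for the existence of a breakpoint
#'
#' Tests whether a one-breakpoint segmented relationship improves on a
#' no-breakpoint null without having to estimate the (non-identified under
#' the null) breakpoint. The averaged hinge regressor
#' `z = mean_k (year - psi_k)_+` over `K` quantile-spaced candidate
#' breakpoints `psi_k` is added to the null design, and its coefficient is
#' tested: for the Gaussian family the statistic is the exact t statistic of
#' the added term (two-sided t p-value), for the binomial family the Wald z
#' (normal p-value). A seeded parametric-bootstrap mode recomputes the
#' statistic under data simulated from the fitted null and is the arbiter
#' when the closed-form reference distribution is in doubt (few distinct
#' years, small n).
#'
#' @inheritParams fit_trend
#' @param left_constrained_null If TRUE the alternative is the
#'   left-horizontal form and the null is the constant model; otherwise the
#'   alternative is the two-slope form and the null is the linear model.
#' @param K Number of candidate breakpoints (quantile-spaced; default 10).
#' @param bootstrap If TRUE, compute a parametric-bootstrap p-value as well.
#' @param reps Bootstrap replicates (default 999).
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `statistic`, `p_value`, `K`, `null_form`,
#'   `family`, `method`, and `p_boot` when `bootstrap = TRUE`.
#' @export
pscore_test <- function(data, family = NULL, response = NULL,
                        left_constrained_null = FALSE, K = 10,
                        bootstrap = FALSE, reps = 999, seed = 1L) {
  if (K < 3) abort("`K` must be at least 3",
                   class = "rangemargins_config_error")
  response <- infer_response(data, response)
  x <- as.numeric(data[["year"]]); y <- as.numeric(data[[response]])
  if (is.null(family)) {
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }
  family <- match.arg(family, c("gaussian", "binomial"))
  t <- x - min(x)
  null_form <- if (left_constrained_null) "constant" else "linear"

  psik <- quantile(t, probs = seq_len(K) / (K + 1), type = 7, names = FALSE)
  psik <- psik[psik > min(t) & psik < max(t)]
  if (length(psik) == 0) {
    abort("no admissible candidate breakpoints",
          class = "rangemargins_config_error")
  }
  zbar <- rowMeans(vapply(psik, function(p) pmax(t - p, 0),
                          numeric(length(t))))

  stat_fun <- function(yy) {
    X0 <- trend_design(t, null_form)
    Xa <- cbind(X0, z = zbar)
    if (family == "gaussian") {
      qa <- qr(Xa)
      if (qa$rank < ncol(Xa)) return(NA_real_)
      fa <- lm.fit(Xa, yy)
      rss <- sum(fa$residuals^2)
      df <- length(yy) - ncol(Xa)
      if (rss <= 1e-12 || df <= 0) {
        abort("pseudo-score test undefined: degenerate (perfect-fit) residuals",
              class = "rangemargins_degenerate_error")
      }
      s2 <- rss / df
      XtXinv <- matrix(NA_real_, ncol(Xa), ncol(Xa))
      XtXinv[qa$pivot, qa$pivot] <- chol2inv(qr.R(qa))
      fa$coefficients[["z"]] / sqrt(s2 * XtXinv[ncol(Xa), ncol(Xa)])
    } else {
      af <- ml_fit(Xa, yy, "binomial")
      af$coef[["z"]] / sqrt(af$vcov["z", "z"])
    }
  }

  stat <- stat_fun(y)
  n <- length(y)
  p_np <- ncol(trend_design(t, null_form))
  p_value <- if (family == "gaussian") {
    2 * pt(-abs(stat), df = n - p_np - 1)
  } else {
    2 * pnorm(-abs(stat))
  }
  out <- tibble::tibble(statistic = stat, p_value = p_value,
                        K = length(psik), null_form = null_form,
                        family = family,
                        method = "augmented-fit pseudo-score")
  if (bootstrap) {
    X0 <- trend_design(t, null_form)
    nf <- ml_fit(X0, y, family)
    mu <- nf$fitted
    bt <- with_seed(seed, {
      vapply(seq_len(reps), function(i) {
        ystar <- if (family == "gaussian") {
          mu + rnorm(n, 0, nf$sigma)
        } else {
          rbinom(n, 1, mu)
        }
        st <- tryCatch(stat_fun(ystar), error = function(e) NA_real_)
        st
      }, 0)
    })
    bt <- bt[is.finite(bt)]
    out$p_boot <- (1 + sum(abs(bt) >= abs(stat))) / (length(bt) + 1)
    out$reps <- length(bt)
  }
  out
}
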