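# Shared fixtures and independent oracles, built in code.

paper_years <- c(1985, 2003, 2013, 2019, 2021)

# Survey records on an exact hinge trajectory (no noise) for pipeline tests.
make_hinge_series <- function(psi = 2006, level = 160, slope = 5,
                              years = 1985:2021, sigma = 0, seed = 1) {
  mu <- level + slope * pmax(years - psi, 0)
  y <- if (sigma > 0) {
    withr::with_seed(seed, mu + rnorm(length(years), 0, sigma))
  } else mu
  tibble::tibble(year = years, distance = y)
}

# O(n^4) brute-force minimum enclosing circle: the smallest circle among all
# pair-diameter and three-point circumscribed circles that contains every
# point. Independent of the package's Welzl implementation.
brute_mec <- function(x, y) {
  n <- length(x)
  cand <- list()
  for (i in seq_len(n)) {
    cand[[length(cand) + 1]] <- c(x[i], y[i], 0)
    if (i < n) for (j in (i + 1):n) {
      cand[[length(cand) + 1]] <- c((x[i] + x[j]) / 2, (y[i] + y[j]) / 2,
                                    sqrt((x[i] - x[j])^2 +
                                           (y[i] - y[j])^2) / 2)
      if (j < n) for (k in (j + 1):n) {
        d <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) +
                    x[k] * (y[i] - y[j]))
        if (abs(d) < 1e-12) next
        ux <- ((x[i]^2 + y[i]^2) * (y[j] - y[k]) +
                 (x[j]^2 + y[j]^2) * (y[k] - y[i]) +
                 (x[k]^2 + y[k]^2) * (y[i] - y[j])) / d
        uy <- ((x[i]^2 + y[i]^2) * (x[k] - x[j]) +
                 (x[j]^2 + y[j]^2) * (x[i] - x[k]) +
                 (x[k]^2 + y[k]^2) * (x[j] - x[i])) / d
        cand[[length(cand) + 1]] <-
          c(ux, uy, sqrt((x[i] - ux)^2 + (y[i] - uy)^2))
      }
    }
  }
  best <- c(NA, NA, Inf)
  for (cc in cand) {
    if (cc[3] >= best[3]) next
    dmax <- max(sqrt((x - cc[1])^2 + (y - cc[2])^2))
    if (dmax <= cc[3] + 1e-9) best <- cc
  }
  best
}

# Exact conditional ML refit at a fixed breakpoint, written independently of
# the package internals (plain lm/glm on hand-built hinge columns).
refit_at_psi <- function(d, psi, left_constrained, family) {
  u <- pmax(d$year - psi, 0)
  if (family == "gaussian") {
    f <- if (left_constrained) lm(distance ~ u, data = d) else
      lm(distance ~ year + u, data = d)
    rss <- sum(resid(f)^2)
    n <- nrow(d)
    (n / 2) * (log(2 * pi) + log(rss / n) + 1)
  } else {
    f <- if (left_constrained) {
      suppressWarnings(glm(detected ~ u, data = d, family = binomial()))
    } else {
      suppressWarnings(glm(detected ~ year + u, data = d,
                           family = binomial()))
    }
    -as.numeric(logLik(f))
  }
}
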