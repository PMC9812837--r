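test_that("constant and linear Gaussian fits recover exact inputs", {
  flat <- tibble::tibble(year = c(2000, 2001, 2002), distance = c(5, 5, 5))
  f <- fit_trend(flat, "constant")
  expect_equal(f$coefficients$estimate[1], 5)
  expect_true(f$degenerate)
  line <- tibble::tibble(year = 1990:1999, distance = 2 * (1990:1999) + 1)
  fl <- fit_trend(line, "linear", year_origin = 0)
  est <- setNames(fl$coefficients$estimate, fl$coefficients$term)
  expect_equal(unname(est["year"]), 2, tolerance = 1e-10)
  expect_equal(unname(est["(Intercept)"]), 1, tolerance = 1e-8)
})

test_that("Gaussian NLL equals the closed form and the pointwise density sum", {
  d <- make_hinge_series(sigma = 12, seed = 4, years = 1985:2010)
  f <- fit_trend(d, "linear")
  mu <- predict_trend(f, x_new = d$year)$estimate
  rss <- sum((d$distance - mu)^2)
  n <- nrow(d)
  closed <- (n / 2) * (log(2 * pi) + log(rss / n) + 1)
  expect_equal(f$nll, closed, tolerance = 1e-8)
  # numeric check: sum of -log N(y; mu, sigma_mle)
  direct <- -sum(dnorm(d$distance, mu, f$sigma, log = TRUE))
  expect_equal(f$nll, direct, tolerance = 1e-8)
})

test_that("binomial constant fit reproduces logit of the detection rate", {
  d <- tibble::tibble(year = rep(2000:2004, each = 10),
                      detected = rep(c(1, 1, 0, 0, 0), 10))
  f <- fit_trend(d, "constant")
  expect_equal(f$family, "binomial")
  expect_equal(f$coefficients$estimate[1], qlogis(mean(d$detected)),
               tolerance = 1e-8)
  expect_equal(f$np, 1L)
  expect_equal(f$k_aicc, 1L)
})

test_that("binomial fits match glm coefficients and likelihood", {
  withr::with_seed(5, {
    yr <- rep(paper_years, times = 25)
    p <- plogis(-1.7 + 0.07 * (yr - 1985))
    d <- tibble::tibble(year = yr, detected = rbinom(length(yr), 1, p))
  })
  f <- fit_trend(d, "linear")
  ref <- glm(detected ~ I(year - min(year)), data = d, family = binomial())
  expect_equal(unname(f$coefficients$estimate[1:2]), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(f$nll, -as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(f$coefficients$std.error[1:2]),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
})

test_that("degenerate designs are refused with informative errors", {
  one_year <- tibble::tibble(year = rep(2000, 10), distance = rnorm(10))
  expect_error(fit_trend(one_year, "linear"),
               class = "rangemargins_rank_error")
  tiny <- tibble::tibble(year = c(2000, 2001), distance = c(1, 2))
  expect_error(fit_trend(tiny, "quadratic"),
               class = "rangemargins_insufficient_data")
})

test_that("perfect separation is flagged rather than silently reported", {
  d <- tibble::tibble(year = rep(c(1990, 2020), each = 8),
                      detected = rep(c(0, 1), each = 8))
  f <- fit_trend(d, "linear")
  expect_false(f$converged)
})

test_that("tidy and glance expose the broom-style surfaces", {
  d <- make_hinge_series(sigma = 10, seed = 2, years = rep(paper_years, 6))
  f <- fit_trend(d, "left_horizontal")
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error", "conf.low",
                    "conf.high") %in% names(td)))
  expect_true("breakpoint_year" %in% td$term)
  expect_true("year_right" %in% td$term)
  gl <- glance(f)
  expect_equal(gl$np, 3L)
  expect_equal(gl$k, 4L)
  expect_equal(gl$aicc, aicc(f$nll, 4, nrow(d)))
})

test_that("prediction bands behave per family", {
  d <- make_hinge_series(sigma = 8, seed = 9, years = rep(paper_years, 6))
  f <- fit_trend(d, "constant")
  pr <- predict_trend(f, x_new = c(1990, 2000, 2010))
  expect_equal(length(unique(round(pr$estimate, 10))), 1)
  expect_equal(length(unique(round(pr$conf.high - pr$conf.low, 10))), 1)
  # noiseless hinge reproduced exactly at observed years
  dn <- make_hinge_series(years = 1985:2021)
  fn <- fit_trend(dn, "left_horizontal")
  prn <- predict_trend(fn, x_new = dn$year)
  expect_equal(prn$estimate, dn$distance, tolerance = 1e-6)
  # binomial bands respect [0, 1]
  withr::with_seed(3, {
    db <- tibble::tibble(year = rep(paper_years, times = 25),
                         detected = rbinom(125, 1, 0.3))
  })
  fb <- fit_trend(db, "linear")
  prb <- predict_trend(fb)
  expect_true(all(prb$conf.low >= 0 & prb$conf.high <= 1))
  expect_true(all(prb$conf.low <= prb$estimate &
                    prb$estimate <= prb$conf.high))
  expect_warning(predict_trend(fn, x_new = 2200), "outside")
})

test_that("autoplot returns ggplot objects for fits and comparison tables", {
  d <- make_hinge_series(sigma = 10, seed = 6, years = rep(paper_years, 6))
  f <- fit_trend(d, "left_horizontal")
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  tab <- compare_trends(d, forms = c("constant", "linear", "left_horizontal"))
  expect_s3_class(ggplot2::autoplot(tab), "ggplot")
})
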