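test_that("margin generator places points on the hinge when sigma = 0", {
  s <- simulate_margin_series(survey_design(),
                              trajectory_params(sigma = 0), seed = 1)
  mu <- 162.5 + 5.48 * pmax(s$year - 2006, 0)
  expect_equal(s$distance, mu)
  expect_equal(nrow(s), 30)
  expect_equal(unique(s$year), paper_years)
})

test_that("generators are deterministic and carry ground-truth metadata", {
  a <- simulate_margin_series(survey_design(), trajectory_params(), seed = 5)
  b <- simulate_margin_series(survey_design(), trajectory_params(), seed = 5)
  expect_identical(a, b)
  expect_equal(attr(a, "truth")$psi, 2006)
  o1 <- simulate_occupancy_series(survey_design(), seed = 5)
  o2 <- simulate_occupancy_series(survey_design(), seed = 5)
  expect_identical(o1, o2)
  expect_false(identical(
    o1$detected,
    simulate_occupancy_series(survey_design(), seed = 6)$detected))
  # ground truth round-trips through CSV text serialization
  tf <- tempfile(fileext = ".csv")
  readr::write_csv(a, tf)
  back <- readr::read_csv(tf, show_col_types = FALSE)
  expect_equal(back$distance, a$distance)
  expect_equal(back$year, a$year)
})

test_that("residual noise matches sigma and the NLL inversion is exact", {
  des <- survey_design(years = seq(1900, 2100, length.out = 5),
                       margin_sites = 600)
  s <- simulate_margin_series(des, trajectory_params(psi = 2000), seed = 9)
  mu <- 162.5 + 5.48 * pmax(s$year - 2000, 0)
  expect_lt(abs(sd(s$distance - mu) - 17.6) / 17.6, 0.1)
  # the default sigma is the residual SD implied by a Gaussian NLL of
  # 128.68 at n = 30 (closed-form inversion, checked against the forward
  # formula)
  sig <- implied_sigma(128.68, 30)
  expect_equal(sig, 17.6, tolerance = 0.01)
  n <- 30; rss <- n * sig^2
  expect_equal((n / 2) * (log(2 * pi) + log(rss / n) + 1), 128.68,
               tolerance = 1e-10)
})

test_that("occupancy defaults pass through the printed probability anchors", {
  p <- occupancy_params()
  eta <- function(yr) p$beta0 + p$slope_left * (yr - 1985) +
    (p$slope_right - p$slope_left) * pmax(yr - p$psi, 0)
  expect_equal(plogis(eta(1985)), 0.151, tolerance = 1e-10)
  expect_equal(plogis(eta(2019)), 0.658, tolerance = 1e-10)
  expect_equal(plogis(eta(2021)), 0.289, tolerance = 1e-10)
  # large-sample empirical frequencies honor the trajectory
  des <- survey_design(periphery_sites = 4000)
  o <- simulate_occupancy_series(des, seed = 2)
  emp <- tapply(o$detected, o$year, mean)
  # 3-SE bands at 4000 draws per period
  expect_lt(abs(emp[["1985"]] - 0.151), 3 * sqrt(0.151 * 0.849 / 4000))
  expect_lt(abs(emp[["2021"]] - 0.289), 3 * sqrt(0.289 * 0.711 / 4000))
})

test_that("flat-logit generator draws fair coins", {
  des <- survey_design(periphery_sites = 1000)
  o <- simulate_occupancy_series(
    des, trajectory_params(psi = 2006, beta0 = 0, slope_left = 0,
                           slope_right = 0, sigma = 0), seed = 4)
  se <- sqrt(0.25 / nrow(o))
  expect_lt(abs(mean(o$detected) - 0.5), 3 * se)
})

test_that("trajectory parameter validation catches impossible configs", {
  expect_error(trajectory_params(sigma = -1),
               class = "rangemargins_config_error")
  expect_error(trajectory_params(psi2 = 2000),
               class = "rangemargins_config_error")
  expect_error(trajectory_params(psi2 = 2010),
               class = "rangemargins_config_error") # missing slope_right2
  expect_error(survey_design(years = 1985),
               class = "rangemargins_config_error")
  two <- survey_design(years = c(1985, 2021))
  s <- simulate_margin_series(two, trajectory_params(psi = 2000), seed = 1)
  expect_true(isTRUE(attr(s, "underdetermined")))
})

test_that("second-breakpoint trajectories bend twice", {
  p <- trajectory_params(psi = 2006, slope_right = 5, psi2 = 2019,
                         slope_right2 = -5, sigma = 0)
  s <- simulate_margin_series(survey_design(years = c(1985, 2003, 2013,
                                                      2019, 2021)),
                              p, seed = 1)
  by_year <- tapply(s$distance, s$year, unique)
  expect_lt(by_year[["2021"]], by_year[["2019"]])
  expect_gt(by_year[["2019"]], by_year[["2003"]])
})

test_that("spatial generator plants recoverable margins", {
  # scatter 0, sigma 0: top-k selection returns exactly the planted margins
  des <- survey_design()
  sv <- simulate_spatial_survey(des, params = trajectory_params(sigma = 0),
                                scatter_km = 0, seed = 3)
  planted <- attr(sv, "planted")
  ctr <- c(0, 0)
  occ <- sv[sv$detected == 1, ]
  for (p in unique(sv$period)) {
    top <- select_margin_topk(occ[occ$period == p, ], ctr, k = 6)
    expect_setequal(top$site_id, planted$site_id[planted$period == p])
  }
  # planted distances survive the pipeline within the scatter bound
  sv2 <- simulate_spatial_survey(des, params = trajectory_params(sigma = 10),
                                 scatter_km = 2, seed = 4)
  pl2 <- attr(sv2, "planted")
  ser <- build_margin_series(
    dplyr::inner_join(sv2, pl2, by = c("site_id", "period")), ctr)
  m <- dplyr::inner_join(ser, pl2, by = "site_id")
  expect_true(all(abs(m$distance - m$planted) <= 2 + 1e-9))
})

test_that("spatial generator is deterministic under a seed", {
  a <- simulate_spatial_survey(survey_design(), seed = 8)
  b <- simulate_spatial_survey(survey_design(), seed = 8)
  expect_identical(a, b)
})
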