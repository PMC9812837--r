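rec_df <- function(x, y, period = "1985", detected = 1,
                   id = sprintf("s%02d", seq_along(x))) {
  tibble::tibble(site_id = id, x = x, y = y, period = period,
                 detected = detected)
}

test_that("grid resampling keeps one record per cell, period and class", {
  one <- rec_df(3, 4)
  expect_equal(nrow(resample_to_grid(one, 10, seed = 1)), 1)
  # cells by floor((coord - origin)/cell): (1,1),(2,2) share cell 0, (15,15)
  # is cell 1 -> 2 records survive
  three <- rec_df(c(1, 2, 15), c(1, 2, 15))
  out <- resample_to_grid(three, 10, origin = c(0, 0), seed = 5)
  expect_equal(nrow(out), 2)
  expect_setequal(unique(paste(out$cell_x, out$cell_y)), c("0 0", "1 1"))
  # detections are never masked by a co-located non-detection
  mixed <- rec_df(c(1, 2), c(1, 2), detected = c(1, 0))
  outm <- resample_to_grid(mixed, 10, seed = 2)
  expect_equal(nrow(outm), 2)
  expect_setequal(outm$detected, c(0L, 1L))
  expect_error(resample_to_grid(three, cell_size = 0),
               class = "rangemargins_config_error")
  expect_equal(nrow(resample_to_grid(rec_df(numeric(), numeric()))), 0)
})

test_that("grid resampling is deterministic, idempotent and order-invariant", {
  withr::with_seed(3, {
    big <- rec_df(runif(200, 0, 100), runif(200, 0, 100),
                  period = sample(c("1985", "2003"), 200, TRUE),
                  detected = rbinom(200, 1, 0.6))
  })
  a <- resample_to_grid(big, 10, seed = 42)
  b <- resample_to_grid(big, 10, seed = 42)
  expect_identical(a, b)
  twice <- resample_to_grid(a, 10, seed = 42)
  expect_setequal(twice$site_id, a$site_id)
  shuf <- big[sample(nrow(big)), ]
  c2 <- resample_to_grid(shuf, 10, seed = 42)
  expect_setequal(c2$site_id, a$site_id)
})

test_that("percentile margin rule uses strict linear-interpolation quantile", {
  # distances 1..100 north of center: 95th percentile = 95.05, 5 sites above
  occ <- rec_df(x = rep(0, 100), y = 1:100)
  sel <- select_margin_percentile(occ, c(0, 0), q = 0.95)
  expect_equal(sort(sel$distance), 96:100)
  # equidistant ring: strictly-above rule excludes the all-tied set
  ring <- rec_df(x = c(0, 0, 5, -5), y = c(5, -5, 0, 0))
  expect_equal(nrow(select_margin_percentile(ring, c(0, 0), q = 0.95,
                                             northern_only = FALSE)), 0)
  # northern_only filters by y > center y
  both <- rec_df(x = rep(0, 40), y = c(1:20, -(1:20)))
  seln <- select_margin_percentile(both, c(0, 0), q = 0.9)
  expect_true(all(seln$y > 0))
  expect_error(select_margin_percentile(rec_df(1, 1), c(0, 0)),
               class = "rangemargins_insufficient_data")
  expect_error(select_margin_percentile(occ, c(0, 0), q = 1.2),
               class = "rangemargins_config_error")
})

test_that("top-k margin rule sorts by distance with stable site_id ties", {
  occ <- rec_df(x = rep(0, 4), y = c(10, 20, 30, 40))
  top2 <- select_margin_topk(occ, c(0, 0), k = 2)
  expect_setequal(top2$distance, c(30, 40))
  expect_equal(nrow(select_margin_topk(occ, c(0, 0), k = 4)), 4)
  # order-invariance given the tie rule
  tied <- rec_df(x = c(0, 0, 0), y = c(10, 10, 5), id = c("b", "a", "c"))
  t1 <- select_margin_topk(tied, c(0, 0), k = 1)
  t2 <- select_margin_topk(tied[c(2, 3, 1), ], c(0, 0), k = 1)
  expect_equal(t1$site_id, "a")
  expect_identical(t1$site_id, t2$site_id)
  expect_warning(short <- select_margin_topk(occ, c(0, 0), k = 9),
                 "top-9")
  expect_equal(nrow(short), 4)
  expect_true(isTRUE(attr(short, "short")))
})

test_that("period labels map to regression years, pooled labels to midpoints", {
  ym <- period_year_map(c("1985", "2012-14", "2019", "2012–14"))
  expect_equal(unname(ym[c("1985", "2012-14")]), c(1985, 2013))
  expect_equal(unname(ym["2012–14"]), 2013)
})

test_that("margin series rows carry distance from center and mapped year", {
  m <- rec_df(x = c(0, 0, 3), y = c(4, 5, 4),
              period = c("1985", "1985", "2012-14"))
  ser <- build_margin_series(m, c(0, 0))
  expect_equal(nrow(ser), 3)
  expect_equal(sort(unique(ser$year)), c(1985, 2013))
  expect_equal(ser$distance[ser$site_id == "s03"], 5)
  expect_error(build_margin_series(m, c(0, 0), year_map = c("1985" = 1985)),
               class = "rangemargins_config_error")
})

test_that("periphery extraction keeps records inside the per-period circle", {
  # margin points = all survey points -> everything returned
  recs <- rec_df(x = c(0, 1, 2), y = c(0, 1, 2), detected = c(1, 1, 0))
  out <- extract_periphery(recs, recs)
  expect_equal(nrow(out), 3)
  # explicit point-in-circle case: circle radius 2 about origin
  m2 <- rec_df(x = c(-2, 2), y = c(0, 0), period = "2003")
  r2 <- rec_df(x = c(1, 5), y = c(0, 0), period = "2003",
               detected = c(1, 0), id = c("in", "out"))
  got <- extract_periphery(r2, m2)
  expect_equal(got$site_id, "in")
  expect_equal(got$detected, 1L)
  expect_equal(got$year, 2003)
})

test_that("periphery counts grow with the enclosing circle radius", {
  withr::with_seed(8, {
    recs <- rec_df(runif(80, -50, 50), runif(80, -50, 50),
                   detected = rbinom(80, 1, 0.5))
  })
  counts <- vapply(c(5, 15, 30, 60), function(r) {
    marg <- rec_df(x = c(-r, r), y = c(0, 0), id = c("ma", "mb"))
    nrow(suppressWarnings(extract_periphery(recs, marg)))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("composite margin selection reproduces the study structure", {
  sv <- simulate_spatial_survey(survey_design(), seed = 30)
  ctr <- range_center(sv, "1985")
  margins <- select_margins(sv, ctr, rule = "auto")
  counts <- table(margins$period)
  # top-k periods all share the reference period's margin count
  kref <- counts[["1985"]]
  expect_true(all(counts[names(counts) != "1985"] == kref))
  ser <- build_margin_series(margins, ctr)
  expect_equal(nrow(ser), sum(counts))
  expect_true(all(ser$distance >= 0))
})
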