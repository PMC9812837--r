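#' Survey design for the synthetic generator
#'
#' The default emulates a five-period survey series (1985, 2003, a pooled
#' 2012-14 mapped to 2013, 2019, 2021) with six range-margin observations
#' per period (30 in total) and 126 range-periphery presence-absence sites
#' split as evenly as possible across periods.
#'
#' @param years Numeric survey years (>= 2).
#' @param margin_sites Margin observations per period.
#' @param periphery_sites Periphery presence-absence sites per period;
#'   either one number recycled or a vector per period. Default splits 126.
#' @param seed Integer seed.
#' @return List of class `survey_design`.
#' @export
survey_design <- function(years = c(1985, 2003, 2013, 2019, 2021),
                          margin_sites = 6, periphery_sites = NULL,
                          seed = 1L) {
  if (length(years) < 2) {
    abort("a survey design needs at least 2 periods",
          class = "rangemargins_config_error")
  }
  if (margin_sites < 1) {
    abort("`margin_sites` must be >= 1", class = "rangemargins_config_error")
  }
  np <- length(years)
  if (is.null(periphery_sites)) {
    base <- 126 %/% np
    periphery_sites <- rep(base, np) + c(rep(1, 126 %% np),
                                         rep(0, np - 126 %% np))
  }
  periphery_sites <- rep_len(periphery_sites, np)
  structure(list(years = sort(years), margin_sites = as.integer(margin_sites),
                 periphery_sites = as.integer(periphery_sites),
                 seed = as.integer(seed)),
            class = "survey_design")
}

#' Ground-truth trajectory parameters for the synthetic generator
#'
#' A flat-then-linear (hinge) trajectory with optional second breakpoint:
#' `mu(t) = beta0 + slope_left*(t - t0) + (slope_right - slope_left)*
#' (t - psi)_+ [+ (slope_right2 - slope_right)*(t - psi2)_+]`, where `t0`
#' is the first design year. For the Gaussian (margin-distance) response
#' `mu` is in km and observations get `N(0, sigma^2)` noise; for the
#' binomial (occupancy) response `mu` is a logit and observations are
#' Bernoulli draws.
#'
#' The margin defaults emulate a range that holds at 162.5 km from the
#' reference center until a 2006 breakpoint and then expands at
#' 5.48 km/year with residual SD 17.6 km (the residual SD implied by a
#' Gaussian fit with NLL 128.68 at n = 30; see [implied_sigma()]).
#'
#' @param psi Breakpoint year (must lie strictly inside the design years).
#' @param beta0 Baseline level (km, or logit for occupancy).
#' @param slope_left Pre-breakpoint slope (km/yr or logit/yr).
#' @param slope_right Post-breakpoint slope.
#' @param sigma Gaussian residual SD (km); ignored for occupancy.
#' @param psi2,slope_right2 Optional second breakpoint and subsequent slope.
#' @return List of class `trajectory_params`.
#' @export
trajectory_params <- function(psi = 2006, beta0 = 162.5, slope_left = 0,
                              slope_right = 5.48, sigma = 17.6,
                              psi2 = NULL, slope_right2 = NULL) {
  if (sigma < 0) abort("`sigma` must be >= 0",
                       class = "rangemargins_config_error")
  if (!is.null(psi2) && psi2 <= psi) {
    abort("`psi2` must exceed `psi`", class = "rangemargins_config_error")
  }
  if (!is.null(psi2) && is.null(slope_right2)) {
    abort("`psi2` requires `slope_right2`", class = "rangemargins_config_error")
  }
  structure(list(psi = psi, beta0 = beta0, slope_left = slope_left,
                 slope_right = slope_right, sigma = sigma,
                 psi2 = psi2, slope_right2 = slope_right2),
            class = "trajectory_params")
}

#' Occupancy trajectory matching the study-like rise-then-fall pattern
#'
#' Defaults solve the two-segment logit path through occupancy 0.151 in
#' 1985, rising to 0.658 at a 2019 breakpoint, then falling to 0.289 by
#' 2021.
#'
#' @param p_start,p_peak,p_end Occupancy probabilities at the start year,
#'   breakpoint year, and end year.
#' @param year_start,psi,year_end The corresponding years.
#' @return A [trajectory_params()] list (logit scale).
#' @export
occupancy_params <- function(p_start = 0.151, p_peak = 0.658, p_end = 0.289,
                             year_start = 1985, psi = 2019, year_end = 2021) {
  b0 <- qlogis(p_start)
  sl <- (qlogis(p_peak) - qlogis(p_start)) / (psi - year_start)
  sr <- (qlogis(p_end) - qlogis(p_peak)) / (year_end - psi)
  trajectory_params(psi = psi, beta0 = b0, slope_left = sl,
                    slope_right = sr, sigma = 0)
}

# Hinge mean trajectory on the original year scale.
trajectory_mean <- function(years, params, t0) {
  mu <- params$beta0 + params$slope_left * (years - t0) +
    (params$slope_right - params$slope_left) * pmax(years - params$psi, 0)
  if (!is.null(params$psi2)) {
    mu <- mu + (params$slope_right2 - params$slope_right) *
      pmax(years - params$psi2, 0)
  }
  mu
}

check_psi_interior <- function(params, years) {
  if (params$psi <= min(years) || params$psi >= max(years)) {
    warn("breakpoint lies outside the design years; fits will be degenerate")
  }
}

#' Simulate a margin-distance series with known ground truth
#'
#' @param design A [survey_design()].
#' @param params A [trajectory_params()] (Gaussian interpretation).
#' @param seed Overrides `design$seed` when given.
#' @return Tibble `year`, `distance`, `site_id` with the generating
#'   parameters attached as attribute `"truth"`. Designs with fewer than 3
#'   periods carry attribute `"underdetermined" = TRUE` (segmented fitting
#'   is not identified there).
#' @export
simulate_margin_series <- function(design = survey_design(),
                                   params = trajectory_params(),
                                   seed = NULL) {
  stopifnot(inherits(design, "survey_design"),
            inherits(params, "trajectory_params"))
  seed <- seed %||% design$seed
  check_psi_interior(params, design$years)
  years <- rep(design$years, each = design$margin_sites)
  mu <- trajectory_mean(years, params, t0 = min(design$years))
  dist <- with_seed(seed, mu + rnorm(length(years), 0, params$sigma))
  out <- tibble::tibble(
    year = years, distance = dist,
    site_id = sprintf("m%02d_%d", seq_along(years), years))
  attr(out, "truth") <- unclass(params)
  attr(out, "seed") <- seed
  if (length(design$years) < 3) attr(out, "underdetermined") <- TRUE
  out
}

#' Simulate a range-periphery presence-absence series
#'
#' @param design A [survey_design()].
#' @param params A [trajectory_params()] on the logit scale; default
#'   [occupancy_params()].
#' @param seed Overrides `design$seed`.
#' @return Tibble `year`, `detected`, `site_id` with `"truth"` attribute.
#' @export
simulate_occupancy_series <- function(design = survey_design(),
                                      params = occupancy_params(),
                                      seed = NULL) {
  stopifnot(inherits(design, "survey_design"),
            inherits(params, "trajectory_params"))
  seed <- seed %||% design$seed
  years <- rep(design$years, times = design$periphery_sites)
  eta <- trajectory_mean(years, params, t0 = min(design$years))
  p <- plogis(eta)
  det <- with_seed(seed, rbinom(length(years), 1, p))
  out <- tibble::tibble(
    year = years, detected = det,
    site_id = sprintf("p%03d_%d", seq_along(years), years))
  attr(out, "truth") <- unclass(params)
  attr(out, "seed") <- seed
  out
}

#' Simulate a full spatial survey snapshot
#'
#' Generates georeferenced survey records whose margin structure follows
#' the stasis-then-expansion trajectory: per period, `margin_sites`
#' occurrence points are planted in the northern half-plane at distances
#' `hinge mean + N(0, sigma)` from `center` (plus a uniform radial jitter of
#' half-width `scatter_km`), interior "filler" occurrences are placed
#' strictly nearer the center, and non-detections are sprinkled around the
#' margin ring. Running the margin-extraction pipeline on the output
#' recovers the planted breakpoint and expansion rate up to simulation
#' error.
#'
#' @param design A [survey_design()]; `periphery_sites` controls the
#'   non-detection count per period.
#' @param center Numeric `c(x, y)` range center (km); default `c(0, 0)`.
#' @param params Gaussian [trajectory_params()].
#' @param scatter_km Half-width (km) of the uniform radial jitter applied to
#'   planted margin points (default 0).
#' @param n_filler Interior occurrences per period, recycled. The default
#'   gives the first (reference) period a range-wide survey's worth of
#'   interior points (110, spread over the full disc) so that the
#'   95th-percentile margin rule selects about `margin_sites` sites there
#'   and the occurrence centroid approximates the planted range center;
#'   later, periphery-restricted periods get 12.
#' @param occupancy Occupancy [trajectory_params()] used to label periphery
#'   sites detected/non-detected; default [occupancy_params()].
#' @param seed Overrides `design$seed`.
#' @return Tibble of survey records (`site_id`, `x`, `y`, `period`,
#'   `detected`) with attributes `"truth"` (margin params) and
#'   `"planted"` (tibble of planted margin distances per site).
#' @export
simulate_spatial_survey <- function(design = survey_design(),
                                    center = c(0, 0),
                                    params = trajectory_params(),
                                    scatter_km = 0, n_filler = NULL,
                                    occupancy = occupancy_params(),
                                    seed = NULL) {
  stopifnot(inherits(design, "survey_design"), scatter_km >= 0)
  if (length(design$years) == 0) {
    abort("design has no periods", class = "rangemargins_config_error")
  }
  seed <- seed %||% design$seed
  t0 <- min(design$years)
  np_periods <- length(design$years)
  n_filler <- n_filler %||% c(110L, rep(12L, max(np_periods - 1, 0)))
  n_filler <- rep_len(as.integer(n_filler), np_periods)
  rows <- with_seed(seed, {
    purrr::imap(design$years, function(yr, i) {
      mu <- trajectory_mean(yr, params, t0)
      k <- design$margin_sites
      planted <- mu + rnorm(k, 0, params$sigma)
      planted <- pmax(planted, 1)          # distances must stay positive
      r <- pmax(planted + runif(k, -scatter_km, scatter_km), 0.5)
      ang <- runif(k, pi / 12, pi - pi / 12)   # northern half-plane
      margin <- tibble::tibble(
        site_id = sprintf("%d_margin%02d", yr, seq_len(k)),
        x = center[1] + r * cos(ang), y = center[2] + r * sin(ang),
        period = as.character(yr), detected = 1L,
        planted = planted)
      # interior occurrences strictly nearer than any planted margin;
      # the reference period's (first, many) cover the full disc like a
      # range-wide survey, so the occurrence centroid sits near `center`
      nf <- n_filler[i]
      rmax <- 0.8 * min(r)
      rf <- runif(nf, 0.1 * rmax, rmax)
      af <- if (i == 1) runif(nf, 0, 2 * pi) else
        runif(nf, pi / 12, pi - pi / 12)
      filler <- tibble::tibble(
        site_id = sprintf("%d_fill%03d", yr, seq_len(nf)),
        x = center[1] + rf * cos(af), y = center[2] + rf * sin(af),
        period = as.character(yr), detected = 1L, planted = NA_real_)
      # periphery sites around the margin ring, occupancy-labelled
      npp <- design$periphery_sites[i]
      p_occ <- plogis(trajectory_mean(yr, occupancy, t0))
      rp <- runif(npp, 0.85 * min(r), 1.0 * min(r))
      ap <- runif(npp, pi / 12, pi - pi / 12)
      periph <- tibble::tibble(
        site_id = sprintf("%d_periph%03d", yr, seq_len(npp)),
        x = center[1] + rp * cos(ap), y = center[2] + rp * sin(ap),
        period = as.character(yr),
        detected = rbinom(npp, 1, p_occ), planted = NA_real_)
      dplyr::bind_rows(margin, filler, periph)
    })
  })
  out <- dplyr::bind_rows(rows)
  planted <- dplyr::filter(out, !is.na(.data$planted)) |>
    dplyr::select("site_id", "period", "planted")
  out <- dplyr::select(out, -"planted")
  attr(out, "truth") <- unclass(params)
  attr(out, "planted") <- planted
  attr(out, "seed") <- seed
  out
}

#' Residual SD implied by a printed Gaussian negative log-likelihood
#'
#' Inverts the closed-form Gaussian NLL,
#' `NLL = (n/2) (log 2*pi + log(RSS/n) + 1)`, for the maximum-likelihood
#' residual SD `sqrt(RSS/n)`. Useful to back a simulation noise level out
#' of a published model-selection table.
#'
#' @param nll Negative log-likelihood.
#' @param n Observation count.
#' @return The implied residual SD (same units as the response).
#' @examples
#' implied_sigma(128.68, 30) # about 17.6
#' @export
implied_sigma <- function(nll, n) {
  sqrt(exp(2 * nll / n - log(2 * pi) - 1))
}
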