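#' Resample survey records to one point per grid cell
#'
#' Surveys of different vintage often differ in spatial resolution; pooling
#' them on a common grid (the 10 x 10 km EEA grid is the usual choice for
#' European atlas data) equalizes effort before range statistics are
#' computed. Within each (cell, period) one record is retained, drawn at
#' random under `seed`. Detections and non-detections are resampled
#' independently, so an occurrence can never be masked by a non-detection
#' that happens to share its cell.
#'
#' @param records Survey records: tibble with `site_id`, `x`, `y`, `period`,
#'   `detected`.
#' @param cell_size Grid cell size in km (default 10).
#' @param origin Numeric `c(x, y)` grid anchor in km (default `c(0, 0)`).
#' @param seed Integer seed making the within-cell draw reproducible.
#' @return Tibble of the retained records, with `cell_x`, `cell_y` index
#'   columns added.
#' @export
resample_to_grid <- function(records, cell_size = 10, origin = c(0, 0),
                             seed = 1L) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort("`cell_size` must be a single positive number",
          class = "rangemargins_config_error")
  }
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, cell_x = integer(), cell_y = integer()))
  }
  check_survey_records(records)
  keyed <- dplyr::mutate(
    records,
    cell_x = floor((.data$x - origin[[1]]) / cell_size),
    cell_y = floor((.data$y - origin[[2]]) / cell_size),
    detected = as.integer(as.logical(.data$detected))
  )
  # stable order so the seeded draw is invariant to input row order
  keyed <- dplyr::arrange(keyed, .data$period, .data$detected,
                          .data$cell_x, .data$cell_y, .data$site_id)
  with_seed(seed, {
    keyed |>
      dplyr::group_by(.data$period, .data$detected,
                      .data$cell_x, .data$cell_y) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup()
  })
}

#' Select range-margin occurrences above a distance percentile
#'
#' For range-wide surveys the margin is described by the occurrences whose
#' distance from the range center exceeds a high quantile (default the 95th
#' percentile) of all that period's occurrence distances, optionally
#' restricted to the poleward (here northern, `y > center$y`) side.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7) and inclusion is strict (`distance >`
#' quantile). Distances are pooled over all of the period's occurrences
#' before the quantile is taken; the directional filter applies only to
#' selection.
#'
#' @param occurrences Occurrence records (detections) for one period:
#'   tibble with `site_id`, `x`, `y` (and optionally `period`).
#' @param center [range_center()] tibble or numeric `c(x, y)`.
#' @param q Quantile level in (0, 1); default 0.95.
#' @param northern_only Restrict selection to sites north of the center
#'   (default TRUE).
#' @return Tibble of selected margin occurrences with a `distance` column.
#' @export
select_margin_percentile <- function(occurrences, center, q = 0.95,
                                     northern_only = TRUE) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort("`q` must be a single value in (0, 1)",
          class = "rangemargins_config_error")
  }
  if (nrow(occurrences) < 2) {
    abort("percentile margin selection needs at least 2 occurrences",
          class = "rangemargins_insufficient_data")
  }
  ctr <- as_center_xy(center)
  withd <- site_distances(occurrences, ctr)
  cut <- quantile(withd$distance, probs = q, type = 7, names = FALSE)
  out <- dplyr::filter(withd, .data$distance > cut)
  if (northern_only) out <- dplyr::filter(out, .data$y > ctr[["y"]])
  out
}

#' Select the k most distant occurrences (margin top-k)
#'
#' For periphery-restricted surveys (where a range-wide percentile is not
#' defined) the margin is the `k` occurrences farthest from the reference
#' range center. Ties are broken by `site_id` order so the result is stable
#' under row permutation.
#'
#' @inheritParams select_margin_percentile
#' @param k Number of margin sites to keep (typically the count the
#'   percentile rule produced in the reference period).
#' @return Tibble of the `k` selected occurrences with `distance`; if fewer
#'   than `k` occurrences exist, all are returned and the result carries
#'   attribute `short = TRUE` plus a warning.
#' @export
select_margin_topk <- function(occurrences, center, k = 6) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("`k` must be a single integer >= 1",
          class = "rangemargins_config_error")
  }
  withd <- site_distances(occurrences, as_center_xy(center))
  withd <- dplyr::arrange(withd, dplyr::desc(.data$distance), .data$site_id)
  if (nrow(withd) < k) {
    warn(sprintf("only %d occurrences available for top-%d margin selection",
                 nrow(withd), k))
    attr(withd, "short") <- TRUE
    return(withd)
  }
  head(withd, n = k)
}

#' Margin selection across all survey periods
#'
#' Applies the study's composite rule: the percentile criterion for the
#' reference (range-wide) period and top-k (k = the reference period's
#' margin count) for later, periphery-restricted periods — or a single rule
#' for every period.
#'
#' @param records Survey records (all periods).
#' @param center [range_center()] tibble (distances are always measured from
#'   this fixed reference center).
#' @param rule `"auto"` (percentile for `reference_period`, top-k matching
#'   its count elsewhere), `"percentile"`, or `"topk"`.
#' @param q,northern_only Percentile-rule parameters.
#' @param k Top-k count; for `rule = "auto"` the default is the reference
#'   period's selected count.
#' @param reference_period Period the percentile rule anchors on
#'   (default `"1985"`).
#' @return Tibble of margin occurrences, all periods, with `distance`.
#' @export
select_margins <- function(records, center, rule = c("auto", "percentile",
                                                     "topk"),
                           q = 0.95, northern_only = TRUE, k = NULL,
                           reference_period = "1985") {
  rule <- match.arg(rule)
  check_survey_records(records)
  occ <- dplyr::filter(records, as.logical(.data$detected))
  periods <- unique(occ$period)
  pick_percentile <- function(d) select_margin_percentile(d, center, q,
                                                          northern_only)
  pick_topk <- function(d, kk) select_margin_topk(d, center, kk)
  if (rule == "percentile") {
    return(dplyr::bind_rows(lapply(split(occ, occ$period), pick_percentile)))
  }
  if (rule == "topk") {
    if (is.null(k)) abort("rule 'topk' requires `k`",
                          class = "rangemargins_config_error")
    return(dplyr::bind_rows(lapply(split(occ, occ$period),
                                   pick_topk, kk = k)))
  }
  # auto: percentile on the reference period, top-k of its size elsewhere
  if (!reference_period %in% periods) {
    abort(sprintf("reference period '%s' absent from data", reference_period),
          class = "rangemargins_config_error")
  }
  ref <- pick_percentile(occ[occ$period == reference_period, , drop = FALSE])
  kk <- k %||% nrow(ref)
  if (kk < 1) {
    abort("percentile rule selected no reference-period margin sites",
          class = "rangemargins_insufficient_data")
  }
  rest <- lapply(split(occ[occ$period != reference_period, , drop = FALSE],
                       occ$period[occ$period != reference_period]),
                 pick_topk, kk = kk)
  dplyr::bind_rows(c(list(ref), rest))
}

#' Map period labels to numeric regression years
#'
#' Plain numeric labels map to themselves; pooled labels of the form
#' `"2012-14"` (or with an en dash) map to the midpoint of the two years,
#' short second years being expanded within the first year's century.
#'
#' @param periods Character vector of period labels.
#' @return Named numeric vector (names = period labels).
#' @examples
#' period_year_map(c("1985", "2012-14", "2021"))
#' @export
period_year_map <- function(periods) {
  periods <- unique(as.character(periods))
  vapply(periods, function(p) {
    if (grepl("^[0-9]{4}$", p)) return(as.numeric(p))
    m <- regmatches(p, regexec("^([0-9]{4})[^0-9]+([0-9]{2,4})$", p))[[1]]
    if (length(m) == 3) {
      y1 <- as.numeric(m[2])
      y2 <- as.numeric(m[3])
      if (y2 < 100) y2 <- floor(y1 / 100) * 100 + y2
      return((y1 + y2) / 2)
    }
    NA_real_
  }, 0, USE.NAMES = TRUE)
}

#' Build the (year, distance) margin series
#'
#' One row per margin occurrence: its distance from the fixed reference
#' range center and the numeric year its survey period maps to. This is the
#' Gaussian-response input of the trend models.
#'
#' @param margins Margin occurrences (all periods), e.g. from
#'   [select_margins()]; must have `site_id`, `x`, `y`, `period`.
#' @param center [range_center()] tibble or numeric `c(x, y)`.
#' @param year_map Named numeric vector period -> year; default
#'   [period_year_map()] of the periods present.
#' @return Tibble with `year`, `distance`, `site_id`, `period`.
#' @export
build_margin_series <- function(margins, center, year_map = NULL) {
  year_map <- year_map %||% period_year_map(margins$period)
  pres <- unique(as.character(margins$period))
  bad <- pres[!(pres %in% names(year_map)) | is.na(year_map[pres])]
  if (length(bad) > 0) {
    abort(paste0("no year mapping for period(s): ", paste(bad, collapse = ", ")),
          class = "rangemargins_config_error")
  }
  site_distances(margins, center) |>
    dplyr::mutate(year = unname(year_map[as.character(.data$period)])) |>
    dplyr::select("year", "distance", "site_id", "period") |>
    dplyr::arrange(.data$year, dplyr::desc(.data$distance), .data$site_id)
}

#' Extract the range-periphery presence-absence series
#'
#' For each survey period, the minimum enclosing circle of that period's
#' margin occurrences delimits the range periphery; every survey record of
#' the period falling inside or on the circle (detections and
#' non-detections alike) is emitted with the period's numeric year. This is
#' the binomial-response input of the occupancy trend models.
#'
#' @param records All survey records (detections and non-detections).
#' @param margins Margin occurrences per period (e.g. [select_margins()]).
#' @param year_map Named numeric vector period -> year; default derived with
#'   [period_year_map()].
#' @param global_circle If TRUE a single circle over all margin occurrences
#'   is used for every period instead of one circle per period.
#' @param tol Inclusion tolerance in km on the circle boundary.
#' @return Tibble with `year`, `detected` (0/1), `site_id`, `period`.
#' @export
extract_periphery <- function(records, margins, year_map = NULL,
                              global_circle = FALSE, tol = 1e-9) {
  check_survey_records(records)
  year_map <- year_map %||% period_year_map(records$period)
  pres <- unique(as.character(margins$period))
  bad <- pres[!(pres %in% names(year_map)) | is.na(year_map[pres])]
  if (length(bad) > 0) {
    abort(paste0("no year mapping for period(s): ", paste(bad, collapse = ", ")),
          class = "rangemargins_config_error")
  }
  circ_all <- if (global_circle) min_enclosing_circle(margins) else NULL
  out <- lapply(unique(as.character(margins$period)), function(p) {
    mp <- margins[margins$period == p, , drop = FALSE]
    if (nrow(mp) == 0) return(NULL)
    circ <- circ_all %||% min_enclosing_circle(mp)
    recs <- records[records$period == p, , drop = FALSE]
    inside <- distance_km(recs$x, recs$y, circ$center_x, circ$center_y) <=
      circ$radius + tol
    sel <- recs[inside, , drop = FALSE]
    if (nrow(sel) == 0) {
      warn(sprintf("no survey records inside the periphery circle of period '%s'",
                   p))
    }
    tibble::tibble(year = unname(year_map[[p]]),
                   detected = as.integer(as.logical(sel$detected)),
                   site_id = sel$site_id, period = p)
  })
  dplyr::bind_rows(out)
}
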