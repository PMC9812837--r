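#' Read survey records from delimited text
#'
#' Expects columns `site_id`, `x`, `y`, `period`, `detected` (0/1 or
#' logical). Comment lines starting with `#` are ignored (output files of
#' this package carry a provenance header comment).
#'
#' @param path CSV file path.
#' @return Tibble of survey records.
#' @export
read_survey <- function(path) {
  rec <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!"site_id" %in% names(rec) && "id" %in% names(rec)) {
    rec <- dplyr::rename(rec, site_id = "id")
  }
  rec$period <- as.character(rec$period)
  bad <- which(!stats::complete.cases(rec[c("x", "y", "period", "detected")]))
  if (length(bad) > 0) {
    abort(paste0("invalid survey rows (missing fields) at line(s): ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "rangemargins_data_error")
  }
  check_survey_records(rec)
  rec
}

write_with_header <- function(df, path, config = NULL, seed = NULL) {
  # hash only the analysis-relevant fields, not volatile paths
  cfg <- config %||% list()
  cfg$out_dir <- NULL
  cfg$input <- NULL
  hdr <- sprintf("# rangemargins %s | seed: %s | config: %s",
                 as.character(utils::packageVersion("rangemargins")),
                 seed %||% "NA",
                 substr(rlang::hash(cfg), 1, 12))
  writeLines(hdr, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects the choices the pipeline stages need: the period-to-year map,
#' grid resolution, margin-selection rule, model suite, and seed.
#'
#' @param input Survey CSV path (for [run_margins()]).
#' @param out_dir Output directory (created if needed).
#' @param year_map Named numeric vector period -> year, or NULL to derive
#'   with [period_year_map()].
#' @param cell_size Grid cell size km; NULL disables resampling.
#' @param grid_origin Grid anchor `c(x, y)`.
#' @param rule,q,northern_only,k Margin-selection rule (see
#'   [select_margins()]).
#' @param reference_period Reference period for the range center.
#' @param forms Candidate model forms.
#' @param families Model families to fit: subset of
#'   `c("gaussian", "binomial")`.
#' @param ci_level Confidence level.
#' @param seed Integer seed used by every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, out_dir = tempfile("rangemargins_run_"),
                       year_map = NULL, cell_size = 10,
                       grid_origin = c(0, 0), rule = "auto", q = 0.95,
                       northern_only = TRUE, k = NULL,
                       reference_period = "1985", forms = trend_forms,
                       families = c("gaussian", "binomial"),
                       ci_level = 0.95, seed = 1L) {
  if (!is.null(cell_size) && cell_size <= 0) {
    abort("`cell_size` must be positive", class = "rangemargins_config_error")
  }
  families <- match.arg(families, c("gaussian", "binomial"),
                        several.ok = TRUE)
  structure(list(input = input, out_dir = out_dir, year_map = year_map,
                 cell_size = cell_size, grid_origin = grid_origin,
                 rule = rule, q = q, northern_only = northern_only, k = k,
                 reference_period = reference_period, forms = forms,
                 families = families, ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Generate synthetic survey input files
#'
#' Writes a synthetic spatial survey CSV plus a ground-truth JSON sidecar
#' into `config$out_dir` and prints a one-line summary of the planted
#' parameters.
#'
#' @param config A [run_config()].
#' @param design,params,occupancy,scatter_km Passed to
#'   [simulate_spatial_survey()].
#' @return Invisibly, a list with the file paths and the survey tibble.
#' @export
run_simulate <- function(config = run_config(), design = survey_design(),
                         params = trajectory_params(),
                         occupancy = occupancy_params(), scatter_km = 0) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (design$margin_sites < 2) {
    warn("margin_sites < 2: the margin series is under-determined for fitting")
  }
  survey <- simulate_spatial_survey(design, params = params,
                                    occupancy = occupancy,
                                    scatter_km = scatter_km,
                                    seed = config$seed)
  survey_path <- file.path(config$out_dir, "survey.csv")
  write_with_header(survey, survey_path, config, config$seed)
  truth_path <- file.path(config$out_dir, "truth.json")
  jsonlite::write_json(
    list(margin = attr(survey, "truth"),
         occupancy = unclass(occupancy),
         design = unclass(design), seed = config$seed),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf(
    "planted: psi = %s, slope_right = %s km/yr, sigma = %s km, %d periods",
    params$psi, params$slope_right, params$sigma, length(design$years)))
  invisible(list(survey = survey_path, truth = truth_path, data = survey))
}

#' Extract margin and periphery series from a survey file
#'
#' Composes the spatial stages: read, (optional) grid resampling, reference
#' range center, margin selection, margin-distance series, periphery
#' extraction. Writes `margin_series.csv`, `periphery_series.csv` and
#' `run_log.json` into `config$out_dir`.
#'
#' @param config A [run_config()] with `input` set (or `records` given).
#' @param records Survey tibble, overriding `config$input`.
#' @return Invisibly, list with `margins` and `periphery` tibbles plus the
#'   counts log.
#' @export
run_margins <- function(config, records = NULL) {
  records <- records %||% {
    if (is.null(config$input)) {
      abort("config$input is not set", class = "rangemargins_config_error")
    }
    read_survey(config$input)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  n0 <- nrow(records)
  if (!is.null(config$cell_size)) {
    records <- resample_to_grid(records, config$cell_size,
                                config$grid_origin, seed = config$seed)
  }
  ctr <- range_center(records, config$reference_period)
  margins <- select_margins(records, ctr, rule = config$rule, q = config$q,
                            northern_only = config$northern_only,
                            k = config$k,
                            reference_period = config$reference_period)
  empty <- setdiff(unique(records$period[as.logical(records$detected)]),
                   unique(margins$period))
  if (length(empty) > 0) {
    abort(paste0("no margin sites selected for period(s): ",
                 paste(empty, collapse = ", ")),
          class = "rangemargins_data_error")
  }
  year_map <- config$year_map %||% period_year_map(records$period)
  mseries <- build_margin_series(margins, ctr, year_map)
  pseries <- extract_periphery(records, margins, year_map)
  write_with_header(mseries, file.path(config$out_dir, "margin_series.csv"),
                    config, config$seed)
  write_with_header(pseries, file.path(config$out_dir,
                                       "periphery_series.csv"),
                    config, config$seed)
  log <- list(seed = config$seed, n_input = n0,
              n_resampled = nrow(records),
              center = list(x = ctr$x, y = ctr$y,
                            reference_period = ctr$reference_period),
              n_margin = nrow(mseries), n_periphery = nrow(pseries),
              rule = config$rule, q = config$q, k = config$k,
              cell_size = config$cell_size)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(margins = mseries, periphery = pseries, log = log,
                 center = ctr))
}

#' Fit the model suite to extracted series and write report tables
#'
#' For each requested family, fits the candidate forms, writes the AICc
#' comparison table, per-model parameter tables, the top model's predicted
#' trend with confidence band, and pseudo-score test results, as CSV/JSON
#' under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param margins,periphery Series tibbles; defaults read the CSVs
#'   `run_margins()` wrote into `config$out_dir`.
#' @return Invisibly, a named list per family with `table` (the
#'   `comparison_tbl`), `fits`, `pscore`, and `prediction`.
#' @export
run_fits <- function(config, margins = NULL, periphery = NULL) {
  read_series <- function(name) {
    p <- file.path(config$out_dir, name)
    if (!file.exists(p)) {
      abort(paste0("series file not found: ", p),
            class = "rangemargins_data_error")
    }
    readr::read_csv(p, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  }
  out <- list()
  for (fam in config$families) {
    dat <- if (fam == "gaussian") {
      margins %||% read_series("margin_series.csv")
    } else {
      periphery %||% read_series("periphery_series.csv")
    }
    if (length(unique(dat$year)) < 2) {
      abort(sprintf(
        "family '%s': only one distinct year; trend fitting refused", fam),
        class = "rangemargins_data_error")
    }
    tab <- compare_trends(dat, forms = config$forms, family = fam,
                          ci_level = config$ci_level)
    fits <- attr(tab, "fits")
    prefix <- file.path(config$out_dir, fam)
    write_with_header(tibble::as_tibble(tab),
                      paste0(prefix, "_comparison.csv"),
                      config, config$seed)
    partab <- dplyr::bind_rows(
      purrr::imap(fits, function(f, nm) {
        dplyr::mutate(tidy(f), model = nm, .before = 1)
      }))
    write_with_header(partab, paste0(prefix, "_parameters.csv"),
                      config, config$seed)
    ps <- dplyr::bind_rows(
      two_slope = pscore_test(dat, family = fam,
                              left_constrained_null = FALSE,
                              seed = config$seed),
      left_horizontal = pscore_test(dat, family = fam,
                                    left_constrained_null = TRUE,
                                    seed = config$seed),
      .id = "alternative")
    write_with_header(ps, paste0(prefix, "_pscore.csv"),
                      config, config$seed)
    top <- fits[[tab$model[1]]]
    pred <- predict_trend(top, level = config$ci_level)
    write_with_header(pred, paste0(prefix, "_prediction.csv"),
                      config, config$seed)
    jsonlite::write_json(
      purrr::map(fits, function(f) {
        list(form = f$form, family = f$family,
             coefficients = f$coefficients, psi = f$psi, psi_se = f$psi_se,
             psi_ci = c(f$psi_conf.low, f$psi_conf.high), sigma = f$sigma,
             nll = f$nll, n = f$n, np = f$np, k = f$k_aicc,
             converged = f$converged, n_iter = f$n_iter)
      }),
      paste0(prefix, "_fits.json"), auto_unbox = TRUE, digits = NA,
      null = "null", na = "null")
    out[[fam]] <- list(table = tab, fits = fits, pscore = ps,
                       prediction = pred)
  }
  invisible(out)
}
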