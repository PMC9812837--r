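# Run code with a locally-seeded RNG, restoring global state afterwards.
# All stochastic operations in the package go through this so that a `seed`
# argument makes them deterministic without clobbering the caller's RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_finite_xy <- function(x, y, what = "coordinates") {
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort(paste0("non-finite ", what, " are not allowed"),
          class = "rangemargins_data_error")
  }
  invisible(TRUE)
}

check_survey_records <- function(records) {
  needed <- c("site_id", "x", "y", "period", "detected")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("survey records lack column(s): ",
                 paste(missing, collapse = ", ")),
          class = "rangemargins_data_error")
  }
  stopifnot_finite_xy(records$x, records$y, "survey coordinates")
  if (!all(records$detected %in% c(0, 1, TRUE, FALSE))) {
    abort("`detected` must be 0/1 or logical",
          class = "rangemargins_data_error")
  }
  invisible(TRUE)
}

as_center_xy <- function(center) {
  if (is.data.frame(center)) {
    c(x = as.numeric(center$x[1]), y = as.numeric(center$y[1]))
  } else if (is.numeric(center) && length(center) >= 2) {
    c(x = center[[1]], y = center[[2]])
  } else {
    abort("`center` must be a range_center() tibble or a numeric (x, y) pair",
          class = "rangemargins_config_error")
  }
}
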