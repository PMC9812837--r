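#' Centroid of occurrence coordinates (the range center)
#'
#' The reference range center is the coordinate-wise arithmetic mean of a set
#' of occurrence locations, typically the detections of a chosen reference
#' survey period. Distances of later range-margin occurrences are measured
#' from this fixed point.
#'
#' @param data A data frame with numeric columns `x` and `y` (planar
#'   projected coordinates in km). If a `detected` column is present, only
#'   detections are used; if a `period` column is present and
#'   `reference_period` is given, only that period's rows are used.
#' @param reference_period Optional period label to subset on before
#'   averaging (default `"1985"` when a `period` column exists, otherwise
#'   ignored).
#' @return A one-row tibble with columns `x`, `y`, `reference_period`, `n`.
#' @examples
#' range_center(tibble::tibble(x = c(0, 3, 0), y = c(0, 0, 3)))
#' @export
range_center <- function(data, reference_period = "1985") {
  pts <- data
  if ("period" %in% names(pts) && !is.null(reference_period) &&
      any(pts$period == reference_period)) {
    pts <- dplyr::filter(pts, .data$period == reference_period)
  } else {
    reference_period <- NA_character_
  }
  if ("detected" %in% names(pts)) {
    pts <- dplyr::filter(pts, as.logical(.data$detected))
  }
  if (nrow(pts) < 1) {
    abort("range_center() needs at least one occurrence point",
          class = "rangemargins_insufficient_data")
  }
  stopifnot_finite_xy(pts$x, pts$y)
  tibble::tibble(
    x = mean(pts$x), y = mean(pts$y),
    reference_period = as.character(reference_period), n = nrow(pts)
  )
}

#' Euclidean distance between planar points, in km
#'
#' @param ax,ay,bx,by Coordinates (km, planar projection). Vectorized.
#' @return Numeric vector of distances.
#' @examples
#' distance_km(0, 0, 3, 4) # 5
#' @export
distance_km <- function(ax, ay, bx, by) {
  stopifnot_finite_xy(c(ax, bx), c(ay, by))
  sqrt((ax - bx)^2 + (ay - by)^2)
}

#' Add distance-from-center to survey records
#'
#' @param data Data frame with `x`, `y` columns.
#' @param center A [range_center()] tibble or numeric `c(x, y)`.
#' @return `data` with a `distance` column (km from `center`).
#' @export
site_distances <- function(data, center) {
  ctr <- as_center_xy(center)
  dplyr::mutate(data,
                distance = distance_km(.data$x, .data$y, ctr[["x"]], ctr[["y"]]))
}

# Circle through three points; NULL if (nearly) collinear.
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

circle_from_boundary <- function(bd) {
  nb <- length(bd)
  if (nb == 0) return(c(0, 0, 0))
  if (nb == 1) return(c(bd[[1]], 0))
  if (nb == 2) {
    p <- bd[[1]]; q <- bd[[2]]
    c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
  } else {
    cc <- circumcircle(bd[[1]], bd[[2]], bd[[3]])
    if (is.null(cc)) {
      # collinear support: fall back to widest diameter pair
      best <- c(0, 0, -1)
      for (i in 1:2) for (j in (i + 1):3) {
        p <- bd[[i]]; q <- bd[[j]]
        r <- sqrt(sum((p - q)^2)) / 2
        if (r > best[3]) best <- c((p + q) / 2, r)
      }
      best
    } else cc
  }
}

in_circle <- function(pt, circ, tol = 1e-9) {
  sqrt((pt[1] - circ[1])^2 + (pt[2] - circ[2])^2) <=
    circ[3] * (1 + 1e-12) + tol
}

# Welzl's move-to-front algorithm, iterative-in-spirit recursion on small n.
welzl <- function(pts, bd) {
  if (length(pts) == 0 || length(bd) == 3) {
    return(circle_from_boundary(bd))
  }
  p <- pts[[length(pts)]]
  circ <- welzl(pts[-length(pts)], bd)
  if (in_circle(p, circ)) return(circ)
  welzl(pts[-length(pts)], c(bd, list(p)))
}

#' Minimum enclosing circle of a point set
#'
#' Computes the smallest circle containing all points (Welzl's algorithm).
#' The minimum enclosing circle is unique, so the result does not depend on
#' input order. Used to delimit the range-periphery sampling region around
#' each period's margin occurrences.
#'
#' @param data Data frame with numeric `x`, `y` columns, or a two-column
#'   matrix.
#' @return One-row tibble with `center_x`, `center_y`, `radius` (km) and the
#'   generating point count `n`.
#' @examples
#' min_enclosing_circle(tibble::tibble(x = c(0, 4), y = c(0, 0)))
#' @export
min_enclosing_circle <- function(data) {
  if (is.matrix(data)) data <- tibble::tibble(x = data[, 1], y = data[, 2])
  if (nrow(data) < 1) {
    abort("min_enclosing_circle() needs at least one point",
          class = "rangemargins_insufficient_data")
  }
  stopifnot_finite_xy(data$x, data$y)
  pts <- unique(purrr::map2(data$x, data$y, c))
  # deterministic shuffle keeps expected O(n) behaviour without touching RNG
  if (length(pts) > 3) {
    idx <- order(vapply(pts, function(p) sum(p * c(sin(1), cos(1))), 0))
    pts <- pts[idx]
  }
  circ <- welzl(pts, list())
  tibble::tibble(center_x = circ[1], center_y = circ[2],
                 radius = circ[3], n = nrow(data))
}
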