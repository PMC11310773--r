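# Ground reference ("base") plane estimation. Crop heights are vertical
# distances from this plane, which is stored as z = a*x + b*y + c in the
# projected (UTM-like) frame and reused across capture dates as an absolute
# reference. Two estimation routes: least-squares over bare-ground
# rectangles, or a slope-constrained fit along ridge crest lines for crops
# grown on raised beds.

#' Construct a base plane
#'
#' @param a,b slopes (m elevation per m easting / northing).
#' @param c offset (m).
#' @param crs_id EPSG code of the projected frame.
#' @return a `base_plane`.
#' @export
base_plane <- function(a, b, c, crs_id = NA_integer_) {
  if (!all(is.finite(c(a, b, c)))) {
    stop_plotpheno("bad_plane", "plane coefficients must be finite")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 crs_id = as.integer(crs_id)),
            class = "base_plane")
}

#' @export
print.base_plane <- function(x, ...) {
  cat(sprintf("<base_plane> z = %.6g x + %.6g y + %.6g (EPSG:%s)\n",
              x$a, x$b, x$c, x$crs_id))
  invisible(x)
}

plane_eval <- function(plane, x, y) plane$a * x + plane$b * y + plane$c

#' Least-squares plane through 3-D points
#'
#' Minimizes the sum of squared VERTICAL residuals
#' `sum((z - a*x - b*y - c)^2)`.
#'
#' @param points data frame or matrix with columns x, y, z (m).
#' @param crs_id EPSG code recorded on the result.
#' @return a `base_plane`.
#' @export
fit_lsq_plane <- function(points, crs_id = NA_integer_) {
  pts <- as.data.frame(points)
  if (nrow(pts) < 3L) {
    stop_plotpheno("too_few_points",
                   "plane fit needs at least 3 points, got ", nrow(pts))
  }
  # center coordinates before the fit: UTM eastings/northings are ~1e5-1e7 m
  # and would otherwise dominate the normal equations' conditioning
  mx <- mean(pts$x); my <- mean(pts$y)
  fit <- stats::lm(z ~ I(x - mx) + I(y - my), data = pts)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop_plotpheno("degenerate_points",
                   "points are collinear; plane is undetermined")
  }
  base_plane(a = cf[[2L]], b = cf[[3L]],
             c = cf[[1L]] - cf[[2L]] * mx - cf[[3L]] * my, crs_id = crs_id)
}

#' Shift a plane down to the deepest retained point
#'
#' For each point, the vertical downward distance below the plane is
#' `d = (a*x + b*y + c) - z` (positive below). The `floor(f * N)` deepest
#' points are discarded as local anomalies (pits, reconstruction noise), so
#' at most an `f`-share of the points can end up strictly below the result;
#' the plane is then translated down so it touches the deepest retained
#' point. If no retained point lies below, the plane is returned unchanged
#' (never shifted upward). Slopes are untouched.
#'
#' @param plane a `base_plane`.
#' @param points data frame/matrix with columns x, y, z.
#' @param exclude_fraction proportion of deepest points discarded, in
#'   `[0, 1)`; default 0.05.
#' @return the shifted `base_plane`.
#' @export
shift_to_base <- function(plane, points, exclude_fraction = 0.05) {
  pts <- as.data.frame(points)
  n <- nrow(pts)
  if (n == 0L) stop_plotpheno("too_few_points", "no points to shift to")
  if (exclude_fraction < 0 || exclude_fraction >= 1) {
    stop_plotpheno("bad_fraction", "exclude_fraction must be in [0, 1)")
  }
  d <- plane_eval(plane, pts$x, pts$y) - pts$z
  n_excl <- min(floor(exclude_fraction * n + 1e-9), n - 1L)
  # ties: deeper first, then input order (order() is stable)
  keep <- if (n_excl > 0L) sort(order(-d)[(n_excl + 1L):n]) else seq_len(n)
  d_star <- max(d[keep])
  if (d_star > 0) plane$c <- plane$c - d_star
  plane
}

#' Vertical height of a point above a plane
#'
#' @param plane a `base_plane`.
#' @param x,y,z point coordinates (m); vectors of equal length.
#' @return `z - (a*x + b*y + c)` (m); may be negative.
#' @export
height_above <- function(plane, x, y, z) z - plane_eval(plane, x, y)

# Gather (x, y, z) of valid DSM pixel centers inside any of the polygons.
dsm_points_in_polygons <- function(dsm, polygons) {
  mask <- matrix(FALSE, dsm$grid$n_rows, dsm$grid$n_cols)
  for (poly in polygons) mask <- mask | pixels_in_polygon(dsm$grid, poly)
  mask <- mask & dsm$valid
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  ctr <- pixel_to_world(dsm$grid, idx[, 1L] - 1L, idx[, 2L] - 1L)
  data.frame(x = ctr[, 1L], y = ctr[, 2L], z = dsm$z[idx])
}

#' Base plane from bare-ground rectangles
#'
#' Collects valid DSM pixel centers inside the user-designated bare-ground
#' rectangles, fits the least-squares plane and shifts it to the deepest
#' retained point ([shift_to_base()], excluding the deepest 5%).
#'
#' @param dsm a `surface_model`.
#' @param rectangles list of polygon vertex matrices (world coordinates);
#'   any simple polygons are accepted.
#' @param exclude_fraction passed to [shift_to_base()].
#' @return a `base_plane`.
#' @export
base_plane_from_rectangles <- function(dsm, rectangles,
                                       exclude_fraction = 0.05) {
  pts <- dsm_points_in_polygons(dsm, rectangles)
  if (nrow(pts) < 3L) {
    stop_plotpheno("too_few_points",
                   "fewer than 3 valid DSM pixels inside the ground regions")
  }
  plane <- fit_lsq_plane(pts, crs_id = dsm$grid$crs_id)
  shift_to_base(plane, pts, exclude_fraction)
}

# angle of a direction in [0, 180) degrees
line_angle_deg <- function(p1, p2) {
  (atan2(p2[2L] - p1[2L], p2[1L] - p1[1L]) * 180 / pi) %% 180
}

#' Base plane from ridge crest lines
#'
#' For crops grown on raised beds, narrow bare-ground strips give unstable
#' cross-slopes; this route instead samples the DSM along user-designated
#' crest lines and constrains the plane so its slope NORMAL to the line
#' direction is exactly zero. Valid pixels whose centers lie within
#' `half_width` of a segment are sampled; elevation is regressed on the
#' along-line coordinate with a shared slope and per-segment intercepts
#' (averaged), and the result is shifted with [shift_to_base()].
#'
#' @param dsm a `surface_model`.
#' @param lines list of `list(p1 = c(x, y), p2 = c(x, y), half_width = m)`;
#'   segments must be parallel within 5 degrees. `half_width` defaults to
#'   one pixel.
#' @param exclude_fraction passed to [shift_to_base()].
#' @return a `base_plane` with zero line-normal slope.
#' @export
base_plane_from_lines <- function(dsm, lines, exclude_fraction = 0.05) {
  if (length(lines) == 0L) {
    stop_plotpheno("too_few_points", "no lines given")
  }
  angles <- vapply(lines, function(l) line_angle_deg(l$p1, l$p2), 1)
  spread <- diff(range((angles - angles[1L] + 90) %% 180))
  if (spread > 5) {
    stop_plotpheno("non_parallel_lines",
                   "crest lines must be parallel within 5 degrees (spread ",
                   format(spread, digits = 3), " deg)")
  }
  # mean direction as a unit vector (angles are near-parallel by now)
  th <- mean((angles - angles[1L] + 90) %% 180 - 90 + angles[1L]) * pi / 180
  u <- c(cos(th), sin(th))

  samples <- list()
  for (i in seq_along(lines)) {
    l <- lines[[i]]
    hw <- if (is.null(l$half_width)) {
      max(dsm$grid$pixel_size_x, dsm$grid$pixel_size_y)
    } else l$half_width
    # rectangle of half-width hw around the segment
    d <- l$p2 - l$p1
    len <- sqrt(sum(d^2))
    dh <- d / len
    nh <- c(-dh[2L], dh[1L])
    rect <- rbind(l$p1 + hw * nh, l$p2 + hw * nh,
                  l$p2 - hw * nh, l$p1 - hw * nh)
    pts <- dsm_points_in_polygons(dsm, list(rect))
    if (nrow(pts) > 0L) {
      pts$t <- pts$x * u[1L] + pts$y * u[2L]
      pts$seg <- i
      samples[[length(samples) + 1L]] <- pts
    }
  }
  pts <- do.call(rbind, samples)
  if (is.null(pts) || nrow(pts) < 2L || length(unique(pts$t)) < 2L) {
    stop_plotpheno("too_few_points",
                   "need at least 2 distinct sample stations along the lines")
  }
  t0 <- mean(pts$t)
  # shared slope, one intercept per segment (ridge crests share grade but
  # not offset noise); intercepts averaged after projecting to t = 0
  seg_ind <- outer(pts$seg, unique(pts$seg), `==`) * 1
  fit <- stats::lm.fit(cbind(seg_ind, pts$t - t0), pts$z)
  cf <- stats::coef(fit)
  slope <- cf[[length(cf)]]
  if (!is.finite(slope)) {
    stop_plotpheno("degenerate_points", "along-line regression is degenerate")
  }
  intercept <- mean(cf[-length(cf)]) - slope * t0
  plane <- base_plane(a = slope * u[1L], b = slope * u[2L], c = intercept,
                      crs_id = dsm$grid$crs_id)
  shift_to_base(plane, pts, exclude_fraction)
}

#' Save / load a base plane as JSON
#'
#' The serialized plane is the absolute ground reference shared by all
#' capture dates of a project.
#'
#' @param plane a `base_plane`.
#' @param path JSON file path.
#' @return `write_base_plane`: the path, invisibly. `read_base_plane`: a
#'   `base_plane`.
#' @export
write_base_plane <- function(plane, path) {
  jsonlite::write_json(list(a = plane$a, b = plane$b, c = plane$c,
                            crs = plane$crs_id),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_base_plane
#' @export
read_base_plane <- function(path) {
  obj <- jsonlite::read_json(path)
  base_plane(obj$a, obj$b, obj$c, crs_id = obj$crs %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
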