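# Georeferenced grids, raster containers and world<->pixel mapping.
#
# Conventions: north-up rasters; the world origin is the TOP-LEFT corner of
# the raster; raster indices are 0-based (row, col) with y decreasing as the
# row index grows. Pixel footprints are half-open, [left, right) in x and
# (bottom, top] in y, so a point on a shared edge belongs to the pixel with
# the larger index.

stop_plotpheno <- function(class, ...) {
  stop(errorCondition(paste0(...),
                      class = c(paste0("plotpheno_", class), "plotpheno_error"),
                      call = sys.call(-1)))
}

warn_plotpheno <- function(class, ...) {
  warning(warningCondition(paste0(...),
                           class = c(paste0("plotpheno_", class),
                                     "plotpheno_warning")))
}

# EPSG codes in 4000-4999 are geographic (degree) systems; everything else
# accepted here is assumed projected/metric. A full CRS registry is out of
# scope -- UTM zones (326xx/327xx) are the expected input.
is_geographic_epsg <- function(crs_id) {
  !is.na(crs_id) && crs_id >= 4000L && crs_id <= 4999L
}

#' Construct a georeferenced raster grid
#'
#' Describes the geometry of a north-up raster in a projected (metric) CRS:
#' world coordinates of the top-left corner, ground sampling distance, and
#' pixel counts.
#'
#' @param origin_x,origin_y world coordinates (m) of the raster's top-left
#'   corner.
#' @param pixel_size_x,pixel_size_y ground sampling distance (m/pixel), both
#'   positive; y increases downward in pixel space.
#' @param n_cols,n_rows raster dimensions (pixels).
#' @param crs_id EPSG code of a projected CRS (e.g. 32654 for UTM 54N).
#'   Geographic (degree) codes are rejected.
#' @return a `geo_grid` object.
#' @export
geo_grid <- function(origin_x, origin_y, pixel_size_x, pixel_size_y,
                     n_cols, n_rows, crs_id) {
  if (!is.finite(pixel_size_x) || !is.finite(pixel_size_y) ||
      pixel_size_x <= 0 || pixel_size_y <= 0) {
    stop_plotpheno("bad_grid", "pixel sizes must be positive")
  }
  if (n_cols < 1L || n_rows < 1L) {
    stop_plotpheno("bad_grid", "raster dimensions must be at least 1x1")
  }
  crs_id <- as.integer(crs_id)
  if (is.na(crs_id)) stop_plotpheno("missing_crs", "grid has no CRS id")
  if (is_geographic_epsg(crs_id)) {
    stop_plotpheno("geographic_crs", "EPSG:", crs_id,
                   " is a geographic (degree) CRS; a projected metric CRS ",
                   "is required")
  }
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 pixel_size_x = as.numeric(pixel_size_x),
                 pixel_size_y = as.numeric(pixel_size_y),
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 crs_id = crs_id),
            class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf("<geo_grid> %d x %d px, %.4g x %.4g m/px, origin (%.3f, %.3f), EPSG:%d\n",
              x$n_rows, x$n_cols, x$pixel_size_x, x$pixel_size_y,
              x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_cols == b$n_cols && a$n_rows == b$n_rows && a$crs_id == b$crs_id &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$pixel_size_x - b$pixel_size_x) < tol &&
    abs(a$pixel_size_y - b$pixel_size_y) < tol
}

grid_extent <- function(grid) {
  c(xmin = grid$origin_x,
    xmax = grid$origin_x + grid$n_cols * grid$pixel_size_x,
    ymin = grid$origin_y - grid$n_rows * grid$pixel_size_y,
    ymax = grid$origin_y)
}

#' Map world coordinates to 0-based pixel indices
#'
#' Returns the (row, col) of the pixel whose footprint contains each point.
#' Footprints are half-open so a point on a shared edge belongs to the pixel
#' with the larger index. Indices may fall outside the raster; callers
#' bound-check.
#'
#' @param grid a `geo_grid`.
#' @param x,y world coordinates (m); vectors of equal length.
#' @return a two-column integer matrix with columns `row`, `col`.
#' @export
world_to_pixel <- function(grid, x, y) {
  # the 1e-9-pixel nudge keeps points that sit exactly on a shared edge in
  # the larger-index pixel under floating-point rounding
  col <- floor((x - grid$origin_x) / grid$pixel_size_x + 1e-9)
  row <- floor((grid$origin_y - y) / grid$pixel_size_y + 1e-9)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Map 0-based pixel indices to the world coordinates of pixel centers
#'
#' @param grid a `geo_grid`.
#' @param row,col 0-based pixel indices (vectors of equal length).
#' @return a two-column matrix with columns `x`, `y` (pixel centers, m).
#' @export
pixel_to_world <- function(grid, row, col) {
  cbind(x = grid$origin_x + (col + 0.5) * grid$pixel_size_x,
        y = grid$origin_y - (row + 0.5) * grid$pixel_size_y)
}

#' Orthomosaic RGB raster
#'
#' @param grid a `geo_grid`.
#' @param r,g,b numeric matrices (`n_rows` x `n_cols`) of 0-255 intensities.
#' @param valid logical validity mask (alpha/nodata); invalid pixels are
#'   excluded from all statistics.
#' @return an `ortho_image`.
#' @export
ortho_image <- function(grid, r, g, b, valid = NULL) {
  dims <- c(grid$n_rows, grid$n_cols)
  for (band in list(r, g, b)) {
    if (!identical(dim(band), as.integer(dims))) {
      stop_plotpheno("bad_raster", "band dimensions must equal grid dimensions")
    }
  }
  if (is.null(valid)) valid <- matrix(TRUE, dims[1L], dims[2L])
  structure(list(grid = grid, r = r, g = g, b = b, valid = valid),
            class = "ortho_image")
}

#' Single-band elevation raster (digital surface model)
#'
#' @param grid a `geo_grid`.
#' @param z numeric matrix (`n_rows` x `n_cols`) of elevations (m above
#'   datum).
#' @param valid logical mask; nodata pixels are excluded from all statistics.
#' @return a `surface_model`.
#' @export
surface_model <- function(grid, z, valid = NULL) {
  dims <- as.integer(c(grid$n_rows, grid$n_cols))
  if (!identical(dim(z), dims)) {
    stop_plotpheno("bad_raster", "elevation dimensions must equal grid dimensions")
  }
  if (is.null(valid)) valid <- is.finite(z)
  structure(list(grid = grid, z = z, valid = valid),
            class = "surface_model")
}

#' Co-registered orthomosaic + DSM pair
#'
#' @param ortho an `ortho_image`.
#' @param dsm a `surface_model` on the same grid.
#' @param capture_date a date label (character).
#' @return a `raster_pair`.
#' @export
raster_pair <- function(ortho, dsm, capture_date = NA_character_) {
  if (!grids_equal(ortho$grid, dsm$grid)) {
    stop_plotpheno("bad_raster", "orthomosaic and DSM grids must agree")
  }
  structure(list(ortho = ortho, dsm = dsm,
                 capture_date = as.character(capture_date)),
            class = "raster_pair")
}

# Nearest-neighbor resampling of a DSM onto a target grid: each target pixel
# center looks up the source pixel containing it; centers outside the source
# extent become nodata. Nearest-neighbor avoids inventing elevations.
resample_dsm_nearest <- function(dsm, target_grid) {
  rows <- rep(seq_len(target_grid$n_rows) - 1L, times = target_grid$n_cols)
  cols <- rep(seq_len(target_grid$n_cols) - 1L, each = target_grid$n_rows)
  ctr <- pixel_to_world(target_grid, rows, cols)
  src <- world_to_pixel(dsm$grid, ctr[, 1L], ctr[, 2L])
  inside <- src[, 1L] >= 0L & src[, 1L] < dsm$grid$n_rows &
    src[, 2L] >= 0L & src[, 2L] < dsm$grid$n_cols
  z <- rep(NA_real_, length(rows))
  ok <- rep(FALSE, length(rows))
  idx <- src[inside, 1L] + 1L + src[inside, 2L] * dsm$grid$n_rows
  z[inside] <- dsm$z[idx]
  ok[inside] <- dsm$valid[idx]
  zm <- matrix(NA_real_, target_grid$n_rows, target_grid$n_cols)
  vm <- matrix(FALSE, target_grid$n_rows, target_grid$n_cols)
  zm[cbind(rows + 1L, cols + 1L)] <- z
  vm[cbind(rows + 1L, cols + 1L)] <- ok
  surface_model(target_grid, zm, vm)
}

#' Read a co-registered orthomosaic/DSM GeoTIFF pair
#'
#' Loads both rasters and puts them on one common grid: when the grids
#' differ, the DSM is resampled to the orthomosaic grid by nearest-neighbor.
#' Alpha and nodata markers propagate into the validity masks.
#'
#' @param ortho_path path to the RGB orthomosaic GeoTIFF.
#' @param dsm_path path to the single-band float DSM GeoTIFF.
#' @param capture_date optional date label attached to the pair.
#' @return a `raster_pair` on the orthomosaic grid.
#' @export
read_raster_pair <- function(ortho_path, dsm_path, capture_date = NA_character_) {
  ortho <- read_ortho_geotiff(ortho_path)
  dsm <- read_dsm_geotiff(dsm_path)
  if (ortho$grid$crs_id != dsm$grid$crs_id) {
    stop_plotpheno("crs_mismatch", "orthomosaic and DSM CRS differ (EPSG:",
                   ortho$grid$crs_id, " vs EPSG:", dsm$grid$crs_id, ")")
  }
  ea <- grid_extent(ortho$grid)
  eb <- grid_extent(dsm$grid)
  if (ea["xmin"] >= eb["xmax"] || eb["xmin"] >= ea["xmax"] ||
      ea["ymin"] >= eb["ymax"] || eb["ymin"] >= ea["ymax"]) {
    stop_plotpheno("disjoint_extents",
                   "orthomosaic and DSM extents do not overlap")
  }
  if (!grids_equal(ortho$grid, dsm$grid)) {
    dsm <- resample_dsm_nearest(dsm, ortho$grid)
  }
  raster_pair(ortho, dsm, capture_date)
}

# Vectorized even-odd (ray casting) point-in-polygon with inclusive
# boundaries: points within `tol` of an edge count as inside.
points_in_ring <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  if (n > 1L && vx[1L] == vx[n] && vy[1L] == vy[n]) {
    vx <- vx[-n]; vy <- vy[-n]; n <- n - 1L
  }
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- rep(FALSE, length(px))
      flip[crosses] <- px[crosses] < xint
      inside <- xor(inside, flip)
    }
    # distance from points to segment (x1,y1)-(x2,y2)
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    }
    on_edge <- on_edge | d2 <= tol * tol
    j <- i
  }
  inside | on_edge
}

ring_signed_area <- function(x, y) {
  n <- length(x)
  if (n > 1L && x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Rasterize a polygon: mask of pixels whose center falls inside
#'
#' Marks exactly those pixels whose CENTER lies inside or on the boundary of
#' the polygon (center-in-polygon membership, the usual zonal-statistics
#' default).
#'
#' @param grid a `geo_grid`.
#' @param polygon a two-column matrix of world vertices (a simple closed
#'   ring; the closing vertex may be present or omitted).
#' @return a logical `n_rows` x `n_cols` matrix.
#' @export
pixels_in_polygon <- function(grid, polygon) {
  polygon <- as.matrix(polygon)
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (abs(ring_signed_area(polygon[, 1L], polygon[, 2L])) < 1e-12) {
    warn_plotpheno("degenerate_polygon", "polygon has zero area; empty mask")
    return(mask)
  }
  # restrict to the polygon's bounding box in pixel space
  ext <- grid_extent(grid)
  xr <- range(polygon[, 1L]); yr <- range(polygon[, 2L])
  if (xr[1L] > ext["xmax"] || xr[2L] < ext["xmin"] ||
      yr[1L] > ext["ymax"] || yr[2L] < ext["ymin"]) {
    return(mask)
  }
  tl <- world_to_pixel(grid, xr[1L], yr[2L])
  br <- world_to_pixel(grid, xr[2L], yr[1L])
  r0 <- max(0L, tl[1L, "row"]); r1 <- min(grid$n_rows - 1L, br[1L, "row"])
  c0 <- max(0L, tl[1L, "col"]); c1 <- min(grid$n_cols - 1L, br[1L, "col"])
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  ctr <- pixel_to_world(grid, rows, cols)
  hit <- points_in_ring(ctr[, 1L], ctr[, 2L], polygon[, 1L], polygon[, 2L])
  mask[cbind(rows + 1L, cols + 1L)] <- hit
  mask
}
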