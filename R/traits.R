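# Per-plot trait extraction: percentile crop-height metrics, per-class
# cover fractions, and the volume index (mean canopy height per unit ground
# area), all measured against the base plane.

#' Percentile height metrics
#'
#' HeightP is the maximum per-pixel height above the base plane after
#' discarding the `ceiling((1 - P/100) * N)` tallest pixels, for
#' P = 100, 95, 90, 80. The trimmed maxima are robust to isolated spikes in
#' the surface model. Negative heights stay in the distribution (maxima
#' ignore them anyway).
#'
#' @param heights numeric vector of per-pixel heights above the base plane
#'   (m); `NA`s (nodata) are dropped.
#' @return a `height_metrics` list with `h100`, `h95`, `h90`, `h80` (m).
#' @export
height_metrics <- function(heights) {
  h <- heights[!is.na(heights)]
  n <- length(h)
  if (n == 0L) stop_plotpheno("no_heights", "no valid heights")
  sorted <- sort(h, decreasing = TRUE)
  pick <- function(p) {
    # the 1e-9 guard keeps ceiling() exact when (1 - p/100) * n is a whole
    # number up to floating-point error
    k <- min(ceiling((1 - p / 100) * n - 1e-9), n - 1L)
    sorted[k + 1L]
  }
  structure(list(h100 = sorted[1L], h95 = pick(95), h90 = pick(90),
                 h80 = pick(80)),
            class = "height_metrics")
}

#' Volume index of a plot
#'
#' Sum of vegetation-pixel heights divided by the total number of (valid)
#' plot pixels: the average canopy height over the plot's ground area, in m
#' (equivalently cm^3/cm^2 when expressed in cm). Vegetation heights below
#' the base plane contribute zero so soil pits cannot subtract volume.
#'
#' @param heights matrix (or vector) of per-pixel heights (m).
#' @param vegetation_mask logical mask of vegetation pixels (subset of
#'   `plot_mask`).
#' @param plot_mask logical mask of the (valid) plot pixels.
#' @return volume index in meters.
#' @export
volume_index <- function(heights, vegetation_mask, plot_mask) {
  n_plot <- sum(plot_mask)
  if (n_plot == 0L) stop_plotpheno("empty_plot", "empty plot mask")
  hv <- heights[vegetation_mask & plot_mask]
  hv <- hv[!is.na(hv)]
  sum(pmax(hv, 0)) / n_plot
}

#' Analyze one microplot on one capture date
#'
#' Trims the plot margin, rasterizes it on the pair's grid, measures
#' per-pixel heights above the base plane, classifies the pixels with the
#' coverage model, and assembles the trait record. Height metrics use ALL
#' valid pixels in the trimmed plot (not only vegetation); coverage and
#' class fractions use the classified pixels; the volume index uses the
#' vegetation mask over the valid plot pixels.
#'
#' @param pair a `raster_pair`.
#' @param plot a `microplot`.
#' @param plane the `base_plane` ground reference.
#' @param model a `coverage_model`.
#' @param margin_fraction proportion of the plot trimmed away (default 0).
#' @param margin_side which dimension to trim (see [trim_margin()]).
#' @param heights_on_vegetation if `TRUE`, restrict the height metrics to
#'   vegetation-classified pixels (off by default; the standard metrics use
#'   the full height distribution of the plot).
#' @return a `plot_traits` list.
#' @export
analyze_plot <- function(pair, plot, plane, model,
                         margin_fraction = 0, margin_side = "width",
                         heights_on_vegetation = FALSE) {
  stopifnot(inherits(pair, "raster_pair"), inherits(plot, "microplot"))
  trimmed <- if (margin_fraction > 0) {
    trim_margin(plot, margin_fraction, margin_side)
  } else plot
  grid <- pair$dsm$grid
  mask <- pixels_in_polygon(grid, trimmed$polygon)
  n_total <- sum(mask)
  if (n_total == 0L) {
    stop_plotpheno("plot_outside_raster", "plot ", plot$plot_id,
                   " covers no raster pixels")
  }
  valid <- mask & pair$dsm$valid & pair$ortho$valid
  n_valid <- sum(valid)
  if (n_valid == 0L) {
    stop_plotpheno("no_valid_pixels", "plot ", plot$plot_id,
                   " has no valid pixels")
  }
  idx <- which(valid, arr.ind = TRUE)
  ctr <- pixel_to_world(grid, idx[, 1L] - 1L, idx[, 2L] - 1L)
  hts <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  hts[valid] <- height_above(plane, ctr[, 1L], ctr[, 2L], pair$dsm$z[valid])

  cmap <- classify_pixels(model, pair$ortho, valid)
  fr <- class_fractions(cmap, model)
  veg_idx <- which(model$classes %in% model$vegetation_classes)
  veg_mask <- !is.na(cmap) & matrix(cmap %in% veg_idx, nrow(cmap), ncol(cmap))

  hm <- if (heights_on_vegetation && sum(veg_mask) > 0L) {
    height_metrics(hts[veg_mask])
  } else height_metrics(hts[valid])
  vi <- volume_index(hts, veg_mask, valid)

  structure(list(plot_id = plot$plot_id, capture_date = pair$capture_date,
                 heights = hm, class_fractions = fr$fractions,
                 coverage = fr$coverage, volume_index = vi,
                 n_pixels_total = n_total, n_pixels_valid = n_valid),
            class = "plot_traits")
}
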