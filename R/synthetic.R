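# Synthetic field generator: raster pairs with a known ground plane,
# optional triangular-profile ridging, canopies of known height and cover
# fraction, and separable crop/soil colors, plus matching plot Shapefiles,
# ground regions and training samples. Every downstream module is testable
# against the generator's closed-form ground truth.

#' Specify a synthetic phenotyping field
#'
#' The defaults emulate a small ridged/flat trial: a sloped ground plane
#' with 5 mm Gaussian surface noise, three 3 x 2.25 m plots, a 0.5 m canopy
#' covering 30% of each plot, and crop/soil color distributions separated
#' by at least 6 standard deviations so the color classifier's task is
#' well-posed.
#'
#' @param pixel_size ground sampling distance (m/pixel).
#' @param crs_id EPSG code of the projected CRS.
#' @param origin_x,origin_y world coordinates of the field's top-left
#'   corner.
#' @param ground_a,ground_b,ground_c ground plane slopes (m/m) and the
#'   elevation (m) at the field origin; the plane is
#'   `z = a (x - origin_x) + b (y - origin_y) + c`.
#' @param noise_sd per-pixel Gaussian elevation noise (m).
#' @param ridges `NULL` for a flat field, or
#'   `list(spacing = m, height = m)` for triangular-profile ridges whose
#'   crests run along the y axis (crop rows).
#' @param plots a `grid_spec` for the microplots; must fit inside the
#'   field.
#' @param margin bare-ground margin around the plot grid (m).
#' @param canopy_height canopy elevation above the local ground reference
#'   (crest level when ridged) (m).
#' @param cover_fraction fraction of each plot covered by canopy, in
#'   `[0, 1]`.
#' @param canopy_shape `"rectangle"` (concentric rectangle of the right
#'   area) or `"disc"` (centered disc).
#' @param crop_color,soil_color RGB means (0-255).
#' @param color_sd per-channel color standard deviation.
#' @param seed RNG seed; everything derives deterministically from it.
#' @return a `field_spec`.
#' @export
field_spec <- function(pixel_size = 0.05, crs_id = 32654L,
                       origin_x = 500000, origin_y = 4000000,
                       ground_a = 0.01, ground_b = 0.02, ground_c = 100,
                       noise_sd = 0.005, ridges = NULL,
                       plots = NULL, margin = 1,
                       canopy_height = 0.5, cover_fraction = 0.30,
                       canopy_shape = c("rectangle", "disc"),
                       crop_color = c(60, 140, 60),
                       soil_color = c(150, 110, 80),
                       color_sd = 12, seed = 1L) {
  canopy_shape <- match.arg(canopy_shape)
  if (cover_fraction < 0 || cover_fraction > 1) {
    stop_plotpheno("bad_spec", "cover_fraction must be in [0, 1]")
  }
  if (noise_sd < 0) stop_plotpheno("bad_spec", "noise sd must be >= 0")
  sep <- sqrt(sum((crop_color - soil_color)^2))
  if (sep < 6 * color_sd) {
    warn_plotpheno("colors_overlap",
                   "crop/soil color separation ", round(sep, 1),
                   " is below 6 sd (", 6 * color_sd, ")")
  }
  if (is.null(plots)) {
    plots <- grid_spec(anchor_x = origin_x + margin,
                       anchor_y = origin_y - margin - 3,
                       plot_length = 3, plot_width = 2.25,
                       n_rows = 1L, n_cols = 3L, col_gap = 0.5)
  }
  structure(list(pixel_size = pixel_size, crs_id = as.integer(crs_id),
                 origin_x = origin_x, origin_y = origin_y,
                 ground_a = ground_a, ground_b = ground_b,
                 ground_c = ground_c, noise_sd = noise_sd, ridges = ridges,
                 plots = plots, margin = margin,
                 canopy_height = canopy_height,
                 cover_fraction = cover_fraction,
                 canopy_shape = canopy_shape, crop_color = crop_color,
                 soil_color = soil_color, color_sd = color_sd,
                 seed = as.integer(seed)),
            class = "field_spec")
}

# triangular ridge profile: 0 in the furrow, `height` on the crest; crests
# at x = crest0 + k * spacing, aligned with pixel centers so crest pixels
# sit exactly at crest height
ridge_profile <- function(x, spacing, height, crest0) {
  frac <- abs(((x - crest0) / spacing) %% 1)
  height * (1 - 2 * pmin(frac, 1 - frac))
}

ridge_crest_positions <- function(spec, grid) {
  # first crest on the pixel-center column nearest the left margin center
  crest0 <- grid$origin_x + (floor(spec$margin / 2 / spec$pixel_size) + 0.5) *
    spec$pixel_size
  xmax <- grid$origin_x + grid$n_cols * spec$pixel_size
  seq(crest0, xmax, by = spec$ridges$spacing)
}

canopy_region <- function(spec, plot) {
  if (spec$cover_fraction == 0) return(NULL)
  if (spec$canopy_shape == "rectangle") {
    if (spec$cover_fraction == 1) return(list(kind = "polygon",
                                              poly = plot$polygon))
    shrunk <- trim_margin(plot, 1 - sqrt(spec$cover_fraction), "both")
    list(kind = "polygon", poly = shrunk$polygon)
  } else {
    ctr <- plot_center(plot)
    area <- abs(ring_signed_area(plot$polygon[, 1L], plot$polygon[, 2L]))
    list(kind = "disc", center = ctr,
         radius = sqrt(spec$cover_fraction * area / pi))
  }
}

region_mask <- function(grid, region) {
  if (is.null(region)) return(matrix(FALSE, grid$n_rows, grid$n_cols))
  if (region$kind == "polygon") return(pixels_in_polygon(grid, region$poly))
  rows <- rep(seq_len(grid$n_rows) - 1L, times = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols) - 1L, each = grid$n_rows)
  ctr <- pixel_to_world(grid, rows, cols)
  d2 <- (ctr[, 1L] - region$center[1L])^2 + (ctr[, 2L] - region$center[2L])^2
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  m[cbind(rows + 1L, cols + 1L)] <- d2 <= region$radius^2
  m
}

#' Generate a synthetic orthomosaic/DSM pair with ground truth
#'
#' Builds the DSM as ground plane + optional ridges + canopy + Gaussian
#' noise, colors the orthomosaic by crop/soil class, and returns the exact
#' ground truth (true reference plane, per-plot cover and height, the
#' vegetation mask, and ready-made ground regions for both base-plane
#' routes). Deterministic given the spec's seed.
#'
#' @param spec a `field_spec`.
#' @param dir optional output directory; when given, writes `ortho.tif`,
#'   `dsm.tif`, `plots.shp` and `truth.json` there.
#' @param capture_date date label for the pair.
#' @return a list with `pair` (`raster_pair`), `plots`, `truth`, and (when
#'   `dir` is given) `paths`.
#' @export
make_field <- function(spec, dir = NULL, capture_date = "2021-06-01") {
  stopifnot(inherits(spec, "field_spec"))
  plots <- generate_grid(spec$plots)
  allv <- do.call(rbind, lapply(plots, function(p) p$polygon))
  ext <- c(xmin = min(allv[, 1L]) - spec$margin,
           xmax = max(allv[, 1L]) + spec$margin,
           ymin = min(allv[, 2L]) - spec$margin,
           ymax = max(allv[, 2L]) + spec$margin)
  if (ext["xmin"] < spec$origin_x - 1e-9 || ext["ymax"] > spec$origin_y + 1e-9) {
    stop_plotpheno("bad_spec", "plot grid extends outside the field origin")
  }
  n_cols <- ceiling((ext["xmax"] - spec$origin_x) / spec$pixel_size)
  n_rows <- ceiling((spec$origin_y - ext["ymin"]) / spec$pixel_size)
  grid <- geo_grid(spec$origin_x, spec$origin_y, spec$pixel_size,
                   spec$pixel_size, n_cols = n_cols, n_rows = n_rows,
                   crs_id = spec$crs_id)

  rows <- rep(seq_len(n_rows) - 1L, times = n_cols)
  cols <- rep(seq_len(n_cols) - 1L, each = n_rows)
  ctr <- pixel_to_world(grid, rows, cols)
  cell <- cbind(rows + 1L, cols + 1L)

  ground <- spec$ground_a * (ctr[, 1L] - spec$origin_x) +
    spec$ground_b * (ctr[, 2L] - spec$origin_y) + spec$ground_c
  ridge_h <- 0
  crest_xs <- numeric(0)
  if (!is.null(spec$ridges)) {
    crest_xs <- ridge_crest_positions(spec, grid)
    ridge_h <- ridge_profile(ctr[, 1L], spec$ridges$spacing,
                             spec$ridges$height, crest_xs[1L])
  }
  zm <- matrix(0, n_rows, n_cols)
  zm[cell] <- ground + ridge_h

  veg_mask <- matrix(FALSE, n_rows, n_cols)
  for (p in plots) {
    veg_mask <- veg_mask | region_mask(grid, canopy_region(spec, p))
  }
  # canopy top sits canopy_height above the local reference level: the
  # crest plane when ridged, the ground plane when flat
  ref <- matrix(0, n_rows, n_cols)
  ref[cell] <- ground + if (is.null(spec$ridges)) 0 else spec$ridges$height
  zm[veg_mask] <- ref[veg_mask] + spec$canopy_height

  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    zm <- zm + matrix(stats::rnorm(n_rows * n_cols, sd = spec$noise_sd),
                      n_rows, n_cols)
  }
  mk_band <- function(i) {
    mu <- ifelse(veg_mask, spec$crop_color[i], spec$soil_color[i])
    v <- round(mu + stats::rnorm(n_rows * n_cols, sd = spec$color_sd))
    matrix(pmin(pmax(v, 0), 255), n_rows, n_cols)
  }
  ortho <- ortho_image(grid, mk_band(1L), mk_band(2L), mk_band(3L))
  dsm <- surface_model(grid, zm)
  pair <- raster_pair(ortho, dsm, capture_date)

  # ground regions for both base-plane routes: bare margin rectangles on
  # opposite sides of the field, and full-length crest lines when ridged
  rects <- list(
    rbind(c(ext["xmin"], ext["ymax"] - spec$margin + 0.1),
          c(ext["xmax"], ext["ymax"] - spec$margin + 0.1),
          c(ext["xmax"], ext["ymax"] - 0.1),
          c(ext["xmin"], ext["ymax"] - 0.1)),
    rbind(c(ext["xmin"], ext["ymin"] + 0.1),
          c(ext["xmax"], ext["ymin"] + 0.1),
          c(ext["xmax"], ext["ymin"] + spec$margin - 0.1),
          c(ext["xmin"], ext["ymin"] + spec$margin - 0.1)))
  lines <- lapply(crest_xs, function(cx) {
    list(p1 = c(cx, ext["ymin"] + 0.1), p2 = c(cx, ext["ymax"] - 0.1),
         half_width = spec$pixel_size / 4)
  })

  base_true <- base_plane(spec$ground_a, spec$ground_b,
                          spec$ground_c - spec$ground_a * spec$origin_x -
                            spec$ground_b * spec$origin_y +
                            (if (is.null(spec$ridges)) 0 else
                               spec$ridges$height),
                          crs_id = spec$crs_id)
  per_plot <- lapply(plots, function(p) {
    pm <- pixels_in_polygon(grid, p$polygon)
    list(plot_id = p$plot_id, canopy_height = spec$canopy_height,
         cover_fraction = spec$cover_fraction,
         veg_fraction = sum(veg_mask & pm) / max(sum(pm), 1L))
  })
  truth <- list(base_plane = base_true, plots = per_plot,
                veg_mask = veg_mask, ground_rectangles = rects,
                crest_lines = lines)

  out <- list(pair = pair, plots = plots, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(ortho = file.path(dir, "ortho.tif"),
                  dsm = file.path(dir, "dsm.tif"),
                  plots = file.path(dir, "plots.shp"),
                  truth = file.path(dir, "truth.json"))
    write_ortho_geotiff(ortho, paths$ortho)
    write_dsm_geotiff(dsm, paths$dsm)
    write_shapefile(plots, paths$plots, crs_id = spec$crs_id)
    jsonlite::write_json(list(
      base_plane = list(a = base_true$a, b = base_true$b, c = base_true$c),
      plots = per_plot, ground_rectangles = rects,
      crest_lines = lines), paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Draw labeled training samples from the spec's color distributions
#'
#' Stands in for the interactive marking of crop and soil pixels: samples
#' `n_per_class` RGB triplets per class from the spec's crop/soil color
#' distributions.
#'
#' @param spec a `field_spec`.
#' @param n_per_class samples per class.
#' @param path optional CSV output path (`class_label,r,g,b`).
#' @return a data frame of the samples, invisibly when `path` is given.
#' @export
make_training_samples <- function(spec, n_per_class = 200L, path = NULL) {
  if (n_per_class < 1L) stop_plotpheno("bad_spec", "n_per_class must be >= 1")
  set.seed(spec$seed + 1L)
  draw <- function(mu, label) {
    m <- matrix(stats::rnorm(3L * n_per_class, mean = rep(mu, each = n_per_class),
                             sd = spec$color_sd), ncol = 3L)
    m <- pmin(pmax(round(m), 0), 255)
    data.frame(class_label = label, r = m[, 1L], g = m[, 2L], b = m[, 3L])
  }
  df <- rbind(draw(spec$crop_color, "crop"), draw(spec$soil_color, "soil"))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
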