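# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (per-point loops, normal equations assembled by hand)
# and independent of the package code paths they check.

# Brute-force center-in-polygon: loops every pixel and every edge, even-odd
# rule with inclusive boundaries.
brute_force_mask <- function(grid, polygon) {
  poly <- as.matrix(polygon)
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (row in seq_len(grid$n_rows) - 1L) {
    for (col in seq_len(grid$n_cols) - 1L) {
      px <- grid$origin_x + (col + 0.5) * grid$pixel_size_x
      py <- grid$origin_y - (row + 0.5) * grid$pixel_size_y
      inside <- FALSE
      on_edge <- FALSE
      j <- n
      for (i in seq_len(n)) {
        x1 <- poly[j, 1]; y1 <- poly[j, 2]
        x2 <- poly[i, 1]; y2 <- poly[i, 2]
        if ((y1 > py) != (y2 > py)) {
          xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
          if (px < xint) inside <- !inside
        }
        # point-to-segment distance
        dx <- x2 - x1; dy <- y2 - y1
        L2 <- dx^2 + dy^2
        t <- if (L2 == 0) 0 else min(max(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
        d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
        if (d2 <= 1e-18) on_edge <- TRUE
        j <- i
      }
      mask[row + 1L, col + 1L] <- inside || on_edge
    }
  }
  mask
}

# Plane fit by hand-assembled 3x3 normal equations (vertical residuals).
normal_equation_plane <- function(x, y, z) {
  A <- cbind(x, y, 1)
  coef <- solve(t(A) %*% A, t(A) %*% z)
  list(a = coef[1], b = coef[2], c = coef[3])
}

shoelace_area <- function(poly) {
  p <- as.matrix(poly)
  n <- nrow(p)
  if (all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  abs(sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2]) / 2)
}

# a small random ortho/dsm pair on disk; returns the paths and the data
write_random_pair <- function(dir, n = 50L, seed = 1L, crs_id = 32654L) {
  set.seed(seed)
  g <- geo_grid(500000, 4000000, 0.1, 0.1, n, n, crs_id)
  r <- matrix(sample(0:255, n * n, TRUE), n, n)
  gr <- matrix(sample(0:255, n * n, TRUE), n, n)
  b <- matrix(sample(0:255, n * n, TRUE), n, n)
  valid <- matrix(TRUE, n, n); valid[1, 2] <- FALSE
  z <- matrix(stats::rnorm(n * n, 100), n, n)
  zv <- matrix(TRUE, n, n); zv[3, 4] <- FALSE
  o <- ortho_image(g, r, gr, b, valid)
  d <- surface_model(g, z, zv)
  op <- file.path(dir, "o.tif"); dp <- file.path(dir, "d.tif")
  write_ortho_geotiff(o, op)
  write_dsm_geotiff(d, dp)
  list(ortho_path = op, dsm_path = dp, ortho = o, dsm = d, grid = g)
}

# a trained two-class crop/soil model reused across tests
fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- field_spec(seed = 3L)
      tr <- make_training_samples(spec, 100L)
      ts <- training_set(tr$class_label, tr$r, tr$g, tr$b)
      cache <<- train_model(ts, vegetation_classes = "crop")
    }
    cache
  }
})
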