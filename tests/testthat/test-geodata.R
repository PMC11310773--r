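test_that("geotiff write/read round-trips band values, masks and grid", {
  td <- withr::local_tempdir()
  fx <- write_random_pair(td)
  pair <- read_raster_pair(fx$ortho_path, fx$dsm_path)
  expect_equal(pair$ortho$r, fx$ortho$r)
  expect_equal(pair$ortho$g, fx$ortho$g)
  expect_equal(pair$ortho$b, fx$ortho$b)
  expect_equal(pair$ortho$valid, fx$ortho$valid)
  expect_equal(pair$dsm$valid, fx$dsm$valid)
  # DSM stored as 32-bit float: values agree to float precision
  expect_lt(max(abs(pair$dsm$z[fx$dsm$valid] - fx$dsm$z[fx$dsm$valid])), 1e-4)
  expect_true(all(unlist(pair$dsm$grid[1:6]) == unlist(fx$grid[1:6])))
  expect_equal(pair$dsm$grid$crs_id, 32654L)
})

test_that("missing or geographic CRS is a named error", {
  td <- withr::local_tempdir()
  fx <- write_random_pair(td)
  # rewrite the DSM without geo keys
  g <- fx$grid
  z <- fx$dsm$z
  pix <- writeBin(as.numeric(as.vector(t(z))), raw(), size = 4,
                  endian = "little")
  TT <- plotpheno:::TIFF_TAG
  base_tags <- list(
    list(tag = TT$width, type = 4L, values = g$n_cols),
    list(tag = TT$length, type = 4L, values = g$n_rows),
    list(tag = TT$bits, type = 3L, values = 32L),
    list(tag = TT$compression, type = 3L, values = 1L),
    list(tag = TT$photometric, type = 3L, values = 1L),
    list(tag = TT$strip_offsets, type = 4L, values = 8L),
    list(tag = TT$samples, type = 3L, values = 1L),
    list(tag = TT$rows_per_strip, type = 4L, values = g$n_rows),
    list(tag = TT$strip_bytes, type = 4L, values = length(pix)),
    list(tag = TT$sample_format, type = 3L, values = 3L))
  geo_loc <- list(
    list(tag = TT$pixel_scale, type = 12L, values = c(0.1, 0.1, 0)),
    list(tag = TT$tiepoint, type = 12L,
         values = c(0, 0, 0, g$origin_x, g$origin_y, 0)))
  nocrs <- file.path(td, "nocrs.tif")
  plotpheno:::write_tiff_raw(nocrs, pix, c(base_tags, geo_loc))
  expect_error(read_raster_pair(fx$ortho_path, nocrs),
               class = "plotpheno_missing_crs")
  # geographic model type (GeoKey GTModelType = 2)
  geo_keys <- list(list(tag = TT$geo_keys, type = 3L,
                        values = c(1L, 1L, 0L, 2L,
                                   1024L, 0L, 1L, 2L,
                                   2048L, 0L, 1L, 4326L)))
  geog <- file.path(td, "geog.tif")
  plotpheno:::write_tiff_raw(geog, pix, c(base_tags, geo_loc, geo_keys))
  expect_error(read_raster_pair(fx$ortho_path, geog),
               class = "plotpheno_geographic_crs")
  expect_error(read_raster_pair(file.path(td, "absent.tif"), fx$dsm_path),
               class = "plotpheno_file_not_found")
})

test_that("a coarser DSM is resampled to the ortho grid by nearest neighbor", {
  td <- withr::local_tempdir()
  set.seed(7)
  go <- geo_grid(100, 200, 0.5, 0.5, 20, 20, 32654L)
  gd <- geo_grid(100, 200, 1.0, 1.0, 10, 10, 32654L)
  o <- ortho_image(go, matrix(10, 20, 20), matrix(20, 20, 20),
                   matrix(30, 20, 20))
  zd <- matrix(rnorm(100, 50), 10, 10)
  d <- surface_model(gd, zd)
  write_ortho_geotiff(o, file.path(td, "o.tif"))
  write_dsm_geotiff(d, file.path(td, "d.tif"))
  pair <- read_raster_pair(file.path(td, "o.tif"), file.path(td, "d.tif"))
  expect_equal(pair$dsm$grid$n_cols, 20L)
  # brute-force per-pixel lookup of the containing source pixel
  for (row in 0:19) {
    for (col in 0:19) {
      cx <- 100 + (col + 0.5) * 0.5
      cy <- 200 - (row + 0.5) * 0.5
      sr <- floor((200 - cy) / 1.0)
      sc <- floor((cx - 100) / 1.0)
      expect_equal(pair$dsm$z[row + 1, col + 1], zd[sr + 1, sc + 1],
                   tolerance = 1e-4)
    }
  }
})

test_that("disjoint extents and CRS mismatch are rejected", {
  td <- withr::local_tempdir()
  fx <- write_random_pair(td)
  g2 <- geo_grid(900000, 4000000, 0.1, 0.1, 10, 10, 32654L)
  d2 <- surface_model(g2, matrix(1, 10, 10))
  write_dsm_geotiff(d2, file.path(td, "far.tif"))
  expect_error(read_raster_pair(fx$ortho_path, file.path(td, "far.tif")),
               class = "plotpheno_disjoint_extents")
  g3 <- geo_grid(500000, 4000000, 0.1, 0.1, 10, 10, 32653L)
  d3 <- surface_model(g3, matrix(1, 10, 10))
  write_dsm_geotiff(d3, file.path(td, "othercrs.tif"))
  expect_error(read_raster_pair(fx$ortho_path, file.path(td, "othercrs.tif")),
               class = "plotpheno_crs_mismatch")
})

test_that("world_to_pixel follows the half-open footprint convention", {
  g <- geo_grid(100, 200, 0.01, 0.01, 100, 100, 32654L)
  expect_equal(world_to_pixel(g, 100.005, 199.995), cbind(row = 0L, col = 0L))
  # points exactly on a shared edge belong to the larger index
  expect_equal(world_to_pixel(g, 100.01, 199.99), cbind(row = 1L, col = 1L))
  set.seed(5)
  x <- runif(1000, 100, 101); y <- runif(1000, 199, 200)
  rc <- world_to_pixel(g, x, y)
  ctr <- pixel_to_world(g, rc[, "row"], rc[, "col"])
  expect_true(all(abs(ctr[, "x"] - x) <= 0.005 + 1e-12))
  expect_true(all(abs(ctr[, "y"] - y) <= 0.005 + 1e-12))
})

test_that("pixels_in_polygon matches the brute-force oracle", {
  g <- geo_grid(0, 10, 1, 1, 10, 10, 32654L)
  rect <- rbind(c(0, 0), c(5, 0), c(5, 10), c(0, 10))
  m <- pixels_in_polygon(g, rect)
  expect_equal(sum(m), 50L)
  expect_equal(m, brute_force_mask(g, rect))
  # rotated square inscribed in the raster
  sq <- rbind(c(5, 10), c(10, 5), c(5, 0), c(0, 5))
  expect_equal(pixels_in_polygon(g, sq), brute_force_mask(g, sq))
  # entirely outside
  far <- rbind(c(100, 100), c(110, 100), c(110, 110), c(100, 110))
  expect_false(any(pixels_in_polygon(g, far)))
  # degenerate polygon warns and returns empty
  expect_warning(dm <- pixels_in_polygon(g, rbind(c(1, 1), c(1, 1), c(1, 1))),
                 class = "plotpheno_degenerate_polygon")
  expect_false(any(dm))
})

test_that("masks of disjoint polygons partition their union", {
  g <- geo_grid(0, 8, 1, 1, 8, 8, 32654L)
  a <- rbind(c(0.2, 0.2), c(3.4, 0.2), c(3.4, 7.7), c(0.2, 7.7))
  b <- rbind(c(4.6, 0.2), c(7.8, 0.2), c(7.8, 7.7), c(4.6, 7.7))
  ma <- pixels_in_polygon(g, a)
  mb <- pixels_in_polygon(g, b)
  expect_false(any(ma & mb))
  expect_equal(sum(ma | mb), sum(ma) + sum(mb))
})

test_that("grid construction rejects invalid geometry and geographic CRS", {
  expect_error(geo_grid(0, 0, -1, 1, 5, 5, 32654L),
               class = "plotpheno_bad_grid")
  expect_error(geo_grid(0, 0, 1, 1, 0, 5, 32654L),
               class = "plotpheno_bad_grid")
  expect_error(geo_grid(0, 0, 1, 1, 5, 5, 4326L),
               class = "plotpheno_geographic_crs")
})
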