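test_that("generate_grid produces the right count, areas and layout", {
  # two-column trial of 9 x 1.2 m plots: 40 plots of 10.8 m^2
  spec <- grid_spec(0, 0, angle = 0, plot_length = 9, plot_width = 1.2,
                    n_rows = 20, n_cols = 2, col_gap = 0.3)
  plots <- generate_grid(spec)
  expect_length(plots, 40L)
  areas <- vapply(plots, function(p) shoelace_area(p$polygon), 1)
  expect_true(all(abs(areas - 10.8) < 1e-9))

  # unrotated single plot: corners in the local frame
  s1 <- grid_spec(0, 0, angle = 0, plot_length = 2, plot_width = 3)
  p1 <- generate_grid(s1)[[1]]
  expect_equal(unname(p1$polygon),
               unname(rbind(c(0, 0), c(3, 0), c(3, 2), c(0, 2))))

  # rotation equals an independent rotation-matrix multiply
  s2 <- grid_spec(0, 0, angle = 90, plot_length = 2, plot_width = 3)
  p2 <- generate_grid(s2)[[1]]
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(unname(p2$polygon), unname(p1$polygon %*% t(R)),
               tolerance = 1e-12)
})

test_that("plot area is invariant under rotation and plots never overlap", {
  set.seed(9)
  for (i in 1:20) {
    spec <- grid_spec(runif(1, -100, 100), runif(1, -100, 100),
                      angle = runif(1, 0, 360),
                      plot_length = runif(1, 1, 10),
                      plot_width = runif(1, 0.5, 4),
                      n_rows = sample(1:4, 1), n_cols = sample(1:4, 1),
                      row_gap = runif(1, 0, 1), col_gap = runif(1, 0, 1))
    plots <- generate_grid(spec)
    expect_length(plots, spec$n_rows * spec$n_cols)
    target <- spec$plot_length * spec$plot_width
    for (p in plots) expect_lt(abs(shoelace_area(p$polygon) - target), 1e-9)
    # rectangle invariants: opposite sides equal, right angles
    for (p in plots) {
      v <- p$polygon
      e <- rbind(v[2, ] - v[1, ], v[3, ] - v[2, ], v[4, ] - v[3, ],
                 v[1, ] - v[4, ])
      expect_lt(abs(sqrt(sum(e[1, ]^2)) - sqrt(sum(e[3, ]^2))), 1e-9)
      expect_lt(abs(sqrt(sum(e[2, ]^2)) - sqrt(sum(e[4, ]^2))), 1e-9)
      expect_lt(abs(sum(e[1, ] * e[2, ])), 1e-9)
    }
  }
})

test_that("numbering schemes and renumbering behave as documented", {
  spec <- grid_spec(0, 0, plot_length = 1, plot_width = 1,
                    n_rows = 2, n_cols = 3)
  plots <- generate_grid(spec)
  ids_of <- function(ps) vapply(ps, function(p) p$plot_id, 1L)
  expect_equal(ids_of(plots), 1:6)
  # serpentine: row 0 left-to-right 1,2,3; row 1 right-to-left 4,5,6
  serp <- renumber(plots, "serpentine_rows")
  by_pos <- function(ps, r, c) {
    Filter(function(p) p$row == r && p$col == c, ps)[[1]]$plot_id
  }
  expect_equal(vapply(0:2, function(c) by_pos(serp, 0L, c), 1L), 1:3)
  expect_equal(vapply(0:2, function(c) by_pos(serp, 1L, c), 1L), c(6L, 5L, 4L))
  # same scheme and start is the identity
  again <- renumber(plots, "row_major", 1L)
  expect_equal(ids_of(again), ids_of(plots))
  # start offset
  off <- renumber(plots[1:5], "row_major", 101L)
  expect_equal(sort(ids_of(off)), 101:105)
  # geometry untouched
  expect_equal(serp[[1]]$polygon %in% lapply(plots, `[[`, "polygon"),
               plots[[1]]$polygon %in% lapply(plots, `[[`, "polygon"))
})

test_that("trim_margin shrinks concentrically", {
  spec <- grid_spec(5, 7, angle = 33, plot_length = 9, plot_width = 1.2)
  p <- generate_grid(spec)[[1]]
  t1 <- trim_margin(p, 0.2, "width")
  v <- t1$polygon
  w <- sqrt(sum((v[2, ] - v[1, ])^2))
  l <- sqrt(sum((v[3, ] - v[2, ])^2))
  expect_equal(w, 0.96, tolerance = 1e-9)
  expect_equal(l, 9, tolerance = 1e-9)
  expect_equal(colMeans(t1$polygon), colMeans(p$polygon), tolerance = 1e-9)
  # zero fraction is the identity
  expect_equal(trim_margin(p, 0)$polygon, p$polygon)
  # both sides at 0.5 quarters the area (shoelace oracle)
  t2 <- trim_margin(p, 0.5, "both")
  expect_equal(shoelace_area(t2$polygon), shoelace_area(p$polygon) / 4,
               tolerance = 1e-9)
  expect_error(trim_margin(p, 1), class = "plotpheno_bad_fraction")
})

test_that("shapefile write/read round-trips ids and geometry", {
  td <- withr::local_tempdir()
  spec <- grid_spec(500010, 4000020, angle = 17, plot_length = 9,
                    plot_width = 1.2, n_rows = 20, n_cols = 2,
                    col_gap = 0.4)
  plots <- generate_grid(spec)
  path <- file.path(td, "plots.shp")
  write_shapefile(plots, path, crs_id = 32654L)
  expect_true(file.exists(file.path(td, "plots.shx")))
  expect_true(file.exists(file.path(td, "plots.dbf")))
  expect_true(file.exists(file.path(td, "plots.prj")))
  back <- read_shapefile(path)
  expect_equal(vapply(back, function(p) p$plot_id, 1L),
               vapply(plots, function(p) p$plot_id, 1L))
  for (i in seq_along(plots)) {
    expect_lt(max(abs(back[[i]]$polygon - plots[[i]]$polygon)), 1e-6)
  }
})

test_that("written shapefile rings are clockwise (signed area < 0)", {
  td <- withr::local_tempdir()
  plots <- generate_grid(grid_spec(0, 0, plot_length = 2, plot_width = 3,
                                   n_rows = 2, n_cols = 2))
  path <- file.path(td, "cw.shp")
  write_shapefile(plots, path)
  # read raw ring vertices without reorientation
  buf <- readBin(path, "raw", file.size(path))
  pos <- 101
  repeat {
    if (pos >= length(buf)) break
    npts_off <- pos + 8 + 40
    npts <- plotpheno:::rd_u32(buf, npts_off)
    pts <- readBin(buf[(pos + 8 + 48):(pos + 8 + 48 + 16 * npts - 1)],
                   "numeric", 2 * npts, size = 8, endian = "little")
    ring <- matrix(pts, ncol = 2, byrow = TRUE)
    sa <- plotpheno:::ring_signed_area(ring[, 1], ring[, 2])
    expect_lt(sa, 0)
    clen <- 4 + 32 + 4 + 4 + 4 + 16 * npts
    pos <- pos + 8 + clen
  }
})

test_that("shapefile contract errors are raised", {
  td <- withr::local_tempdir()
  expect_error(write_shapefile(list(), file.path(td, "x.shp")),
               class = "plotpheno_empty_plots")
  # a point-type shapefile (type 1) is rejected
  hdr <- c(plotpheno:::be32r(9994L), raw(20),
           plotpheno:::be32r(50L), plotpheno:::u32r(1000L),
           plotpheno:::u32r(1L),
           writeBin(rep(0, 8), raw(), size = 8, endian = "little"))
  pt <- file.path(td, "pt.shp")
  writeBin(hdr, pt)
  expect_error(read_shapefile(pt), class = "plotpheno_non_polygon_shapefile")
  # missing plot_id attribute falls back to record order with a warning
  plots <- generate_grid(grid_spec(0, 0, plot_length = 1, plot_width = 1,
                                   n_rows = 1, n_cols = 2))
  p2 <- file.path(td, "noid.shp")
  write_shapefile(plots, p2)
  foreign::write.dbf(data.frame(other = c(5L, 6L)), file.path(td, "noid.dbf"))
  expect_warning(back <- read_shapefile(p2),
                 class = "plotpheno_missing_plot_id")
  expect_equal(vapply(back, function(p) p$plot_id, 1L), 1:2)
})
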