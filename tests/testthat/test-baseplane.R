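test_that("fit_lsq_plane recovers exact planes and matches normal equations", {
  set.seed(21)
  x <- runif(50, 0, 100); y <- runif(50, 0, 100)
  z <- 0.01 * x + 0.02 * y + 5
  p <- fit_lsq_plane(data.frame(x, y, z))
  expect_equal(c(p$a, p$b, p$c), c(0.01, 0.02, 5), tolerance = 1e-12)
  # horizontal plane
  ph <- fit_lsq_plane(data.frame(x, y, z = rep(7, 50)))
  expect_equal(c(ph$a, ph$b, ph$c), c(0, 0, 7), tolerance = 1e-12)
  # noisy points: agree with hand-assembled 3x3 normal equations
  zn <- z + rnorm(50, sd = 0.05)
  pn <- fit_lsq_plane(data.frame(x, y, z = zn))
  ne <- normal_equation_plane(x, y, zn)
  expect_equal(pn$a, ne$a, tolerance = 1e-8)
  expect_equal(pn$b, ne$b, tolerance = 1e-8)
  expect_equal(pn$c, ne$c, tolerance = 1e-8)
  expect_error(fit_lsq_plane(data.frame(x = 1:2, y = 1:2, z = 1:2)),
               class = "plotpheno_too_few_points")
  expect_error(fit_lsq_plane(data.frame(x = 1:5, y = 2 * (1:5), z = 1:5)),
               class = "plotpheno_degenerate_points")
})

test_that("shift_to_base reproduces the hand-computed outlier example", {
  set.seed(22)
  pts <- data.frame(x = runif(100), y = runif(100),
                    z = c(rep(-10, 5), -2, rep(0, 94)))
  plane <- base_plane(0, 0, 0)
  shifted <- shift_to_base(plane, pts, 0.05)
  # the five -10 outliers are the excluded top 5% by downward distance;
  # the deepest retained point (-2) sets the offset
  expect_equal(shifted$c, -2)
  expect_equal(shifted$a, 0)
  expect_equal(shifted$b, 0)
})

test_that("shift_to_base honors its contract and edge cases", {
  set.seed(23)
  # all points on the plane: unchanged
  pts0 <- data.frame(x = runif(10), y = runif(10), z = 0)
  expect_equal(shift_to_base(base_plane(0, 0, 0), pts0, 0.05)$c, 0)
  # no retained point below: never shift upward
  ptsu <- data.frame(x = runif(10), y = runif(10), z = 1)
  expect_equal(shift_to_base(base_plane(0, 0, 0), ptsu, 0.05)$c, 0)
  # fraction 0, one point 0.3 below: plane drops by exactly 0.3 and no
  # retained point lies below afterwards
  pts1 <- data.frame(x = runif(10), y = runif(10), z = c(rep(0, 9), -0.3))
  s1 <- shift_to_base(base_plane(0, 0, 0), pts1, 0)
  expect_equal(s1$c, -0.3)
  expect_true(all(pts1$z - (s1$a * pts1$x + s1$b * pts1$y + s1$c) >= -1e-12))
  expect_error(shift_to_base(base_plane(0, 0, 0), pts1[0, ], 0.05),
               class = "plotpheno_too_few_points")
})

test_that("shift_to_base leaves at most the excluded fraction below and is idempotent", {
  set.seed(24)
  for (i in 1:20) {
    n <- sample(20:300, 1)
    pts <- data.frame(x = runif(n, 0, 10), y = runif(n, 0, 10),
                      z = rnorm(n, sd = 0.3))
    f <- runif(1, 0, 0.2)
    pl <- fit_lsq_plane(pts)
    s <- shift_to_base(pl, pts, f)
    below <- sum(pts$z < (s$a * pts$x + s$b * pts$y + s$c) - 1e-12)
    expect_lte(below, ceiling(f * n))
    s2 <- shift_to_base(s, pts, f)
    expect_equal(s2$c, s$c, tolerance = 1e-12)
  }
})

test_that("base_plane_from_rectangles recovers a planar DSM", {
  g <- geo_grid(0, 60, 1, 1, 60, 60, 32654L)
  rows <- rep(1:60, times = 60); cols <- rep(1:60, each = 60)
  ctr <- pixel_to_world(g, rows - 1L, cols - 1L)
  z <- matrix(0, 60, 60)
  z[cbind(rows, cols)] <- 0.01 * ctr[, 1] + 0.02 * ctr[, 2] + 5
  dsm <- surface_model(g, z)
  rect <- list(rbind(c(0, 0), c(60, 0), c(60, 60), c(0, 60)))
  bp <- base_plane_from_rectangles(dsm, rect)
  expect_equal(c(bp$a, bp$b, bp$c), c(0.01, 0.02, 5), tolerance = 1e-9)

  # with 3% depressed pixels: slopes still recovered, offset equals a
  # flat brute-force recomputation of fit + shift
  set.seed(25)
  holes <- sample(3600, 108)
  z2 <- z; z2[holes] <- z2[holes] - 1
  dsm2 <- surface_model(g, z2)
  bp2 <- base_plane_from_rectangles(dsm2, rect)
  expect_lt(abs(bp2$a - 0.01), 1e-3)
  expect_lt(abs(bp2$b - 0.02), 1e-3)
  xs <- ctr[, 1]; ys <- ctr[, 2]; zs <- z2[cbind(rows, cols)]
  ne <- normal_equation_plane(xs, ys, zs)
  d <- ne$a * xs + ne$b * ys + ne$c - zs
  keep <- sort(order(-d)[(ceiling(0.05 * 3600) + 1):3600])
  dstar <- max(d[keep])
  expected_c <- if (dstar > 0) ne$c - dstar else ne$c
  expect_equal(bp2$c, expected_c, tolerance = 1e-8)

  # two disjoint rectangles with the same pixel set as one covering both
  ra <- rbind(c(0, 0), c(60, 0), c(60, 20), c(0, 20))
  rb <- rbind(c(0, 20), c(60, 20), c(60, 60), c(0, 60))
  both <- base_plane_from_rectangles(dsm2, list(ra, rb))
  expect_equal(c(both$a, both$b, both$c), c(bp2$a, bp2$b, bp2$c),
               tolerance = 1e-6)
})

test_that("line-based plane suppresses the cross-line slope by construction", {
  g <- geo_grid(0, 10, 0.1, 0.1, 200, 100, 32654L)
  rows <- rep(1:100, times = 200); cols <- rep(1:200, each = 100)
  ctr <- pixel_to_world(g, rows - 1L, cols - 1L)
  # crest along x with a cross slope in y
  z <- matrix(0, 100, 200)
  z[cbind(rows, cols)] <- 0.05 * ctr[, 1] + 0.5 * ctr[, 2]
  dsm <- surface_model(g, z)
  # line along a pixel-center row so the sampled stations share one y
  yline <- 10 - (49 + 0.5) * 0.1
  lines <- list(list(p1 = c(0.2, yline), p2 = c(19.8, yline),
                     half_width = 0.04))
  bp <- base_plane_from_lines(dsm, lines)
  expect_identical(bp$b, 0 * bp$b)      # exactly zero in the aligned frame
  expect_equal(bp$a, 0.05, tolerance = 1e-6)

  # flat DSM: (0, 0, 3)
  dflat <- surface_model(g, matrix(3, 100, 200))
  bf <- base_plane_from_lines(dflat, lines)
  expect_equal(c(bf$a, bf$b, bf$c), c(0, 0, 3), tolerance = 1e-9)

  # ridge crest z = 0.05 x sampled along the x axis
  z3 <- matrix(0, 100, 200)
  z3[cbind(rows, cols)] <- 0.05 * ctr[, 1]
  b3 <- base_plane_from_lines(surface_model(g, z3), lines)
  expect_equal(b3$a, 0.05, tolerance = 1e-9)
  expect_equal(b3$b, 0)

  # non-parallel lines are rejected
  bad <- c(lines, list(list(p1 = c(0, 1), p2 = c(10, 9), half_width = 0.04)))
  expect_error(base_plane_from_lines(dsm, bad),
               class = "plotpheno_non_parallel_lines")
})

test_that("the base-plane procedure is invariant under rigid translation", {
  set.seed(26)
  g <- geo_grid(0, 30, 1, 1, 30, 30, 32654L)
  rows <- rep(1:30, times = 30); cols <- rep(1:30, each = 30)
  ctr <- pixel_to_world(g, rows - 1L, cols - 1L)
  z <- matrix(0, 30, 30)
  z[cbind(rows, cols)] <- 0.01 * ctr[, 1] - 0.03 * ctr[, 2] + 2 +
    rnorm(900, sd = 0.01)
  rect <- list(rbind(c(0, 0), c(30, 0), c(30, 30), c(0, 30)))
  bp <- base_plane_from_rectangles(surface_model(g, z), rect)
  dx <- 1000; dy <- -500; dz <- 42
  g2 <- geo_grid(dx, 30 + dy, 1, 1, 30, 30, 32654L)
  rect2 <- list(sweep(rect[[1]], 2, c(-dx, -dy), `-`))
  bp2 <- base_plane_from_rectangles(surface_model(g2, z + dz), rect2)
  expect_equal(bp2$a, bp$a, tolerance = 1e-9)
  expect_equal(bp2$b, bp$b, tolerance = 1e-9)
  expect_equal(bp2$c, bp$c + dz - bp$a * dx - bp$b * dy, tolerance = 1e-6)
})

test_that("height_above is the plane equation and planes round-trip as JSON", {
  expect_equal(height_above(base_plane(0, 0, 0), 3, 4, 1.5), 1.5)
  expect_equal(height_above(base_plane(0.01, 0.02, 5), 10, 20, 5.5), 0)
  expect_equal(height_above(base_plane(0.01, 0.02, 5), 10, 20, 6), 0.5)
  td <- withr::local_tempdir()
  p <- base_plane(0.0123456789, -0.02, 87.654321, crs_id = 32654L)
  f <- file.path(td, "plane.json")
  write_base_plane(p, f)
  q <- read_base_plane(f)
  expect_equal(q$a, p$a)
  expect_equal(q$b, p$b)
  expect_equal(q$c, p$c)
  expect_equal(q$crs_id, 32654L)
})
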