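# B-spline body model: basis properties, profile evaluation,
# reconstruction, rendering, morphology.

test_that("tangent-angle evaluation matches the spline model", {
  g0 <- worm_geometry(rep(0, 8), rep(1, 8), 60)
  u <- seq(0, 1, 0.05)
  expect_equal(eval_theta(g0, u), rep(0, length(u)))

  gc <- worm_geometry(rep(1.7, 8), rep(1, 8), 60)
  expect_equal(eval_theta(gc, u), rep(1.7, length(u)), tolerance = 1e-12)

  # single active coefficient vs an independent de Boor evaluation
  basis <- spline_basis()
  for (j in c(2, 5, 7)) {
    alpha <- rep(0, 8); alpha[j] <- 1
    gj <- worm_geometry(alpha, rep(1, 8), 60, basis = basis)
    for (uu in c(0.17, 0.5, 0.83)) {
      expect_equal(eval_theta(gj, uu),
                   deboor_basis(basis$knot_vector, 3, j, uu),
                   tolerance = 1e-12)
    }
  }
})

test_that("width profile evaluation and nonnegativity", {
  u <- seq(0, 1, 0.02)
  g0 <- worm_geometry(rep(0, 8), rep(0, 8), 60)
  expect_equal(eval_width(g0, u), rep(0, length(u)))
  g4 <- worm_geometry(rep(0, 8), rep(4, 8), 60)
  expect_equal(eval_width(g4, u), rep(4, length(u)), tolerance = 1e-12)
  gs <- worm_geometry(rep(0, 8), c(0, 1, 2, 3, 3, 2, 1, 0), 60)
  w <- eval_width(gs, u)
  expect_true(all(w >= 0))
  expect_equal(w, rev(w), tolerance = 1e-9)          # symmetric profile
  expect_equal(which.max(w), which.min(abs(u - 0.5)), tolerance = 1)
  expect_equal(eval_width(gs, 0.5),
               sum(c(0, 1, 2, 3, 3, 2, 1, 0) *
                     sapply(1:8, function(j)
                       deboor_basis(spline_basis()$knot_vector, 3, j, 0.5))),
               tolerance = 1e-12)
})

test_that("evaluation outside [0,1] is a domain error", {
  g <- worm_geometry(rep(0, 8), rep(1, 8), 60)
  expect_error(eval_theta(g, -0.01), "0, 1")
  expect_error(eval_width(g, 1.01), "0, 1")
})

test_that("clamped basis is a partition of unity", {
  basis <- spline_basis()
  set.seed(1)
  u <- runif(1000)
  B <- basis_matrix(basis, u)
  expect_true(all(B >= -1e-12))
  expect_true(all(abs(rowSums(B) - 1) < 1e-9))
})

test_that("straight body reconstructs to a horizontal capsule band", {
  g <- worm_geometry(rep(0, 8), rep(4, 8), 60, origin = c(10, 20))
  body <- reconstruct_body(g, 100)
  expect_equal(body$centerline[1, ], c(x = 10, y = 20))
  expect_equal(body$centerline[100, ], c(x = 70, y = 20), tolerance = 1e-9)
  expect_true(all(abs(body$outline[, 2] - 20) <= 4 + 1e-9))
  expect_error(reconstruct_body(g, 8), "16")
})

test_that("full-turn geometry closes into a circle", {
  g <- geometry_from_theta(function(u) 2 * pi * u, L = 60,
                           r = rep(0.5, 8))
  body <- reconstruct_body(g, 400)
  gap <- sqrt(sum((body$centerline[400, ] - body$centerline[1, ])^2))
  # trapezoid error is O(h^2); allow a small multiple of L * h
  expect_lt(gap, 60 * (1 / 399))
  radii <- sqrt(rowSums(sweep(body$centerline, 2,
                              colMeans(body$centerline))^2))
  expect_equal(mean(radii), 60 / (2 * pi), tolerance = 0.02)
})

test_that("negating the angle coefficients mirrors the outline", {
  set.seed(4)
  alpha <- rnorm(8, 0, 0.8)
  g1 <- worm_geometry(alpha, taper_profile(), 60)
  g2 <- worm_geometry(-alpha, taper_profile(), 60)
  b1 <- reconstruct_body(g1, 120)
  b2 <- reconstruct_body(g2, 120)
  expect_equal(b1$centerline[, 1], b2$centerline[, 1], tolerance = 1e-9)
  expect_equal(b1$centerline[, 2], -b2$centerline[, 2], tolerance = 1e-9)
})

test_that("morphology metrics match closed forms", {
  rod <- worm_geometry(rep(0, 8), rep(4, 8), 60)
  m <- morphology(rod)
  expect_equal(m$arc_length, 60)
  expect_equal(m$total_turning, 0)
  expect_equal(m$head_tail_distance, 60, tolerance = 1e-6)
  expect_equal(m$mean_half_width, 4, tolerance = 1e-9)

  half <- geometry_from_theta(function(u) pi * u, L = 60, r = rep(2, 8))
  mh <- morphology(half)
  expect_equal(mh$total_turning, pi, tolerance = 1e-6)
  expect_equal(mh$head_tail_distance, 2 * 60 / pi, tolerance = 0.01)

  # similarity scaling: lengths x2, area x4
  big <- worm_geometry(half$alpha, 2 * half$r, 2 * half$body_length)
  mb <- morphology(big)
  expect_equal(mb$arc_length, 2 * mh$arc_length)
  expect_equal(mb$projected_area, 4 * mh$projected_area, tolerance = 1e-9)
  expect_equal(mb$total_turning, mh$total_turning, tolerance = 1e-9)
})

test_that("rendering a straight rod gives the analytic capsule area", {
  g <- worm_geometry(rep(0, 8), rep(4, 8), 60)
  m <- render_mask(g, c(128, 128))
  expect_equal(sum(m), 2 * 4 * 60 + pi * 16, tolerance = 0.10 * 2 * 4 * 60)
  expect_equal(wormsnap:::n_components(m), 1)
})

test_that("tight coil renders with a background hole; empty list renders blank", {
  g <- geometry_from_theta(function(u) 2.3 * pi * u, L = 60)
  m <- render_mask(g, c(140, 140))
  expect_gte(count_holes(m), 1)
  blank <- render_mask(list(), c(64, 64))
  expect_equal(sum(blank), 0)
})

test_that("outline too large for the canvas errors with the required size", {
  g <- worm_geometry(rep(0, 8), rep(4, 8), 200)
  expect_error(render_mask(g, c(128, 128)), "requires at least")
})

test_that("geometry JSON round-trips", {
  set.seed(2)
  g <- worm_geometry(rnorm(8), taper_profile(), 57.5, origin = c(3, -2))
  path <- tempfile(fileext = ".json")
  write_geometry(g, path)
  g2 <- read_geometry(path)[[1]]
  expect_equal(g2$alpha, g$alpha, tolerance = 1e-12)
  expect_equal(g2$r, g$r, tolerance = 1e-12)
  expect_equal(g2$body_length, g$body_length)
  expect_equal(g2$origin, g$origin)
})
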