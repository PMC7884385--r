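# Segmentation: circumcircle, multilevel Otsu, jaggedness, detection on
# synthetic wells, crop standardization, preliminary labeling.

test_that("circumcircle recovers known circles and rejects collinear points", {
  w1 <- fit_well_circle(c(1, 0), c(0, 1), c(-1, 0))
  expect_equal(w1$center, c(0, 0), tolerance = 1e-12)
  expect_equal(w1$radius, 1, tolerance = 1e-12)
  w2 <- fit_well_circle(c(0, 0), c(2, 0), c(1, 1))
  expect_equal(w2$center, c(1, 0), tolerance = 1e-12)
  expect_equal(w2$radius, 1, tolerance = 1e-12)
  expect_error(fit_well_circle(c(0, 0), c(1, 1), c(2, 2)), "collinear")
})

test_that("otsu thresholds separate a bimodal histogram and flag degeneracy", {
  h <- rep(0, 256); h[51] <- 100; h[201] <- 80   # deltas at bins 50, 200
  t1 <- otsu_thresholds(h, 1)
  expect_gte(t1, 50); expect_lt(t1, 200)
  hd <- rep(0, 256); hd[101] <- 50
  expect_warning(td <- otsu_thresholds(hd, 2), "degenerate")
  expect_equal(as.integer(td), c(100L, 100L))
})

test_that("otsu matches the exhaustive oracle on random histograms", {
  set.seed(51)
  for (i in 1:30) {
    h <- rpois(256, exp(rnorm(256, 2, 1.2)))
    for (m in 1:2) {
      expect_identical(as.integer(otsu_thresholds(h, m)),
                       as.integer(otsu_bruteforce(h, m)),
                       info = sprintf("hist %d, m=%d", i, m))
    }
  }
})

test_that("uniform histogram thresholds at the midpoint", {
  h <- rep(10, 256)
  expect_identical(as.integer(otsu_thresholds(h, 1)),
                   as.integer(otsu_bruteforce(h, 1)))
  expect_true(otsu_thresholds(h, 1) %in% c(127L, 128L))
})

test_that("jaggedness is near 1 for smooth outlines and high for stars", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  circle <- cbind(30 * cos(th), 30 * sin(th))
  expect_lte(jaggedness(circle, 60), 1.05)
  expect_gte(jaggedness(circle, 60), 1 - 0.02)
  star <- cbind((20 + 8 * cos(16 * th)) * cos(th),
                (20 + 8 * cos(16 * th)) * sin(th))
  expect_gt(jaggedness(star, 60), 1.3)
  # an already-smooth n-node contour is nearly a fixed point of smoothing
  nodes <- wormsnap:::resample_polygon(circle, 60)
  expect_equal(jaggedness(nodes, 60), 1, tolerance = 0.01)
  expect_error(jaggedness(circle[1:2, ], 60), "3 points")
})

test_that("detection finds all worms in a clean well and nothing else", {
  spec <- well_spec("clean", curl_probability = 0.3, n_worms = 10,
                    seed = 52, debris_rate = 0, overlap_fraction = 0)
  snap <- generate_snapshot(spec)
  det <- detect_objects(snap$image,
                        well = structure(list(center = snap$well$center,
                                              radius = snap$well$radius),
                                         class = "well_circle"))
  expect_equal(nrow(det$table), 10)
  # each detection matches a distinct ground-truth worm
  d <- as.matrix(dist(rbind(as.matrix(det$table[, c("x", "y")]),
                            as.matrix(snap$truth[, c("x", "y")]))))
  match_d <- d[seq_len(10), 10 + seq_len(10)]
  expect_true(all(apply(match_d, 2, min) < 15))
})

test_that("specks below the area filter and jagged debris are rejected", {
  spec <- well_spec("debris", curl_probability = 0, n_worms = 1,
                    seed = 53, debris_rate = 0, overlap_fraction = 0)
  snap <- generate_snapshot(spec)
  img <- snap$image
  # plant a 5-pixel speck and a large jagged star inside the well
  ctr <- snap$well$center
  img[ctr[1] + 60 + (0:1), ctr[2] + 60 + (0:1)] <- 0.9
  img[ctr[1] + 62, ctr[2] + 60] <- 0.9
  img <- wormsnap:::render_star(img, ctr[1] - 70, ctr[2] - 70, 9, 0.75, 12)
  det <- detect_objects(img,
                        well = structure(list(center = ctr,
                                              radius = snap$well$radius),
                                         class = "well_circle"))
  expect_equal(nrow(det$table), 1)
  expect_lt(abs(det$table$x[1] - snap$truth$x[1]), 15)
})

test_that("blank image yields an empty detection list", {
  img <- matrix(0.05, 256, 256) +
    matrix(rnorm(256^2, 0, 0.01), 256, 256)
  det <- detect_objects(img, params = detection_params())
  expect_equal(nrow(det$table), 0)
})

test_that("crop standardization isolates one object at the dilation radius", {
  # disk of radius rho: dilation radius 4A/P = 2 rho
  img <- matrix(0, 200, 200)
  mask <- matrix(0, 200, 200)
  for (x in 1:200) for (y in 1:200)
    if ((x - 70)^2 + (y - 100)^2 <= 10^2) { img[x, y] <- 1; mask[x, y] <- 1 }
  A <- sum(mask); P <- wormsnap:::poly_perim(wormsnap:::trace_contour(mask))
  expect_equal(4 * A / P, 2 * 10, tolerance = 1.5)

  # neighbor close by: crop must keep exactly one component
  img2 <- img
  for (x in 1:200) for (y in 1:200)
    if ((x - 95)^2 + (y - 100)^2 <= 8^2) img2[x, y] <- 1
  labels <- wormsnap:::cpp_label8(matrix(as.integer(img2 > 0), 200, 200))
  crop <- standardize_crop(img2, labels == 1, labels, 1)
  expect_equal(dim(crop), c(128, 128))
  expect_equal(wormsnap:::n_components(crop > 0), 1)
})

test_that("oversized objects are rescaled into the crop, aspect preserved", {
  img <- matrix(0, 300, 300)
  img[21:260, 141:160] <- 1   # 240 x 20 bar
  mask <- img > 0
  crop <- standardize_crop(img, mask)
  expect_equal(dim(crop), c(128, 128))
  wh <- which(crop > 0, arr.ind = TRUE)
  bb <- c(diff(range(wh[, 1])) + 1, diff(range(wh[, 2])) + 1)
  expect_equal(bb[1] / bb[2], 240 / 20, tolerance = 0.35)
})

test_that("preliminary labels censor outliers and pre-bin by circularity", {
  set.seed(54)
  spec <- well_spec("prelim", curl_probability = 0.5, n_worms = 8,
                    seed = 54, debris_rate = 0, overlap_fraction = 0)
  snap <- generate_snapshot(spec)
  img <- snap$image
  # plant a huge blob (area outlier, ~20x worm scale)
  ctr <- snap$well$center
  for (x in -40:40) for (y in -40:40)
    if (x^2 + y^2 <= 38^2)
      img[ctr[1] + 100 + x, ctr[2] + 10 + y] <- 0.9
  det <- detect_objects(img,
                        well = structure(list(center = ctr,
                                              radius = snap$well$radius),
                                         class = "well_circle"),
                        params = detection_params(max_area_factor = 40))
  det <- prelim_label(det)
  big <- which.max(det$table$area)
  expect_identical(det$table$prelim_label[big], "Censored")

  # circle-like object pre-bins toward Coiled
  circ <- 4 * pi * det$table$area / det$table$perimeter^2
  disky <- which(circ > 0.8)
  expect_true(all(det$table$prelim_label[disky] %in% c("Coiled", "Censored")))

  # off-switch: no censoring when filters are zero
  det0 <- prelim_label(det, filters = list(area_levels = 0, perim_levels = 0,
                                           dim_limit = Inf,
                                           circularity_bins = c(0.35, 0.55, 0.8)))
  expect_false(any(det0$table$prelim_label == "Censored" & circ <= 0.8))
})

test_that("detection success rate does not improve as overlap increases", {
  set.seed(55)
  success_rate <- function(overlap_frac, n_wells = 5) {
    found <- 0; total <- 0
    for (w in seq_len(n_wells)) {
      spec <- well_spec("ov", curl_probability = 0.3, n_worms = 10,
                        debris_rate = 0, overlap_fraction = overlap_frac)
      snap <- generate_snapshot(spec)
      det <- detect_objects(snap$image,
                            well = structure(list(center = snap$well$center,
                                                  radius = snap$well$radius),
                                             class = "well_circle"))
      total <- total + nrow(snap$truth)
      if (nrow(det$table) > 0) {
        for (t in seq_len(nrow(snap$truth))) {
          dd <- sqrt((det$table$x - snap$truth$x[t])^2 +
                       (det$table$y - snap$truth$y[t])^2)
          # a clean single-worm detection has roughly worm-sized area
          if (min(dd) < 15 &&
              det$table$area[which.min(dd)] < 1.8 * 300) found <- found + 1
        }
      }
    }
    found / total
  }
  s0 <- success_rate(0)
  s_hi <- success_rate(0.45)
  expect_gt(s0, s_hi - 0.02)   # monotone up to sampling slack
  expect_lt(s_hi, 0.97)        # crowding visibly costs detections
})
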