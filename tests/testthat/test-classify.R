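# Snapshot classification machinery (network-free parts): texture
# binarization, mask variants, ensemble arithmetic, overrides.

test_that("texture binaries are nested and empty for constant images", {
  spec <- well_spec("tb", curl_probability = 0.3, n_worms = 6, seed = 71,
                    debris_rate = 0)
  snap <- generate_snapshot(spec)
  b <- texture_binarize(snap$image)
  expect_length(b, 3)
  expect_true(all(b[[2]][b[[3]] == 1] == 1))  # binary3 subset of binary2
  expect_true(all(b[[1]][b[[2]] == 1] == 1))  # binary2 subset of binary1
  th <- attr(b, "thresholds")
  expect_true(all(diff(th) >= 0))

  expect_warning(b0 <- texture_binarize(matrix(0, 64, 64)), "constant")
  expect_true(all(sapply(b0, sum) == 0))
})

test_that("worm pixels are foreground at the lowest texture threshold", {
  img <- matrix(0.05, 200, 200)
  set.seed(72)
  g <- sample_posture("NonCurled")
  gw <- wormsnap:::render_worm_gray(g, c(200, 200))
  img <- pmax(img, 0.55 + 0.45 * gw * (gw > 0))
  img <- img + matrix(rnorm(200 * 200, 0, 0.01), 200, 200)
  b <- texture_binarize(img)
  core <- gw > 0.8   # spine pixels, far from any mask boundary effect
  expect_gt(mean(b[[1]][core]), 0.9)
})

test_that("mask variants are nested dilations standardized to one object", {
  set.seed(73)
  spec <- well_spec("mv", curl_probability = 0, n_worms = 2, seed = 73,
                    debris_rate = 0, overlap_fraction = 0)
  snap <- generate_snapshot(spec)
  mask <- snap$image > 0.5
  lab <- wormsnap:::cpp_label8(matrix(as.integer(mask), 384, 384))
  comp <- lab == 1
  v <- mask_variants(comp, snap$image)
  expect_length(v, 4)
  r <- attr(v, "radii")
  expect_equal(r / r[1], c(1, 2, 3, 4), tolerance = 1e-9)
  areas <- sapply(v, function(m) sum(m > 0))
  expect_true(all(diff(areas) >= 0))  # larger dilation keeps more pixels
  for (crop in v) expect_equal(wormsnap:::n_components(crop > 0), 1)
})

test_that("component at the image edge still yields a single-object crop", {
  img <- matrix(0, 150, 150)
  img[1:20, 70:76] <- 0.9   # touching x = 1 border
  v <- mask_variants(img > 0, img)
  for (crop in v) expect_equal(wormsnap:::n_components(crop > 0), 1)
})

test_that("ensemble averaging follows exact arithmetic with Censored ties", {
  s <- rbind(c(0.9, 0.1, 0, 0, 0), c(0.5, 0.5, 0, 0, 0))
  e <- ensemble_classify(s)
  expect_equal(unname(e$scores), c(0.7, 0.3, 0, 0, 0))
  expect_identical(e$label, "Coiled")

  one <- c(0.2, 0.3, 0.1, 0.25, 0.15)
  expect_equal(unname(ensemble_classify(rbind(one, one, one))$scores), one)

  set.seed(74)
  m <- matrix(runif(60), 12, 5); m <- m / rowSums(m)
  expect_equal(unname(ensemble_classify(m)$scores), colMeans(m),
               tolerance = 1e-9)

  tie <- rbind(c(0.4, 0.1, 0.05, 0.05, 0.4))
  expect_identical(ensemble_classify(tie)$label, "Censored")
})

test_that("override replaces labels, flags, and logs provenance", {
  res <- wormsnap:::empty_snapshot_result()
  res <- rbind(res, data.frame(object_id = 1L, x = 5, y = 5, n_masks = 4L,
                               Coiled = 0.9, Curled = 0.05, NearCurled = 0.02,
                               NonCurled = 0.02, Censored = 0.01,
                               label = "Coiled", overridden = FALSE))
  class(res) <- c("snapshot_result", "data.frame")
  r2 <- override(res, 1, "Censored")
  expect_identical(r2$label, "Censored")
  expect_true(r2$overridden)
  expect_equal(nrow(attr(r2, "override_log")), 1)
  # no-op override still sets the audit flag
  r3 <- override(res, 1, "Coiled")
  expect_true(r3$overridden)
  expect_error(override(res, 99, "Coiled"), "unknown object")
  # overridden-to-Censored objects drop out of posture statistics
  wm <- well_metrics(r2$label)
  expect_equal(wm$n_classified, 0)
})

test_that("empty frame lists and blank frames produce empty results", {
  expect_identical(analyze_video(list(), NULL), list())
})
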