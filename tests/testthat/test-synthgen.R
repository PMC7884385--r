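# Synthetic generator: class rules by construction, determinism,
# bookkeeping at the crop / snapshot / screen scales.

test_that("sampled postures satisfy their class rules when re-measured", {
  set.seed(31)
  for (cls in posture_classes(worm_only = TRUE)) {
    for (i in 1:8) {
      g <- sample_posture(cls)
      expect_identical(posture_rule_class(g), cls)
    }
  }
})

test_that("coiled samples render with a hole; fixed seed reproduces geometry", {
  set.seed(32)
  g <- sample_posture("Coiled")
  ext <- ceiling(g$body_length + 4 * max(g$r) + 8)
  expect_gte(count_holes(render_mask(g, c(ext, ext))), 1)

  set.seed(99); g1 <- sample_posture("Curled")
  set.seed(99); g2 <- sample_posture("Curled")
  expect_identical(g1$alpha, g2$alpha)
  expect_identical(g1$r, g2$r)
  expect_identical(g1$body_length, g2$body_length)
})

test_that("mask dataset is balanced, labeled, single-object", {
  ds <- generate_mask_dataset(6, seed = 33)
  expect_equal(as.integer(table(ds$labels)[posture_classes()]),
               c(6L, 6L, 6L, 6L, 24L))
  expect_equal(dim(ds$images), c(128, 128, 48))
  for (i in seq_len(48)) {
    img <- matrix(as.integer(ds$images[, , i]), 128, 128)
    expect_equal(wormsnap:::n_components(img > 0), 1)
  }
  # custom censored pool size
  ds2 <- generate_mask_dataset(4, seed = 34, n_censored = 4)
  expect_equal(as.integer(table(ds2$labels)[posture_classes()]),
               rep(4L, 5))
})

test_that("mask dataset generation is deterministic under a fixed seed", {
  d1 <- generate_mask_dataset(3, seed = 35)
  d2 <- generate_mask_dataset(3, seed = 35)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$labels, d2$labels)
})

test_that("snapshot generation respects worm counts and class draws", {
  spec0 <- well_spec("empty", n_worms = 0, seed = 36, debris_rate = 0)
  s0 <- generate_snapshot(spec0)
  expect_equal(nrow(s0$truth), 0)
  expect_equal(dim(s0$image), c(384, 384))

  spec_nc <- well_spec("flat", curl_probability = 0, n_worms = 8, seed = 37)
  snc <- generate_snapshot(spec_nc)
  expect_equal(nrow(snc$truth), 8)
  expect_true(all(snc$truth$class == "NonCurled"))

  spec_crowd <- well_spec("crowded", n_worms = 400, seed = 38)
  expect_error(generate_snapshot(spec_crowd), "cannot place")
})

test_that("screen truth bookkeeping: wells, rounds, snapshots, Poisson counts", {
  conds <- list(well_spec("a", 0.3, n_worms = 12),
                well_spec("b", 0.1, n_worms = 12))
  scr <- generate_screen(conds, wells_per_condition = 35, rounds = 2,
                         snapshots_per_round = 3, seed = 39)
  expect_equal(nrow(scr$plate_map), 70)
  expect_setequal(unique(scr$truth$round), 1:2)
  expect_setequal(unique(scr$truth$snapshot), 1:3)
  # per-well worm count constant across stills, Poisson(12) across wells
  per_still <- stats::aggregate(worm_id ~ well + round + snapshot,
                                scr$truth, length)
  per_well <- stats::aggregate(worm_id ~ well, per_still,
                               function(x) length(unique(x)))
  expect_true(all(per_well$worm_id == 1))
  counts <- stats::aggregate(worm_id ~ well, per_still, max)$worm_id
  se <- sqrt(12 / length(counts))
  expect_lt(abs(mean(counts) - 12), 4 * se + 0.5)
})

test_that("pooled curled-family fraction matches the generating probability", {
  conds <- list(well_spec("p3", 0.3, n_worms = 12))
  scr <- generate_screen(conds, wells_per_condition = 7, rounds = 3,
                         snapshots_per_round = 7, seed = 40)
  curled <- scr$truth$class %in% c("Coiled", "Curled", "NearCurled")
  n <- length(curled)
  ci <- 0.3 + c(-1, 1) * 3.5 * sqrt(0.3 * 0.7 / n)
  expect_gt(mean(curled), ci[1])
  expect_lt(mean(curled), ci[2])
})

test_that("time-decay option produces a linear ratio trend across rounds", {
  conds <- list(
    well_spec("ctrl", 0.10, n_worms = 14, decay = 0),
    well_spec("trt", 0.30, n_worms = 14, decay = -0.005))
  scr <- generate_screen(conds, wells_per_condition = 30, rounds = 3,
                         snapshots_per_round = 7, seed = 41,
                         round_times = c(0, 20, 40))
  curled <- scr$truth$class %in% c("Coiled", "Curled", "NearCurled")
  agg <- stats::aggregate(curled ~ condition + time_min,
                          cbind(scr$truth, curled = curled), mean)
  ratios <- sapply(c(0, 20, 40), function(t)
    agg$curled[agg$condition == "trt" & agg$time_min == t] /
      agg$curled[agg$condition == "ctrl" & agg$time_min == t])
  fit <- time_decay_fit(c(0, 20, 40), ratios)
  # true ratio slope = decay / p_ctrl = -0.005 / 0.10 = -0.05 per minute
  expect_lt(abs(fit$slope - (-0.05)), 0.02)
})
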