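# Assay analytics: well metrics, exclusion, normalization, hit calls,
# time-decay fits, and group comparisons against closed-form oracles.

test_that("well metrics compute counts and percentages over classified worms", {
  labels <- c(rep("Coiled", 2), "Curled", "NearCurled", rep("NonCurled", 6),
              rep("Censored", 3))
  wm <- well_metrics(labels)
  expect_equal(wm$n_classified, 10)
  expect_equal(wm$n_censored, 3)
  expect_equal(wm$percent_coiled, 20)
  expect_equal(wm$percent_coiled_curled, 30)
  expect_equal(wm$percent_curling_all, 40)
  expect_false(wm$excluded)

  expect_true(well_metrics(c("Coiled", "NonCurled", "Censored"))$excluded)
  all_non <- well_metrics(rep("NonCurled", 8))
  expect_equal(all_non$percent_coiled, 0)
  expect_equal(all_non$percent_curling_all, 0)
})

test_that("count conservation holds per well and globally", {
  set.seed(81)
  labels <- sample(posture_classes(), 200, replace = TRUE)
  wells <- sample(sprintf("W%02d", 1:10), 200, replace = TRUE)
  obj <- data.frame(condition = "c", well = wells, label = labels)
  wt <- summarize_wells(obj)
  per_well_tot <- wt$n_coiled + wt$n_curled + wt$n_nearcurled +
    wt$n_noncurled + wt$n_censored
  expect_equal(per_well_tot, as.integer(table(wells)[wt$well]),
               ignore_attr = TRUE)
  expect_equal(sum(per_well_tot), 200)
  expect_equal(sum(wt$n_classified), sum(labels != "Censored"))
})

test_that("mean ratio and its degenerate case", {
  expect_equal(mean_ratio(list(mean = 27), list(mean = 10)), 2.7)
  expect_equal(mean_ratio(list(mean = 5), list(mean = 5)), 1.0)
  expect_warning(r <- mean_ratio(list(mean = 5), list(mean = 0)), "zero")
  expect_true(is.na(r))
})

test_that("screen normalization sets vehicle to 100 and flags hits", {
  drugs <- data.frame(condition = c("d1", "d2"), mean = c(8, 19),
                      n_wells = 7, n_worms = 80)
  veh <- data.frame(condition = "vehicle", mean = 20, n_wells = 7,
                    n_worms = 80)
  st <- normalize_screen(drugs, veh)
  expect_equal(st$normalized_pct[st$condition == "vehicle"], 100)
  expect_equal(st$normalized_pct[st$condition == "d1"], 40)
  expect_true(st$hit[st$condition == "d1"])
  expect_equal(st$normalized_pct[st$condition == "d2"], 95)
  expect_false(st$hit[st$condition == "d2"])
  # scale invariance of hit calling
  st2 <- normalize_screen(transform(drugs, mean = mean * 3),
                          transform(veh, mean = mean * 3))
  expect_equal(st2$hit, st$hit)
})

test_that("time-decay fit recovers exact lines and flat series", {
  f <- time_decay_fit(c(0, 10, 20), c(3, 2, 1))
  expect_equal(f$slope, -0.1, tolerance = 1e-12)
  expect_equal(f$intercept, 3, tolerance = 1e-12)
  expect_equal(time_decay_fit(c(0, 5, 10, 15), rep(2.2, 4))$slope, 0,
               tolerance = 1e-12)
  expect_error(time_decay_fit(c(0, 1), c(1, 2)), "3")
})

test_that("two-group comparison matches the pooled-variance t oracle", {
  rep2 <- compare_conditions(list(a = c(1, 2, 3), b = c(4, 5, 6)),
                             control = "a")
  # hand-computed: diff -3, sp^2 = 1, se = sqrt(2/3), t = -3/0.8165
  expect_equal(rep2$statistic, -3 / sqrt(2 / 3), tolerance = 1e-3)
  expect_equal(rep2$statistic, -3.674, tolerance = 1e-3)
  expect_equal(rep2$df, 4)
  expect_equal(rep2$p, 0.02131, tolerance = 1e-3)
  expect_identical(rep2$stars, "*")

  same <- compare_conditions(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gt(same$p, 0.99)
  expect_identical(same$stars, "ns")
  expect_error(compare_conditions(list(a = 1, b = c(1, 2))), "2 wells")
})

test_that("Dunnett comparisons flag only the shifted group", {
  set.seed(82)
  hits <- 0
  for (rep_i in 1:10) {
    groups <- list(ctrl = rnorm(8, 10, 1), g1 = rnorm(8, 10, 1),
                   g2 = rnorm(8, 15, 1))
    out <- compare_conditions(groups, control = "ctrl")
    p2 <- out$p[grepl("g2", out$comparison)]
    p1 <- out$p[grepl("g1", out$comparison)]
    if (p2 < 0.05 && p1 >= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("truth-level screen recovers planted hits through the assay stack", {
  set.seed(83)
  conds <- c(list(well_spec("vehicle", 0.30, n_worms = 12, role = "vehicle")),
             lapply(1:3, function(i)
               well_spec(paste0("hit", i), 0.30 * 0.4, n_worms = 12)),
             lapply(1:4, function(i)
               well_spec(paste0("null", i), 0.30 * 0.9, n_worms = 12)))
  scr <- generate_screen(conds, wells_per_condition = 7, rounds = 3,
                         snapshots_per_round = 7, seed = 83)
  obj <- data.frame(condition = scr$truth$condition, well = scr$truth$well,
                    label = scr$truth$class)
  wt <- summarize_wells(obj)
  cs <- condition_summary(wt, metric = "all")
  veh <- cs[cs$condition == "vehicle", ]
  st <- normalize_screen(cs[cs$condition != "vehicle", ], veh)
  expect_setequal(st$condition[st$hit], c("hit1", "hit2", "hit3"))
})
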