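# Training machinery: augmentation bookkeeping, stratified splits,
# evaluation reports, capacity sanity check, softmax invariants.

test_that("reflections are involutions and rotation by 0 is near-identity", {
  set.seed(61)
  img <- wormsnap:::worm_crop(sample_posture("NonCurled"))
  expect_identical(img[128:1, ][128:1, ], img)
  expect_identical(img[, 128:1][, 128:1], img)
  rot0 <- wormsnap:::cpp_rotate(img, 0)
  expect_equal(rot0, img, tolerance = 1e-6)
  rot360 <- wormsnap:::cpp_rotate(img, 360)
  expect_equal(rot360, img, tolerance = 1e-5)
})

test_that("augmentation multiplies class counts exactly", {
  ds <- generate_mask_dataset(3, seed = 62, n_censored = 3)
  aug <- augment(ds, factor = 3, seed = 1)
  expect_equal(unname(table(aug$labels)), unname(table(ds$labels)) * 3)
  expect_equal(dim(aug$images)[3], 45)
})

test_that("stratified split is exact, disjoint, exhaustive, reproducible", {
  ds <- generate_mask_dataset(20, seed = 63, n_censored = 20)  # 100 crops
  sp <- split_dataset(ds, training_config(seed = 7))
  expect_equal(length(sp$train$labels), 75)
  expect_equal(length(sp$val$labels), 10)
  expect_equal(length(sp$test$labels), 15)
  for (cls in posture_classes())
    expect_equal(sum(sp$train$labels == cls), 15)
  sp2 <- split_dataset(ds, training_config(seed = 7))
  expect_identical(sp$train$labels, sp2$train$labels)
  expect_identical(sp$train$images, sp2$train$images)
  # union of parts equals the input set
  all_imgs <- c(sp$train$images, sp$val$images, sp$test$images)
  expect_equal(length(all_imgs), length(ds$images))
  expect_error(split_dataset(subset_dataset(ds, 1:10)), "20")
  small <- subset_dataset(ds, c(1:2, 21:30, 41:50, 61:70, 81:90))
  expect_error(split_dataset(small), "at least 3")
})

test_that("evaluation report matches hand-computed confusion matrices", {
  classes <- posture_classes()
  truth <- rep(classes, times = c(4, 3, 3, 5, 5))
  # perfect predictor
  rp <- wormsnap:::report_from_predictions(truth, truth)
  expect_true(all(rp$confusion_matrix[row(rp$confusion_matrix) !=
                                        col(rp$confusion_matrix)] == 0))
  expect_equal(unname(rp$per_class_fdr), rep(0, 5))
  expect_equal(unname(rp$per_class_fnr), rep(0, 5))
  expect_equal(rp$worm_vs_censored_accuracy, 1)
  expect_equal(rp$worm_class_accuracy, 1)

  # constant predictor: one filled row, FNR 1 elsewhere
  rc <- wormsnap:::report_from_predictions(rep("Coiled", 20), truth)
  expect_equal(unname(rowSums(rc$confusion_matrix)), c(20, 0, 0, 0, 0))
  expect_equal(unname(rc$per_class_fnr), c(0, 1, 1, 1, 1))
  expect_equal(rc$worm_vs_censored_accuracy, 15 / 20)

  # hand-tallied 20-item case
  pred <- truth
  pred[1] <- "Curled"      # Coiled -> Curled
  pred[8] <- "Censored"    # NearCurled -> Censored
  pred[16] <- "NonCurled"  # Censored -> NonCurled
  rh <- wormsnap:::report_from_predictions(pred, truth)
  expect_equal(rh$confusion_matrix["Curled", "Coiled"], 1)
  expect_equal(rh$accuracy, 17 / 20)
  expect_equal(rh$worm_vs_censored_accuracy, 18 / 20)
  # among both-worm pairs: 14 cases, 1 wrong (Coiled->Curled)
  expect_equal(rh$worm_class_accuracy, 13 / 14)
})

test_that("network outputs are probability vectors and reproducible", {
  ds <- generate_mask_dataset(2, seed = 64, n_censored = 2)
  arch <- network_architecture()
  ptr <- wormsnap:::new_network_ptr(arch, 5)
  s <- wormsnap:::cnn_predict_cpp(ptr, ds$images, seq_len(10))
  expect_true(all(s >= 0))
  expect_equal(rowSums(s), rep(1, 10), tolerance = 1e-6)
  ptr2 <- wormsnap:::new_network_ptr(arch, 5)
  s2 <- wormsnap:::cnn_predict_cpp(ptr2, ds$images, seq_len(10))
  expect_identical(s, s2)  # same init seed, same weights, same scores
})

test_that("the network can overfit a tiny training set", {
  ds <- generate_mask_dataset(2, seed = 65, n_censored = 2)  # 10 crops
  datasets <- list(train = ds, val = ds, test = ds)
  cfg <- training_config(batch_size = 10, max_epochs = 80, seed = 2,
                         patience = 80, val_stop = 0.999, augment = FALSE)
  net <- train_network(network_architecture(), datasets, cfg)
  expect_gte(max(net$history$val_acc), 0.999)
})

test_that("trained networks serialize and reload with identical scores", {
  ds <- generate_mask_dataset(2, seed = 66, n_censored = 2)
  datasets <- list(train = ds, val = ds)
  cfg <- training_config(batch_size = 10, max_epochs = 1, seed = 3,
                         augment = FALSE)
  net <- train_network(network_architecture(), datasets, cfg)
  s1 <- predict_scores(net, ds)
  path <- tempfile(fileext = ".rds")
  save_network(net, path)
  net2 <- load_network(path)
  expect_equal(predict_scores(net2, ds), s1, tolerance = 1e-7)
  expect_true(file.exists(sub("\\.rds$", ".json", path)))
})
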