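# Training of the five-class posture network: augmentation, stratified
# splitting, SGD optimization, and evaluation reporting.

#' Training configuration
#'
#' Optimizer and split settings. Defaults: mini-batch 256, momentum 0.9,
#' L2 penalty 1e-4, learning rate 0.005, 75/10/15 train/validation/test
#' split, at most 30 epochs with early stopping on validation accuracy
#' (patience 5), per-epoch shuffling and random re-rotation of the
#' training images.
#'
#' @param batch_size Mini-batch size.
#' @param momentum SGD momentum.
#' @param weight_decay L2 regularization coefficient.
#' @param learning_rate Learning rate.
#' @param max_epochs Epoch cap.
#' @param seed RNG seed for initialization, shuffling and augmentation.
#' @param split Train/validation/test fractions (sum to 1).
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_stop Stop once validation accuracy reaches this value.
#' @param augment Re-rotate/reflect training images every epoch.
#' @return `training_config` list.
#' @export
training_config <- function(batch_size = 256, momentum = 0.9,
                            weight_decay = 1e-4, learning_rate = 0.005,
                            max_epochs = 30, seed = 1,
                            split = c(0.75, 0.10, 0.15), patience = 5,
                            val_stop = 0.995, augment = TRUE) {
  stopifnot(batch_size >= 1, abs(sum(split) - 1) < 1e-8, length(split) == 3)
  structure(list(batch_size = batch_size, momentum = momentum,
                 weight_decay = weight_decay, learning_rate = learning_rate,
                 max_epochs = max_epochs, seed = seed, split = split,
                 patience = patience, val_stop = val_stop, augment = augment),
            class = "training_config")
}

#' Augment a mask dataset
#'
#' Expands each crop into `factor` copies under random rotation (uniform
#' 0-360 degrees, mask-safe nearest-neighbor sampling, zero background)
#' and independent
#' horizontal/vertical reflections; labels are preserved. Per-epoch
#' re-augmentation during training is handled by [train_network()]
#' itself; this builds static augmented sets.
#'
#' @param dataset A `mask_dataset`.
#' @param factor Copies per image.
#' @param seed Optional RNG seed.
#' @return Augmented `mask_dataset` (`N * factor` crops).
#' @export
augment <- function(dataset, factor = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(dataset$labels)
  size <- dim(dataset$images)[1]
  imgs <- vector("list", n * factor)
  labels <- character(n * factor)
  k <- 0
  for (i in seq_len(n)) {
    img <- matrix(as.integer(dataset$images[, , i]) / 255, size, size)
    for (f in seq_len(factor)) {
      k <- k + 1
      out <- cpp_rotate(img, runif(1, 0, 360), bilinear = FALSE)
      if (runif(1) < 0.5) out <- out[size:1, ]
      if (runif(1) < 0.5) out <- out[, size:1]
      imgs[[k]] <- out
      labels[k] <- as.character(dataset$labels[i])
    }
  }
  structure(list(images = to_raw_images(imgs, size),
                 labels = factor(labels, levels = POSTURE_CLASSES),
                 meta = data.frame(index = seq_len(k), label = labels,
                                   source = "augment")),
            class = "mask_dataset")
}

#' Stratified train/validation/test split
#'
#' Disjoint, exhaustive, stratified by class, deterministic under the
#' seed.
#'
#' @param dataset A `mask_dataset` (>= 20 crops; every present class
#'   needs at least 3 members).
#' @param config A [training_config()] (uses `split` and `seed`), or a
#'   length-3 fraction vector.
#' @return List of `mask_dataset`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(dataset, config = training_config()) {
  split <- if (is.numeric(config)) config else config$split
  seed <- if (is.numeric(config)) NULL else config$seed
  n <- length(dataset$labels)
  if (n < 20) stop("dataset too small to split (need >= 20)")
  counts <- table(dataset$labels)
  present <- counts[counts > 0]
  if (any(present < 3))
    stop("every class needs at least 3 members; offending: ",
         paste(names(present)[present < 3], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  idx <- list(train = integer(), val = integer(), test = integer())
  for (cls in names(present)) {
    ci <- sample(which(dataset$labels == cls))
    m <- length(ci)
    n_tr <- round(split[1] * m)
    n_va <- round(split[2] * m)
    idx$train <- c(idx$train, ci[seq_len(n_tr)])
    idx$val <- c(idx$val, ci[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, ci[setdiff(seq_len(m), seq_len(n_tr + n_va))])
  }
  lapply(idx, function(i) subset_dataset(dataset, sort(i)))
}

#' Train the posture network
#'
#' SGD with momentum on cross-entropy plus L2 penalty; training images
#' are shuffled and randomly rotated/reflected every epoch; the returned
#' weights are those of the best validation-accuracy epoch.
#'
#' @param arch A [network_architecture()].
#' @param datasets List with `train`, `val`, `test` `mask_dataset`s (as
#'   from [split_dataset()]).
#' @param config A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return A `trained_network`: weights, architecture, config, training
#'   `history` (per-epoch loss and accuracies), and `best_epoch`.
#' @export
train_network <- function(arch = network_architecture(), datasets,
                          config = training_config(), verbose = FALSE) {
  stopifnot(inherits(datasets$train, "mask_dataset"),
            inherits(datasets$val, "mask_dataset"))
  ptr <- new_network_ptr(arch, config$seed)
  res <- cnn_train_cpp(ptr,
                       datasets$train$images,
                       as.integer(datasets$train$labels),
                       datasets$val$images,
                       as.integer(datasets$val$labels),
                       as.integer(config$max_epochs),
                       as.integer(config$batch_size),
                       config$learning_rate, config$momentum,
                       config$weight_decay, isTRUE(config$augment),
                       as.integer(config$seed) + 1L,
                       as.integer(config$patience), config$val_stop,
                       isTRUE(verbose))
  if (isTRUE(res$diverged))
    stop("training diverged (loss became NaN); lower the learning rate")
  ep <- res$epochs
  history <- data.frame(epoch = seq_len(ep),
                        train_loss = res$train_loss[seq_len(ep)],
                        train_acc = res$train_acc[seq_len(ep)],
                        val_acc = res$val_acc[seq_len(ep)])
  structure(list(ptr = ptr, weights = cnn_get_weights(ptr), arch = arch,
                 config = config, history = history,
                 best_epoch = res$best_epoch,
                 stop_reason = res$stop_reason,
                 labels = POSTURE_CLASSES),
            class = "trained_network")
}

#' Evaluate a network on a labeled test set
#'
#' @param network A `trained_network`.
#' @param test_set A `mask_dataset`.
#' @return `evaluation_report`: 5x5 `confusion_matrix` (rows = predicted,
#'   columns = true), per-class false discovery and false negative rates,
#'   `worm_vs_censored_accuracy` (binary collapse), `worm_class_accuracy`
#'   (4-class accuracy among objects whose true and predicted classes are
#'   both worm postures), and overall `accuracy`.
#' @export
evaluate <- function(network, test_set) {
  if (length(test_set$labels) == 0) stop("test set is empty")
  pred <- predict_classes(network, test_set)
  report_from_predictions(pred, test_set$labels)
}

# confusion matrix and rates from predicted/true label vectors
report_from_predictions <- function(pred, truth) {
  pred <- factor(as.character(pred), levels = POSTURE_CLASSES)
  truth <- factor(as.character(truth), levels = POSTURE_CLASSES)
  cm <- table(predicted = pred, true = truth)
  fdr <- vapply(POSTURE_CLASSES, function(k) {
    tot <- sum(cm[k, ])
    if (tot == 0) 0 else (tot - cm[k, k]) / tot
  }, numeric(1))
  fnr <- vapply(POSTURE_CLASSES, function(k) {
    tot <- sum(cm[, k])
    if (tot == 0) 0 else (tot - cm[k, k]) / tot
  }, numeric(1))
  worm_t <- truth %in% WORM_CLASSES
  worm_p <- pred %in% WORM_CLASSES
  wc <- worm_t & worm_p
  structure(list(confusion_matrix = cm, per_class_fdr = fdr,
                 per_class_fnr = fnr,
                 worm_vs_censored_accuracy = mean(worm_t == worm_p),
                 worm_class_accuracy =
                   if (any(wc)) mean(pred[wc] == truth[wc]) else NA_real_,
                 accuracy = mean(pred == truth),
                 n = length(truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation on %d crops: accuracy %.3f\n", x$n, x$accuracy))
  cat(sprintf("  worm vs censored: %.3f | worm 4-class: %.3f\n",
              x$worm_vs_censored_accuracy, x$worm_class_accuracy))
  print(x$confusion_matrix)
  invisible(x)
}
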