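# R-side wrapper around the compiled five-class CNN.

#' Network architecture description
#'
#' Fixed convolutional topology for 128x128 single-channel crops:
#' conv 16@3x3 (stride 1, pad 2), 3x3 max-pool (stride 1, pad 1),
#' conv 32@3x3 (pad 1), 2x2 max-pool (stride 2), conv `conv3_filters`@3x3
#' (pad `conv3_pad`), then fully connected 100 - 100 - 5 with dropout
#' before the last layer and a softmax output. ReLU follows every
#' convolution and hidden fully connected layer.
#'
#' @param conv3_filters Filters in the third convolution (64 default; 16
#'   with `conv3_pad = 2` is the narrower alternative).
#' @param conv3_pad Padding of the third convolution.
#' @param dropout Dropout probability before the final layer.
#' @return `network_architecture` list.
#' @export
network_architecture <- function(conv3_filters = 64, conv3_pad = 1,
                                 dropout = 0.25, input_scale = 1,
                                 init_gain = 1) {
  stopifnot(conv3_filters >= 1, conv3_pad %in% c(1, 2),
            dropout >= 0, dropout < 1, input_scale > 0, init_gain > 0)
  structure(list(conv3_filters = conv3_filters, conv3_pad = conv3_pad,
                 dropout = dropout, input_scale = input_scale,
                 init_gain = init_gain, input = c(128, 128, 1),
                 n_classes = 5),
            class = "network_architecture")
}

#' @export
print.network_architecture <- function(x, ...) {
  cat("C-NN architecture (input 128x128x1):\n")
  cat("  conv 16@3x3 s1 p2 + ReLU | maxpool 3x3 s1 p1\n")
  cat("  conv 32@3x3 s1 p1 + ReLU | maxpool 2x2 s2\n")
  cat(sprintf("  conv %d@3x3 s1 p%d + ReLU\n", x$conv3_filters, x$conv3_pad))
  cat(sprintf("  fc 100 + ReLU | fc 100 + ReLU | dropout %.2f | fc 5 | softmax\n",
              x$dropout))
  invisible(x)
}

new_network_ptr <- function(arch, seed) {
  cnn_new(arch$conv3_filters, arch$conv3_pad, arch$dropout, as.integer(seed),
          if (is.null(arch$input_scale)) 1 else arch$input_scale,
          if (is.null(arch$init_gain)) 1 else arch$init_gain)
}

# rebuild the external pointer from stored weights if it went stale
# (e.g. after loading a serialized network in a fresh session)
network_ptr <- function(network) {
  ptr <- network$ptr
  ok <- !is.null(ptr) &&
    tryCatch(cnn_ptr_valid(ptr), error = function(e) FALSE)
  if (!ok) {
    ptr <- new_network_ptr(network$arch, 1L)
    cnn_set_weights(ptr, network$weights)
  }
  ptr
}

# images: list of 128x128 matrices (0-1) or raw array -> raw array
crops_to_raw <- function(crops, size = 128) {
  if (is.raw(crops)) return(crops)
  if (is.matrix(crops)) crops <- list(crops)
  to_raw_images(crops, size)
}

#' Class scores for mask crops
#'
#' Softmax probabilities over the five posture classes (dropout off).
#'
#' @param network A `trained_network`.
#' @param crops A `mask_dataset`, raw image array, matrix, or list of
#'   128x128 grayscale matrices.
#' @return Matrix `n x 5` with columns [posture_classes()]; rows sum to 1.
#' @export
predict_scores <- function(network, crops) {
  if (inherits(crops, "mask_dataset")) crops <- crops$images
  raw <- crops_to_raw(crops)
  n <- dim(raw)[3]
  s <- cnn_predict_cpp(network_ptr(network), raw, seq_len(n))
  colnames(s) <- POSTURE_CLASSES
  s
}

#' Predicted class labels for mask crops
#'
#' @inheritParams predict_scores
#' @return Factor of predicted classes.
#' @export
predict_classes <- function(network, crops) {
  s <- predict_scores(network, crops)
  factor(POSTURE_CLASSES[max.col(s, ties.method = "first")],
         levels = POSTURE_CLASSES)
}

#' Save a trained network
#'
#' Weights go to an RDS checkpoint; the architecture and label map go to
#' a JSON sidecar (same path with extension `.json`).
#'
#' @param network A `trained_network`.
#' @param path Checkpoint file path.
#' @export
save_network <- function(network, path) {
  obj <- network
  obj$ptr <- NULL
  saveRDS(obj, path)
  jsonlite::write_json(
    list(architecture = unclass(network$arch), labels = POSTURE_CLASSES,
         best_epoch = network$best_epoch),
    paste0(tools::file_path_sans_ext(path), ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a trained network saved by [save_network()]
#'
#' @param path Checkpoint file path.
#' @return A `trained_network`.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  network <- readRDS(path)
  network$ptr <- new_network_ptr(network$arch, 1L)
  cnn_set_weights(network$ptr, network$weights)
  network
}

#' @export
print.trained_network <- function(x, ...) {
  cat("trained_network:")
  if (!is.null(x$history)) {
    cat(sprintf(" %d epochs, best val acc %.3f (epoch %d)\n",
                nrow(x$history), max(x$history$val_acc, na.rm = TRUE),
                x$best_epoch))
  } else cat(" (untrained weights)\n")
  invisible(x)
}
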