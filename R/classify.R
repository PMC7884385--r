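# Fully automated snapshot scoring: texture binarization at three Otsu
# levels, 8-connected component extraction, de-duplication across
# binarizations, four dilation mask variants per component, and
# ensemble-averaged network scores per object.

#' Binarize a snapshot at three texture thresholds
#'
#' The image is passed through a local standard-deviation filter (worms
#' are thin, so every window over a worm spans an intensity edge and
#' responds strongly), then binarized at each of the three thresholds of
#' a 3-level Otsu decomposition of the filtered image. Thresholds are
#' ascending, so the binaries are nested.
#'
#' @param image Grayscale matrix.
#' @param params A [detection_params()] (uses `std_window`).
#' @return List of three binary matrices (attr `thresholds`); a constant
#'   image yields three empty binaries with a warning.
#' @export
texture_binarize <- function(image, params = detection_params()) {
  sf <- cpp_stdfilt(image, params$std_window)
  hi <- max(sf)
  if (hi <= 1e-12) {
    warning("constant image: no texture to binarize")
    empty <- matrix(0L, nrow(image), ncol(image))
    return(structure(list(empty, empty, empty), thresholds = c(NA, NA, NA)))
  }
  th <- otsu_thresholds(hist256(as.vector(sf), hi), 3) / 255 * hi
  out <- lapply(th, function(t)
    matrix(as.integer(sf > t), nrow(image), ncol(image)))
  structure(out, thresholds = th)
}

#' Four dilation mask variants of a component
#'
#' Dilates the component with disks of radius `r0 * {0.5, 1, 1.5, 2}`
#' where `r0 = 4 * A / P`, and standardizes each to a 128x128 crop
#' containing exactly one 8-connected object.
#'
#' @param mask Binary component mask.
#' @param image Grayscale source image.
#' @param labels Optional label matrix for neighbor deletion.
#' @param id Label id of the component.
#' @param params A [detection_params()].
#' @return List of four 128x128 crops (attr `radii`).
#' @export
mask_variants <- function(mask, image, labels = NULL, id = NULL,
                          params = detection_params()) {
  A <- sum(mask != 0)
  wh <- which(mask != 0, arr.ind = TRUE)
  bx0 <- max(1, min(wh[, 1]) - 2); bx1 <- min(nrow(mask), max(wh[, 1]) + 2)
  by0 <- max(1, min(wh[, 2]) - 2); by1 <- min(ncol(mask), max(wh[, 2]) + 2)
  P <- poly_perim(trace_contour(mask[bx0:bx1, by0:by1, drop = FALSE]))
  r0 <- 4 * A / max(P, 1)
  radii <- r0 * c(0.5, 1, 1.5, 2)
  out <- lapply(radii, function(r)
    standardize_crop(image, mask, labels, id, params, perimeter = P,
                     dilation_radius = r))
  attr(out, "radii") <- radii
  out
}

#' Ensemble-average class scores and decide a label
#'
#' @param scores Matrix of per-mask class scores (rows = masks).
#' @return List with `scores` (averaged probability vector) and `label`;
#'   ties at the maximum break toward Censored (conservative).
#' @export
ensemble_classify <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (nrow(scores) < 1) stop("need at least one mask score")
  avg <- colMeans(scores)
  names(avg) <- POSTURE_CLASSES
  mx <- max(avg)
  cand <- which(avg >= mx - 1e-12)
  label <- if (length(cand) > 1 && 5 %in% cand) "Censored"
    else POSTURE_CLASSES[cand[1]]
  list(scores = avg, label = label)
}

# match components across the three binarizations: greedy grouping by
# IoU >= iou_min against group representatives (lowest threshold first)
dedup_components <- function(comp_list, iou_min = 0.5) {
  groups <- list()
  for (b in seq_along(comp_list)) {
    for (comp in comp_list[[b]]) {
      matched <- FALSE
      for (gi in seq_along(groups)) {
        rep_mask <- groups[[gi]]$members[[1]]$mask
        if (mask_iou(rep_mask, comp$mask) >= iou_min) {
          groups[[gi]]$members[[length(groups[[gi]]$members) + 1]] <-
            c(comp, list(binary = b))
          matched <- TRUE
          break
        }
      }
      if (!matched)
        groups[[length(groups) + 1]] <-
          list(members = list(c(comp, list(binary = b))))
    }
  }
  groups
}

#' Analyze one snapshot with a trained network
#'
#' Texture binarization at three thresholds, 8-connected components per
#' binary (area-filtered, well-restricted), de-duplication across the
#' binaries by IoU matching, four dilation mask variants per member
#' component (up to 12 crops per object), ensemble scoring, and final
#' labels. Censored objects are listed but flagged for exclusion from
#' posture statistics.
#'
#' @param image Grayscale matrix or image file path.
#' @param network A `trained_network`.
#' @param params A [detection_params()].
#' @param well Optional `well_circle` restricting the analysis.
#' @param max_masks Cap on scored masks per object (default all 12).
#' @return `snapshot_result` data.frame: one row per object with
#'   centroid, mask count, the five averaged scores, `label`, and
#'   `overridden`.
#' @export
analyze_snapshot <- function(image, network, params = detection_params(),
                             well = NULL, max_masks = 12L) {
  image_id <- NA_character_
  if (is.character(image)) {
    image_id <- basename(image)
    image <- tryCatch(read_snapshot(image), error = function(e) {
      warning("skipping unreadable image: ", conditionMessage(e))
      NULL
    })
    if (is.null(image)) return(empty_snapshot_result(image_id))
  }
  binaries <- suppressWarnings(texture_binarize(image, params))
  comp_list <- lapply(binaries, function(b) {
    wc <- well_components(b, well, params)
    if (is.null(wc$table)) return(list())
    lapply(wc$table$label_id[wc$table$keep], function(i)
      list(mask = wc$labels == i, x = wc$table$x[i], y = wc$table$y[i]))
  })
  groups <- dedup_components(comp_list)
  rows <- list()
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]$members
    crops <- list()
    for (mb in members) {
      if (length(crops) >= max_masks) break
      v <- mask_variants(mb$mask, image, params = params)
      take <- seq_len(min(length(v), max_masks - length(crops)))
      crops <- c(crops, v[take])
    }
    sc <- predict_scores(network, crops)
    dec <- ensemble_classify(sc)
    rep_m <- members[[1]]
    rows[[gi]] <- data.frame(
      object_id = gi, x = rep_m$x, y = rep_m$y, n_masks = nrow(sc),
      t(dec$scores), label = dec$label, overridden = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_snapshot_result()
  attr(out, "image_id") <- image_id
  class(out) <- c("snapshot_result", "data.frame")
  out
}

empty_snapshot_result <- function(image_id = NA_character_) {
  out <- data.frame(object_id = integer(), x = numeric(), y = numeric(),
                    n_masks = integer(),
                    Coiled = numeric(), Curled = numeric(),
                    NearCurled = numeric(), NonCurled = numeric(),
                    Censored = numeric(),
                    label = character(), overridden = logical())
  attr(out, "image_id") <- image_id
  class(out) <- c("snapshot_result", "data.frame")
  out
}

#' Analyze an ordered set of video frames
#'
#' Frames are scored independently (no tracking); results are returned in
#' frame order.
#'
#' @param frames List of images (matrices or file paths).
#' @param network A `trained_network`.
#' @param params A [detection_params()].
#' @param well Optional `well_circle`.
#' @return List of `snapshot_result`s.
#' @export
analyze_video <- function(frames, network, params = detection_params(),
                          well = NULL) {
  lapply(frames, analyze_snapshot, network = network, params = params,
         well = well)
}

#' Manually override an object's label
#'
#' Replaces the label, sets the override flag (also for a no-op override
#' to the same label), and appends a provenance record to the result's
#' `override_log` attribute.
#'
#' @param result A `snapshot_result`.
#' @param object_id Object to override.
#' @param new_label One of [posture_classes()].
#' @return The modified `snapshot_result`.
#' @export
override <- function(result, object_id, new_label) {
  new_label <- match.arg(new_label, POSTURE_CLASSES)
  i <- which(result$object_id == object_id)
  if (length(i) != 1) stop("unknown object id: ", object_id)
  log <- attr(result, "override_log")
  log <- rbind(log, data.frame(object_id = object_id,
                               old_label = result$label[i],
                               new_label = new_label,
                               time = format(Sys.time())))
  result$label[i] <- new_label
  result$overridden[i] <- TRUE
  attr(result, "override_log") <- log
  result
}
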