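# Object detection in well snapshots: gradient edges, multilevel Otsu
# thresholding, 8-connected labeling, shape filters, standardized crops.

#' Detection parameters
#'
#' @param reference_worm_area Average adult worm area in pixels^2; the
#'   area filter keeps objects between `min_area_factor` and
#'   `max_area_factor` times this value.
#' @param min_area_factor,max_area_factor Area filter bounds (defaults
#'   0.1 and 8 times the reference area).
#' @param mask_area Crop padding margin as a multiplier of the dilation
#'   radius.
#' @param otsu_levels Integer pair `[m, k]`: compute `m` multilevel Otsu
#'   thresholds on the gradient image and binarize at the `k`-th.
#' @param n_node Number of nodes used to outline each detected object.
#' @param jaggedness_threshold Objects whose raw-to-smoothed perimeter
#'   ratio exceeds this are discarded as debris.
#' @param std_window Window of the local standard-deviation filter used by
#'   the snapshot classifier path.
#' @param hole_fill_max Enclosed background holes up to this area (pixels)
#'   are filled after thresholding; larger holes (coil signatures) are
#'   preserved.
#' @param boundary_margin Objects within this many pixels of the well
#'   circle are discarded (meniscus artifacts).
#' @return A `detection_params` list.
#' @export
detection_params <- function(reference_worm_area = 220, min_area_factor = 0.1,
                             max_area_factor = 8, mask_area = 1,
                             otsu_levels = c(1, 1), n_node = 60,
                             jaggedness_threshold = 1.3, std_window = 5,
                             hole_fill_max = 4, boundary_margin = 2) {
  stopifnot(min_area_factor > 0, min_area_factor < max_area_factor,
            length(otsu_levels) == 2,
            otsu_levels[2] >= 1, otsu_levels[2] <= otsu_levels[1],
            n_node >= 8)
  structure(list(reference_worm_area = reference_worm_area,
                 min_area_factor = min_area_factor,
                 max_area_factor = max_area_factor, mask_area = mask_area,
                 otsu_levels = otsu_levels, n_node = n_node,
                 jaggedness_threshold = jaggedness_threshold,
                 std_window = std_window, hole_fill_max = hole_fill_max,
                 boundary_margin = boundary_margin),
            class = "detection_params")
}

#' Circle through three points on the well circumference
#'
#' @param p1,p2,p3 Numeric `c(x, y)` pixel points.
#' @return List of class `well_circle` with `center` and `radius`.
#' @export
fit_well_circle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-9) stop("points are collinear; cannot fit a circle")
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  structure(list(center = c(ux, uy),
                 radius = sqrt((ax - ux)^2 + (ay - uy)^2)),
            class = "well_circle")
}

#' Multilevel Otsu thresholds of a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over all threshold
#' tuples; ties break toward the lower thresholds. A threshold `t` puts
#' bins `0..t` in the lower class.
#'
#' @param histogram 256 bin counts (bins 0-255).
#' @param m Number of thresholds (1-3).
#' @return Integer thresholds (bin values, ascending). If the histogram
#'   has a single occupied bin, that bin is returned (for all `m`) with a
#'   warning and attribute `degenerate = TRUE`.
#' @export
otsu_thresholds <- function(histogram, m = 1) {
  stopifnot(length(histogram) == 256, all(histogram >= 0))
  occupied <- which(histogram > 0)
  if (length(occupied) == 0) stop("empty histogram")
  if (length(occupied) == 1) {
    warning("degenerate single-value histogram")
    return(structure(rep(occupied - 1L, m), degenerate = TRUE))
  }
  cpp_otsu_multi(as.numeric(histogram), as.integer(m))
}

# 256-bin histogram of values scaled to 0..255 over [0, hi]
hist256 <- function(values, hi = max(values)) {
  if (hi <= 0) hi <- 1
  bins <- pmin(pmax(floor(values / hi * 255), 0), 255)
  tabulate(bins + 1L, 256)
}

# polygon perimeter (closed)
poly_perim <- function(p) {
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(diff(q[, 1])^2 + diff(q[, 2])^2))
}

# resample a closed polygon to n equally spaced nodes (by arclength)
resample_polygon <- function(p, n) {
  q <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)
  s <- c(0, cumsum(seg))
  tot <- s[length(s)]
  if (tot <= 0) return(p[rep(1, n), , drop = FALSE])
  at <- seq(0, tot, length.out = n + 1)[-(n + 1)]
  cbind(stats::approx(s, q[, 1], at, rule = 2)$y,
        stats::approx(s, q[, 2], at, rule = 2)$y)
}

#' Contour jaggedness
#'
#' Ratio of the raw contour perimeter to the perimeter of a smoothed
#' version (resampled to `n_node` equally spaced nodes, then one pass of a
#' circular 3-point moving average). Values near 1 indicate a smooth
#' outline; debris scores high.
#'
#' @param contour Polygon matrix (ordered boundary points, columns x, y).
#' @param n_node Number of resampled nodes.
#' @return Jaggedness ratio (>= 1 up to small discretization slack).
#' @export
jaggedness <- function(contour, n_node = 60) {
  if (nrow(contour) < 3) stop("contour needs at least 3 points")
  raw <- poly_perim(contour)
  nodes <- resample_polygon(contour, min(n_node, nrow(contour)))
  n <- nrow(nodes)
  sm <- (nodes[c(n, 1:(n - 1)), ] + nodes + nodes[c(2:n, 1), ]) / 3
  raw / poly_perim(sm)
}

# ordered boundary polygon of a binary mask (x, y raster coords)
trace_contour <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  oc[[1]] + 1  # 0-based -> 1-based
}

# components of a binary image within the well, with area filter;
# returns label matrix and a table of component stats
well_components <- function(binary, well, params) {
  W <- nrow(binary); H <- ncol(binary)
  lab <- cpp_label8(matrix(as.integer(binary != 0), W, H))
  n <- attr(lab, "n")
  if (n == 0) return(list(labels = lab, table = NULL))
  idx <- which(lab > 0)
  ids <- lab[idx]
  xs <- (idx - 1) %% W + 1
  ys <- (idx - 1) %/% W + 1
  area <- tabulate(ids, n)
  cx <- as.numeric(rowsum(xs, ids)[, 1]) / area
  cy <- as.numeric(rowsum(ys, ids)[, 1]) / area
  # boundary restriction: drop components leaving the well interior
  keep <- rep(TRUE, n)
  if (!is.null(well)) {
    d <- sqrt((xs - well$center[1])^2 + (ys - well$center[2])^2)
    dmax <- vapply(split(d, ids), max, numeric(1))
    keep <- dmax <= well$radius - params$boundary_margin
  }
  amin <- params$min_area_factor * params$reference_worm_area
  amax <- params$max_area_factor * params$reference_worm_area
  keep <- keep & area >= amin & area <= amax
  tab <- data.frame(label_id = seq_len(n), x = cx, y = cy, area = area,
                    keep = keep)
  list(labels = lab, table = tab)
}

#' Detect candidate objects in a well snapshot
#'
#' Sobel gradient magnitude is thresholded at the `k`-th of `m` multilevel
#' Otsu levels, cleaned by morphological closing and small-hole filling
#' (coil-scale holes preserved), labeled 8-connected within the well
#' interior, filtered by area and contour jaggedness, and standardized to
#' 128x128 single-object crops.
#'
#' @param image Grayscale matrix (`width x height`, 0-1).
#' @param well A `well_circle`, or `NULL` to use the full frame.
#' @param params A [detection_params()].
#' @return Object of class `detected_objects`: list with `table`
#'   (per-object stats) and `objects` (per-object masks and crops).
#' @export
detect_objects <- function(image, well = NULL, params = detection_params()) {
  W <- nrow(image); H <- ncol(image)
  g <- cpp_sobel(image)
  inside <- if (is.null(well)) rep(TRUE, length(g)) else {
    xg <- matrix(seq_len(W), W, H); yg <- matrix(rep(seq_len(H), each = W), W, H)
    sqrt((xg - well$center[1])^2 + (yg - well$center[2])^2) <= well$radius
  }
  th <- otsu_thresholds(hist256(g[inside], max(g)), params$otsu_levels[1])
  tsel <- th[params$otsu_levels[2]] / 255 * max(g)
  binary <- matrix(as.integer(g > tsel), W, H)
  binary <- EBImage::closing(binary, matrix(1L, 3, 3))
  binary <- cpp_fill_small_holes(binary, params$hole_fill_max)

  wc <- well_components(binary, well, params)
  objects <- list(); rows <- list()
  if (!is.null(wc$table)) {
    for (i in wc$table$label_id[wc$table$keep]) {
      mask <- wc$labels == i
      contour <- trace_contour(mask)
      perim <- poly_perim(contour)
      jag <- jaggedness(contour, params$n_node)
      if (jag > params$jaggedness_threshold) next
      crop <- standardize_crop(image, mask, wc$labels, i, params,
                               perimeter = perim)
      o <- list(label_id = i, pixel_mask = mask,
                contour = resample_polygon(contour, params$n_node),
                area = wc$table$area[i], perimeter = perim, jaggedness = jag,
                crop = crop, prelim_label = NA_character_)
      objects[[length(objects) + 1]] <- o
      rows[[length(rows) + 1]] <- data.frame(
        label_id = i, x = wc$table$x[i], y = wc$table$y[i],
        area = o$area, perimeter = perim, jaggedness = jag)
    }
  }
  structure(list(objects = objects,
                 table = if (length(rows)) do.call(rbind, rows) else
                   data.frame(label_id = integer(), x = numeric(),
                              y = numeric(), area = numeric(),
                              perimeter = numeric(), jaggedness = numeric())),
            class = "detected_objects")
}

#' @export
print.detected_objects <- function(x, ...) {
  cat("detected_objects:", nrow(x$table), "objects\n")
  if (nrow(x$table)) print(head(x$table, 10))
  invisible(x)
}

#' Standardize an object to a 128x128 single-object crop
#'
#' Grayscale pixels are retained under the object's mask dilated by a
#' disk of radius `4 * A / P` (area over perimeter); pixels of neighboring
#' objects are deleted so the crop contains exactly one 8-connected
#' object. Small objects are zero-padded to the center; larger ones are
#' rescaled isotropically.
#'
#' @param image Grayscale source image.
#' @param mask Binary mask of the object.
#' @param labels Label matrix of all detected objects (or `NULL`).
#' @param id Label of the target object in `labels`.
#' @param params A [detection_params()].
#' @param perimeter Precomputed contour perimeter (computed if missing).
#' @param dilation_radius Override for the dilation radius.
#' @param size Output side length.
#' @return `size x size` grayscale matrix.
#' @export
standardize_crop <- function(image, mask, labels = NULL, id = NULL,
                             params = detection_params(), perimeter = NULL,
                             dilation_radius = NULL, size = 128) {
  A <- sum(mask != 0)
  if (A == 0) return(matrix(0, size, size))
  # window everything to the object's padded bounding box before any
  # morphology: dilating the full frame per variant dominates runtime
  wh0 <- which(mask != 0, arr.ind = TRUE)
  if (is.null(perimeter)) {
    px0 <- max(1, min(wh0[, 1]) - 2); px1 <- min(nrow(mask), max(wh0[, 1]) + 2)
    py0 <- max(1, min(wh0[, 2]) - 2); py1 <- min(ncol(mask), max(wh0[, 2]) + 2)
    perimeter <- poly_perim(trace_contour(mask[px0:px1, py0:py1, drop = FALSE]))
  }
  r0 <- if (is.null(dilation_radius)) 4 * A / max(perimeter, 1) else
    dilation_radius
  brush_r <- max(1, round(r0))
  margin <- ceiling(params$mask_area * r0)
  pad <- brush_r + margin + 2
  x0 <- max(1, min(wh0[, 1]) - pad); x1 <- min(nrow(mask), max(wh0[, 1]) + pad)
  y0 <- max(1, min(wh0[, 2]) - pad); y1 <- min(ncol(mask), max(wh0[, 2]) + pad)
  wmask <- mask[x0:x1, y0:y1, drop = FALSE]
  wimg <- image[x0:x1, y0:y1, drop = FALSE]
  wlab <- if (!is.null(labels)) labels[x0:x1, y0:y1, drop = FALSE] else NULL

  dmask <- EBImage::dilate(wmask + 0,
                           EBImage::makeBrush(2 * brush_r + 1, "disc")) > 0
  gray <- wimg * dmask
  if (!is.null(wlab)) gray[wlab > 0 & wlab != id] <- 0
  keep <- largest_overlap_component(gray > 0, wmask)
  gray[!keep] <- 0
  # crop to the padded bounding box
  wh <- which(keep, arr.ind = TRUE)
  if (nrow(wh) == 0) return(matrix(0, size, size))
  kx0 <- max(1, min(wh[, 1]) - margin); kx1 <- min(nrow(gray), max(wh[, 1]) + margin)
  ky0 <- max(1, min(wh[, 2]) - margin); ky1 <- min(ncol(gray), max(wh[, 2]) + margin)
  sub <- gray[kx0:kx1, ky0:ky1, drop = FALSE]
  bw <- nrow(sub); bh <- ncol(sub)
  if (bw > size || bh > size) {  # isotropic rescale to fit
    sc <- size / max(bw, bh)
    sub <- EBImage::resize(sub, w = max(1, round(bw * sc)),
                           h = max(1, round(bh * sc)))
    bw <- nrow(sub); bh <- ncol(sub)
  }
  out <- matrix(0, size, size)
  ox <- (size - bw) %/% 2; oy <- (size - bh) %/% 2
  out[ox + seq_len(bw), oy + seq_len(bh)] <- sub
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

# component of `binary` with the largest overlap with `ref`
largest_overlap_component <- function(binary, ref) {
  lab <- cpp_label8(matrix(as.integer(binary), nrow(binary), ncol(binary)))
  n <- attr(lab, "n")
  if (n <= 1) return(binary & TRUE)
  ov <- vapply(seq_len(n), function(i) sum(lab == i & ref), numeric(1))
  lab == which.max(ov)
}

#' Preliminary labels from batch statistics and shape factors
#'
#' Objects whose area or perimeter falls in the lowest or highest
#' Otsu-derived band of the batch distribution are flagged Censored
#' (level 0 disables a filter), as are extremely thin or long objects
#' (bounding-box aspect ratio beyond the dim-filter limit). Remaining
#' objects are coarsely pre-binned by circularity \eqn{4\pi A / P^2}.
#'
#' @param detected A `detected_objects` result.
#' @param filters List with `area_levels`, `perim_levels` (multilevel
#'   Otsu band counts; 0 = off), `dim_limit` (aspect ratio), and
#'   `circularity_bins` (breaks for the Coiled/Curled/NearCurled/NonCurled
#'   guesses).
#' @return `detected` with `prelim_label` filled in table and objects.
#' @export
prelim_label <- function(detected,
                         filters = list(area_levels = 2, perim_levels = 2,
                                        dim_limit = 8,
                                        circularity_bins = c(0.35, 0.55, 0.8))) {
  tab <- detected$table
  n <- nrow(tab)
  if (n == 0) return(detected)
  lab <- rep(NA_character_, n)
  # censor the lowest/highest Otsu band, but only when that band is a
  # small minority of the batch (a band holding the bulk is not an outlier
  # band even if a threshold slices the main cluster)
  band_censor <- function(values, m, max_frac = 0.25) {
    if (m < 1 || n < 2) return(rep(FALSE, n))
    th <- otsu_thresholds(hist256(values), m) / 255 * max(values)
    lo <- values <= th[1]
    hi <- values > th[m]
    (lo & sum(lo) <= max_frac * n) | (hi & sum(hi) <= max_frac * n)
  }
  cens <- band_censor(tab$area, filters$area_levels) |
    band_censor(tab$perimeter, filters$perim_levels)
  for (i in seq_len(n)) {
    obj <- detected$objects[[i]]
    wh <- which(obj$pixel_mask, arr.ind = TRUE)
    bb <- c(diff(range(wh[, 1])) + 1, diff(range(wh[, 2])) + 1)
    if (max(bb) / max(min(bb), 1) > filters$dim_limit) cens[i] <- TRUE
    if (cens[i]) { lab[i] <- "Censored"; next }
    circ <- 4 * pi * obj$area / obj$perimeter^2
    b <- filters$circularity_bins
    lab[i] <- if (circ > b[3]) "Coiled" else if (circ > b[2]) "Curled"
      else if (circ > b[1]) "NearCurled" else "NonCurled"
  }
  detected$table$prelim_label <- lab
  for (i in seq_len(n)) detected$objects[[i]]$prelim_label <- lab[i]
  detected
}
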