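# Rasterization of body geometries.
#
# Raster images are matrices with dim1 = x (width), dim2 = y (height),
# matching EBImage. Cartesian geometry (y up) maps to raster rows via
# y_raster = H + 1 - y_cartesian.

# dense centerline samples (Cartesian) with per-sample half-widths
tube_samples <- function(geometry, spacing = 0.25) {
  n <- max(64L, ceiling(geometry$body_length / spacing))
  body <- reconstruct_body(geometry, n)
  list(x = body$centerline[, 1], y = body$centerline[, 2],
       r = body$half_width)
}

# translate Cartesian samples onto a canvas; returns raster coordinates
place_tube <- function(s, canvas, center = TRUE) {
  W <- canvas[1]; H <- canvas[2]
  xlo <- min(s$x - s$r); xhi <- max(s$x + s$r)
  ylo <- min(s$y - s$r); yhi <- max(s$y + s$r)
  need_w <- ceiling(xhi - xlo + 2); need_h <- ceiling(yhi - ylo + 2)
  if (need_w > W || need_h > H)
    stop(sprintf("outline does not fit canvas %d x %d; requires at least %d x %d",
                 W, H, need_w, need_h))
  if (center) {
    dx <- (W + 1) / 2 - (xlo + xhi) / 2
    dy <- (H + 1) / 2 - (ylo + yhi) / 2
  } else {
    dx <- 0; dy <- 0
    if (xlo < 0.5 || xhi > W + 0.5 || ylo < 0.5 || yhi > H + 0.5)
      stop(sprintf("outline exceeds canvas %d x %d; requires at least %d x %d",
                   W, H, need_w, need_h))
  }
  list(cx = s$x + dx, cy = H + 1 - (s$y + dy), r = s$r,
       offset = c(dx, dy))
}

#' Render a geometry (or list of geometries) as a binary mask
#'
#' The tube is rasterized as the union of disks centered on a dense
#' centerline sampling with the local half-width as radius. Coiled
#' (self-occluding) geometries produce a single 8-connected component that
#' may enclose a background hole; an empty geometry list yields an
#' all-background canvas.
#'
#' @param geometry A [worm_geometry()] or a list of them.
#' @param canvas Integer `c(width, height)` of the output image.
#' @param center Translate the outline to the canvas center (`TRUE`), or
#'   keep absolute coordinates from the geometry origin (`FALSE`; errors
#'   if the outline leaves the canvas).
#' @return Binary integer matrix (`width x height`), attribute `offset`
#'   holding the applied Cartesian translation.
#' @export
render_mask <- function(geometry, canvas = c(128, 128), center = TRUE) {
  if (inherits(geometry, "worm_geometry")) geometry <- list(geometry)
  out <- matrix(0L, canvas[1], canvas[2])
  off <- c(0, 0)
  for (g in geometry) {
    p <- place_tube(tube_samples(g), canvas, center)
    out <- out | cpp_render_tube(p$cx, p$cy, p$r, canvas[1], canvas[2])
    off <- p$offset
  }
  out <- matrix(as.integer(out), canvas[1], canvas[2])
  attr(out, "offset") <- off
  out
}

# grayscale render with cylindrical elevation shading (bright spine),
# max-combined with an existing canvas
render_worm_gray <- function(geometry, canvas, center = TRUE, base = NULL,
                             intensity = 1) {
  p <- place_tube(tube_samples(geometry), canvas, center)
  g <- cpp_render_tube_gray(p$cx, p$cy, p$r, canvas[1], canvas[2]) * intensity
  if (!is.null(base)) g <- pmax(base, g)
  attr(g, "offset") <- p$offset
  g
}

#' Number of enclosed background holes in a binary mask
#'
#' Counts 8-connected background components that do not touch the image
#' border; a coiled worm produces at least one.
#'
#' @param mask Binary matrix.
#' @return Integer hole count.
#' @export
count_holes <- function(mask) {
  cpp_count_holes(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Binary matrices of equal size.
#' @return IoU in `[0, 1]` (1 if both are empty).
#' @export
mask_iou <- function(a, b) {
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
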