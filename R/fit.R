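# Centerline-based fitting of the body model to a binary mask.

unfittable <- function(reason) {
  stop(structure(class = c("wormsnap_unfittable", "error", "condition"),
                 list(message = paste0("unfittable mask: ", reason),
                      call = sys.call(-1))))
}

# centered moving average; window shrinks at the ends
smooth_ma <- function(x, w = 5) {
  h <- w %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Fit a worm geometry to a single-object binary mask
#'
#' The mask is thinned to a skeleton; the longest path through the
#' skeleton graph becomes the centerline (ordered by lexicographic
#' endpoint order), extended at both ends by the local distance-transform
#' value to recover the tapered tips lost to thinning. Tangent angles come
#' from finite differences of the smoothed centerline and are projected
#' onto the B-spline basis by linear least squares; half-widths are fitted
#' the same way from distance-transform values along the centerline.
#'
#' Masks with an enclosed hole (self-occluding coils) or with skeleton
#' branches longer than 10\% of the main path (after spur pruning) raise
#' an `"wormsnap_unfittable"` condition so callers can censor the object.
#'
#' @param mask Binary matrix containing exactly one 8-connected component.
#' @param basis A [spline_basis()].
#' @return A [worm_geometry()]; the extracted centerline (Cartesian) is
#'   attached as attribute `"centerline"`.
#' @export
fit_geometry <- function(mask, basis = spline_basis()) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- cpp_label8(m)
  n_comp <- attr(lab, "n")
  if (n_comp != 1)
    stop("mask must contain exactly one 8-connected component (found ",
         n_comp, ")")
  if (cpp_count_holes(m) > 0)
    unfittable("component contains an enclosed hole")
  skel <- cpp_thin(m)
  sp <- cpp_skeleton_path(skel)
  path <- sp$path
  if (nrow(path) < 8) unfittable("skeleton too short")
  if (length(sp$branch_lengths) > 0 &&
      any(sp$branch_lengths >= 0.1 * nrow(path)))
    unfittable("more than two skeleton endpoints after spur pruning")

  W <- nrow(m); H <- ncol(m)
  D <- EBImage::distmap(m)

  # thinning erodes the tapered tips; recover them by walking from each
  # skeleton end along the local tangent until the mask is left
  extend_end <- function(p, at_start) {
    k <- min(5, nrow(p) - 1)
    if (at_start) {
      tip <- p[1, ]; dir <- p[1, ] - p[1 + k, ]
    } else {
      tip <- p[nrow(p), ]; dir <- p[nrow(p), ] - p[nrow(p) - k, ]
    }
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) return(NULL)
    dir <- dir / nrm
    step <- 0.5
    pts <- NULL
    for (i in seq_len(24)) {
      pos <- tip + dir * step * i
      xi <- round(pos[1]); yi <- round(pos[2])
      if (xi < 1 || yi < 1 || xi > W || yi > H || m[xi, yi] == 0) break
      pts <- rbind(pts, pos)
    }
    pts
  }
  ext_s <- extend_end(path, TRUE)
  ext_e <- extend_end(path, FALSE)
  pts <- rbind(if (!is.null(ext_s)) ext_s[rev(seq_len(nrow(ext_s))), , drop = FALSE],
               path, ext_e)

  # head/tail order is arbitrary; fix it lexicographically
  a <- pts[1, ]; b <- pts[nrow(pts), ]
  if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2]))
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]

  # smooth the pixel chain (raster coordinates)
  px <- smooth_ma(pts[, 1], 5)
  py <- smooth_ma(pts[, 2], 5)

  # sub-pixel refinement: the skeleton is quantized to pixel centers, so
  # shift each point transversely to the parabolic peak of the distance
  # transform (the tube's medial ridge)
  dbil <- function(x, y) {
    x <- pmin(pmax(x, 1), W); y <- pmin(pmax(y, 1), H)
    x0 <- pmin(floor(x), W - 1); y0 <- pmin(floor(y), H - 1)
    fx <- x - x0; fy <- y - y0
    D[cbind(x0, y0)] * (1 - fx) * (1 - fy) + D[cbind(x0 + 1, y0)] * fx * (1 - fy) +
      D[cbind(x0, y0 + 1)] * (1 - fx) * fy + D[cbind(x0 + 1, y0 + 1)] * fx * fy
  }
  n <- length(px)
  tx <- smooth_ma(c(diff(px), px[n] - px[n - 1]), 3)
  ty <- smooth_ma(c(diff(py), py[n] - py[n - 1]), 3)
  tn <- sqrt(tx^2 + ty^2); tn[tn < 1e-9] <- 1
  nx <- -ty / tn; ny <- tx / tn
  d0 <- dbil(px, py)
  dm <- dbil(px - nx, py - ny)
  dp <- dbil(px + nx, py + ny)
  den <- dm - 2 * d0 + dp
  off <- ifelse(den < -1e-6, 0.5 * (dm - dp) / den, 0)
  off <- pmin(pmax(off, -0.75), 0.75)
  px <- smooth_ma(px + off * nx, 3)
  py <- smooth_ma(py + off * ny, 3)

  # raster -> Cartesian
  xs <- px
  ys <- H + 1 - py
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  keep <- c(TRUE, seg > 1e-9)
  xs <- xs[keep]; ys <- ys[keep]
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  L <- sum(seg)
  if (L <= 0 || length(xs) < 9) unfittable("degenerate centerline")
  s <- c(0, cumsum(seg))
  u <- s / L

  # tangent angles at segment midpoints, unwrapped
  th <- atan2(diff(ys), diff(xs))
  dth <- diff(th)
  dth <- dth - 2 * pi * round(dth / (2 * pi))
  th <- th[1] + c(0, cumsum(dth))
  u_mid <- (u[-1] + u[-length(u)]) / 2

  # tangent angles near the tapered tips come from few, narrow pixels;
  # weight stations by local half-width so the wide mid-body dominates
  wmid <- dbil((xs[-1] + xs[-length(xs)]) / 2,
               H + 1 - (ys[-1] + ys[-length(ys)]) / 2)
  wts <- pmax(pmin(wmid, 3), 0.2)
  B_th <- basis_matrix(basis, u_mid)
  alpha <- stats::lm.wfit(B_th, th, wts)$coefficients
  alpha[is.na(alpha)] <- 0

  # half-widths from the distance transform ridge along the centerline
  wvals <- pmax(smooth_ma(dbil(xs, H + 1 - ys), 7) - 0.1, 0)
  B_r <- basis_matrix(basis, u)
  rcoef <- stats::lm.fit(B_r, wvals)$coefficients
  rcoef[is.na(rcoef)] <- 0
  rcoef <- pmax(rcoef, 0)

  geom <- worm_geometry(alpha, rcoef, L, origin = c(xs[1], ys[1]),
                        basis = basis)
  attr(geom, "centerline") <- cbind(x = xs, y = ys)
  geom
}
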