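#' Clamped uniform cubic B-spline basis
#'
#' The worm body model expresses the tangent angle and the half-width
#' profile along the centerline as cubic B-spline curves with `n_splines`
#' coefficients over normalized arclength \eqn{u \in [0, 1]}. The knot
#' vector is clamped (degree + 1 repeated boundary knots) and uniform in
#' the interior, so the basis is nonnegative, sums to one at every `u`
#' (partition of unity), and interpolates the first and last coefficient
#' at the endpoints.
#'
#' @param degree Spline degree (cubic, 3).
#' @param n_splines Number of basis functions (8).
#' @return An object of class `spline_basis` with the knot vector.
#' @export
spline_basis <- function(degree = 3, n_splines = 8) {
  stopifnot(degree >= 1, n_splines > degree)
  n_inner <- n_splines - degree - 1
  knots <- c(rep(0, degree + 1),
             if (n_inner > 0) seq_len(n_inner) / (n_inner + 1),
             rep(1, degree + 1))
  structure(list(degree = degree, n_splines = n_splines, knot_vector = knots),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("Clamped B-spline basis: degree", x$degree, "with", x$n_splines,
      "functions on [0, 1]\n")
  invisible(x)
}

#' Evaluate the B-spline basis (or a derivative) at points u
#'
#' @param basis A [spline_basis()].
#' @param u Evaluation points in `[0, 1]`.
#' @param deriv Derivative order (0 = value).
#' @return Matrix `length(u) x n_splines`.
#' @export
basis_matrix <- function(basis, u, deriv = 0) {
  if (any(u < 0 | u > 1)) stop("u must be in [0, 1]")
  splines::splineDesign(basis$knot_vector, u, ord = basis$degree + 1,
                        derivs = rep(deriv, length(u)))
}

#' Worm body geometry
#'
#' A worm body is a tube around a planar centerline. The tangent angle
#' \eqn{\Theta(u) = \sum_j \alpha_j \phi_j^3(u)} fixes the centerline shape
#' (reconstructed by integrating the unit tangent over arclength scaled by
#' `body_length`), and \eqn{R(u) = \sum_j r_j \phi_j^3(u)} gives the
#' half-width at each station. Geometry lives in standard Cartesian
#' coordinates (y up); rasterization applies the y-flip.
#'
#' @param alpha Numeric vector of 8 tangent-angle coefficients (radians).
#' @param r Numeric vector of 8 nonnegative half-width coefficients (pixels).
#' @param body_length Centerline arc length in pixels (> 0).
#' @param origin Cartesian position of the head end `X(0, 0)` (pixels).
#' @param basis A [spline_basis()].
#' @return Object of class `worm_geometry`.
#' @export
worm_geometry <- function(alpha, r, body_length, origin = c(0, 0),
                          basis = spline_basis()) {
  alpha <- as.numeric(alpha); r <- as.numeric(r)
  if (length(alpha) != basis$n_splines || length(r) != basis$n_splines)
    stop("alpha and r must have length ", basis$n_splines)
  if (any(r < 0)) stop("half-width coefficients r must be nonnegative")
  if (!is.numeric(body_length) || body_length <= 0)
    stop("body_length must be positive")
  structure(list(alpha = alpha, r = r, body_length = body_length,
                 origin = as.numeric(origin), basis = basis),
            class = "worm_geometry")
}

#' @export
print.worm_geometry <- function(x, ...) {
  m <- morphology(x)
  cat(sprintf(
    "worm_geometry: length %.1f px, mean half-width %.2f px, total turning %.2f rad\n",
    m$arc_length, m$mean_half_width, m$total_turning))
  invisible(x)
}

#' Tangent angle along the centerline
#'
#' @param geometry A [worm_geometry()].
#' @param u Normalized arclength in `[0, 1]` (vectorized).
#' @return Tangent angle(s) in radians.
#' @export
eval_theta <- function(geometry, u) {
  drop(basis_matrix(geometry$basis, u) %*% geometry$alpha)
}

#' Half-width profile along the centerline
#'
#' @inheritParams eval_theta
#' @return Half-width(s) in pixels.
#' @export
eval_width <- function(geometry, u) {
  drop(basis_matrix(geometry$basis, u) %*% geometry$r)
}

# cumulative trapezoid of y over x (same length), starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

#' Reconstruct the body outline from a geometry
#'
#' The centerline is \eqn{X(u) = L \int_0^u (\cos\Theta, \sin\Theta)\,ds}
#' from `origin` (composite trapezoid on the sample grid, error
#' \eqn{O(h^2)}); the outline offsets the centerline by \eqn{\pm R(u)}
#' along the normal \eqn{(-\sin\Theta, \cos\Theta)}.
#'
#' @param geometry A [worm_geometry()].
#' @param n_samples Number of samples along `u` (at least 16).
#' @return List of class `worm_outline` with `outline` (closed polygon,
#'   `2*n_samples` rows of x, y), `centerline` (`n_samples` rows), the
#'   sample grid `u`, `theta`, and `half_width`.
#' @export
reconstruct_body <- function(geometry, n_samples = 200) {
  if (n_samples < 16) stop("n_samples must be at least 16")
  u <- seq(0, 1, length.out = n_samples)
  theta <- eval_theta(geometry, u)
  rw <- pmax(eval_width(geometry, u), 0)
  L <- geometry$body_length
  cx <- geometry$origin[1] + L * cumtrapz(u, cos(theta))
  cy <- geometry$origin[2] + L * cumtrapz(u, sin(theta))
  nx <- -sin(theta); ny <- cos(theta)
  upper <- cbind(cx + rw * nx, cy + rw * ny)
  lower <- cbind(cx - rw * nx, cy - rw * ny)
  outline <- rbind(upper, lower[n_samples:1, , drop = FALSE])
  colnames(outline) <- c("x", "y")
  structure(list(outline = outline,
                 centerline = cbind(x = cx, y = cy),
                 u = u, theta = theta, half_width = rw),
            class = "worm_outline")
}

#' Morphology metrics of a geometry
#'
#' Deterministic descriptors used for size and curvature phenotyping:
#' arc length, mean half-width, projected area (tube area
#' \eqn{2L\int R\,du} plus the end caps; self-overlap of coiled bodies is
#' not subtracted), total turning \eqn{\int |d\Theta/du|\,du}, and the
#' head-to-tail Euclidean distance.
#'
#' @param geometry A [worm_geometry()].
#' @param n_samples Quadrature grid size.
#' @return A one-row `data.frame` with the five metrics.
#' @export
morphology <- function(geometry, n_samples = 400) {
  u <- seq(0, 1, length.out = n_samples)
  rw <- pmax(eval_width(geometry, u), 0)
  L <- geometry$body_length
  dtheta <- drop(basis_matrix(geometry$basis, u, deriv = 1) %*% geometry$alpha)
  total_turning <- tail(cumtrapz(u, abs(dtheta)), 1)
  body <- reconstruct_body(geometry, n_samples)
  ht <- sqrt(sum((body$centerline[n_samples, ] - body$centerline[1, ])^2))
  area <- 2 * L * tail(cumtrapz(u, rw), 1) + pi * (rw[1]^2 + rw[n_samples]^2) / 2
  data.frame(arc_length = L,
             mean_half_width = tail(cumtrapz(u, rw), 1),
             projected_area = area,
             total_turning = total_turning,
             head_tail_distance = ht)
}

#' Total turning of a geometry
#'
#' Convenience accessor for \eqn{\int_0^1 |d\Theta/du|\,du}.
#'
#' @inheritParams morphology
#' @return Total turning in radians.
#' @export
total_turning <- function(geometry, n_samples = 400) {
  u <- seq(0, 1, length.out = n_samples)
  dtheta <- drop(basis_matrix(geometry$basis, u, deriv = 1) %*% geometry$alpha)
  tail(cumtrapz(u, abs(dtheta)), 1)
}

#' Serialize geometries to JSON
#'
#' @param geometry A [worm_geometry()] or list of them.
#' @param path Output file.
#' @export
write_geometry <- function(geometry, path) {
  if (inherits(geometry, "worm_geometry")) geometry <- list(geometry)
  recs <- lapply(geometry, function(g)
    list(alpha = g$alpha, r = g$r, body_length = g$body_length,
         origin = g$origin))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read geometries from JSON
#'
#' @param path File written by [write_geometry()].
#' @return List of [worm_geometry()] objects.
#' @export
read_geometry <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(recs)) {
    lapply(seq_len(nrow(recs)), function(i)
      worm_geometry(unlist(recs$alpha[i]), unlist(recs$r[i]),
                    recs$body_length[i], unlist(recs$origin[i])))
  } else {
    lapply(recs, function(r)
      worm_geometry(r$alpha, r$r, r$body_length, r$origin))
  }
}
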