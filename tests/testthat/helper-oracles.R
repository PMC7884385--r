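# Independent oracles used across the suite.

# Cox-de Boor recursion, written independently of splines::splineDesign
deboor_basis <- function(knots, degree, j, u) {
  # basis function j (1-based) of given degree at point u
  b <- function(j, d, u) {
    if (d == 0) {
      lo <- knots[j]; hi <- knots[j + 1]
      # half-open support, closed at the final knot
      if ((u >= lo && u < hi) || (u == knots[length(knots)] && u >= lo && u <= hi))
        return(1)
      return(0)
    }
    out <- 0
    den1 <- knots[j + d] - knots[j]
    if (den1 > 0) out <- out + (u - knots[j]) / den1 * b(j, d - 1, u)
    den2 <- knots[j + d + 1] - knots[j + 1]
    if (den2 > 0) out <- out + (knots[j + d + 1] - u) / den2 * b(j + 1, d - 1, u)
    out
  }
  b(j, degree, u)
}

# exhaustive between-class variance maximizer over threshold tuples
# (cumulative-sum formulation; ties resolve to the lexicographically
# smallest tuple, matching the implementation's tie rule)
otsu_bruteforce <- function(counts, m) {
  stopifnot(length(counts) == 256, m %in% c(1, 2))
  cw <- cumsum(counts)
  cm <- cumsum(counts * (0:255))
  tot <- cw[256]
  seg <- function(a, b) {          # bins a..b inclusive, 0-based, vectorized
    w <- cw[b + 1] - ifelse(a > 0, cw[a], 0)
    mu_num <- cm[b + 1] - ifelse(a > 0, cm[a], 0)
    ifelse(w > 0, mu_num^2 / w / tot, 0)
  }
  if (m == 1) {
    t <- 0:254
    s <- seg(rep(0, 255), t) + seg(t + 1, rep(255, 255))
    return(t[which.max(s)])
  }
  best <- -Inf; best_t <- NULL
  for (t1 in 0:253) {
    t2 <- (t1 + 1):254
    s <- seg(0, t1) + seg(rep(t1 + 1, length(t2)), t2) +
      seg(t2 + 1, rep(255, length(t2)))
    j <- which.max(s)
    if (s[j] > best + 1e-12) { best <- s[j]; best_t <- c(t1, t2[j]) }
  }
  best_t
}

# problem sizes for the acceptance suite (documented in the methods
# vignette; chosen for single-core runtimes)
ACCEPT_N_PER_CLASS <- 150
ACCEPT_MAX_EPOCHS <- 10
ACCEPT_E2E_ROUNDS <- 2
ACCEPT_E2E_SNAPSHOTS <- 2

# standard worm half-width profile used in round-trip tests
taper_profile <- function(w = 2.6) w * c(0.12, 0.55, 0.9, 1, 1, 0.9, 0.55, 0.12)

# geometry with a prescribed tangent-angle curve
geometry_from_theta <- function(theta_fun, L = 60, r = taper_profile(),
                                basis = spline_basis()) {
  u <- seq(0, 1, length.out = 200)
  alpha <- qr.solve(basis_matrix(basis, u), theta_fun(u))
  worm_geometry(alpha, r, L, basis = basis)
}
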