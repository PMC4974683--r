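# Independent oracles used across the suite.

# through-origin quadratic least squares via explicitly assembled normal
# equations (2x2 solve), independent of dpq_fit's lm.fit path
fit_dpq_oracle <- function(q, dp) {
  X <- cbind(q, q^2)
  ab <- solve(crossprod(X), crossprod(X, dp))
  res <- dp - X %*% ab
  list(A = ab[1, 1], B = ab[2, 1],
       rmse = if (length(q) > 2) sqrt(sum(res^2) / (length(q) - 2)) else NA_real_)
}

# rotation matrix about a unit axis (Rodrigues)
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rigidly rotate a flow field (points and vectors)
rotate_field <- function(field, Rm) {
  flow_field(points = field$points %*% t(Rm),
             velocity = field$velocity %*% t(Rm),
             pressure = field$pressure, cells = field$cells,
             region = field$region)
}

# small helical field reused by several tests
small_helical <- function(omega = 500, flow = 60, radius = 2, length = 8,
                          density = 10) {
  helical_field(analytic_field_spec("helical", radius = radius,
                                    length = length, flow = flow,
                                    omega = omega, mesh_density = density))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
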