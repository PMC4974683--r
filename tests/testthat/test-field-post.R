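test_that("vorticity reconstruction is exact on affine velocity fields", {
  f <- small_helical()  # mesh donor; velocities replaced below
  set.seed(11)
  A <- matrix(rnorm(9), 3, 3)
  b <- rnorm(3)
  vel <- (f$points * 1e-3) %*% t(A) + rep(b, each = nrow(f$points))
  fa <- flow_field(f$points, vel, f$pressure, f$cells)
  om <- vorticity(fa)
  expected <- c(A[3, 2] - A[2, 3], A[1, 3] - A[3, 1], A[2, 1] - A[1, 2])
  scale <- max(abs(expected))
  for (k in 1:3)
    expect_lt(max(abs(om[, k] - expected[k])) / scale, 1e-10)
})

test_that("rigid rotation and uniform flow give the closed-form curls", {
  f <- small_helical(omega = 500, flow = 60)
  om <- vorticity(f)
  # v = (-Omega y, Omega x, W): curl = (0, 0, 2 Omega)
  expect_lt(max(abs(om[, 3] - 1000)), 1e-9)
  expect_lt(max(abs(om[, 1:2])), 1e-9)
  uni <- flow_field(f$points, matrix(rep(c(0.1, 0.2, 0.3), each = nrow(f$points)), ncol = 3),
                    f$pressure, f$cells)
  expect_lt(max(abs(vorticity(uni))), 1e-12)
})

test_that("Poiseuille vorticity magnitude follows 2 v_max r / R^2", {
  p <- poiseuille_field(analytic_field_spec("poiseuille", radius = 1.65,
                                            length = 8, flow = 120,
                                            mesh_density = 12))
  om <- vorticity(p)
  wmag <- sqrt(rowSums(om^2))
  R_m <- 1.65e-3
  v_max <- max(p$velocity[, 3])
  r_m <- sqrt(rowSums((p$points[, 1:2] * 1e-3)^2))
  expected <- 2 * v_max * r_m / R_m^2
  wall <- 2 * v_max / R_m
  interior <- p$points[, 3] > 2 & p$points[, 3] < 6
  dev <- abs(wmag - expected) / wall
  # least-squares gradients are first-order biased at boundary stencils:
  # require the interior bulk to be accurate and the error to shrink on
  # refinement
  expect_lt(median(dev[interior]), 0.02)
  p2 <- poiseuille_field(analytic_field_spec("poiseuille", radius = 1.65,
                                             length = 8, flow = 120,
                                             mesh_density = 18))
  om2 <- vorticity(p2)
  dev2 <- abs(sqrt(rowSums(om2^2)) -
              2 * max(p2$velocity[, 3]) * sqrt(rowSums((p2$points[, 1:2] * 1e-3)^2)) / R_m^2) / wall
  int2 <- p2$points[, 3] > 2 & p2$points[, 3] < 6
  expect_lt(median(dev2[int2]), median(dev[interior]))
})

test_that("local normalized helicity matches the helical closed form", {
  omega <- 500; flow <- 60; radius <- 2
  f <- small_helical(omega = omega, flow = flow, radius = radius)
  om <- vorticity(f)
  lnh <- local_normalized_helicity(f, om)
  W <- flow / 6e7 / (pi * (radius * 1e-3)^2)
  r_m <- sqrt(rowSums((f$points[, 1:2] * 1e-3)^2))
  expected <- W / sqrt(omega^2 * r_m^2 + W^2)
  expect_lt(max(abs(lnh - expected)), 1e-3)
  # on the axis velocity and vorticity align exactly
  axis <- which(r_m < 1e-12)
  expect_equal(lnh[axis], rep(1, length(axis)))
  # bounded in [-1, 1]
  expect_true(all(lnh >= -1 & lnh <= 1))
})

test_that("Poiseuille flow has zero helicity and reversal flips the sign", {
  p <- poiseuille_field(analytic_field_spec("poiseuille", radius = 1.65,
                                            length = 8, flow = 120,
                                            mesh_density = 10))
  expect_equal(max(abs(local_normalized_helicity(p))), 0)
  f1 <- small_helical(omega = 400)
  f2 <- small_helical(omega = -400)
  l1 <- local_normalized_helicity(f1)
  l2 <- local_normalized_helicity(f2)
  expect_equal(l2, -l1, tolerance = 1e-12)
})

test_that("helicity intensity matches 2 Omega W and its invariances", {
  omega <- 500; flow <- 60; radius <- 2
  f <- small_helical(omega = omega, flow = flow, radius = radius)
  om <- vorticity(f)
  W <- flow / 6e7 / (pi * (radius * 1e-3)^2)
  expect_rel_equal(helicity_intensity(f, om), 2 * omega * W, 1e-3)
  # scales quadratically with velocity
  f2 <- flow_field(f$points, 2 * f$velocity, f$pressure, f$cells)
  expect_rel_equal(helicity_intensity(f2), 4 * helicity_intensity(f), 1e-9)
  # invariant under rigid rotation of the whole field
  Rm <- rotation_matrix(c(1, 2, 3), 0.7)
  expect_rel_equal(helicity_intensity(rotate_field(f, Rm)),
                   helicity_intensity(f), 1e-9)
  # quiescent field has zero intensity
  f0 <- flow_field(f$points, 0 * f$velocity, f$pressure, f$cells)
  expect_equal(helicity_intensity(f0), 0)
})

test_that("section probes average pressure exactly for constant and linear fields", {
  f <- small_helical()
  pr <- stenoflow:::section_probe_at(f, c(0, 0, 4), c(0, 0, 1))
  expect_equal(mean_pressure(pr), 100)  # uniform pressure
  # linear pressure field: area-weighted mean = value at the section centroid
  lin <- flow_field(f$points, f$velocity,
                    5 + 2 * f$points[, 1] - 3 * f$points[, 2] + 0.5 * f$points[, 3],
                    f$cells)
  pr2 <- stenoflow:::section_probe_at(lin, c(0, 0, 4), c(0, 0, 1))
  expect_rel_equal(mean_pressure(pr2), 5 + 0.5 * 4, 1e-9)
  # samples lie on the plane
  expect_lt(max(abs(pr2$samples$z - 4)), 1e-6)
  # plane outside the domain errors
  expect_error(stenoflow:::section_probe_at(f, c(0, 0, 50), c(0, 0, 1)),
               "does not intersect")
})

test_that("pressure drop and FFR arithmetic behave as defined", {
  expect_equal(pressure_drop(100, 77.47), 22.53)
  expect_equal(pressure_drop(100, 100), 0)
  # antisymmetry: drop(p_ref, p) = -(p - p_ref)
  expect_equal(pressure_drop(90, 95), -pressure_drop(95, 90) - 0)  # = -5
  expect_equal(ffr(100, 14.02), 0.1402)
  expect_equal(ffr(100, 100), 1)
  expect_equal(round(ffr(100, 77.47), 3), 0.775)
  expect_error(ffr(0, 50), "positive")
})

test_that("probe planes anchor one diameter beyond the lesion window", {
  spec <- bifurcation_spec(alpha_deg = 55, stenosis_sb_pct = 60)
  cl <- build_centerlines(spec)
  f <- stenotic_jet_field(cl, flow_conditions(), dp_mb = 10, dp_sb = 12,
                          mesh_density = 8)
  pp <- extract_section(f, cl$PMB, 1, "proximal")
  expect_equal(pp$location, 26.4 - 3.30)
  pd <- extract_section(f, cl$DMB, 1, "distal")
  expect_equal(pd$location, 6 + 2.77)
  ps <- extract_section(f, cl$SB, 1, "distal")
  expect_equal(ps$location, 6 + 2.10)
  # plane offset beyond the branch extent errors
  expect_error(extract_section(f, cl$SB, 50, "distal"), "outside the domain")
})
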