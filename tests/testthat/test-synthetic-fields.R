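test_that("Poiseuille generator matches its analytic profile and conserves mass", {
  spec <- analytic_field_spec("poiseuille", radius = 1.65, length = 12,
                              flow = 120, mesh_density = 16)
  f <- poiseuille_field(spec)
  # centreline velocity ~ 2 Q / (pi R^2) ~ 0.468 m/s for the inlet conditions
  v_ana <- 2 * (120 / 6e7) / (pi * 1.65e-3^2)
  expect_rel_equal(max(f$velocity[, 3]), v_ana, 0.01)
  # discrete mass conservation across sections
  for (z in c(3, 6, 9)) {
    pr <- stenoflow:::section_probe_at(f, c(0, 0, z), c(0, 0, 1))
    expect_rel_equal(section_flux(pr), 120, 0.005)
  }
  # axial pressure gradient follows the Poiseuille relation with mu_inf
  g_ana <- 8 * 0.0035 * (120 / 6e7) / (pi * 1.65e-3^4) * 1e-3 / 133.322
  p0 <- mean_pressure(stenoflow:::section_probe_at(f, c(0, 0, 2), c(0, 0, 1)))
  p1 <- mean_pressure(stenoflow:::section_probe_at(f, c(0, 0, 10), c(0, 0, 1)))
  expect_rel_equal((p0 - p1) / 8, g_ana, 1e-6)
})

test_that("mirrored helical half-domains cancel signed helicity, not intensity", {
  f1 <- small_helical(omega = 400)
  f2 <- small_helical(omega = -400)
  # net signed helicity of the combined domain ~ 0, intensity > 0
  signed <- function(f) {
    om <- vorticity(f)
    h <- rowSums(f$velocity * om)
    hc <- rowMeans(matrix(h[f$cells], ncol = 4))
    sum(hc * f$cell_volumes) / sum(f$cell_volumes)
  }
  net <- signed(f1) + signed(f2)
  expect_lt(abs(net), 1e-9 * abs(signed(f1)))
  expect_gt(helicity_intensity(f1), 0)
})

test_that("generators are deterministic", {
  s <- analytic_field_spec("helical", omega = 300, mesh_density = 10)
  f1 <- helical_field(s); f2 <- helical_field(s)
  expect_identical(f1, f2)
  spec <- bifurcation_spec(alpha_deg = 55)
  cl <- build_centerlines(spec)
  j1 <- stenotic_jet_field(cl, flow_conditions(), dp_mb = 10, dp_sb = 15,
                           mesh_density = 8, swirl_fraction = 0.2)
  j2 <- stenotic_jet_field(cl, flow_conditions(), dp_mb = 10, dp_sb = 15,
                           mesh_density = 8, swirl_fraction = 0.2)
  expect_identical(j1, j2)
})

test_that("stenotic jet reproduces prescribed pressure drops through the probes", {
  spec <- bifurcation_spec(alpha_deg = 70, stenosis_sb_pct = 80)
  cl <- build_centerlines(spec)
  fl <- flow_conditions(split_dmb = 0.55, split_sb = 0.45)
  f <- stenotic_jet_field(cl, fl, dp_mb = 12.60, dp_sb = 85.98,
                          mesh_density = 10, swirl_fraction = 0.2)
  p_prox <- mean_pressure(extract_section(f, cl$PMB, 1, "proximal"))
  p_dmb <- mean_pressure(extract_section(f, cl$DMB, 1, "distal"))
  p_sb <- mean_pressure(extract_section(f, cl$SB, 1, "distal"))
  expect_lt(abs(p_prox - 100), 1e-6)
  # prescribed drops recovered well within 0.5 %
  expect_rel_equal(pressure_drop(100, p_dmb), 12.60, 0.005)
  expect_rel_equal(pressure_drop(100, p_sb), 85.98, 0.005)
  # the calibration case: FFR_SB = 0.140 +- 0.001
  expect_lt(abs(ffr(p_prox, p_sb) - 0.140), 0.001)
  expect_equal(round(ffr(p_prox, p_dmb), 3), 0.874)
  # mass conservation: inlet flux equals the two outlet fluxes
  q_in <- section_flux(extract_section(f, cl$PMB, 1, "proximal"))
  q_d <- section_flux(extract_section(f, cl$DMB, 1, "distal"))
  q_s <- section_flux(extract_section(f, cl$SB, 1, "distal"))
  expect_rel_equal(q_in, 120, 0.005)
  expect_rel_equal(q_d + q_s, q_in, 0.005)
  expect_rel_equal(q_s, 54, 0.005)
})

test_that("zero prescribed drop yields unit FFR; negative drops are rejected", {
  spec <- bifurcation_spec(alpha_deg = 40, stenosis_sb_pct = 40)
  cl <- build_centerlines(spec)
  f <- stenotic_jet_field(cl, flow_conditions(), dp_mb = 0, dp_sb = 0,
                          mesh_density = 8)
  p_prox <- mean_pressure(extract_section(f, cl$PMB, 1, "proximal"))
  p_sb <- mean_pressure(extract_section(f, cl$SB, 1, "distal"))
  expect_equal(round(ffr(p_prox, p_sb), 3), 1.000)
  expect_error(stenotic_jet_field(cl, flow_conditions(), dp_mb = -1, dp_sb = 0),
               "non-negative")
})

test_that("noisy dP-Q samples are reproducible and unbiased", {
  d0 <- noisy_dpq(0.451, 0.010, c(30, 42, 54), sigma = 0)
  f0 <- dpq_fit(d0)
  expect_equal(unname(coef(f0)), c(0.451, 0.010), tolerance = 1e-12)
  d1 <- noisy_dpq(0.451, 0.010, c(30, 42, 54), sigma = 0.5, seed = 42)
  d2 <- noisy_dpq(0.451, 0.010, c(30, 42, 54), sigma = 0.5, seed = 42)
  expect_identical(d1, d2)
  expect_false(identical(d1$dp, d0$dp))
  # the seeded draw must not disturb the global RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(noisy_dpq(1, 0, 1:3, sigma = 1, seed = 99)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("Monte-Carlo recovery of the quadratic coefficients is unbiased", {
  q <- c(30, 42, 54); sigma <- 0.5
  nrep <- 1000
  A <- numeric(nrep); rm_ <- numeric(nrep)
  set.seed(20160805)
  for (i in seq_len(nrep)) {
    d <- noisy_dpq(0.451, 0.010, q, sigma = sigma)
    fit <- dpq_fit(d)
    A[i] <- coef(fit)["A"]
    rm_[i] <- fit$rmse
  }
  # mean fitted A within 2 standard errors of the truth
  expect_lt(abs(mean(A) - 0.451), 2 * sd(A) / sqrt(nrep))
  # with n - m = 1 residual dof the RMSE is sigma * |N(0,1)|, so its mean is
  # sigma * sqrt(2/pi)
  expect_lt(abs(mean(rm_) - sigma * sqrt(2 / pi)), 3 * sd(rm_) / sqrt(nrep))
})

test_that("the reference table is internally consistent", {
  ref <- reference_results()
  expect_equal(nrow(ref), 27)
  expect_setequal(unique(ref$q_sb_ml_min), c(30, 42, 54))
  # FFR_SB consistent with dP_SB at 3 decimals across all rows
  expect_lt(max(abs(ref$ffr_sb - (100 - ref$dp_sb) / 100)), 5e-4 + 1e-9)
  # spot values
  r1 <- ref[ref$case_id == "40%-40deg-25%sb", ]
  expect_equal(c(r1$dp_mb, r1$ffr_mb), c(14.89, 0.851))
  r2 <- ref[ref$case_id == "80%-70deg-45%sb", ]
  expect_equal(c(r2$dp_sb, r2$ffr_sb), c(85.98, 0.140))
})
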