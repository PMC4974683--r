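test_that("Finet's law reproduces the population-based mother diameter", {
  expect_equal(round(finet_pmb_diameter(2.77, 2.10), 2), 3.30)
  expect_equal(finet_pmb_diameter(0, 0), 0)
  expect_equal(finet_pmb_diameter(2.0, 2.0), 2.712)
  expect_error(finet_pmb_diameter(-1, 2), "non-negative")
  # default spec is Finet-consistent at 2 decimals
  spec <- bifurcation_spec()
  expect_equal(round(finet_pmb_diameter(spec$d_dmb, spec$d_sb), 2), spec$d_pmb)
})

test_that("curvature ratio matches vessel radius over sphere radius", {
  expect_equal(round(curvature_ratio(bifurcation_spec()), 2), 0.03)
  expect_equal(curvature_ratio(bifurcation_spec()), (3.30 / 2) / 56.25)
  # vanishes as the sphere flattens out
  r1 <- curvature_ratio(bifurcation_spec(sphere_radius = 500))
  r2 <- curvature_ratio(bifurcation_spec(sphere_radius = 5000))
  expect_true(r2 < r1 && r2 < 1e-3)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(bifurcation_spec(alpha_deg = 0), "alpha_deg")
  expect_error(bifurcation_spec(stenosis_sb_pct = 100), "stenosis_sb_pct")
  expect_error(bifurcation_spec(d_sb = -1), "positive|non-negative")
  expect_error(bifurcation_spec(sphere_radius = 2), "sphere_radius")
})

test_that("centerlines meet at one carina on the sphere with the spec angles", {
  for (alpha in c(40, 55, 70)) {
    spec <- bifurcation_spec(alpha_deg = alpha)
    cl <- build_centerlines(spec)
    ang <- bifurcation_angles(cl)
    expect_lt(abs(ang["alpha_deg"] - alpha), 0.1)
    expect_lt(abs(ang["beta_deg"] - 150), 0.1)
    # single carina point: PMB end == DMB start == SB start
    carina <- cl$PMB$position[nrow(cl$PMB$position), ]
    expect_lt(max(abs(cl$DMB$position[1, ] - carina)), 1e-9)
    expect_lt(max(abs(cl$SB$position[1, ] - carina)), 1e-9)
    # sphere constraint, all branches
    for (br in names(cl)) {
      dev <- abs(sqrt(rowSums(cl[[br]]$position^2)) - spec$sphere_radius)
      expect_lt(max(dev), 1e-6)
      # unit tangents
      expect_lt(max(abs(sqrt(rowSums(cl[[br]]$tangent^2)) - 1)), 1e-9)
      # strictly increasing arc length
      expect_true(all(diff(cl[[br]]$arc_length) > 0))
    }
  }
})

test_that("proximal segment length and lesion windows follow the spec", {
  spec <- bifurcation_spec()
  cl <- build_centerlines(spec)
  # stenosis starts 8 diameters (26.4 mm) from the inlet
  expect_equal(attr(cl$PMB, "lesion_window")[1], 26.4)
  # each branch pathway sees 12 mm of lesion in total
  wp <- attr(cl$PMB, "lesion_window")
  wd <- attr(cl$DMB, "lesion_window")
  ws <- attr(cl$SB, "lesion_window")
  expect_equal(diff(wp) + diff(wd), 12)
  expect_equal(diff(wp) + diff(ws), 12)
  # PMB window ends at the carina
  expect_equal(wp[2], max(cl$PMB$arc_length))
})

test_that("infeasible angle combinations are rejected", {
  expect_error(build_centerlines(bifurcation_spec(alpha_deg = 179, beta_deg = 10)),
               "infeasible|folds back")
})

test_that("stenosis profile narrows to the prescribed throat and stays C1", {
  spec <- bifurcation_spec(stenosis_sb_pct = 80)
  # PMB: 60 % stenosis of 3.30 mm -> 1.32 mm at the throat
  throat <- mean(c(26.4, 32.4))
  expect_equal(stenosis_profile(spec, "PMB", throat)$diameter, 3.30 * 0.40)
  # outside the window: nominal diameter, zero offset
  out <- stenosis_profile(spec, "PMB", c(0, 10, 26.4))
  expect_equal(out$diameter, rep(3.30, 3))
  expect_equal(out$offset, rep(0, 3))
  # unstenosed branch: identity everywhere
  spec0 <- bifurcation_spec(stenosis_sb_pct = 0)
  s <- seq(0, 6, by = 0.1)
  expect_equal(stenosis_profile(spec0, "SB", s)$diameter, rep(2.10, length(s)))
  # eccentric: outer wall fixed (center offset equals half the lost diameter)
  pr <- stenosis_profile(spec, "SB", 3)
  expect_equal(pr$offset, (2.10 - pr$diameter) / 2)
  # C1: numerical derivative of diameter is continuous across the window edge
  h <- 1e-5
  d1 <- (stenosis_profile(spec, "SB", h)$diameter -
         stenosis_profile(spec, "SB", 0)$diameter) / h
  expect_lt(abs(d1), 1e-3)
  expect_error(stenosis_profile(spec, "XX", 1), "unknown branch")
})

test_that("tessellation is watertight with circular inlet and labelled caps", {
  spec <- bifurcation_spec(alpha_deg = 70, stenosis_sb_pct = 80)
  mesh <- tessellate(spec, resolution = 32)
  expect_true(is_watertight(mesh))
  expect_true(all(triangle_areas(mesh$vertices, mesh$triangles) > 0))
  expect_gt(stenoflow:::mesh_volume(mesh$vertices, mesh$triangles), 0)
  expect_setequal(names(mesh$cap_labels), c("inlet", "outlet_dmb", "outlet_sb"))
  expect_lt(abs(cap_equivalent_diameter(mesh, "inlet") / 3.30 - 1), 0.01)
  expect_error(tessellate(spec, resolution = 4), "resolution")
})

test_that("self-measured stenosis closes on the requested severity", {
  for (sten in c(40, 80)) {
    mesh <- tessellate(bifurcation_spec(alpha_deg = 55, stenosis_sb_pct = sten),
                       resolution = 32)
    expect_lt(abs(measure_stenosis(mesh, "SB") - sten), 1)
    expect_lt(abs(measure_stenosis(mesh, "PMB") - 60), 1)
    expect_lt(abs(measure_stenosis(mesh, "DMB") - 60), 1)
  }
  # unstenosed branch measures ~0
  mesh0 <- tessellate(bifurcation_spec(alpha_deg = 55, stenosis_sb_pct = 0),
                      resolution = 32)
  expect_lt(abs(measure_stenosis(mesh0, "SB")), 1)
})

test_that("throat measurement is mesh-converged", {
  spec <- bifurcation_spec(alpha_deg = 55, stenosis_sb_pct = 60)
  m1 <- measure_stenosis(tessellate(spec, resolution = 24), "SB")
  m2 <- measure_stenosis(tessellate(spec, resolution = 48), "SB")
  d1 <- 2.10 * (1 - m1 / 100)
  d2 <- 2.10 * (1 - m2 / 100)
  expect_lt(abs(d2 - d1) / d1, 0.005)
})

test_that("interpenetrating daughter tubes are rejected with a diagnostic", {
  spec <- bifurcation_spec(alpha_deg = 40, stenosis_pmb_pct = 0,
                           stenosis_dmb_pct = 0, stenosis_sb_pct = 0)
  expect_error(tessellate(spec, resolution = 16), "self-intersect")
})

test_that("spec YAML serialization round-trips", {
  spec <- bifurcation_spec(alpha_deg = 70, stenosis_sb_pct = 80)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_bifurcation_spec(spec, path)
  spec2 <- read_bifurcation_spec(path)
  expect_equal(unclass(spec2), unclass(spec))
})

test_that("centerline CSV and STL exports produce well-formed files", {
  spec <- bifurcation_spec()
  cl <- build_centerlines(spec, ds = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_centerlines_csv(cl, csv)
  d <- read.csv(csv)
  expect_setequal(unique(d$branch), c("PMB", "DMB", "SB"))
  expect_true(all(c("x", "y", "z", "arc_length", "diameter") %in% names(d)))
  mesh <- tessellate(spec, resolution = 16, ds = 2)
  stl <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, stl)
  lines <- readLines(stl)
  expect_match(lines[1], "^solid")
  expect_equal(sum(grepl("^facet", lines)), nrow(mesh$triangles))
})
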