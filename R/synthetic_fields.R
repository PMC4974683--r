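# Analytic flow-field generators. These stand in for an external CFD solver:
# every field is prescribed in closed form (velocity from mass conservation,
# pressure imposed), and NONE of them solves the Navier-Stokes equations.
# Their value is that section probing, FFR, vorticity and helicity metrics
# can be verified against closed-form oracles.

#' Analytic field specification
#'
#' Parameters for the synthetic field generators.
#'
#' @param kind one of \code{"poiseuille"}, \code{"helical"},
#'   \code{"stenotic_jet"}.
#' @param radius tube radius (mm).
#' @param length tube length (mm).
#' @param flow volumetric flow (mL/min).
#' @param omega solid-body rotation rate for the helical field (rad/s).
#' @param prescribed_dp imposed pressure drop for the stenotic jet (mmHg).
#' @param mesh_density points per diameter (>= 8).
#' @param seed integer seed for any stochastic downstream use; the fields
#'   themselves are deterministic.
#' @return object of class \code{analytic_field_spec}.
#' @export
analytic_field_spec <- function(kind = c("poiseuille", "helical", "stenotic_jet"),
                                radius = 1.65, length = 20, flow = 120,
                                omega = 0, prescribed_dp = 0,
                                mesh_density = 16, seed = 20160805) {
  kind <- match.arg(kind)
  if (radius <= 0 || length <= 0) stopf("analytic_field_spec: dimensions must be positive")
  if (flow <= 0) stopf("analytic_field_spec: flow must be positive")
  if (mesh_density < 8) stopf("analytic_field_spec: mesh_density must be >= 8")
  structure(list(kind = kind, radius = radius, length = length, flow = flow,
                 omega = omega, prescribed_dp = prescribed_dp,
                 mesh_density = mesh_density, seed = as.integer(seed)),
            class = "analytic_field_spec")
}

# unit-disc template: center point + n_r rings of n_theta points,
# triangulated. Ring radii are inflated so every annulus polygon has the
# same area as the annulus it discretizes (the inscribed-polygon area
# deficit, ~2 pi^2 / (3 n_theta^2), would otherwise bias section fluxes).
disc_template <- function(n_theta, n_r) {
  infl <- sqrt(2 * pi / (n_theta * sin(2 * pi / n_theta)))
  rho <- infl * seq_len(n_r) / n_r
  th <- 2 * pi * (0:(n_theta - 1)) / n_theta
  pts <- rbind(c(0, 0),
               do.call(rbind, lapply(rho, function(r) cbind(r * cos(th), r * sin(th)))))
  ring_start <- 1L + (seq_len(n_r) - 1L) * n_theta + 1L  # first index of each ring
  k <- 0:(n_theta - 1); k1 <- (k + 1) %% n_theta
  tris <- cbind(1L, ring_start[1] + k, ring_start[1] + k1)
  if (n_r > 1) {
    for (j in seq_len(n_r - 1)) {
      a <- ring_start[j]; b <- ring_start[j + 1]
      tris <- rbind(tris,
                    cbind(a + k, a + k1, b + k1),
                    cbind(a + k, b + k1, b + k))
    }
  }
  xy1 <- pts[tris[, 1], , drop = FALSE]
  xy2 <- pts[tris[, 2], , drop = FALSE]
  xy3 <- pts[tris[, 3], , drop = FALSE]
  areas <- abs((xy2[, 1] - xy1[, 1]) * (xy3[, 2] - xy1[, 2]) -
               (xy3[, 1] - xy1[, 1]) * (xy2[, 2] - xy1[, 2])) / 2
  list(xy = pts, tris = tris, areas = areas,
       rho = c(0, rep(rho, each = n_theta)),
       theta = c(0, rep(th, n_r)))
}

# scale factor that makes the piecewise-linear discrete flux of an axial
# profile (node values f, one column per layer) equal the analytic target
# v_bar * pi R^2; cancels the interpolation bias of curved profiles
template_flux_correction <- function(template, f) {
  f <- as.matrix(f)
  M <- (f[template$tris[, 1], , drop = FALSE] +
        f[template$tris[, 2], , drop = FALSE] +
        f[template$tris[, 3], , drop = FALSE]) / 3
  pi / colSums(template$areas * M)
}

# extrude a disc template through a list of layer frames into tetrahedra;
# frame: list(center, e1, e2, radius)
extrude_layers <- function(template, frames) {
  np <- nrow(template$xy)
  nl <- length(frames)
  pts <- matrix(0, np * nl, 3)
  for (i in seq_len(nl)) {
    f <- frames[[i]]
    pts[(i - 1) * np + seq_len(np), ] <-
      sweep(outer(f$radius * template$xy[, 1], f$e1) +
            outer(f$radius * template$xy[, 2], f$e2), 2, f$center, "+")
  }
  t2 <- template$tris
  tets <- vector("list", nl - 1)
  for (i in seq_len(nl - 1)) {
    off <- (i - 1L) * np
    a <- t2[, 1] + off; b <- t2[, 2] + off; c_ <- t2[, 3] + off
    a2 <- a + np; b2 <- b + np; c2 <- c_ + np
    tets[[i]] <- rbind(cbind(a, b, c_, a2),
                       cbind(b, c_, a2, b2),
                       cbind(c_, a2, b2, c2))
  }
  list(points = pts, cells = do.call(rbind, tets),
       rho = rep(template$rho, nl), theta = rep(template$theta, nl),
       layer = rep(seq_len(nl), each = np))
}

template_dims <- function(density) {
  list(n_theta = max(16L, as.integer(round(3 * density))),
       n_r = max(4L, as.integer(ceiling(0.75 * density))))
}

#' Poiseuille flow in a straight tube
#'
#' Parabolic axial velocity matching the requested flow, with the analytic
#' Poiseuille axial pressure gradient evaluated at the infinite-shear
#' viscosity. Local normalized helicity is identically zero (velocity is
#' perpendicular to vorticity everywhere).
#'
#' @param spec an \code{\link{analytic_field_spec}} with
#'   \code{kind = "poiseuille"}.
#' @param p_inlet inlet pressure (mmHg).
#' @param rheology a \code{\link{rheology_params}}.
#' @return a \code{\link{flow_field}}; the tube axis is +z, inlet at z = 0.
#' @export
poiseuille_field <- function(spec, p_inlet = 100, rheology = rheology_params()) {
  stopifnot(inherits(spec, "analytic_field_spec"), spec$kind == "poiseuille")
  dims <- template_dims(spec$mesh_density)
  tpl <- disc_template(dims$n_theta, dims$n_r)
  dz <- 2 * spec$radius / spec$mesh_density
  z <- seq(0, spec$length, by = dz)
  if (z[length(z)] < spec$length) z <- c(z, spec$length)
  frames <- lapply(z, function(zi)
    list(center = c(0, 0, zi), e1 = c(1, 0, 0), e2 = c(0, 1, 0),
         radius = spec$radius))
  ex <- extrude_layers(tpl, frames)
  R_m <- spec$radius * 1e-3
  Q_si <- spec$flow * .MLMIN_M3S
  v_max <- 2 * Q_si / (pi * R_m^2)
  corr <- template_flux_correction(tpl, 2 * (1 - tpl$rho^2))
  vel <- cbind(0, 0, corr * v_max * (1 - ex$rho^2))
  G_pa_m <- 8 * rheology$mu_inf * Q_si / (pi * R_m^4)
  pres <- p_inlet - ex$points[, 3] * (G_pa_m * 1e-3 / .MMHG_PA)
  flow_field(points = ex$points, velocity = vel, pressure = pres, cells = ex$cells)
}

#' Helical (rotating plug) flow in a straight tube
#'
#' v = (-Omega y, Omega x, W) inside a cylinder, with the axial component W
#' set from the requested flow (plug profile). Closed forms: local
#' normalized helicity W / sqrt(Omega^2 r^2 + W^2) (1 on the axis), helicity
#' density |v . omega| = 2 Omega W everywhere, hence helicity intensity
#' exactly 2 Omega W.
#'
#' @param spec an \code{\link{analytic_field_spec}} with
#'   \code{kind = "helical"}; \code{omega} in rad/s.
#' @param p_uniform uniform pressure (mmHg).
#' @return a \code{\link{flow_field}}.
#' @export
helical_field <- function(spec, p_uniform = 100) {
  stopifnot(inherits(spec, "analytic_field_spec"), spec$kind == "helical")
  dims <- template_dims(spec$mesh_density)
  tpl <- disc_template(dims$n_theta, dims$n_r)
  dz <- 2 * spec$radius / spec$mesh_density
  z <- seq(0, spec$length, by = dz)
  if (z[length(z)] < spec$length) z <- c(z, spec$length)
  frames <- lapply(z, function(zi)
    list(center = c(0, 0, zi), e1 = c(1, 0, 0), e2 = c(0, 1, 0),
         radius = spec$radius))
  ex <- extrude_layers(tpl, frames)
  R_m <- spec$radius * 1e-3
  W <- spec$flow * .MLMIN_M3S / (pi * R_m^2)
  xy_m <- ex$points[, 1:2] * 1e-3
  vel <- cbind(-spec$omega * xy_m[, 2], spec$omega * xy_m[, 1], W)
  flow_field(points = ex$points, velocity = vel,
             pressure = rep(p_uniform, nrow(ex$points)), cells = ex$cells)
}

#' Stenotic jet field over a bifurcation geometry
#'
#' Desk-scale stand-in for a CFD solution on the stenosed bifurcation:
#' builds curved tube grids along the three branch centerlines, fills them
#' with a mass-conserving axial velocity (parabolic blending toward plug in
#' the throat, scaled by the local lumen area), an optional post-throat
#' swirl, and an imposed pressure field calibrated so the pressure drop
#' between the proximal probe plane and each branch's distal probe plane
#' equals the prescribed values exactly. NOT a Navier-Stokes solution: a
#' calibrated fixture for testing the probe/FFR pipeline end to end.
#'
#' @param geom a \code{centerline_set} (or a \code{\link{bifurcation_spec}},
#'   from which centerlines are built).
#' @param flow a \code{\link{flow_conditions}}.
#' @param dp_mb,dp_sb prescribed pressure drops (mmHg, >= 0) from the
#'   proximal probe plane to the DMB and SB distal probe planes.
#' @param p_ref pressure at the proximal probe plane (mmHg).
#' @param probe_offset probe-plane offset in local diameters (must match the
#'   offset used when probing).
#' @param mesh_density points per diameter.
#' @param swirl_fraction azimuthal velocity at the wall as a fraction of the
#'   local excess axial velocity; gives the jet a helical structure whose
#'   intensity grows with stenosis severity and flow. Non-physical knob.
#' @return a \code{\link{flow_field}} with cells labelled by branch.
#' @export
stenotic_jet_field <- function(geom, flow = flow_conditions(),
                               dp_mb = 0, dp_sb = 0, p_ref = 100,
                               probe_offset = 1, mesh_density = 10,
                               swirl_fraction = 0) {
  if (inherits(geom, "bifurcation_spec")) geom <- build_centerlines(geom)
  stopifnot(inherits(geom, "centerline_set"))
  if (dp_mb < 0 || dp_sb < 0)
    stopf("stenotic_jet_field: prescribed pressure drops must be non-negative")
  spec <- attr(geom, "spec")
  Q <- c(PMB = flow$inlet_flow,
         DMB = flow$inlet_flow * flow$split_dmb,
         SB = flow$inlet_flow * flow$split_sb)

  # resistance density ~ (A_ref/A)^2, integrated per branch between probes
  gfun <- function(branch, s) {
    d <- stenosis_profile(spec, branch, s)$diameter
    (branch_nominal_diameter(spec, "PMB") / d)^4
  }
  trap <- function(s, y) sum(diff(s) * (head(y, -1) + tail(y, -1)) / 2)
  probe_s <- list(
    PMB = lesion_window(spec, "PMB")[1] - probe_offset * spec$d_pmb,
    DMB = lesion_window(spec, "DMB")[2] + probe_offset * spec$d_dmb,
    SB  = lesion_window(spec, "SB")[2] + probe_offset * spec$d_sb)
  sP <- seq(probe_s$PMB, branch_total_length(spec, "PMB"), length.out = 400)
  I_P <- trap(sP, gfun("PMB", sP))
  sD <- seq(0, probe_s$DMB, length.out = 400)
  I_D <- trap(sD, gfun("DMB", sD))
  sS <- seq(0, probe_s$SB, length.out = 400)
  I_S <- trap(sS, gfun("SB", sS))
  c_mb <- dp_mb / (I_P + I_D)
  c_sb <- (dp_sb - c_mb * I_P) / I_S
  p_carina <- p_ref - c_mb * I_P

  pressure_at <- function(branch, s) {
    # cumulative imposed drop along the branch arc
    vapply(s, function(si) {
      if (branch == "PMB") {
        grid <- seq(probe_s$PMB, si, length.out = 200)
        p_ref - c_mb * trap(grid, gfun("PMB", grid))
      } else {
        cc <- if (branch == "DMB") c_mb else c_sb
        grid <- seq(0, max(si, 1e-9), length.out = 200)
        p_carina - cc * trap(grid, gfun(branch, grid))
      }
    }, 1)
  }

  dims <- template_dims(mesh_density)
  tpl <- disc_template(dims$n_theta, dims$n_r)
  parts <- list()
  for (br in c("PMB", "DMB", "SB")) {
    cl <- geom[[br]]
    L <- branch_total_length(spec, br)
    win <- lesion_window(spec, br)
    d_nom <- branch_nominal_diameter(spec, br)
    dz_fine <- d_nom / mesh_density
    s <- sort(unique(c(seq(0, L, by = 4 * dz_fine),
                       seq(max(0, win[1] - d_nom), min(L, win[2] + d_nom),
                           by = dz_fine), L)))
    prof <- stenosis_profile(spec, br, s)
    frames <- lapply(seq_along(s), function(i) {
      at <- centerline_at(cl, s[i])
      e1 <- unitv(at$position)
      e2 <- unitv(cross3(at$tangent, e1))
      list(center = at$position + prof$offset[i] * e1, e1 = e1, e2 = e2,
           radius = prof$diameter[i] / 2, tangent = at$tangent, s = s[i])
    })
    ex <- extrude_layers(tpl, frames)
    A_m2 <- pi * (vapply(frames, `[[`, 1, "radius") * 1e-3)^2
    vbar <- Q[br] * .MLMIN_M3S / A_m2               # per layer, m/s
    vbar_nom <- Q[br] * .MLMIN_M3S / (pi * (d_nom / 2 * 1e-3)^2)
    bump <- stenosis_profile(spec, br, s)$diameter / d_nom
    k_exp <- 2 + 6 * (1 - bump)                     # plug-like in the throat
    lay <- ex$layer
    f_tpl <- vapply(k_exp, function(k) ((k + 2) / k) * (1 - tpl$rho^max(k, 2)),
                    numeric(length(tpl$rho)))
    corr <- template_flux_correction(tpl, f_tpl)
    f_ax <- corr[lay] * ((k_exp[lay] + 2) / k_exp[lay]) * (1 - ex$rho^pmax(k_exp[lay], 2))
    tvec <- t(vapply(frames, `[[`, numeric(3), "tangent"))
    vel <- tvec[lay, , drop = FALSE] * (vbar[lay] * f_ax)
    if (swirl_fraction > 0) {
      excess <- pmax(vbar[lay] - vbar_nom, 0)
      vth <- swirl_fraction * excess * ex$rho
      e1m <- t(vapply(frames, `[[`, numeric(3), "e1"))[lay, , drop = FALSE]
      e2m <- t(vapply(frames, `[[`, numeric(3), "e2"))[lay, , drop = FALSE]
      ct <- cos(ex$theta); st <- sin(ex$theta)
      e_th <- -e1m * st + e2m * ct
      vel <- vel + e_th * vth
    }
    pres <- pressure_at(br, s)[lay]
    parts[[br]] <- list(points = ex$points, velocity = vel, pressure = pres,
                        cells = ex$cells, region = rep(br, nrow(ex$cells)))
  }
  off <- cumsum(c(0, vapply(parts, function(p) nrow(p$points), 1)))
  pts <- do.call(rbind, lapply(parts, `[[`, "points"))
  vel <- do.call(rbind, lapply(parts, `[[`, "velocity"))
  pres <- unlist(lapply(parts, `[[`, "pressure"), use.names = FALSE)
  cells <- do.call(rbind, lapply(seq_along(parts),
                                 function(i) parts[[i]]$cells + off[i]))
  region <- unlist(lapply(parts, `[[`, "region"), use.names = FALSE)
  flow_field(points = pts, velocity = vel, pressure = pres, cells = cells,
             region = region)
}

#' Simulated pressure-drop/flow points with Gaussian noise
#'
#' dp = a q + b q^2 + N(0, sigma), reproducible under the given seed (the
#' global RNG state is preserved).
#'
#' @param a,b quadratic law coefficients (mmHg min/mL, mmHg min^2/mL^2).
#' @param q_values flow values (mL/min).
#' @param sigma noise standard deviation (mmHg).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return data frame with columns \code{q}, \code{dp}, \code{case_id}.
#' @export
noisy_dpq <- function(a, b, q_values, sigma = 0, seed = NULL) {
  if (sigma < 0) stopf("noisy_dpq: sigma must be non-negative")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  dp <- a * q_values + b * q_values^2 + stats::rnorm(length(q_values), 0, sigma)
  data.frame(q = q_values, dp = dp,
             case_id = sprintf("sim_%02d", seq_along(q_values)))
}
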