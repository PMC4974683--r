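#' Carreau rheology parameters for blood
#'
#' Shear-thinning Carreau constants: zero-shear viscosity \code{mu_0},
#' infinite-shear viscosity \code{mu_inf}, time constant \code{lambda},
#' power-law index \code{n}, and density \code{rho}. Defaults are the
#' standard blood values mu_inf = 0.0035 Pa s, mu_0 = 0.25 Pa s,
#' lambda = 25 s, n = 0.25, rho = 1060 kg/m^3.
#'
#' @param mu_inf infinite-shear viscosity (Pa s).
#' @param mu_0 zero-shear viscosity (Pa s).
#' @param lambda time constant (s).
#' @param n power-law index, in (0, 1].
#' @param rho density (kg/m^3).
#' @return object of class \code{rheology_params}.
#' @export
rheology_params <- function(mu_inf = 0.0035, mu_0 = 0.25, lambda = 25,
                            n = 0.25, rho = 1060) {
  if (!(mu_0 >= mu_inf && mu_inf > 0)) stopf("rheology_params: need mu_0 >= mu_inf > 0")
  if (lambda <= 0) stopf("rheology_params: lambda must be positive")
  if (n <= 0 || n > 1) stopf("rheology_params: n must lie in (0, 1]")
  if (rho <= 0) stopf("rheology_params: rho must be positive")
  structure(list(mu_inf = mu_inf, mu_0 = mu_0, lambda = lambda, n = n, rho = rho),
            class = "rheology_params")
}

#' Flow boundary conditions for one bifurcation case
#'
#' @param inlet_flow imposed inlet flow (mL/min); the default 120 mL/min is
#'   the hyperemic flow of the study conditions.
#' @param cfr_multiplier coronary flow reserve (hyperemic/resting ratio).
#' @param split_dmb,split_sb outflow fractions to the distal main branch and
#'   side branch; must sum to 1.
#' @param rheology a \code{\link{rheology_params}}.
#' @return object of class \code{flow_conditions}.
#' @export
flow_conditions <- function(inlet_flow = 120, cfr_multiplier = 3,
                            split_dmb = 0.65, split_sb = 1 - split_dmb,
                            rheology = rheology_params()) {
  if (inlet_flow <= 0) stopf("flow_conditions: inlet_flow must be positive")
  if (abs(split_dmb + split_sb - 1) > 1e-9)
    stopf("flow_conditions: split fractions must sum to 1")
  if (split_dmb <= 0 || split_dmb >= 1 || split_sb <= 0 || split_sb >= 1)
    stopf("flow_conditions: split fractions must lie in (0, 1)")
  structure(list(inlet_flow = inlet_flow, cfr_multiplier = cfr_multiplier,
                 split_dmb = split_dmb, split_sb = split_sb,
                 rheology = rheology),
            class = "flow_conditions")
}

#' Resting coronary flow from vessel diameter
#'
#' Diameter-based scaling law for resting flow, q = 1.43 d^2.55 (q in
#' mL/min, d in mm).
#'
#' @param d vessel diameter (mm).
#' @return resting flow (mL/min).
#' @export
resting_flow <- function(d) {
  if (any(d <= 0)) stopf("resting_flow: diameter must be positive")
  1.43 * d^2.55
}

#' Hyperemic flow from resting flow and coronary flow reserve
#'
#' @param resting resting flow (mL/min).
#' @param cfr coronary flow reserve multiplier.
#' @return hyperemic flow (mL/min).
#' @export
hyperemic_flow <- function(resting, cfr = 3) {
  if (any(resting <= 0) || any(cfr <= 0))
    stopf("hyperemic_flow: inputs must be positive")
  resting * cfr
}

#' Physiological flow split from daughter diameters
#'
#' Diameter-ratio law for the flow split of an unstenosed bifurcation:
#' Q_SB / Q_DMB = (d_SB / d_DMB)^2.27. For the default daughter diameters
#' (2.10 and 2.77 mm) this gives a 65:35 DMB:SB split at integer-percent
#' rounding.
#'
#' @param d_sb side branch diameter (mm).
#' @param d_dmb distal main branch diameter (mm).
#' @return named vector \code{c(sb_fraction, dmb_fraction)}; sums to 1.
#' @export
diameter_flow_split <- function(d_sb, d_dmb) {
  if (d_sb <= 0 || d_dmb <= 0) stopf("diameter_flow_split: diameters must be positive")
  r <- (d_sb / d_dmb)^2.27
  c(sb_fraction = r / (1 + r), dmb_fraction = 1 / (1 + r))
}

#' Carreau dynamic viscosity
#'
#' mu(S) = mu_inf + (mu_0 - mu_inf) [1 + (lambda S)^2]^((n-1)/2); strictly
#' decreasing in the shear rate for n < 1, bounded between the two limiting
#' viscosities.
#'
#' @param shear_rate shear rate (1/s), non-negative; vectorized.
#' @param p a \code{\link{rheology_params}}.
#' @return dynamic viscosity (Pa s).
#' @export
carreau_viscosity <- function(shear_rate, p = rheology_params()) {
  if (any(shear_rate < 0)) stopf("carreau_viscosity: shear rate must be non-negative")
  p$mu_inf + (p$mu_0 - p$mu_inf) * (1 + (p$lambda * shear_rate)^2)^((p$n - 1) / 2)
}

#' Tube Reynolds number
#'
#' Re = rho v d / mu with the bulk velocity v = Q / (pi d^2 / 4); diameter in
#' mm and flow in mL/min are converted to SI internally. With the default
#' inlet conditions (3.30 mm, 120 mL/min, mu_inf) this is ~234.
#'
#' @param d diameter (mm).
#' @param Q flow (mL/min).
#' @param p a \code{\link{rheology_params}} (supplies the density).
#' @param mu_eff effective dynamic viscosity (Pa s); defaults to the
#'   infinite-shear viscosity.
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(d, Q, p = rheology_params(), mu_eff = p$mu_inf) {
  if (any(d <= 0) || any(Q < 0) || any(mu_eff <= 0))
    stopf("reynolds_number: inputs must be positive")
  d_m <- d * 1e-3
  Q_si <- Q * .MLMIN_M3S
  v <- Q_si / (pi * d_m^2 / 4)
  p$rho * v * d_m / mu_eff
}

#' The 27-case study grid
#'
#' Full factorial of 3 distal angles (40, 55, 70 deg) x 3 side-branch
#' stenoses (40, 60, 80 %) x 3 flow splits (DMB:SB 55:45, 65:35, 75:25), with
#' PMB/DMB stenosis fixed at 60 % and 120 mL/min hyperemic inlet flow. The
#' order is deterministic: stenosis block, then SB flow percentage, then
#' angle, matching the reference results table.
#'
#' @param inlet_flow inlet flow (mL/min).
#' @return list of 27 cases, each a list with \code{case_id},
#'   \code{spec} (a \code{\link{bifurcation_spec}}) and \code{flow}
#'   (a \code{\link{flow_conditions}}).
#' @export
case_grid <- function(inlet_flow = 120) {
  cases <- list()
  for (sten in c(40, 60, 80))
    for (sb_pct in c(25, 35, 45))
      for (ang in c(40, 55, 70)) {
        spec <- bifurcation_spec(alpha_deg = ang, stenosis_sb_pct = sten)
        flow <- flow_conditions(inlet_flow = inlet_flow,
                                split_dmb = 1 - sb_pct / 100,
                                split_sb = sb_pct / 100)
        cases[[length(cases) + 1L]] <- list(
          case_id = case_id(sten, ang, sb_pct),
          spec = spec, flow = flow)
      }
  cases
}

case_id <- function(sb_stenosis_pct, alpha_deg, sb_flow_pct) {
  sprintf("%d%%-%ddeg-%d%%sb", sb_stenosis_pct, alpha_deg, sb_flow_pct)
}

#' Export the study grid as a CSV table
#'
#' One row per case with the geometry nomenclature string
#' "PMB%,DMB%,SB%-angle" plus the flow split.
#'
#' @param cases output of \code{\link{case_grid}}.
#' @param path optional output file; when NULL the data frame is returned
#'   without writing.
#' @return data frame of the grid (invisibly when written).
#' @export
case_grid_table <- function(cases = case_grid(), path = NULL) {
  df <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(case_id = cs$case_id,
               nomenclature = sprintf("%g%%,%g%%,%g%%-%gdeg",
                                      cs$spec$stenosis_pmb_pct,
                                      cs$spec$stenosis_dmb_pct,
                                      cs$spec$stenosis_sb_pct,
                                      cs$spec$alpha_deg),
               alpha_deg = cs$spec$alpha_deg,
               sb_stenosis_pct = cs$spec$stenosis_sb_pct,
               split_dmb = cs$flow$split_dmb,
               split_sb = cs$flow$split_sb,
               inlet_flow_ml_min = cs$flow$inlet_flow,
               q_sb_ml_min = cs$flow$inlet_flow * cs$flow$split_sb)
  }))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Read a study-grid configuration from YAML
#'
#' Expected keys: \code{angles_deg}, \code{sb_stenosis_pct}, \code{splits}
#' (SB percentages), \code{inlet_flow_ml_min}, optional \code{rheology}
#' block.
#'
#' @param path YAML file.
#' @return list of cases as in \code{\link{case_grid}}.
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rheo <- do.call(rheology_params, cfg$rheology %||% list())
  inlet <- cfg$inlet_flow_ml_min %||% 120
  cases <- list()
  for (sten in cfg$sb_stenosis_pct)
    for (sb_pct in cfg$splits)
      for (ang in cfg$angles_deg) {
        spec <- bifurcation_spec(alpha_deg = ang, stenosis_sb_pct = sten)
        flow <- flow_conditions(inlet_flow = inlet,
                                split_dmb = 1 - sb_pct / 100,
                                split_sb = sb_pct / 100,
                                rheology = rheo)
        cases[[length(cases) + 1L]] <-
          list(case_id = case_id(sten, ang, sb_pct), spec = spec, flow = flow)
      }
  cases
}
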