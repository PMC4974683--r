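#' Mother-vessel diameter from Finet's law
#'
#' Empirical fractal branching rule for coronary bifurcations: the mother
#' vessel diameter is 0.678 times the sum of the two daughter diameters.
#'
#' @param d_dmb distal main branch diameter (mm).
#' @param d_sb side branch diameter (mm).
#' @return proximal main branch diameter (mm).
#' @examples
#' finet_pmb_diameter(2.77, 2.10)  # ~3.30 mm
#' @export
finet_pmb_diameter <- function(d_dmb, d_sb) {
  if (any(d_dmb < 0) || any(d_sb < 0))
    stopf("finet_pmb_diameter: diameters must be non-negative")
  0.678 * (d_dmb + d_sb)
}

#' Bifurcation case specification
#'
#' All geometric and lesion parameters of one stenosed bifurcation case.
#' Defaults describe the population-based LAD/first-diagonal model: daughter
#' diameters 2.77 and 2.10 mm (mother 3.30 mm by Finet's law), main-branch
#' angle beta = 150 deg, vessel curvature imposed by placing all centerlines
#' on a sphere of radius 56.25 mm (curvature ratio ~0.03), an 8-diameter
#' (26.4 mm) proximal segment, and a 12 mm total lesion per branch pathway
#' with 60 % diameter stenosis in the proximal and distal main branch.
#' Lesions are eccentric: the plaque sits on the inner (sphere-facing) arc,
#' the outer wall stays fixed.
#'
#' @param alpha_deg distal bifurcation angle between DMB and SB axes (deg).
#' @param beta_deg angle between the proximal segment axis (pointing upstream
#'   from the carina) and the DMB axis (deg); 180 would be a straight vessel.
#' @param d_dmb,d_sb daughter diameters (mm).
#' @param d_pmb mother diameter (mm); default from \code{finet_pmb_diameter}
#'   rounded to 2 decimals.
#' @param sphere_radius radius of curvature of the heart surface (mm).
#' @param pmb_length proximal segment length, inlet to stenosis start (mm).
#' @param lesion_length total lesion length seen by each branch pathway (mm).
#' @param stenosis_pmb_pct,stenosis_dmb_pct,stenosis_sb_pct percent diameter
#'   stenosis per branch, in [0, 100).
#' @param dmb_length,sb_length post-stenosis daughter segment lengths (mm);
#'   default 10 local diameters so the distal pressure probe plane is well
#'   inside the domain.
#' @return object of class \code{bifurcation_spec}.
#' @examples
#' spec <- bifurcation_spec(alpha_deg = 70, stenosis_sb_pct = 80)
#' spec$d_pmb
#' @export
bifurcation_spec <- function(alpha_deg = 55,
                             beta_deg = 150,
                             d_dmb = 2.77,
                             d_sb = 2.10,
                             d_pmb = round(finet_pmb_diameter(d_dmb, d_sb), 2),
                             sphere_radius = 56.25,
                             pmb_length = 26.4,
                             lesion_length = 12,
                             stenosis_pmb_pct = 60,
                             stenosis_dmb_pct = 60,
                             stenosis_sb_pct = 60,
                             dmb_length = 10 * d_dmb,
                             sb_length = 10 * d_sb) {
  spec <- list(
    d_pmb = d_pmb, d_dmb = d_dmb, d_sb = d_sb,
    alpha_deg = alpha_deg, beta_deg = beta_deg,
    sphere_radius = sphere_radius,
    pmb_length = pmb_length, lesion_length = lesion_length,
    stenosis_pmb_pct = stenosis_pmb_pct,
    stenosis_dmb_pct = stenosis_dmb_pct,
    stenosis_sb_pct = stenosis_sb_pct,
    dmb_length = dmb_length, sb_length = sb_length)
  class(spec) <- "bifurcation_spec"
  validate_bifurcation_spec(spec)
  spec
}

validate_bifurcation_spec <- function(spec) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in names(spec))
    if (!num1(spec[[f]])) stopf("bifurcation_spec: field '%s' must be a finite scalar", f)
  if (spec$d_pmb <= 0 || spec$d_dmb <= 0 || spec$d_sb <= 0)
    stopf("bifurcation_spec: all diameters must be positive")
  if (spec$alpha_deg <= 0 || spec$alpha_deg >= 180)
    stopf("bifurcation_spec: alpha_deg must lie in (0, 180)")
  if (spec$beta_deg <= 0 || spec$beta_deg >= 180)
    stopf("bifurcation_spec: beta_deg must lie in (0, 180)")
  for (f in c("stenosis_pmb_pct", "stenosis_dmb_pct", "stenosis_sb_pct"))
    if (spec[[f]] < 0 || spec[[f]] >= 100)
      stopf("bifurcation_spec: %s must lie in [0, 100)", f)
  if (spec$pmb_length <= 0) stopf("bifurcation_spec: pmb_length must be positive")
  if (spec$lesion_length <= 0) stopf("bifurcation_spec: lesion_length must be positive")
  if (spec$dmb_length <= 0 || spec$sb_length <= 0)
    stopf("bifurcation_spec: daughter segment lengths must be positive")
  if (spec$sphere_radius <= spec$d_pmb)
    stopf("bifurcation_spec: sphere_radius must exceed the mother diameter")
  invisible(spec)
}

#' @export
print.bifurcation_spec <- function(x, ...) {
  cat("Coronary bifurcation case\n")
  cat(sprintf("  diameters (mm):   PMB %.2f | DMB %.2f | SB %.2f\n",
              x$d_pmb, x$d_dmb, x$d_sb))
  cat(sprintf("  angles (deg):     alpha %.1f (DMB-SB) | beta %.1f (PMB-DMB)\n",
              x$alpha_deg, x$beta_deg))
  cat(sprintf("  stenosis (%%DS):   PMB %g | DMB %g | SB %g (lesion %g mm/pathway)\n",
              x$stenosis_pmb_pct, x$stenosis_dmb_pct, x$stenosis_sb_pct,
              x$lesion_length))
  cat(sprintf("  sphere radius:    %.2f mm (curvature ratio %.3f)\n",
              x$sphere_radius, curvature_ratio(x)))
  invisible(x)
}

#' Vessel curvature ratio
#'
#' Ratio of the mother-vessel radius to the radius of curvature imposed by
#' the sphere the bifurcation is draped on (vessel radius / radius of
#' curvature); ~0.03 for the default model.
#'
#' @param spec a \code{\link{bifurcation_spec}}.
#' @return dimensionless curvature ratio.
#' @export
curvature_ratio <- function(spec) {
  if (spec$sphere_radius <= 0) stopf("curvature_ratio: sphere_radius must be positive")
  (spec$d_pmb / 2) / spec$sphere_radius
}

#' Read / write a bifurcation spec as YAML
#'
#' @param spec a \code{\link{bifurcation_spec}}.
#' @param path file path.
#' @return \code{read_bifurcation_spec} returns a \code{bifurcation_spec};
#'   \code{write_bifurcation_spec} returns \code{path} invisibly.
#' @export
write_bifurcation_spec <- function(spec, path) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_bifurcation_spec
#' @export
read_bifurcation_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(bifurcation_spec, vals)
}
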