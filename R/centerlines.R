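# Centerline construction: the three branch axes are great-circle arcs on the
# curvature sphere (center at the origin), meeting at a single carina point.
# All tangent vectors therefore lie in the sphere's tangent plane at the
# carina, where the branch angles are laid out.

deg2rad <- function(d) d * pi / 180

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

# great-circle arc from point C (on sphere radius R about origin) with unit
# departure tangent t; s = arc length >= 0
arc_point <- function(C, t, R, s) {
  a <- s / R
  outer(cos(a), C) + outer(sin(a), R * t)
}
arc_tangent <- function(C, t, R, s) {
  a <- s / R
  outer(-sin(a), C / R) + outer(cos(a), t)
}

# lesion window [w0, w1] along a branch's own arc-length coordinate
lesion_window <- function(spec, branch) {
  half <- spec$lesion_length / 2
  switch(branch,
    PMB = c(spec$pmb_length, spec$pmb_length + half),
    DMB = c(0, half),
    SB  = c(0, half),
    stopf("unknown branch label '%s'", branch))
}

branch_nominal_diameter <- function(spec, branch) {
  switch(branch, PMB = spec$d_pmb, DMB = spec$d_dmb, SB = spec$d_sb,
         stopf("unknown branch label '%s'", branch))
}

branch_stenosis_pct <- function(spec, branch) {
  switch(branch, PMB = spec$stenosis_pmb_pct, DMB = spec$stenosis_dmb_pct,
         SB = spec$stenosis_sb_pct, stopf("unknown branch label '%s'", branch))
}

branch_total_length <- function(spec, branch) {
  half <- spec$lesion_length / 2
  switch(branch,
    PMB = spec$pmb_length + half,
    DMB = half + spec$dmb_length,
    SB  = half + spec$sb_length)
}

#' Axial stenosis profile of a branch
#'
#' Effective lumen diameter and eccentric center offset at arc length
#' \code{s} along a branch. The lesion narrows the lumen with a raised-cosine
#' diameter profile over the branch's lesion window (C1-continuous, symmetric,
#' throat at the window midpoint reaching the branch's nominal diameter times
#' (1 - stenosis/100)). The plaque is eccentric on the inner (sphere-facing)
#' arc: the lumen center is displaced radially away from the sphere center by
#' half the lost diameter, so the outer wall stays fixed.
#'
#' @param spec a \code{\link{bifurcation_spec}}.
#' @param branch one of \code{"PMB"}, \code{"DMB"}, \code{"SB"}.
#' @param s arc length along the branch (mm, vectorized). For the PMB, s runs
#'   from 0 at the inlet to the carina; for daughters, from 0 at the carina.
#' @return list with \code{diameter} (mm, same length as s) and \code{offset}
#'   (signed radial center displacement, mm; positive = away from the sphere
#'   center).
#' @export
stenosis_profile <- function(spec, branch, s) {
  d_nom <- branch_nominal_diameter(spec, branch)
  pct <- branch_stenosis_pct(spec, branch)
  w <- lesion_window(spec, branch)
  L <- branch_total_length(spec, branch)
  if (any(s < -1e-9 | s > L + 1e-9))
    stopf("stenosis_profile: s outside branch extent [0, %.2f]", L)
  bump <- numeric(length(s))
  inside <- s >= w[1] & s <= w[2]
  bump[inside] <- 0.5 * (1 - cos(2 * pi * (s[inside] - w[1]) / (w[2] - w[1])))
  d_eff <- d_nom * (1 - pct / 100 * bump)
  list(diameter = d_eff, offset = (d_nom - d_eff) / 2)
}

#' Build the three branch centerlines of a bifurcation case
#'
#' Lays the proximal main branch (PMB), distal main branch (DMB) and side
#' branch (SB) axes as great-circle arcs on the curvature sphere, meeting at
#' a single carina point. The DMB departs the carina at (180 - beta) degrees
#' from the incoming PMB flow direction (so beta, measured between the
#' upstream PMB axis and the DMB axis, matches the clinical convention where
#' a straight vessel has beta = 180); the SB departs at alpha degrees from
#' the DMB on the opposite side of the main vessel.
#'
#' @param spec a \code{\link{bifurcation_spec}}.
#' @param ds sampling step along the arcs (mm).
#' @return object of class \code{centerline_set}: a list with elements
#'   \code{PMB}, \code{DMB}, \code{SB} (each a \code{centerline}) plus the
#'   spec, the carina point and the tangent-plane frame as attributes.
#' @export
build_centerlines <- function(spec, ds = 0.25) {
  validate_bifurcation_spec(spec)
  R <- spec$sphere_radius
  C <- c(0, 0, R)            # carina on the sphere
  u <- c(1, 0, 0)            # PMB flow direction at the carina
  w <- c(0, 1, 0)            # in-plane normal direction

  th_D <- deg2rad(180 - spec$beta_deg)
  th_S <- th_D - deg2rad(spec$alpha_deg)
  t_D <- cos(th_D) * u + sin(th_D) * w
  t_S <- cos(th_S) * u + sin(th_S) * w

  # feasibility: neither daughter may fold back along the mother vessel
  if (abs(th_D) > deg2rad(150) || abs(th_S) > deg2rad(150))
    stopf("build_centerlines: infeasible angle combination (a daughter branch folds back onto the PMB; alpha=%.1f, beta=%.1f)",
          spec$alpha_deg, spec$beta_deg)
  for (br in c("PMB", "DMB", "SB"))
    if (branch_total_length(spec, br) >= pi * R / 2)
      stopf("build_centerlines: branch %s too long for the sphere radius", br)

  sample_branch <- function(branch, tangent, upstream = FALSE) {
    L <- branch_total_length(spec, branch)
    win <- lesion_window(spec, branch)
    s <- sort(unique(c(seq(0, L, by = ds), L, win, mean(win))))
    if (upstream) {
      # PMB: parametrize by arc length from the inlet; the arc runs backward
      # from the carina along -tangent
      pos <- arc_point(C, -tangent, R, L - s)
      tan_ <- -arc_tangent(C, -tangent, R, L - s)
    } else {
      pos <- arc_point(C, tangent, R, s)
      tan_ <- arc_tangent(C, tangent, R, s)
    }
    prof <- stenosis_profile(spec, branch, s)
    cl <- list(position = pos, tangent = tan_, arc_length = s,
               local_diameter = prof$diameter, center_offset = prof$offset,
               branch = branch)
    attr(cl, "lesion_window") <- win
    attr(cl, "nominal_diameter") <- branch_nominal_diameter(spec, branch)
    attr(cl, "sphere_radius") <- R
    class(cl) <- "centerline"
    cl
  }

  out <- list(PMB = sample_branch("PMB", u, upstream = TRUE),
              DMB = sample_branch("DMB", t_D),
              SB  = sample_branch("SB", t_S))
  attr(out, "spec") <- spec
  attr(out, "carina") <- C
  attr(out, "frame") <- list(u = u, w = w, t_D = t_D, t_S = t_S,
                             n_sep = unitv(t_D - t_S))
  class(out) <- "centerline_set"
  out
}

#' @export
print.centerline_set <- function(x, ...) {
  spec <- attr(x, "spec")
  ang <- bifurcation_angles(x)
  cat(sprintf("Centerline set: alpha %.2f deg, beta %.2f deg, sphere R %.2f mm\n",
              ang["alpha_deg"], ang["beta_deg"], spec$sphere_radius))
  for (br in names(x))
    cat(sprintf("  %-3s: %d samples, length %.2f mm, lesion [%.1f, %.1f] mm\n",
                br, length(x[[br]]$arc_length), max(x[[br]]$arc_length),
                attr(x[[br]], "lesion_window")[1], attr(x[[br]], "lesion_window")[2]))
  invisible(x)
}

#' Measure the bifurcation angles of a centerline set
#'
#' Recovers alpha (between the DMB and SB departure tangents at the carina)
#' and beta (between the upstream PMB axis and the DMB departure tangent)
#' from the sampled centerlines, for closure checks against the spec.
#'
#' @param cl a \code{centerline_set}.
#' @return named vector \code{c(alpha_deg, beta_deg)}.
#' @export
bifurcation_angles <- function(cl) {
  stopifnot(inherits(cl, "centerline_set"))
  ang <- function(a, b) acos(max(-1, min(1, sum(a * b) / (vnorm(a) * vnorm(b))))) * 180 / pi
  tD <- cl$DMB$tangent[1, ]
  tS <- cl$SB$tangent[1, ]
  tP <- cl$PMB$tangent[nrow(cl$PMB$tangent), ]
  c(alpha_deg = ang(tD, tS), beta_deg = ang(-tP, tD))
}

# interpolate centerline position/tangent/diameter at arbitrary arc length
centerline_at <- function(cl, s) {
  stopifnot(inherits(cl, "centerline"))
  sl <- cl$arc_length
  if (s < min(sl) - 1e-9 || s > max(sl) + 1e-9)
    stopf("centerline_at: s=%.3f outside branch extent", s)
  i <- findInterval(s, sl, all.inside = TRUE)
  f <- (s - sl[i]) / (sl[i + 1] - sl[i])
  pos <- (1 - f) * cl$position[i, ] + f * cl$position[i + 1, ]
  tan_ <- unitv((1 - f) * cl$tangent[i, ] + f * cl$tangent[i + 1, ])
  d <- (1 - f) * cl$local_diameter[i] + f * cl$local_diameter[i + 1]
  list(position = pos, tangent = tan_, diameter = d)
}

#' Export centerlines as CSV
#'
#' One row per sample: branch, x, y, z (mm), arc_length (mm), diameter (mm).
#'
#' @param cl a \code{centerline_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_centerlines_csv <- function(cl, path) {
  stopifnot(inherits(cl, "centerline_set"))
  rows <- do.call(rbind, lapply(names(cl), function(br) {
    b <- cl[[br]]
    data.frame(branch = br, x = b$position[, 1], y = b$position[, 2],
               z = b$position[, 3], arc_length = b$arc_length,
               diameter = b$local_diameter)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
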