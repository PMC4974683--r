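# Hemodynamic read-outs from an unstructured flow field: cross-section
# pressure probes, pressure drops, FFR, vorticity (weighted-least-squares
# gradient reconstruction), local normalized helicity and helicity intensity.

#' Extract a cross-section probe from a flow field
#'
#' Cuts the field with a plane anchored at a branch's lesion-window boundary,
#' offset by a number of local nominal diameters: \code{side = "proximal"}
#' puts the plane upstream of the lesion start, \code{side = "distal"}
#' downstream of the lesion end (the locations where pressures are read for
#' FFR). The plane normal is the local centerline tangent. Each tetrahedron
#' crossed by the plane contributes its intersection polygon, with pressure
#' and velocity linearly interpolated along the cut edges; samples are the
#' fan triangles of those polygons (centroid position, area weight,
#' centroid-averaged values).
#'
#' @param field a \code{\link{flow_field}}.
#' @param centerline a \code{centerline} from \code{\link{build_centerlines}}.
#' @param offset_diameters plane offset from the lesion-window boundary in
#'   local nominal diameters.
#' @param side \code{"proximal"} or \code{"distal"}.
#' @return object of class \code{section_probe}: list with \code{samples}
#'   (data frame: position, pressure, velocity, weight), \code{plane_origin},
#'   \code{plane_normal}, \code{branch}, \code{location} (arc length, mm).
#' @export
extract_section <- function(field, centerline, offset_diameters = 1,
                            side = c("distal", "proximal")) {
  side <- match.arg(side)
  stopifnot(inherits(field, "flow_field"), inherits(centerline, "centerline"))
  win <- attr(centerline, "lesion_window")
  d_nom <- attr(centerline, "nominal_diameter")
  s <- if (side == "proximal") win[1] - offset_diameters * d_nom
       else win[2] + offset_diameters * d_nom
  if (s < min(centerline$arc_length) - 1e-9 || s > max(centerline$arc_length) + 1e-9)
    stopf("extract_section: probe plane (s=%.2f mm on %s) lies outside the domain",
          s, centerline$branch)
  at <- centerline_at(centerline, s)
  probe <- section_probe_at(field, at$position, at$tangent,
                            region = centerline$branch,
                            max_dist = 1.5 * d_nom)
  probe$branch <- centerline$branch
  probe$location <- s
  probe
}

# plane probe at an arbitrary origin/normal; `region` restricts to labelled
# cells when the field carries labels, `max_dist` drops intersection polygons
# farther than this from the origin (guards against the infinite plane
# cutting another branch)
section_probe_at <- function(field, origin, normal, region = NULL,
                             max_dist = Inf) {
  normal <- unitv(normal)
  use <- seq_len(nrow(field$cells))
  if (!is.null(region) && !is.null(field$region))
    use <- which(field$region == region)
  cells <- field$cells[use, , drop = FALSE]
  d <- (field$points %*% normal - sum(origin * normal))[, 1]
  d[abs(d) < 1e-9] <- 1e-9   # plane through mesh nodes: nudge to one side
  dc <- matrix(d[cells], ncol = 4)
  hit <- which(apply(dc, 1, min) < 0 & apply(dc, 1, max) > 0)
  samples <- list()
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (ci in hit) {
    vi <- cells[ci, ]
    dd <- d[vi]
    pts <- NULL; pr <- NULL; vel <- NULL
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      if (dd[a] * dd[b] < 0) {
        t <- dd[a] / (dd[a] - dd[b])
        pts <- rbind(pts, field$points[vi[a], ] + t * (field$points[vi[b], ] - field$points[vi[a], ]))
        pr <- c(pr, field$pressure[vi[a]] + t * (field$pressure[vi[b]] - field$pressure[vi[a]]))
        vel <- rbind(vel, field$velocity[vi[a], ] + t * (field$velocity[vi[b], ] - field$velocity[vi[a], ]))
      }
    }
    if (is.null(pts) || nrow(pts) < 3) next
    ctr <- colMeans(pts)
    if (sqrt(sum((ctr - origin)^2)) > max_dist) next
    # order polygon vertices around the centroid in the cut plane
    b1 <- unitv(pts[1, ] - ctr)
    b2 <- cross3(normal, b1)
    ang <- atan2((pts - rep(ctr, each = nrow(pts))) %*% b2,
                 (pts - rep(ctr, each = nrow(pts))) %*% b1)
    o <- order(ang)
    pts <- pts[o, , drop = FALSE]; pr <- pr[o]; vel <- vel[o, , drop = FALSE]
    k <- nrow(pts)
    for (j in seq_len(k - 2)) {
      tri <- c(1, j + 1, j + 2)
      A <- 0.5 * vnorm(cross3(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ]))
      if (A <= 0) next
      samples[[length(samples) + 1L]] <- c(colMeans(pts[tri, , drop = FALSE]),
                                           mean(pr[tri]),
                                           colMeans(vel[tri, , drop = FALSE]), A)
    }
  }
  if (!length(samples))
    stopf("extract_section: probe plane does not intersect the field")
  S <- do.call(rbind, samples)
  samples <- data.frame(x = S[, 1], y = S[, 2], z = S[, 3], pressure = S[, 4],
                        vx = S[, 5], vy = S[, 6], vz = S[, 7], weight = S[, 8])
  structure(list(samples = samples, plane_origin = origin,
                 plane_normal = normal, branch = NA_character_,
                 location = NA_real_),
            class = "section_probe")
}

#' @export
print.section_probe <- function(x, ...) {
  cat(sprintf("Section probe (%s, s = %.2f mm): %d samples, area %.3f mm^2\n",
              x$branch, x$location, nrow(x$samples), sum(x$samples$weight)))
  cat(sprintf("  mean pressure %.3f mmHg, flux %.2f mL/min\n",
              mean_pressure(x), section_flux(x)))
  invisible(x)
}

#' Area-weighted mean pressure of a section probe
#'
#' @param probe a \code{section_probe}.
#' @return mean static pressure on the section (mmHg).
#' @export
mean_pressure <- function(probe) {
  stopifnot(inherits(probe, "section_probe"))
  if (nrow(probe$samples) == 0) stopf("mean_pressure: empty probe")
  sum(probe$samples$weight * probe$samples$pressure) / sum(probe$samples$weight)
}

#' Volumetric flux through a section probe
#'
#' @param probe a \code{section_probe}.
#' @return flux through the section (mL/min); sign follows the plane normal.
#' @export
section_flux <- function(probe) {
  s <- probe$samples
  vn <- s$vx * probe$plane_normal[1] + s$vy * probe$plane_normal[2] +
        s$vz * probe$plane_normal[3]
  sum(s$weight * vn) * 60   # mm^2 * m/s -> mL/min
}

#' Pressure drop relative to a reference pressure
#'
#' @param p_ref reference pressure (mmHg), e.g. the 100 mmHg aortic pressure
#'   anchored one diameter proximal to the stenosis.
#' @param probe a \code{section_probe} (or a numeric mean pressure).
#' @return p_ref minus the probe's mean pressure (mmHg).
#' @export
pressure_drop <- function(p_ref, probe) {
  p <- if (inherits(probe, "section_probe")) mean_pressure(probe) else probe
  p_ref - p
}

#' Fractional flow reserve
#'
#' Ratio of the mean pressure distal to a stenosis to the proximal (aortic)
#' mean pressure under maximal hyperemia.
#'
#' @param p_prox proximal mean pressure (mmHg), must be positive.
#' @param p_dist distal mean pressure (mmHg).
#' @return dimensionless FFR.
#' @export
ffr <- function(p_prox, p_dist) {
  if (any(p_prox <= 0)) stopf("ffr: proximal pressure must be positive")
  p_dist / p_prox
}

#' Vorticity by weighted-least-squares gradient reconstruction
#'
#' Reconstructs the velocity gradient at every point from its cell-sharing
#' neighbors by inverse-square-distance weighted least squares, then takes
#' the curl. Exact (to round-off) for affine velocity fields on any mesh.
#' Points with fewer than 4 non-coplanar neighbors are flagged and filled
#' with the nearest valid value.
#'
#' @param field a \code{\link{flow_field}}.
#' @return n x 3 matrix of vorticity vectors (1/s, SI); attribute
#'   \code{flagged} lists any degenerate points.
#' @export
vorticity <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  pts <- field$points * 1e-3          # mm -> m
  n <- nrow(pts)
  cells <- field$cells
  pair_idx <- rbind(c(1,2), c(1,3), c(1,4), c(2,1), c(2,3), c(2,4),
                    c(3,1), c(3,2), c(3,4), c(4,1), c(4,2), c(4,3))
  ii <- as.vector(cells[, pair_idx[, 1]])
  jj <- as.vector(cells[, pair_idx[, 2]])
  key <- ii * (n + 1) + jj
  keep <- !duplicated(key)
  ii <- ii[keep]; jj <- jj[keep]
  dx <- pts[jj, , drop = FALSE] - pts[ii, , drop = FALSE]
  w <- 1 / pmax(rowSums(dx^2), 1e-30)
  du <- field$velocity[jj, , drop = FALSE] - field$velocity[ii, , drop = FALSE]
  acc <- function(v) rowsum(v, ii, reorder = FALSE)
  grp <- sort(unique(ii))
  # normal-equation blocks A (3x3 symmetric) and B (3x3) per point
  A11 <- acc(w * dx[,1]^2); A22 <- acc(w * dx[,2]^2); A33 <- acc(w * dx[,3]^2)
  A12 <- acc(w * dx[,1]*dx[,2]); A13 <- acc(w * dx[,1]*dx[,3]); A23 <- acc(w * dx[,2]*dx[,3])
  B <- lapply(1:3, function(a) lapply(1:3, function(b) acc(w * dx[, a] * du[, b])))
  ord <- order(unique(ii))  # rowsum groups in first-appearance order
  grp_first <- unique(ii)
  # invert each 3x3 via adjugate (vectorized)
  a <- A11[,1]; b <- A12[,1]; c_ <- A13[,1]; d <- A22[,1]; e <- A23[,1]; f <- A33[,1]
  det <- a*(d*f - e*e) - b*(b*f - e*c_) + c_*(b*e - d*c_)
  bad <- abs(det) < 1e-12 * pmax(a*d*f, 1e-30)
  det[bad] <- 1
  i11 <- (d*f - e*e)/det; i12 <- (c_*e - b*f)/det; i13 <- (b*e - c_*d)/det
  i22 <- (a*f - c_*c_)/det; i23 <- (b*c_ - a*e)/det; i33 <- (a*d - b*b)/det
  G <- array(0, c(n, 3, 3))  # G[i, a, b] = d v_b / d x_a
  for (bcomp in 1:3) {
    r1 <- B[[1]][[bcomp]][,1]; r2 <- B[[2]][[bcomp]][,1]; r3 <- B[[3]][[bcomp]][,1]
    G[grp_first, 1, bcomp] <- i11*r1 + i12*r2 + i13*r3
    G[grp_first, 2, bcomp] <- i12*r1 + i22*r2 + i23*r3
    G[grp_first, 3, bcomp] <- i13*r1 + i23*r2 + i33*r3
  }
  omega <- cbind(G[, 2, 3] - G[, 3, 2],
                 G[, 3, 1] - G[, 1, 3],
                 G[, 1, 2] - G[, 2, 1])
  flagged <- grp_first[bad]
  isolated <- setdiff(seq_len(n), grp_first)
  flagged <- sort(c(flagged, isolated))
  if (length(flagged)) {
    good <- setdiff(seq_len(n), flagged)
    if (!length(good)) stopf("vorticity: no well-posed points")
    for (i in flagged) {
      nn <- good[which.min(rowSums((pts[good, , drop = FALSE] -
                                     matrix(pts[i, ], length(good), 3, byrow = TRUE))^2))]
      omega[i, ] <- omega[nn, ]
    }
  }
  attr(omega, "flagged") <- flagged
  omega
}

#' Local normalized helicity
#'
#' LNH = (v . omega) / (|v| |omega|), the cosine of the angle between
#' velocity and vorticity, in [-1, 1]. Positive and negative values mark
#' clockwise and counter-clockwise rotating fluid structures along the main
#' flow direction. Degenerate points (|v||omega| below \code{eps}) are set
#' to 0.
#'
#' @param field a \code{\link{flow_field}}.
#' @param omega optional precomputed \code{\link{vorticity}}.
#' @param eps degeneracy threshold on |v||omega| (SI).
#' @return length-n vector of LNH values.
#' @export
local_normalized_helicity <- function(field, omega = NULL, eps = 1e-12) {
  if (is.null(omega)) omega <- vorticity(field)
  num <- rowSums(field$velocity * omega)
  den <- sqrt(rowSums(field$velocity^2)) * sqrt(rowSums(omega^2))
  out <- ifelse(den < eps, 0, num / den)
  pmin(1, pmax(-1, out))
}

#' Helicity intensity
#'
#' Volume-average of the absolute helicity density |v . omega| over the
#' fluid domain: (1/V) sum_cells |v . omega| vol_cell, with the cell value
#' taken as the mean of its vertex values. A magnitude measure of helical
#' flow strength (m/s^2).
#'
#' @param field a \code{\link{flow_field}}.
#' @param omega optional precomputed \code{\link{vorticity}}.
#' @return helicity intensity (m/s^2).
#' @export
helicity_intensity <- function(field, omega = NULL) {
  stopifnot(inherits(field, "flow_field"))
  if (sum(field$cell_volumes) <= 0) stopf("helicity_intensity: zero total volume")
  if (is.null(omega)) omega <- vorticity(field)
  h <- abs(rowSums(field$velocity * omega))
  hc <- rowMeans(matrix(h[field$cells], ncol = 4))
  sum(hc * field$cell_volumes) / sum(field$cell_volumes)
}
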