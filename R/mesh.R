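# Surface tessellation of the bifurcation lumen. Each branch is swept as a
# ring tube along its centerline (ring frame: radial direction of the sphere
# and its binormal, so the frame never twists); the three tubes are joined at
# the carina by a three-strip "pair of pants" stitch plus two pole triangles,
# which is watertight by construction. Caps close the inlet and the two
# outlets.

ring_points <- function(center, e1, e2, radius, n) {
  th <- 2 * pi * (0:(n - 1)) / n
  sweep(outer(cos(th), radius * e1) + outer(sin(th), radius * e2), 2, center, "+")
}

# stitch two rings (base vertex indices a0, b0; n points each) into 2n triangles
stitch_rings <- function(a0, b0, n) {
  k <- 0:(n - 1); k1 <- (k + 1) %% n
  rbind(cbind(a0 + k, a0 + k1, b0 + k1),
        cbind(a0 + k, b0 + k1, b0 + k))
}

# stitch two open chains of equal length into a triangle strip
stitch_chains <- function(a, b) {
  m <- length(a) - 1
  i <- seq_len(m)
  rbind(cbind(a[i], a[i + 1], b[i]),
        cbind(a[i + 1], b[i + 1], b[i]))
}

# index sequences of a ring half, from the pole at theta=0 to the pole at
# theta=pi, running through the +e2 side (plus) or the -e2 side (minus)
half_seq <- function(base, n, side) {
  h <- n / 2
  if (side == "plus") base + 0:h else base + c(0, (n - 1):h)
}

#' Tessellate a bifurcation lumen surface
#'
#' Builds a watertight, consistently oriented triangulated surface of the
#' stenosed bifurcation lumen with labelled inlet and outlet caps. Daughter
#' tubes start one nominal diameter past the carina; the junction is closed
#' by a three-strip loft. Tessellation fails with a diagnostic if the two
#' daughter tubes would interpenetrate (small distal angle combined with wide
#' unstenosed daughters).
#'
#' @param spec a \code{\link{bifurcation_spec}}.
#' @param resolution points per ring circumference (even, >= 8).
#' @param ds ring spacing along the centerlines (mm); lesion windows are
#'   sampled at \code{ds/2}.
#' @return object of class \code{lumen_mesh}: list with \code{vertices}
#'   (n x 3, mm), \code{triangles} (m x 3 vertex indices), \code{tri_label}
#'   (branch wall / junction / cap per triangle) and \code{cap_labels}
#'   (triangle index sets for inlet, outlet_dmb, outlet_sb).
#' @export
tessellate <- function(spec, resolution = 48, ds = 0.5) {
  if (resolution < 8) stopf("tessellate: resolution must be >= 8")
  n <- as.integer(resolution)
  if (n %% 2L == 1L) n <- n + 1L
  cl <- build_centerlines(spec, ds = min(ds, 0.25))
  check_daughter_clearance(spec, cl)

  branch_stations <- function(branch) {
    L <- branch_total_length(spec, branch)
    win <- lesion_window(spec, branch)
    s <- c(seq(0, L, by = ds), seq(win[1], win[2], by = ds / 2), win, mean(win), L)
    if (branch != "PMB") {
      d0 <- branch_nominal_diameter(spec, branch)  # loft gap: 1 local diameter
      s <- c(d0, s[s > d0 + 1e-9])
    }
    sort(unique(round(s, 9)))
  }

  verts <- list(); vcount <- 0L
  tris <- list(); labels <- list()
  ring_base <- list()   # per branch: first-ring and last-ring base indices
  frame <- attr(cl, "frame")
  R <- spec$sphere_radius

  for (br in c("PMB", "DMB", "SB")) {
    s <- branch_stations(br)
    bases <- integer(length(s))
    for (i in seq_along(s)) {
      at <- centerline_at(cl[[br]], s[i])
      e1 <- unitv(at$position)                     # radial (sphere center at origin)
      e2 <- unitv(cross3(at$tangent, e1))
      off <- stenosis_profile(spec, br, s[i])$offset
      center <- at$position + off * e1
      pts <- ring_points(center, e1, e2, at$diameter / 2, n)
      verts[[length(verts) + 1L]] <- pts
      bases[i] <- vcount
      vcount <- vcount + n
    }
    for (i in seq_len(length(s) - 1L)) {
      tris[[length(tris) + 1L]] <- stitch_rings(bases[i] + 1L, bases[i + 1L] + 1L, n)
      labels[[length(labels) + 1L]] <- rep(br, 2L * n)
    }
    ring_base[[br]] <- c(first = bases[1] + 1L, last = bases[length(s)] + 1L)
  }

  V <- do.call(rbind, verts)

  # --- carina junction -------------------------------------------------------
  n_sep <- frame$n_sep
  e2_of <- function(br, end) {
    b <- cl[[br]]
    i <- if (end == "first") 1L else nrow(b$position)
    unitv(cross3(b$tangent[i, ], unitv(b$position[i, ])))
  }
  facing_plus <- function(br, end) sum(e2_of(br, end) * n_sep) > 0

  pmb_base <- ring_base$PMB["last"]
  dmb_base <- ring_base$DMB["first"]
  sb_base  <- ring_base$SB["first"]

  p_to_d <- half_seq(pmb_base, n, if (facing_plus("PMB", "last")) "plus" else "minus")
  p_to_s <- half_seq(pmb_base, n, if (facing_plus("PMB", "last")) "minus" else "plus")
  d_out  <- half_seq(dmb_base, n, if (facing_plus("DMB", "first")) "plus" else "minus")
  d_in   <- half_seq(dmb_base, n, if (facing_plus("DMB", "first")) "minus" else "plus")
  s_out  <- half_seq(sb_base,  n, if (facing_plus("SB", "first")) "minus" else "plus")
  s_in   <- half_seq(sb_base,  n, if (facing_plus("SB", "first")) "plus" else "minus")

  jt <- rbind(stitch_chains(p_to_d, d_out),
              stitch_chains(p_to_s, s_out),
              stitch_chains(d_in, s_in),
              c(pmb_base, dmb_base, sb_base),                       # pole theta=0
              c(pmb_base + n / 2, dmb_base + n / 2, sb_base + n / 2))  # pole theta=pi
  tris[[length(tris) + 1L]] <- jt
  labels[[length(labels) + 1L]] <- rep("junction", nrow(jt))

  # --- caps ------------------------------------------------------------------
  cap_specs <- list(inlet = ring_base$PMB["first"],
                    outlet_dmb = ring_base$DMB["last"],
                    outlet_sb = ring_base$SB["last"])
  cap_tri_idx <- list()
  tri_count_before <- sum(vapply(tris, nrow, 1L))
  for (cap in names(cap_specs)) {
    b <- cap_specs[[cap]]
    centroid <- colMeans(V[b + 0:(n - 1), , drop = FALSE])
    V <- rbind(V, centroid)
    cidx <- nrow(V)
    k <- 0:(n - 1); k1 <- (k + 1) %% n
    fan <- cbind(rep(cidx, n), b + k, b + k1)
    tris[[length(tris) + 1L]] <- fan
    labels[[length(labels) + 1L]] <- rep(paste0("cap_", cap), n)
    cap_tri_idx[[cap]] <- tri_count_before + seq_len(n)
    tri_count_before <- tri_count_before + n
  }

  T_ <- do.call(rbind, tris)
  lab <- unlist(labels)
  storage.mode(T_) <- "integer"

  T_ <- orient_mesh(V, T_)

  mesh <- list(vertices = V, triangles = T_, tri_label = lab,
               cap_labels = cap_tri_idx)
  attr(mesh, "spec") <- spec
  attr(mesh, "centerlines") <- cl
  attr(mesh, "resolution") <- n
  class(mesh) <- "lumen_mesh"
  mesh
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# conservative interpenetration check: bounding spheres of daughter rings
check_daughter_clearance <- function(spec, cl) {
  grid_of <- function(br) {
    d0 <- branch_nominal_diameter(spec, br)
    L <- min(branch_total_length(spec, br), 1.5 * spec$lesion_length)
    s <- seq(d0, L, by = 0.5)
    prof <- stenosis_profile(spec, br, s)
    at <- t(vapply(s, function(si) centerline_at(cl[[br]], si)$position, numeric(3)))
    list(pos = at, r = prof$diameter / 2)
  }
  D <- grid_of("DMB"); S <- grid_of("SB")
  d2 <- outer(rowSums(D$pos^2), rowSums(S$pos^2), "+") - 2 * D$pos %*% t(S$pos)
  clearance <- sqrt(pmax(d2, 0)) - outer(D$r, S$r, "+")
  if (min(clearance) < 0) {
    i <- which(clearance == min(clearance), arr.ind = TRUE)[1, ]
    stopf(paste0("tessellate: daughter tubes self-intersect near the carina ",
                 "(clearance %.2f mm at DMB s=%.1f / SB s=%.1f; distal angle too ",
                 "small for these diameters/stenoses)"),
          min(clearance), 0.5 * (i[1] - 1) + branch_nominal_diameter(spec, "DMB"),
          0.5 * (i[2] - 1) + branch_nominal_diameter(spec, "SB"))
  }
  invisible(TRUE)
}

# flip triangles so the whole closed surface is consistently oriented with
# outward normals (positive enclosed volume)
orient_mesh <- function(V, T_) {
  nt <- nrow(T_)
  E <- rbind(T_[, 1:2], T_[, 2:3], T_[, c(3, 1)])
  key <- pmin(E[, 1], E[, 2]) * (nrow(V) + 1) + pmax(E[, 1], E[, 2])
  eid <- match(key, key)          # representative row per undirected edge
  dirn <- ifelse(E[, 1] < E[, 2], 1L, -1L)
  tri_of <- rep(seq_len(nt), 3)
  inc <- split(seq_along(eid), eid)
  if (any(lengths(inc) != 2))
    stopf("orient_mesh: surface is not edge-manifold (open or non-manifold edges)")
  # adjacency: neighbor triangle and both edge directions, per (triangle, slot)
  nbr <- integer(3 * nt); nbr_d <- integer(3 * nt)
  for (rows in inc) {
    r1 <- rows[1]; r2 <- rows[2]
    nbr[r1] <- tri_of[r2]; nbr[r2] <- tri_of[r1]
    nbr_d[r1] <- dirn[r2]; nbr_d[r2] <- dirn[r1]
  }
  sgn <- integer(nt)  # 0 = unvisited, +1 keep, -1 flip
  sgn[1] <- 1L
  queue <- integer(nt); queue[1] <- 1L
  qhead <- 1L; qtail <- 1L
  while (qhead <= qtail) {
    t <- queue[qhead]; qhead <- qhead + 1L
    for (slot in 0:2) {
      row <- t + slot * nt
      u <- nbr[row]
      need <- -dirn[row] * nbr_d[row] * sgn[t]
      if (sgn[u] == 0L) {
        sgn[u] <- need
        qtail <- qtail + 1L
        queue[qtail] <- u
      } else if (sgn[u] != need) {
        stopf("orient_mesh: surface is non-orientable")
      }
    }
  }
  if (any(sgn == 0L))
    stopf("orient_mesh: surface has %d disconnected triangles", sum(sgn == 0L))
  flip <- sgn < 0
  T_[flip, 2:3] <- T_[flip, 3:2]
  if (mesh_volume(V, T_) < 0) T_[, 2:3] <- T_[, 3:2]
  T_
}

# signed enclosed volume (divergence theorem); positive for outward normals
mesh_volume <- function(V, T_) {
  a <- V[T_[, 1], , drop = FALSE]
  b <- V[T_[, 2], , drop = FALSE]
  c_ <- V[T_[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

triangle_areas <- function(V, T_) {
  u <- V[T_[, 2], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  w <- V[T_[, 3], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Watertightness and orientation checks for a lumen mesh
#'
#' A closed surface is watertight when every edge is shared by exactly two
#' triangles; consistent orientation additionally requires each undirected
#' edge to be traversed once in each direction.
#'
#' @param mesh a \code{lumen_mesh}.
#' @return logical scalar; attributes carry diagnostics.
#' @export
is_watertight <- function(mesh) {
  T_ <- mesh$triangles
  E <- rbind(T_[, 1:2], T_[, 2:3], T_[, c(3, 1)])
  nv <- nrow(mesh$vertices)
  key <- pmin(E[, 1], E[, 2]) * (nv + 1) + pmax(E[, 1], E[, 2])
  cnt <- table(key)
  closed <- all(cnt == 2)
  dkey <- E[, 1] * (nv + 1) + E[, 2]
  oriented <- !anyDuplicated(dkey)
  ok <- closed && oriented
  attr(ok, "closed") <- closed
  attr(ok, "oriented") <- oriented
  ok
}

#' @export
print.lumen_mesh <- function(x, ...) {
  cat(sprintf("Lumen surface mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  cat(sprintf("  watertight: %s | enclosed volume %.1f mm^3\n",
              is_watertight(x), mesh_volume(x$vertices, x$triangles)))
  cat(sprintf("  caps: %s\n", paste(names(x$cap_labels), collapse = ", ")))
  invisible(x)
}

# area of the cross-section cut by plane (origin o, unit normal nrm) through
# the triangles in `use` of a consistently oriented mesh
slice_section_area <- function(V, T_, use, o, nrm) {
  T_ <- T_[use, , drop = FALSE]
  d <- (V %*% nrm - sum(o * nrm))[, 1]
  d[abs(d) < 1e-12] <- 1e-12
  d1 <- d[T_[, 1]]; d2 <- d[T_[, 2]]; d3 <- d[T_[, 3]]
  hit <- (pmin(d1, d2, d3) < 0) & (pmax(d1, d2, d3) > 0)
  if (!any(hit)) return(0)
  T_ <- T_[hit, , drop = FALSE]
  area2 <- 0
  segs <- apply(cbind(T_, d[T_[, 1]], d[T_[, 2]], d[T_[, 3]]), 1, function(r) {
    vi <- r[1:3]; dd <- r[4:6]
    pts <- NULL
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      da <- dd[e[1]]; db <- dd[e[2]]
      if (da * db < 0) {
        t <- da / (da - db)
        p <- V[vi[e[1]], ] + t * (V[vi[e[2]], ] - V[vi[e[1]], ])
        pts <- rbind(pts, p)
      }
    }
    pts
  }, simplify = FALSE)
  for (pp in segs) {
    if (is.null(pp) || nrow(pp) != 2) next
    a <- pp[1, ] - o; b <- pp[2, ] - o
    area2 <- area2 + sum(cross3(a, b) * nrm)
  }
  abs(area2) / 2
}

#' Measure percent diameter stenosis from a lumen mesh
#'
#' Self-measurement closure: slices the named branch across its lesion
#' window, converts each cross-section area to an equivalent diameter
#' (2 sqrt(A/pi)) and reports 100 (1 - min diameter / nominal diameter).
#'
#' @param mesh a \code{lumen_mesh} produced by \code{\link{tessellate}}.
#' @param branch one of \code{"PMB"}, \code{"DMB"}, \code{"SB"}.
#' @param n_stations number of slicing stations across the lesion window.
#' @return percent diameter stenosis (0 for an unstenosed branch, up to
#'   discretization error).
#' @export
measure_stenosis <- function(mesh, branch, n_stations = 41) {
  stopifnot(inherits(mesh, "lumen_mesh"))
  spec <- attr(mesh, "spec")
  cl <- attr(mesh, "centerlines")
  d_nom <- branch_nominal_diameter(spec, branch)
  win <- lesion_window(spec, branch)
  lo <- if (branch == "PMB") win[1] else max(win[1], branch_nominal_diameter(spec, branch))
  hi <- if (branch == "PMB") win[2] - 1e-6 else win[2]
  stations <- sort(unique(c(seq(lo, hi, length.out = n_stations), mean(win))))
  use <- which(mesh$tri_label == branch)
  d_min <- Inf
  for (s in stations) {
    at <- centerline_at(cl[[branch]], s)
    A <- slice_section_area(mesh$vertices, mesh$triangles, use, at$position, at$tangent)
    if (A > 0) d_min <- min(d_min, 2 * sqrt(A / pi))
  }
  if (!is.finite(d_min)) return(0)
  100 * (1 - d_min / d_nom)
}

#' Equivalent diameter of a labelled cap
#'
#' @param mesh a \code{lumen_mesh}.
#' @param cap one of \code{"inlet"}, \code{"outlet_dmb"}, \code{"outlet_sb"}.
#' @return equivalent circular diameter 2 sqrt(A/pi) of the cap (mm).
#' @export
cap_equivalent_diameter <- function(mesh, cap = "inlet") {
  idx <- mesh$cap_labels[[cap]]
  if (is.null(idx)) stopf("cap_equivalent_diameter: unknown cap '%s'", cap)
  A <- sum(triangle_areas(mesh$vertices, mesh$triangles[idx, , drop = FALSE]))
  2 * sqrt(A / pi)
}

#' Export a lumen mesh as ASCII STL
#'
#' @param mesh a \code{lumen_mesh}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_stl <- function(mesh, path) {
  V <- mesh$vertices; T_ <- mesh$triangles
  u <- V[T_[, 2], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  w <- V[T_[, 3], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid stenoflow_lumen", con)
  body <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    nx / nn, ny / nn, nz / nn,
    V[T_[, 1], 1], V[T_[, 1], 2], V[T_[, 1], 3],
    V[T_[, 2], 1], V[T_[, 2], 2], V[T_[, 2], 3],
    V[T_[, 3], 1], V[T_[, 3], 2], V[T_[, 3], 3])
  writeLines(body, con)
  writeLines("endsolid stenoflow_lumen", con)
  invisible(path)
}
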