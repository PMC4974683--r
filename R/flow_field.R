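#' Unstructured flow field container
#'
#' Point cloud with tetrahedral connectivity holding a steady velocity and
#' static pressure sample, the container for solver output or for the
#' package's synthetic analytic fields. Units: point coordinates mm,
#' velocity m/s, pressure mmHg.
#'
#' @param points n x 3 matrix of coordinates (mm).
#' @param velocity n x 3 matrix of velocity vectors (m/s).
#' @param pressure length-n vector of static pressure (mmHg).
#' @param cells m x 4 integer matrix of tetrahedron vertex indices (1-based).
#' @param cell_volumes optional length-m vector (mm^3); computed from the
#'   connectivity when missing.
#' @param region optional length-m labels assigning each cell to a named
#'   region (e.g. a branch); used to restrict section probes.
#' @return object of class \code{flow_field}.
#' @export
flow_field <- function(points, velocity, pressure, cells,
                       cell_volumes = NULL, region = NULL) {
  points <- as.matrix(points); velocity <- as.matrix(velocity)
  cells <- matrix(as.integer(as.matrix(cells)), ncol = 4)
  n <- nrow(points)
  if (!all(dim(velocity) == c(n, 3)))
    stopf("flow_field: velocity must be %d x 3", n)
  if (length(pressure) != n) stopf("flow_field: pressure must have %d values", n)
  if (any(cells < 1L) || any(cells > n)) stopf("flow_field: cell index out of range")
  if (!all(is.finite(points)) || !all(is.finite(velocity)) || !all(is.finite(pressure)))
    stopf("flow_field: non-finite values")
  if (is.null(cell_volumes)) cell_volumes <- tet_volumes(points, cells)
  if (length(cell_volumes) != nrow(cells))
    stopf("flow_field: cell_volumes length mismatch")
  if (any(cell_volumes <= 0)) stopf("flow_field: all cell volumes must be positive")
  if (!is.null(region) && length(region) != nrow(cells))
    stopf("flow_field: region labels must be one per cell")
  structure(list(points = points, velocity = velocity, pressure = pressure,
                 cells = cells, cell_volumes = cell_volumes, region = region),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Flow field: %d points, %d tetrahedra, volume %.1f mm^3\n",
              nrow(x$points), nrow(x$cells), sum(x$cell_volumes)))
  cat(sprintf("  |v| in [%.3g, %.3g] m/s; p in [%.2f, %.2f] mmHg\n",
              min(sqrt(rowSums(x$velocity^2))), max(sqrt(rowSums(x$velocity^2))),
              min(x$pressure), max(x$pressure)))
  if (!is.null(x$region))
    cat(sprintf("  regions: %s\n", paste(unique(x$region), collapse = ", ")))
  invisible(x)
}

tet_volumes <- function(points, cells) {
  a <- points[cells[, 1], , drop = FALSE]
  b <- points[cells[, 2], , drop = FALSE] - a
  c_ <- points[cells[, 3], , drop = FALSE] - a
  d <- points[cells[, 4], , drop = FALSE] - a
  abs(b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
      b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
      b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Write a flow field as legacy ASCII VTK
#'
#' Unstructured-grid legacy VTK with named point arrays \code{pressure}
#' (SCALARS, mmHg) and \code{velocity} (VECTORS, m/s); optionally an extra
#' scalar array (e.g. local normalized helicity) for visualization.
#'
#' @param field a \code{\link{flow_field}}.
#' @param path output file.
#' @param extra_scalars optional named list of length-n numeric vectors to
#'   write as additional point arrays.
#' @return \code{path}, invisibly.
#' @export
write_vtk_field <- function(field, path, extra_scalars = NULL) {
  stopifnot(inherits(field, "flow_field"))
  n <- nrow(field$points); m <- nrow(field$cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "stenoflow field (points mm, velocity m/s, pressure mmHg)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(field$points, 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(apply(cbind(4L, field$cells - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(field$pressure, digits = 12, trim = TRUE, scientific = FALSE), con)
  writeLines("VECTORS velocity double", con)
  writeLines(apply(field$velocity, 1, paste, collapse = " "), con)
  for (nm in names(extra_scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(extra_scalars[[nm]], digits = 12, trim = TRUE,
                      scientific = FALSE), con)
  }
  invisible(path)
}

#' Read a flow field from legacy ASCII VTK
#'
#' Expects an unstructured grid of tetrahedra with point arrays
#' \code{pressure} and \code{velocity} as written by
#' \code{\link{write_vtk_field}}. Pressure may be declared as Pa and is
#' converted to mmHg.
#'
#' @param path VTK file.
#' @param pressure_unit \code{"mmHg"} (default) or \code{"Pa"}.
#' @return a \code{\link{flow_field}}.
#' @export
read_vtk_field <- function(path, pressure_unit = c("mmHg", "Pa")) {
  pressure_unit <- match.arg(pressure_unit)
  lines <- readLines(path)
  hit <- function(pat) grep(pat, lines)[1]
  nums <- function(from, count, ncol) {
    vals <- scan(text = lines[from:(from + count - 1)], quiet = TRUE)
    matrix(vals, ncol = ncol, byrow = TRUE)
  }
  ip <- hit("^POINTS ")
  n <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  pts <- nums(ip + 1, n, 3)
  ic <- hit("^CELLS ")
  m <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cl <- nums(ic + 1, m, 5)
  if (any(cl[, 1] != 4)) stopf("read_vtk_field: only tetrahedral cells supported")
  cells <- cl[, 2:5] + 1L
  isc <- grep("^SCALARS pressure", lines)[1]
  p <- as.numeric(scan(text = lines[(isc + 2):(isc + 1 + n)], quiet = TRUE))
  if (pressure_unit == "Pa") p <- p / .MMHG_PA
  iv <- grep("^VECTORS velocity", lines)[1]
  v <- nums(iv + 1, n, 3)
  flow_field(points = pts, velocity = v, pressure = p, cells = cells)
}
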