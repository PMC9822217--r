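# Legacy ASCII VTK unstructured-grid output (cell type 10 = tetrahedron),
# for visual inspection of mapped material fields and solver output.

#' Write a mesh with per-cell and per-point fields as legacy VTK
#'
#' Emits an ASCII legacy VTK unstructured grid (tetrahedra, cell type 10).
#' Cell data are per-element scalar fields; point data may contain scalar
#' fields or an n x 3 matrix, written as `VECTORS`.
#'
#' @param mesh An [fe_mesh].
#' @param path Output `.vtk` path.
#' @param cell_data Named list of numeric vectors (one value per element,
#'   in `mesh$elem_ids` order).
#' @param point_data Named list of numeric vectors or n x 3 matrices (one
#'   row per node, in `mesh$node_ids` order).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  conn0 <- matrix(match(mesh$elements, mesh$node_ids), ncol = 4L) - 1L
  out <- c("# vtk DataFile Version 3.0",
           "bonemapr unstructured grid",
           "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           sprintf("POINTS %d double", n),
           sprintf("%s %s %s", fmt_num(mesh$nodes[, 1]),
                   fmt_num(mesh$nodes[, 2]), fmt_num(mesh$nodes[, 3])),
           sprintf("CELLS %d %d", m, 5L * m),
           sprintf("4 %d %d %d %d", conn0[, 1], conn0[, 2], conn0[, 3],
                   conn0[, 4]),
           sprintf("CELL_TYPES %d", m),
           rep("10", m))
  if (length(cell_data) > 0) {
    out <- c(out, sprintf("CELL_DATA %d", m))
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      bm_assert(length(v) == m, "validation",
                "cell_data field '%s' has %d values for %d elements",
                nm, length(v), m)
      int_field <- is.integer(v) || all(v == round(v))
      out <- c(out,
               sprintf("SCALARS %s %s 1", nm,
                       if (int_field) "int" else "double"),
               "LOOKUP_TABLE default",
               if (int_field) sprintf("%d", as.integer(v)) else fmt_num(v))
    }
  }
  if (length(point_data) > 0) {
    out <- c(out, sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        bm_assert(nrow(v) == n && ncol(v) == 3L, "validation",
                  "point_data field '%s' must be n x 3", nm)
        out <- c(out, sprintf("VECTORS %s double", nm),
                 sprintf("%s %s %s", fmt_num(v[, 1]), fmt_num(v[, 2]),
                         fmt_num(v[, 3])))
      } else {
        bm_assert(length(v) == n, "validation",
                  "point_data field '%s' has %d values for %d nodes",
                  nm, length(v), n)
        out <- c(out, sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default", fmt_num(v))
      }
    }
  }
  write_atomic(path, function(tmp) writeLines(out, tmp))
  invisible(path)
}

#' Write a mapped mesh (HU, densities, modulus, bin id) as legacy VTK
#'
#' Convenience wrapper over [write_vtk()] attaching the per-element fields
#' of a material assignment, and the bin index when bins are supplied.
#'
#' @param mesh An [fe_mesh].
#' @param assignment A [map_materials()] result.
#' @param path Output `.vtk` path.
#' @param bins Optional bin list; adds a `bin` cell field.
#' @return `path`, invisibly.
#' @export
write_vtk_assignment <- function(mesh, assignment, path, bins = NULL) {
  ord <- match(mesh$elem_ids, assignment$eid)
  bm_assert(!anyNA(ord), "validation",
            "assignment does not cover every mesh element")
  cd <- list(HU = assignment$hu_mean[ord],
             rho_ash = assignment$rho[ord],
             young_modulus = assignment$young_modulus[ord])
  if (!is.null(bins)) {
    bin_of <- integer(length(mesh$elem_ids))
    for (b in bins) bin_of[match(b$element_ids, mesh$elem_ids)] <- b$index
    cd$bin <- bin_of
  }
  write_vtk(mesh, path, cell_data = cd)
}
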