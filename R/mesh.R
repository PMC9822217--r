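# Tetrahedral (tet4) FE mesh container and geometric predicates.
# Node and element ids are arbitrary positive integers (1-based in files);
# matrices are stored in id order with explicit id vectors, as in the
# Abaqus format.

#' Tetrahedral finite-element mesh
#'
#' Container for a 4-node tetrahedral mesh: node coordinates in mm, element
#' connectivity by node id, and named element/node sets. On construction,
#' element orientation is fixed up so that every signed volume is positive
#' (nodes 3 and 4 are swapped where needed); elements with volume below
#' `1e-12` mm^3 are rejected as degenerate.
#'
#' @param nodes n x 3 numeric matrix of node coordinates (mm).
#' @param elements m x 4 integer matrix of node ids per element.
#' @param node_ids Length-n integer vector of node ids (default `1:n`).
#' @param elem_ids Length-m integer vector of element ids (default `1:m`).
#' @param elsets Named list of element-id vectors.
#' @param nsets Named list of node-id vectors.
#' @param extra Character vector of verbatim input-deck lines to pass
#'   through on write (unrecognized Abaqus keywords).
#' @return An object of class `fe_mesh`.
#' @examples
#' m <- fe_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'              matrix(1:4, nrow = 1))
#' tet_volume(m, 1)
#' @export
fe_mesh <- function(nodes, elements, node_ids = NULL, elem_ids = NULL,
                    elsets = list(), nsets = list(), extra = character()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  bm_assert(ncol(nodes) == 3L && all(is.finite(nodes)), "validation",
            "nodes must be a finite n x 3 matrix (mm)")
  elements <- as.matrix(elements)
  dimnames(elements) <- NULL
  if (nrow(elements) > 0) storage.mode(elements) <- "integer"
  bm_assert(ncol(elements) == 4L, "validation",
            "elements must be an m x 4 matrix of node ids (tet4)")
  if (is.null(node_ids)) node_ids <- seq_len(nrow(nodes))
  if (is.null(elem_ids)) elem_ids <- seq_len(nrow(elements))
  node_ids <- as.integer(node_ids)
  elem_ids <- as.integer(elem_ids)
  bm_assert(!anyDuplicated(node_ids), "validation", "duplicate node ids")
  bm_assert(!anyDuplicated(elem_ids), "validation", "duplicate element ids")
  conn <- matrix(match(elements, node_ids), ncol = 4L)
  if (anyNA(conn)) {
    bad <- elem_ids[which(rowSums(is.na(conn)) > 0)[1L]]
    bm_stop("validation", "element %d references a missing node id", bad)
  }
  mesh <- structure(
    list(nodes = nodes, elements = elements, node_ids = node_ids,
         elem_ids = elem_ids, elsets = elsets, nsets = nsets, extra = extra),
    class = "fe_mesh")
  if (nrow(elements) > 0) {
    v6 <- tet_signed_volume6(mesh)
    neg <- v6 < 0
    if (any(neg)) {
      mesh$elements[neg, 3:4] <- mesh$elements[neg, 4:3]
      v6 <- abs(v6)
    }
    degen <- abs(v6) / 6 < 1e-12
    if (any(degen)) {
      bm_stop("geometry", "degenerate (zero-volume) element(s): %s",
              paste(mesh$elem_ids[degen], collapse = ", "))
    }
  }
  mesh
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("fe_mesh: %d nodes, %d tet4 elements, %d elset(s)\n",
              nrow(x$nodes), nrow(x$elements), length(x$elsets)))
  invisible(x)
}

elem_rows <- function(mesh, eids) {
  rows <- match(eids, mesh$elem_ids)
  if (anyNA(rows)) {
    bm_stop("validation", "unknown element id(s): %s",
            paste(eids[is.na(rows)], collapse = ", "))
  }
  rows
}

# 6 * signed volume for each element (or subset), vectorized
tet_signed_volume6 <- function(mesh, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(mesh$elements))
  conn <- matrix(match(mesh$elements[rows, , drop = FALSE], mesh$node_ids),
                 ncol = 4L)
  p1 <- mesh$nodes[conn[, 1], , drop = FALSE]
  a <- mesh$nodes[conn[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[conn[, 3], , drop = FALSE] - p1
  c_ <- mesh$nodes[conn[, 4], , drop = FALSE] - p1
  a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
}

#' Element volume and centroid
#'
#' `tet_volume()` returns `|det(edge matrix)| / 6` in mm^3;
#' `element_centroid()` the vertex mean. Both are vectorized over element
#' ids and default to all elements in id order.
#'
#' @param mesh An [fe_mesh].
#' @param eids Element id(s); `NULL` for all.
#' @return `tet_volume`: numeric vector of volumes (mm^3);
#'   `element_centroid`: n x 3 matrix of centroids (mm).
#' @export
tet_volume <- function(mesh, eids = NULL) {
  rows <- if (is.null(eids)) seq_len(nrow(mesh$elements))
  else elem_rows(mesh, eids)
  v <- abs(tet_signed_volume6(mesh, rows)) / 6
  degen <- v < 1e-12
  if (any(degen)) {
    bm_stop("geometry", "degenerate (zero-volume) element(s): %s",
            paste(mesh$elem_ids[rows[degen]], collapse = ", "))
  }
  v
}

#' @rdname tet_volume
#' @export
element_centroid <- function(mesh, eids = NULL) {
  rows <- if (is.null(eids)) seq_len(nrow(mesh$elements))
  else elem_rows(mesh, eids)
  conn <- matrix(match(mesh$elements[rows, , drop = FALSE], mesh$node_ids),
                 ncol = 4L)
  (mesh$nodes[conn[, 1], , drop = FALSE] +
     mesh$nodes[conn[, 2], , drop = FALSE] +
     mesh$nodes[conn[, 3], , drop = FALSE] +
     mesh$nodes[conn[, 4], , drop = FALSE]) / 4
}

#' Barycentric coordinates of points with respect to one element
#'
#' @param mesh An [fe_mesh].
#' @param eid A single element id.
#' @param p Length-3 vector or n x 3 matrix of world points (mm).
#' @return n x 4 matrix of barycentric coordinates (rows sum to 1).
#' @export
tet_barycentric <- function(mesh, eid, p) {
  row <- elem_rows(mesh, eid)
  conn <- match(mesh$elements[row, ], mesh$node_ids)
  v <- mesh$nodes[conn, , drop = FALSE]
  M <- t(v[2:4, , drop = FALSE]) - v[1, ]
  d <- det(M)
  if (abs(d) / 6 < 1e-12) {
    bm_stop("geometry", "degenerate (zero-volume) element(s): %s", eid)
  }
  p <- as_points(p)
  lam234 <- sweep(p, 2L, v[1, ], `-`) %*% t(solve(M))
  cbind(1 - rowSums(lam234), lam234, deparse.level = 0)
}

#' Point-in-tetrahedron test
#'
#' True iff all four barycentric coordinates of `p` with respect to element
#' `eid` are at least `-tol` (boundary-inclusive for `tol >= 0`).
#'
#' @param mesh An [fe_mesh].
#' @param eid A single element id.
#' @param p Length-3 vector or n x 3 matrix of world points (mm).
#' @param tol Non-negative barycentric tolerance.
#' @return Logical vector, one entry per point.
#' @export
point_in_tet <- function(mesh, eid, p, tol = 1e-9) {
  bm_assert(tol >= 0, "validation", "tol must be non-negative")
  lam <- tet_barycentric(mesh, eid, p)
  rowSums(lam < -tol) == 0L
}

#' Total mesh volume
#'
#' @param mesh An [fe_mesh].
#' @return Sum of element volumes (mm^3).
#' @export
mesh_volume <- function(mesh) sum(tet_volume(mesh))
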