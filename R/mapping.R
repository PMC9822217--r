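# Element-wise HU averaging and material assignment.
#
# Three strategies for the representative element HU:
#   node_average       - mean of the interpolated HU at the 4 element nodes;
#   voxel_average      - mean raw HU of voxels whose centers fall inside the
#                        element (degrades when elements shrink below voxel
#                        size; falls back to integration for empty elements);
#   volume_integration - (1/V) * integral of the interpolated HU field over
#                        the element, by congruent 8-way tet subdivision with
#                        centroid sampling (exact for affine fields at every
#                        refinement level).

#' Mapping configuration
#'
#' @param chain A [law_chain] (or builtin chain name).
#' @param strategy Element HU strategy: `"volume_integration"` (default),
#'   `"node_average"` or `"voxel_average"`.
#' @param refinement Subdivision level for `volume_integration`
#'   (`8^refinement` samples per element); default 2.
#' @param transform A [rigid_transform] mapping mesh coordinates into CT
#'   world coordinates (identity default).
#' @param oob Out-of-bounds policy for HU evaluations: `"clamp"` (default,
#'   counted) or `"error"`.
#' @param voxel_fallback What `voxel_average` does for elements containing
#'   no voxel center: `"integration"` (default, logged) or `"error"`.
#' @param average Averaging order: `"hu"` (default; average HU first, then
#'   convert once to density and modulus) or `"modulus"` (convert each HU
#'   sample and average the resulting moduli).
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(chain,
                           strategy = c("volume_integration", "node_average",
                                        "voxel_average"),
                           refinement = 2L,
                           transform = rigid_transform(),
                           oob = c("clamp", "error"),
                           voxel_fallback = c("integration", "error"),
                           average = c("hu", "modulus")) {
  strategy <- match.arg(strategy)
  oob <- match.arg(oob)
  voxel_fallback <- match.arg(voxel_fallback)
  average <- match.arg(average)
  if (is.character(chain)) chain <- builtin_chain(chain)
  bm_assert(inherits(chain, "law_chain"), "validation",
            "chain must be a law_chain or builtin chain name")
  bm_assert(is.numeric(refinement) && refinement >= 1 &&
              refinement == round(refinement), "validation",
            "refinement must be a positive integer")
  bm_assert(inherits(transform, "rigid_transform"), "validation",
            "transform must be a rigid_transform")
  structure(list(chain = chain, strategy = strategy,
                 refinement = as.integer(refinement), transform = transform,
                 oob = oob, voxel_fallback = voxel_fallback,
                 average = average),
            class = "mapping_config")
}

# Barycentric coordinates (rows: sub-tet centroids; cols: parent vertices)
# of the centroids of the 8^level congruent sub-tets of a tetrahedron.
# The 8-way split (4 corner tets + the central octahedron cut into 4 along
# one diagonal) yields equal-volume pieces, and volume ratios are affine
# invariants, so equal weights integrate affine fields exactly.
subtet_centroids <- function(level) {
  tets <- list(diag(4))  # rows = vertices in barycentric coords
  split_one <- function(Tm) {
    v <- lapply(1:4, function(i) Tm[i, ])
    m <- function(i, j) (v[[i]] + v[[j]]) / 2
    list(
      rbind(v[[1]], m(1, 2), m(1, 3), m(1, 4)),
      rbind(m(1, 2), v[[2]], m(2, 3), m(2, 4)),
      rbind(m(1, 3), m(2, 3), v[[3]], m(3, 4)),
      rbind(m(1, 4), m(2, 4), m(3, 4), v[[4]]),
      # octahedron m12 m13 m14 m23 m24 m34, split along diagonal m13-m24
      rbind(m(1, 2), m(1, 3), m(1, 4), m(2, 4)),
      rbind(m(1, 2), m(1, 3), m(2, 3), m(2, 4)),
      rbind(m(1, 3), m(1, 4), m(2, 4), m(3, 4)),
      rbind(m(1, 3), m(2, 3), m(2, 4), m(3, 4)))
  }
  for (l in seq_len(level)) {
    tets <- do.call(c, lapply(tets, split_one))
  }
  t(vapply(tets, colMeans, numeric(4)))
}

# cache: centroid tables per refinement level
.subtet_cache <- new.env(parent = emptyenv())
subtet_centroids_cached <- function(level) {
  key <- as.character(level)
  if (is.null(.subtet_cache[[key]])) {
    .subtet_cache[[key]] <- subtet_centroids(level)
  }
  .subtet_cache[[key]]
}

transformed_nodes <- function(mesh, cfg) {
  apply_transform(cfg$transform, mesh$nodes)
}

# Internal worker: per-element HU samples for a subset of elements, as a
# list(samples = numeric vector, index = element index per sample).
element_vertex_coords <- function(mesh, rows, nodes_world) {
  conn <- matrix(match(mesh$elements[rows, , drop = FALSE], mesh$node_ids),
                 ncol = 4L)
  list(conn = conn,
       p1 = nodes_world[conn[, 1], , drop = FALSE],
       p2 = nodes_world[conn[, 2], , drop = FALSE],
       p3 = nodes_world[conn[, 3], , drop = FALSE],
       p4 = nodes_world[conn[, 4], , drop = FALSE])
}

#' Per-element HU by node averaging
#'
#' Mean of the interpolated HU at the element's four (transformed) nodes.
#'
#' @param mesh An [fe_mesh].
#' @param vol A [ct_volume].
#' @param cfg A [mapping_config].
#' @param eids Element id(s); `NULL` for all.
#' @return Numeric vector of element HU with attribute `clamped_fraction`
#'   (per element) and `n_samples`.
#' @export
element_hu_node_average <- function(mesh, vol, cfg, eids = NULL) {
  rows <- if (is.null(eids)) seq_len(nrow(mesh$elements))
  else elem_rows(mesh, eids)
  nodes_world <- transformed_nodes(mesh, cfg)
  vc <- element_vertex_coords(mesh, rows, nodes_world)
  pts <- rbind(vc$p1, vc$p2, vc$p3, vc$p4)
  hu <- tryCatch(hu_at(vol, pts, oob = cfg$oob), error = function(e) {
    if (inherits(e, "bonemapr_geometry")) {
      bm_stop("geometry", "%s (while sampling element nodes)",
              conditionMessage(e))
    }
    stop(e)
  })
  k <- length(rows)
  samp <- matrix(hu, nrow = k)              # k x 4, one column per vertex
  clamp <- matrix(attr(hu, "clamped"), nrow = k)
  out <- rowMeans(samp)
  attr(out, "samples") <- samp
  attr(out, "clamped_fraction") <- rowMeans(clamp)
  attr(out, "n_samples") <- rep(4L, k)
  out
}

#' Per-element HU by volume integration
#'
#' Approximates `(1/V) * integral of HU dV` by splitting each tetrahedron
#' into `8^refinement` congruent sub-tets and averaging the interpolated HU
#' at their centroids with equal weights. The sample set's centroid equals
#' the element centroid, so the rule is exact for HU fields affine in world
#' coordinates at every refinement level.
#'
#' @inheritParams element_hu_node_average
#' @return Numeric vector of element HU with attributes as in
#'   [element_hu_node_average()].
#' @export
element_hu_integration <- function(mesh, vol, cfg, eids = NULL) {
  rows <- if (is.null(eids)) seq_len(nrow(mesh$elements))
  else elem_rows(mesh, eids)
  nodes_world <- transformed_nodes(mesh, cfg)
  vc <- element_vertex_coords(mesh, rows, nodes_world)
  W <- subtet_centroids_cached(cfg$refinement)   # q x 4 barycentric weights
  q <- nrow(W)
  k <- length(rows)
  # sample points: for each element, W %*% vertices; build as q blocks
  pts <- matrix(0, nrow = k * q, ncol = 3L)
  for (s in seq_len(q)) {
    pts[((s - 1L) * k + 1L):(s * k), ] <-
      W[s, 1] * vc$p1 + W[s, 2] * vc$p2 + W[s, 3] * vc$p3 + W[s, 4] * vc$p4
  }
  hu <- hu_at(vol, pts, oob = cfg$oob)
  samp <- matrix(hu, nrow = k)                  # k x q
  clamp <- matrix(attr(hu, "clamped"), nrow = k)
  out <- rowMeans(samp)
  attr(out, "samples") <- samp
  attr(out, "clamped_fraction") <- rowMeans(clamp)
  attr(out, "n_samples") <- rep(q, k)
  out
}

#' Per-element HU by interior-voxel averaging
#'
#' Mean raw HU over voxels whose centers lie inside the (transformed)
#' element. Elements that contain no voxel center — typical when the
#' element size drops below the voxel size — fall back to
#' [element_hu_integration()] (logged in the `fallback_eids` attribute) or
#' raise an error, per `cfg$voxel_fallback`.
#'
#' @inheritParams element_hu_node_average
#' @return Numeric vector of element HU with attributes `n_samples`,
#'   `clamped_fraction` and `fallback_eids`.
#' @export
element_hu_voxel_average <- function(mesh, vol, cfg, eids = NULL) {
  rows <- if (is.null(eids)) seq_len(nrow(mesh$elements))
  else elem_rows(mesh, eids)
  nodes_world <- transformed_nodes(mesh, cfg)
  conn <- matrix(match(mesh$elements[rows, , drop = FALSE], mesh$node_ids),
                 ncol = 4L)
  k <- length(rows)
  out <- numeric(k)
  n_samples <- integer(k)
  clamped_fraction <- numeric(k)
  empty <- logical(k)
  hi <- vol$dims - 1L
  for (i in seq_len(k)) {
    v <- nodes_world[conn[i, ], , drop = FALSE]
    # candidate voxels: element bounding box in voxel index space
    vidx <- world_to_voxel(vol, v)
    lo_i <- pmax(ceiling(apply(vidx, 2L, min) - 1e-9), 0)
    hi_i <- pmin(floor(apply(vidx, 2L, max) + 1e-9), hi)
    if (any(lo_i > hi_i)) { empty[i] <- TRUE; next }
    grid <- as.matrix(expand.grid(x = lo_i[1]:hi_i[1], y = lo_i[2]:hi_i[2],
                                  z = lo_i[3]:hi_i[3]))
    centers <- voxel_to_world(vol, grid)
    M <- t(v[2:4, , drop = FALSE]) - v[1, ]
    lam234 <- sweep(centers, 2L, v[1, ], `-`) %*% t(solve(M))
    lam <- cbind(1 - rowSums(lam234), lam234)
    inside <- rowSums(lam < -1e-9) == 0L
    if (!any(inside)) { empty[i] <- TRUE; next }
    sel <- grid[inside, , drop = FALSE]
    vals <- vol$hu[sel[, 1] + vol$dims[1] * (sel[, 2] + vol$dims[2] * sel[, 3]) + 1]
    out[i] <- mean(vals)
    n_samples[i] <- length(vals)
  }
  fallback_eids <- mesh$elem_ids[rows[empty]]
  if (any(empty)) {
    if (cfg$voxel_fallback == "error") {
      bm_stop("geometry",
              "element(s) contain no voxel center: %s",
              paste(utils::head(fallback_eids, 10), collapse = ", "))
    }
    fb <- element_hu_integration(mesh, vol, cfg,
                                 eids = mesh$elem_ids[rows[empty]])
    out[empty] <- as.numeric(fb)
    n_samples[empty] <- attr(fb, "n_samples")
    clamped_fraction[empty] <- attr(fb, "clamped_fraction")
  }
  attr(out, "n_samples") <- n_samples
  attr(out, "clamped_fraction") <- clamped_fraction
  attr(out, "fallback_eids") <- fallback_eids
  out
}

#' Map CT materials onto a mesh
#'
#' Runs the configured HU-averaging strategy over every element, converts
#' the element HU to density and Young's modulus through the chain, and
#' returns the per-element assignment. The run is fully deterministic.
#'
#' A warning is raised when fewer than 99% of element centroids fall inside
#' the volume's voxel-center hull, since a largely non-overlapping
#' mesh/volume pair usually indicates a missing or wrong rigid transform.
#'
#' @param mesh An [fe_mesh].
#' @param vol A [ct_volume].
#' @param cfg A [mapping_config].
#' @return A data frame of class `material_assignment` with columns `eid`,
#'   `hu_mean`, `rho`, `young_modulus`, `n_samples`, `clamped_fraction`,
#'   and a `counts` attribute (flooring/clamping/fallback tallies plus the
#'   ids of fully-clamped elements).
#' @export
map_materials <- function(mesh, vol, cfg) {
  bm_assert(inherits(cfg, "mapping_config"), "validation",
            "cfg must be a mapping_config")
  bm_assert(nrow(mesh$elements) > 0, "validation", "mesh has no elements")
  cent <- element_centroid(mesh)
  cent_w <- apply_transform(cfg$transform, cent)
  cin <- hu_at(vol, cent_w, oob = "clamp")
  frac_inside <- 1 - attr(cin, "n_clamped") / nrow(cent)
  if (frac_inside < 0.99) {
    warning(sprintf(
      "only %.1f%% of element centroids lie inside the CT volume; check the rigid transform",
      100 * frac_inside))
  }
  hu <- switch(cfg$strategy,
               node_average = element_hu_node_average(mesh, vol, cfg),
               voxel_average = element_hu_voxel_average(mesh, vol, cfg),
               volume_integration = element_hu_integration(mesh, vol, cfg))
  if (cfg$average == "modulus") {
    samp <- attr(hu, "samples")
    if (is.null(samp)) {
      bm_stop("config",
              "average = 'modulus' is not available with the '%s' strategy",
              cfg$strategy)
    }
    rho_s <- hu_to_density(cfg$chain, as.numeric(samp))
    E_s <- density_to_modulus(cfg$chain, as.numeric(rho_s))
    rho <- rowMeans(matrix(as.numeric(rho_s), nrow = nrow(samp)))
    E <- rowMeans(matrix(as.numeric(E_s), nrow = nrow(samp)))
    n_floored_rho <- attr(rho_s, "n_floored")
    n_floored_e <- attr(E_s, "n_floored")
  } else {
    rho_a <- hu_to_density(cfg$chain, as.numeric(hu))
    E_a <- density_to_modulus(cfg$chain, as.numeric(rho_a))
    rho <- as.numeric(rho_a)
    E <- as.numeric(E_a)
    n_floored_rho <- attr(rho_a, "n_floored")
    n_floored_e <- attr(E_a, "n_floored")
  }
  clamped_fraction <- attr(hu, "clamped_fraction") %||% numeric(length(hu))
  fully_clamped <- mesh$elem_ids[clamped_fraction >= 1]
  assignment <- data.frame(eid = mesh$elem_ids,
                           hu_mean = as.numeric(hu),
                           rho = rho,
                           young_modulus = E,
                           n_samples = attr(hu, "n_samples"),
                           clamped_fraction = clamped_fraction)
  class(assignment) <- c("material_assignment", "data.frame")
  attr(assignment, "strategy") <- cfg$strategy
  attr(assignment, "chain_name") <- cfg$chain$name
  attr(assignment, "counts") <- list(
    n_floored_rho = n_floored_rho,
    n_floored_e = n_floored_e,
    n_clamped_samples = sum(clamped_fraction *
                              attr(hu, "n_samples")),
    fallback_eids = attr(hu, "fallback_eids") %||% integer(),
    fully_clamped_eids = fully_clamped,
    centroid_fraction_inside = frac_inside)
  assignment
}
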