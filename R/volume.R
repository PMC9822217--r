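# CT volume container, voxel/world geometry and trilinear HU interpolation.
#
# Conventions (fixed across the package):
#   * voxel indices are 0-based and refer to voxel centers;
#   * world = origin + orientation %*% (spacing * index), everything in mm;
#   * HU values are stored as doubles after any rescale has been applied.

#' CT volume of Hounsfield units
#'
#' Container for a regular voxel grid of Hounsfield units (HU) together with
#' its voxel-to-world geometry. The value of voxel `(i, j, k)` (0-based) sits
#' at world position `origin + orientation %*% (spacing * c(i, j, k))`, with
#' all lengths in mm.
#'
#' @param hu 3-d numeric array of HU values (finite).
#' @param spacing Positive length-3 numeric, voxel spacing in mm.
#' @param origin Length-3 numeric, world position of voxel `(0, 0, 0)` in mm.
#' @param orientation 3x3 direction-cosine matrix (orthonormal within 1e-8);
#'   column `j` is the world direction of increasing voxel index `j`.
#' @return An object of class `ct_volume` with fields `hu`, `dims`, `spacing`,
#'   `origin`, `orientation`.
#' @examples
#' vol <- ct_volume(array(100, dim = c(2, 2, 2)), spacing = c(1, 1, 1))
#' hu_at(vol, c(0.5, 0.5, 0.5))
#' @export
ct_volume <- function(hu, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = diag(3)) {
  bm_assert(is.array(hu) && length(dim(hu)) == 3L, "validation",
            "hu must be a 3-d array")
  dims <- dim(hu)
  bm_assert(all(dims >= 2L), "validation",
            "each volume dimension must be at least 2 voxels, got %s",
            paste(dims, collapse = "x"))
  storage.mode(hu) <- "double"
  bm_assert(all(is.finite(hu)), "validation", "HU values must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  bm_assert(length(spacing) == 3L && all(spacing > 0), "validation",
            "spacing must be 3 positive numbers (mm)")
  bm_assert(length(origin) == 3L && all(is.finite(origin)), "validation",
            "origin must be a finite length-3 vector (mm)")
  orientation <- as.matrix(orientation)
  bm_assert(is_orthonormal(orientation), "validation",
            "orientation must be orthonormal within 1e-8")
  structure(
    list(hu = hu, dims = as.integer(dims), spacing = spacing,
         origin = origin, orientation = orientation),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("ct_volume: %s voxels, spacing %s mm, HU range [%g, %g]\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              min(x$hu), max(x$hu)))
  invisible(x)
}

#' Voxel/world coordinate maps
#'
#' `voxel_to_world()` maps continuous 0-based voxel indices to world mm
#' coordinates; `world_to_voxel()` is its exact inverse.
#'
#' @param vol A [ct_volume].
#' @param idx,p Length-3 vector or n x 3 matrix of coordinates.
#' @return n x 3 matrix of mapped coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- as_points(idx)
  sweep(tcrossprod(sweep(idx, 2L, vol$spacing, `*`), vol$orientation),
        2L, vol$origin, `+`)
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, p) {
  p <- as_points(p)
  sweep(sweep(p, 2L, vol$origin, `-`) %*% vol$orientation, 2L,
        vol$spacing, `/`)
}

#' The voxel-to-world affine of a volume
#'
#' @param vol A [ct_volume].
#' @return 4x4 matrix mapping homogeneous 0-based voxel indices to world mm.
#' @export
volume_affine <- function(vol) {
  A <- diag(4)
  A[1:3, 1:3] <- vol$orientation %*% diag(vol$spacing)
  A[1:3, 4] <- vol$origin
  A
}

#' Trilinear HU interpolation at world coordinates
#'
#' Evaluates the HU field at arbitrary world points by trilinear interpolation
#' among the 8 surrounding voxel centers. Points outside the voxel-center hull
#' are either clamped onto the hull boundary (`oob = "clamp"`, the default;
#' the number of clamped evaluations is returned in the `n_clamped`
#' attribute) or raise an out-of-bounds error (`oob = "error"`).
#'
#' @param vol A [ct_volume].
#' @param p World point(s), length-3 vector or n x 3 matrix (mm).
#' @param oob Out-of-bounds policy, `"clamp"` or `"error"`.
#' @return Numeric vector of interpolated HU, with attributes `n_clamped`
#'   (count of clamped evaluations) and `clamped` (logical per point).
#' @export
hu_at <- function(vol, p, oob = c("clamp", "error")) {
  oob <- match.arg(oob)
  v <- world_to_voxel(vol, p)
  hi <- vol$dims - 1L
  # tolerance absorbs round-off from the world<->voxel maps only
  eps <- 1e-9
  out_lo <- sweep(v, 2L, -eps, `<`)
  out_hi <- sweep(v, 2L, hi + eps, `>`)
  clamped <- rowSums(out_lo | out_hi) > 0L
  if (oob == "error" && any(clamped)) {
    bad <- which(clamped)[1L]
    pw <- as_points(p)[bad, ]
    bm_stop("geometry",
            "point (%g, %g, %g) mm is outside the voxel-center hull",
            pw[1], pw[2], pw[3])
  }
  for (a in 1:3) v[, a] <- pmin(pmax(v[, a], 0), hi[a])
  i0 <- pmin(floor(v), matrix(hi - 1L, nrow(v), 3L, byrow = TRUE))
  f <- v - i0
  d <- vol$dims
  # linear index of corner (i0 + c(dx,dy,dz)), 0-based voxel indices
  base <- i0[, 1] + d[1] * (i0[, 2] + d[2] * i0[, 3]) + 1
  corner <- function(dx, dy, dz) {
    vol$hu[base + dx + d[1] * dy + d[1] * d[2] * dz]
  }
  w1 <- 1 - f
  val <-
    corner(0, 0, 0) * w1[, 1] * w1[, 2] * w1[, 3] +
    corner(1, 0, 0) * f[, 1]  * w1[, 2] * w1[, 3] +
    corner(0, 1, 0) * w1[, 1] * f[, 2]  * w1[, 3] +
    corner(1, 1, 0) * f[, 1]  * f[, 2]  * w1[, 3] +
    corner(0, 0, 1) * w1[, 1] * w1[, 2] * f[, 3] +
    corner(1, 0, 1) * f[, 1]  * w1[, 2] * f[, 3] +
    corner(0, 1, 1) * w1[, 1] * f[, 2]  * f[, 3] +
    corner(1, 1, 1) * f[, 1]  * f[, 2]  * f[, 3]
  attr(val, "clamped") <- clamped
  attr(val, "n_clamped") <- sum(clamped)
  val
}

#' Rigid transform mapping mesh coordinates into CT world coordinates
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  bm_assert(is_orthonormal(rotation), "validation",
            "rotation must be orthonormal within 1e-8")
  bm_assert(det(rotation) > 0, "validation",
            "rotation must be proper (determinant +1)")
  bm_assert(length(translation) == 3L && all(is.finite(translation)),
            "validation", "translation must be a finite length-3 vector (mm)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf A [rigid_transform].
#' @param p Length-3 vector or n x 3 matrix of points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(tf, p) {
  p <- as_points(p)
  sweep(tcrossprod(p, tf$rotation), 2L, tf$translation, `+`)
}
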