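# Deterministic synthetic CT volumes and structured tet meshes. Every
# phantom kind has a closed-form field value at any world point
# (phantom_field), which makes exact oracles available for the
# interpolation and mapping stages.

#' Synthetic phantom specification
#'
#' Kinds and their parameters:
#' \describe{
#'   \item{`constant`}{`value`: the uniform HU.}
#'   \item{`affine`}{`coeffs = c(a, b, c, d)`:
#'     `HU(x, y, z) = a x + b y + c z + d` in world mm.}
#'   \item{`shell`}{A bone-like body: a thin high-HU cortical shell around
#'     a low-HU trabecular interior. `center`, `r_inner`, `r_outer` (mm,
#'     `0 < r_inner < r_outer`), `hu_shell` (default 1500), `hu_interior`
#'     (default 300), `hu_background` (default 0), `norm` (`"l2"` default:
#'     spherical shell; `"linf"`: cubic shell with axis-aligned interfaces
#'     that a structured box mesh can conform to exactly, which is what
#'     strict element-wise contrast checks need).}
#'   \item{`two_phase`}{Checkerboard of two HU values with cubic cells:
#'     `period` (mm), `hu_low`, `hu_high`.}
#' }
#' Optional Gaussian HU noise (`noise_sd > 0`) requires an explicit `seed`;
#' volumes are bitwise reproducible for a fixed spec.
#'
#' @param kind Phantom kind (see above).
#' @param dims Voxels per axis (each at least 2).
#' @param spacing Voxel spacing in mm.
#' @param origin World position of voxel (0,0,0), mm.
#' @param ... Kind-specific parameters.
#' @param noise_sd Gaussian HU noise standard deviation (default 0, off).
#' @param seed Integer RNG seed; mandatory when `noise_sd > 0`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("constant", "affine", "shell", "two_phase"),
                         dims, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         ..., noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  params <- list(...)
  defaults <- switch(kind,
    constant = list(value = 0),
    affine = list(coeffs = c(0, 0, 0, 0)),
    shell = list(center = NULL, r_inner = NULL, r_outer = NULL,
                 hu_shell = 1500, hu_interior = 300, hu_background = 0,
                 norm = "l2"),
    two_phase = list(period = 1, hu_low = 0, hu_high = 1000))
  unknown <- setdiff(names(params), names(defaults))
  bm_assert(length(unknown) == 0, "config",
            "unknown parameter(s) for %s phantom: %s", kind,
            paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, params)
  if (kind == "shell") {
    bm_assert(!is.null(params$center) && !is.null(params$r_inner) &&
                !is.null(params$r_outer), "config",
              "shell phantom needs center, r_inner and r_outer")
    bm_assert(params$r_inner > 0 && params$r_inner < params$r_outer,
              "config", "shell radii must satisfy 0 < r_inner < r_outer")
  }
  if (kind == "affine") {
    bm_assert(length(params$coeffs) == 4L, "config",
              "affine phantom needs 4 coefficients (a, b, c, d)")
  }
  bm_assert(noise_sd >= 0, "config", "noise_sd must be non-negative")
  bm_assert(noise_sd == 0 || !is.null(seed), "config",
            "noisy phantoms require an explicit seed")
  structure(list(kind = kind, dims = as.integer(dims),
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 params = params, noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

#' Closed-form phantom field value at world points
#'
#' The analytic ground truth the voxelized phantom samples; noise-free.
#'
#' @param spec A [phantom_spec].
#' @param p Length-3 vector or n x 3 matrix of world points (mm).
#' @return Numeric vector of HU.
#' @export
phantom_field <- function(spec, p) {
  p <- as_points(p)
  pr <- spec$params
  switch(spec$kind,
    constant = rep(pr$value, nrow(p)),
    affine = p %*% pr$coeffs[1:3] + pr$coeffs[4],
    shell = {
      d <- sweep(p, 2L, pr$center, `-`)
      r <- if (pr$norm == "linf") apply(abs(d), 1L, max)
      else sqrt(rowSums(d^2))
      ifelse(r <= pr$r_inner, pr$hu_interior,
             ifelse(r <= pr$r_outer, pr$hu_shell, pr$hu_background))
    },
    two_phase = {
      parity <- (floor(p[, 1] / pr$period) + floor(p[, 2] / pr$period) +
                   floor(p[, 3] / pr$period)) %% 2
      ifelse(parity == 0, pr$hu_low, pr$hu_high)
    })
}

#' Voxelize a phantom into a CT volume
#'
#' Samples the analytic field at voxel centers; optional Gaussian noise is
#' drawn behind the spec's seed with the RNG state restored afterwards, so
#' repeated calls are bitwise identical and do not disturb the caller's
#' random stream.
#'
#' @param spec A [phantom_spec].
#' @return A [ct_volume].
#' @export
make_volume <- function(spec) {
  bm_assert(inherits(spec, "phantom_spec"), "validation",
            "spec must be a phantom_spec")
  d <- spec$dims
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1L), y = 0:(d[2] - 1L),
                               z = 0:(d[3] - 1L)))
  centers <- sweep(sweep(idx, 2L, spec$spacing, `*`), 2L, spec$origin, `+`)
  hu <- phantom_field(spec, centers)
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    hu <- hu + stats::rnorm(length(hu), sd = spec$noise_sd)
  }
  ct_volume(array(as.numeric(hu), dim = d), spacing = spec$spacing,
            origin = spec$origin)
}

#' Structured tet4 box mesh
#'
#' Subdivides an axis-aligned box into a regular grid of cubes and each
#' cube into 6 congruent tetrahedra sharing the main diagonal (Kuhn
#' subdivision), which is face-to-face conforming across the grid and
#' tiles the box exactly: the total mesh volume equals the box volume.
#'
#' @param extent Box edge lengths in mm (length-3).
#' @param divisions Cells per axis (length-3 positive integers).
#' @param origin Minimum corner of the box (mm).
#' @return An [fe_mesh]; the grid cell size is `extent / divisions`.
#' @examples
#' m <- make_box_mesh(c(1, 1, 1), c(1, 1, 1))
#' nrow(m$elements)  # 6
#' @export
make_box_mesh <- function(extent, divisions, origin = c(0, 0, 0)) {
  extent <- as.numeric(extent)
  divisions <- as.integer(divisions)
  bm_assert(length(extent) == 3L && all(extent > 0), "validation",
            "extent must be 3 positive lengths (mm)")
  bm_assert(length(divisions) == 3L && all(divisions >= 1L), "validation",
            "divisions must be 3 positive integers")
  nd <- divisions + 1L
  h <- extent / divisions
  grid <- expand.grid(x = 0:(nd[1] - 1L), y = 0:(nd[2] - 1L),
                      z = 0:(nd[3] - 1L))
  nodes <- sweep(sweep(as.matrix(grid), 2L, h, `*`), 2L, origin, `+`)
  nid <- function(ix, iy, iz) 1L + ix + nd[1] * (iy + nd[2] * iz)
  # Kuhn: 6 tets per cube, one per permutation of the axis walk 000 -> 111
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- as.matrix(expand.grid(ix = 0:(divisions[1] - 1L),
                                 iy = 0:(divisions[2] - 1L),
                                 iz = 0:(divisions[3] - 1L)))
  nc <- nrow(cells)
  elems <- matrix(0L, nrow = 6L * nc, ncol = 4L)
  steps <- diag(3L)
  for (p in seq_along(perms)) {
    pm <- perms[[p]]
    c0 <- cells
    c1 <- c0 + matrix(steps[pm[1], ], nc, 3L, byrow = TRUE)
    c2 <- c1 + matrix(steps[pm[2], ], nc, 3L, byrow = TRUE)
    c3 <- c2 + matrix(steps[pm[3], ], nc, 3L, byrow = TRUE)
    rows <- seq.int(p, by = 6L, length.out = nc)
    elems[rows, 1] <- nid(c0[, 1], c0[, 2], c0[, 3])
    elems[rows, 2] <- nid(c1[, 1], c1[, 2], c1[, 3])
    elems[rows, 3] <- nid(c2[, 1], c2[, 2], c2[, 3])
    elems[rows, 4] <- nid(c3[, 1], c3[, 2], c3[, 3])
  }
  fe_mesh(nodes, elems)
}

#' Load a phantom spec from YAML
#'
#' @param path YAML file with fields matching [phantom_spec()] (`kind`,
#'   `dims`, `spacing`, `origin`, kind parameters, `noise_sd`, `seed`).
#' @return A [phantom_spec].
#' @export
load_phantom_spec <- function(path) {
  bm_assert(file.exists(path), "io", "phantom spec not found: %s", path)
  y <- yaml::read_yaml(path)
  bm_assert(!is.null(y$kind) && !is.null(y$dims), "config",
            "phantom spec must define 'kind' and 'dims'")
  args <- list(kind = y$kind, dims = unlist(y$dims),
               spacing = unlist(y$spacing %||% c(1, 1, 1)),
               origin = unlist(y$origin %||% c(0, 0, 0)),
               noise_sd = y$noise_sd %||% 0, seed = y$seed)
  extra <- y[setdiff(names(y), c("kind", "dims", "spacing", "origin",
                                 "noise_sd", "seed", "mesh"))]
  extra <- lapply(extra, function(v) if (is.list(v)) unlist(v) else v)
  spec <- do.call(phantom_spec, c(args, extra))
  attr(spec, "mesh") <- y$mesh
  spec
}
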