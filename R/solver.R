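# Minimal linear-elastic tet4 (constant-strain) solver. Verification-scale
# only: assembles a sparse global stiffness and does one direct solve.
# Voigt order throughout: (xx, yy, zz, xy, yz, xz) with engineering shear.

#' Boundary conditions and material constants for a verification solve
#'
#' @param poisson_ratio Global Poisson ratio in `[0, 0.5)`. The bone
#'   literature rarely prints one; the conventional 0.3 is the default and
#'   the chosen value is echoed in every solve's output.
#' @param dirichlet `data.frame(node, ux, uy, uz)` of prescribed nodal
#'   displacements in mm; `NA` leaves a component free.
#' @param neumann `data.frame(n1, n2, n3, tx, ty, tz)`: triangular faces
#'   (by node id) carrying a uniform traction vector in MPa.
#' @return An object of class `verify_config`.
#' @export
verify_config <- function(poisson_ratio = 0.3, dirichlet = NULL,
                          neumann = NULL) {
  bm_assert(is.numeric(poisson_ratio) && poisson_ratio >= 0 &&
              poisson_ratio < 0.5, "validation",
            "poisson_ratio must lie in [0, 0.5)")
  structure(list(poisson_ratio = poisson_ratio, dirichlet = dirichlet,
                 neumann = neumann),
            class = "verify_config")
}

# Isotropic elasticity matrix (Voigt, engineering shear), E in MPa.
elastic_matrix <- function(E, nu) {
  f <- E / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- f * nu
  diag(D)[1:3] <- f * (1 - nu)
  diag(D)[4:6] <- f * (1 - 2 * nu) / 2
  D
}

# Strain-displacement matrix (6 x 12) and volume for one tet.
tet_b_matrix <- function(v) {
  M <- t(v[2:4, , drop = FALSE]) - v[1, ]
  detM <- det(M)
  vol <- abs(detM) / 6
  grads234 <- solve(M)                 # rows: grad lambda_2..4
  grads <- rbind(-colSums(grads234), grads234)  # 4 x 3
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    g <- grads[a, ]
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[1]
    B[2, c0 + 2] <- g[2]
    B[3, c0 + 3] <- g[3]
    B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
    B[5, c0 + 2] <- g[3]; B[5, c0 + 3] <- g[2]
    B[6, c0 + 1] <- g[3]; B[6, c0 + 3] <- g[1]
  }
  list(B = B, vol = vol)
}

#' Static linear-elastic solve on a mapped mesh
#'
#' Small-strain isotropic elasticity with constant-strain tetrahedra.
#' Element Young's moduli come from the material assignment; the Poisson
#' ratio is the global value in `cfg`. Dirichlet constraints must remove
#' all six rigid-body modes.
#'
#' @param mesh An [fe_mesh].
#' @param assignment A [map_materials()] result (or any data frame with
#'   `eid` and `young_modulus` columns covering every element).
#' @param cfg A [verify_config].
#' @return An object of class `fe_solution`: `displacement` (n x 3 mm, in
#'   `mesh$node_ids` order), `stress` (m x 6 Voigt, MPa), `von_mises`
#'   (per element, MPa), and `poisson_ratio`.
#' @export
solve_static <- function(mesh, assignment, cfg) {
  bm_assert(inherits(cfg, "verify_config"), "validation",
            "cfg must be a verify_config")
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  Ee <- assignment$young_modulus[match(mesh$elem_ids, assignment$eid)]
  bm_assert(!anyNA(Ee), "validation",
            "assignment does not provide a modulus for every element")
  bm_assert(all(Ee > 0), "validation", "element moduli must be positive")
  nu <- cfg$poisson_ratio
  conn <- matrix(match(mesh$elements, mesh$node_ids), ncol = 4L)
  D1 <- elastic_matrix(1, nu)          # scaled by E per element
  nnz_per <- 144L
  ii <- integer(m * nnz_per); jj <- integer(m * nnz_per)
  xx <- numeric(m * nnz_per)
  Bs <- vector("list", m)
  vols <- numeric(m)
  for (e in seq_len(m)) {
    v <- mesh$nodes[conn[e, ], , drop = FALSE]
    bp <- tet_b_matrix(v)
    Bs[[e]] <- bp$B
    vols[e] <- bp$vol
    Ke <- (Ee[e] * bp$vol) * (t(bp$B) %*% D1 %*% bp$B)
    dof <- as.integer(t(outer(conn[e, ], 1:3,
                              function(a, c) 3L * (a - 1L) + c)))
    idx <- ((e - 1L) * nnz_per + 1L):(e * nnz_per)
    ii[idx] <- rep(dof, each = 12L)
    jj[idx] <- rep(dof, times = 12L)
    xx[idx] <- as.numeric(Ke)
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * n, 3L * n))
  f <- numeric(3L * n)
  if (!is.null(cfg$neumann)) {
    nm <- cfg$neumann
    for (r in seq_len(nrow(nm))) {
      fn <- match(c(nm$n1[r], nm$n2[r], nm$n3[r]), mesh$node_ids)
      bm_assert(!anyNA(fn), "validation",
                "neumann face references a missing node id")
      p <- mesh$nodes[fn, , drop = FALSE]
      a <- p[2, ] - p[1, ]; b <- p[3, ] - p[1, ]
      area <- sqrt(sum(c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])^2)) / 2
      tr <- c(nm$tx[r], nm$ty[r], nm$tz[r])
      for (a_ in fn) {
        dof <- 3L * (a_ - 1L) + 1:3
        f[dof] <- f[dof] + tr * area / 3
      }
    }
  }
  u <- numeric(3L * n)
  fixed <- logical(3L * n)
  if (!is.null(cfg$dirichlet)) {
    dd <- cfg$dirichlet
    rows <- match(dd$node, mesh$node_ids)
    bm_assert(!anyNA(rows), "validation",
              "dirichlet constraint references a missing node id")
    for (c_ in 1:3) {
      comp <- dd[[c("ux", "uy", "uz")[c_]]]
      sel <- !is.na(comp)
      dof <- 3L * (rows[sel] - 1L) + c_
      u[dof] <- comp[sel]
      fixed[dof] <- TRUE
    }
  }
  n_fixed <- sum(fixed)
  if (n_fixed < 6L) {
    bm_stop("solver",
            "insufficient constraints: %d rigid-body mode(s) remain unconstrained",
            6L - n_fixed)
  }
  free <- which(!fixed)
  rhs <- f[free] - as.numeric(K[free, fixed, drop = FALSE] %*% u[fixed])
  Kff <- K[free, free, drop = FALSE]
  uf <- tryCatch(
    as.numeric(Matrix::solve(Kff, rhs)),
    error = function(e) bm_stop("solver",
                                "singular stiffness system (%s); constraints may leave rigid-body modes free",
                                conditionMessage(e)))
  u[free] <- uf
  U <- matrix(u, ncol = 3L, byrow = TRUE)
  stress <- matrix(0, m, 6L,
                   dimnames = list(NULL, c("sxx", "syy", "szz",
                                           "sxy", "syz", "sxz")))
  for (e in seq_len(m)) {
    ue <- as.numeric(t(U[conn[e, ], , drop = FALSE]))
    stress[e, ] <- Ee[e] * (D1 %*% (Bs[[e]] %*% ue))
  }
  structure(list(displacement = U, stress = stress,
                 von_mises = von_mises(stress),
                 poisson_ratio = nu),
            class = "fe_solution")
}

#' Von Mises equivalent stress
#'
#' Second deviatoric invariant form
#' `sqrt(((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2)/2 + 3 (t12^2 + t23^2 + t31^2))`.
#'
#' @param stress A symmetric 3x3 stress tensor, a length-6 Voigt vector
#'   `(xx, yy, zz, xy, yz, xz)`, or an m x 6 matrix of Voigt rows (MPa).
#' @return Non-negative von Mises stress (MPa), one value per tensor.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3L, 3L))) {
    bm_assert(max(abs(stress - t(stress))) < 1e-8 * (1 + max(abs(stress))),
              "validation", "stress tensor must be symmetric")
    stress <- matrix(c(stress[1, 1], stress[2, 2], stress[3, 3],
                       stress[1, 2], stress[2, 3], stress[1, 3]), nrow = 1L)
  } else if (!is.matrix(stress)) {
    bm_assert(length(stress) == 6L, "validation",
              "expected a length-6 Voigt stress vector")
    stress <- matrix(stress, nrow = 1L)
  }
  s <- stress
  sqrt(pmax(0,
            0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                     (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}

#' Write a verification solution as legacy VTK
#'
#' @param mesh An [fe_mesh].
#' @param solution An [solve_static()] result.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_solution <- function(mesh, solution, path) {
  write_vtk(mesh, path,
            cell_data = list(von_mises = solution$von_mises),
            point_data = list(displacement = solution$displacement))
}
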