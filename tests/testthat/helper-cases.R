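# Shared verification cases used by both the module tests and the
# end-to-end suite.

boundary_nodes <- function(mesh, extent, origin = c(0, 0, 0), tol = 1e-9) {
  on_face <- rep(FALSE, nrow(mesh$nodes))
  for (axis in 1:3) {
    on_face <- on_face |
      abs(mesh$nodes[, axis] - origin[axis]) < tol |
      abs(mesh$nodes[, axis] - origin[axis] - extent[axis]) < tol
  }
  mesh$node_ids[on_face]
}

# Two-layer bar along x under uniform end traction, symmetry BCs, nu = 0
# (which makes the 1D series-spring solution exact in 3D). Exact solution:
# uniform sigma_xx = t; end displacement t * (L1/E1 + L2/E2).
laminate_case <- function(E1, E2, t_axial = 2, nx = 4) {
  L <- 2
  mesh <- make_box_mesh(c(L, 1, 1), c(nx, 2, 2))
  cent <- element_centroid(mesh)
  E <- ifelse(cent[, 1] < L / 2, E1, E2)
  assignment <- data.frame(eid = mesh$elem_ids, young_modulus = E)
  nd <- mesh$nodes
  d0 <- data.frame(node = mesh$node_ids[abs(nd[, 1]) < 1e-9],
                   ux = 0, uy = NA, uz = NA)
  dy <- data.frame(node = mesh$node_ids[abs(nd[, 2]) < 1e-9],
                   ux = NA, uy = 0, uz = NA)
  dz <- data.frame(node = mesh$node_ids[abs(nd[, 3]) < 1e-9],
                   ux = NA, uy = NA, uz = 0)
  end_ids <- mesh$node_ids[abs(nd[, 1] - L) < 1e-9]
  faces <- t(utils::combn(end_ids, 3))
  keep <- apply(faces, 1, function(f) {
    any(apply(mesh$elements, 1, function(el) all(f %in% el)))
  })
  faces <- faces[keep, , drop = FALSE]
  nm <- data.frame(n1 = faces[, 1], n2 = faces[, 2], n3 = faces[, 3],
                   tx = t_axial, ty = 0, tz = 0)
  cfg <- verify_config(poisson_ratio = 0,
                       dirichlet = rbind(d0, dy, dz), neumann = nm)
  list(mesh = mesh, assignment = assignment, cfg = cfg, L = L,
       sol = solve_static(mesh, assignment, cfg))
}

# Constant-phantom pipeline fixture for cmd_map determinism and output
# checks.
write_pipeline_fixture <- function(dir) {
  spec_path <- file.path(dir, "phantom.yaml")
  yaml::write_yaml(list(
    kind = "constant", value = 800,
    dims = c(10, 10, 10), spacing = c(1, 1, 1), origin = c(-2, -2, -2),
    mesh = list(extent = c(6, 6, 6), divisions = c(2, 2, 2))
  ), spec_path)
  vol_path <- file.path(dir, "vol.nii")
  mesh_path <- file.path(dir, "mesh.inp")
  cmd_phantom(spec_path, vol_path, mesh_path)
  cfg <- list(
    volume = list(path = vol_path),
    mesh = list(path = mesh_path),
    chain = "pelvis_uniform_eq1_2",
    mapping = list(strategy = "volume_integration", refinement = 2L),
    binning = list(n_bins = 4L),
    output = list(inp = file.path(dir, "mapped.inp"),
                  vtk = file.path(dir, "mapped.vtk"),
                  csv = file.path(dir, "elements.csv"),
                  report = file.path(dir, "report.yaml")))
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  list(cfg = cfg, cfg_path = cfg_path, dir = dir)
}
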