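# Mesh container, geometry predicates, Abaqus and VTK I/O.

test_that("a minimal Abaqus deck reads as one tet", {
  path <- write_minimal_inp(file.path(withr::local_tempdir(), "one.inp"))
  mesh <- read_abaqus_inp(path)
  expect_identical(nrow(mesh$elements), 1L)
  expect_identical(nrow(mesh$nodes), 4L)
  expect_equal(tet_volume(mesh, 1), 1 / 6)
})

test_that("quadratic tets and duplicate ids are rejected loudly", {
  dir <- withr::local_tempdir()
  p10 <- write_minimal_inp(file.path(dir, "c3d10.inp"), "C3D10")
  expect_bonemapr_error(read_abaqus_inp(p10), "format", "C3D10")
  dup <- file.path(dir, "dup.inp")
  writeLines(c("*NODE", "1, 0,0,0", "1, 1,0,0", "3, 0,1,0", "4, 0,0,1",
               "*ELEMENT, TYPE=C3D4", "1, 1, 1, 3, 4"), dup)
  expect_bonemapr_error(read_abaqus_inp(dup), "validation", "duplicate")
})

test_that("Abaqus round-trip preserves node and element tables", {
  dir <- withr::local_tempdir()
  mesh <- make_box_mesh(c(1, 1, 1), c(1, 1, 1))
  p1 <- file.path(dir, "cube.inp")
  write_abaqus_inp(mesh, p1)
  back <- read_abaqus_inp(p1)
  expect_identical(back$node_ids, mesh$node_ids)
  expect_identical(back$elem_ids, mesh$elem_ids)
  expect_equal(back$nodes, mesh$nodes)
  expect_identical(back$elements, mesh$elements)
  p2 <- file.path(dir, "cube2.inp")
  write_abaqus_inp(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("tet volume and centroid match closed forms and affine scaling", {
  m <- unit_tet_mesh()
  expect_equal(tet_volume(m, 1), 1 / 6)
  expect_equal(as.numeric(element_centroid(m, 1)), c(0.25, 0.25, 0.25))
  set.seed(5)
  A <- matrix(rnorm(9), 3, 3)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
  b <- rnorm(3)
  m2 <- fe_mesh(sweep(tcrossprod(m$nodes, A), 2L, b, `+`),
                matrix(1:4, nrow = 1))
  expect_equal(tet_volume(m2, 1), abs(det(A)) / 6, tolerance = 1e-12)
})

test_that("degenerate elements are rejected with their id", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_bonemapr_error(fe_mesh(nodes, matrix(1:4, nrow = 1)),
                        "geometry", "degenerate.*1")
})

test_that("point-in-tet honours the barycentric tolerance convention", {
  m <- unit_tet_mesh()
  expect_true(point_in_tet(m, 1, as.numeric(element_centroid(m, 1))))
  expect_true(point_in_tet(m, 1, c(0, 0, 1), tol = 1e-9))  # vertex
  # point at barycentric (-0.01, 0.41, 0.3, 0.3)
  lam <- c(-0.01, 0.41, 0.3, 0.3)
  p <- as.numeric(t(m$nodes) %*% lam)
  expect_false(point_in_tet(m, 1, p, tol = 0))
  expect_true(point_in_tet(m, 1, p, tol = 0.02))
})

test_that("orientation fix-up yields positive volumes summing to the box volume", {
  mesh <- make_box_mesh(c(2, 3, 4), c(3, 2, 2))
  # scramble some connectivity into negative orientation and rebuild
  elems <- mesh$elements
  flip <- seq(1, nrow(elems), by = 2)
  elems[flip, 3:4] <- elems[flip, 4:3]
  rebuilt <- fe_mesh(mesh$nodes, elems)
  expect_true(all(tet_volume(rebuilt) > 0))
  expect_equal(mesh_volume(rebuilt), 24, tolerance = 1e-10)
})

test_that("a mapped deck carries one elset/material/section triple per bin", {
  dir <- withr::local_tempdir()
  mesh <- make_box_mesh(c(2, 1, 1), c(2, 1, 1))
  assignment <- data.frame(eid = mesh$elem_ids,
                           hu_mean = 0, rho = 0.5,
                           young_modulus = rep(c(100, 1000), each = 6),
                           n_samples = 1, clamped_fraction = 0)
  class(assignment) <- c("material_assignment", "data.frame")
  bins <- material_bins(assignment, mesh, n_bins = 2)
  path <- file.path(dir, "mapped.inp")
  write_abaqus_inp(mesh, path, assignment = assignment, bins = bins,
                   poisson_ratio = 0.3)
  txt <- readLines(path)
  expect_length(grep("^\\*ELSET", txt), 2L)
  expect_length(grep("^\\*MATERIAL", txt), 2L)
  expect_length(grep("^\\*SOLID SECTION", txt), 2L)
  back <- read_abaqus_inp(path)
  got <- sort(unlist(back$elsets))
  expect_identical(as.integer(got), sort(mesh$elem_ids))  # partition
  expect_setequal(back$elsets$MAT_001, assignment$eid[1:6])
  # single-bin deck has exactly one triple
  b1 <- material_bins(assignment, mesh, n_bins = 1)
  p1 <- file.path(dir, "one.inp")
  write_abaqus_inp(mesh, p1, assignment = assignment, bins = b1)
  expect_length(grep("^\\*MATERIAL", readLines(p1)), 1L)
})

test_that("writing with an unassigned element lists the missing ids", {
  mesh <- make_box_mesh(c(1, 1, 1), c(1, 1, 1))
  assignment <- data.frame(eid = mesh$elem_ids, rho = 1,
                           young_modulus = 1000)
  bins <- list(structure(list(index = 1L, lo = 0, hi = 2000,
                              element_ids = mesh$elem_ids[-2],
                              representative_modulus = 1000,
                              volume_fraction = 1),
                         class = "material_bin"))
  expect_bonemapr_error(
    write_abaqus_inp(mesh, tempfile(fileext = ".inp"),
                     assignment = assignment, bins = bins),
    "validation", "not assigned.*2")
})

test_that("VTK output re-reads identically with an independent parser", {
  dir <- withr::local_tempdir()
  mesh <- make_box_mesh(c(1, 2, 1), c(1, 2, 1))
  E <- seq_len(nrow(mesh$elements)) * 10
  assignment <- data.frame(eid = mesh$elem_ids, hu_mean = E / 10,
                           rho = 1, young_modulus = E,
                           n_samples = 1, clamped_fraction = 0)
  path <- file.path(dir, "m.vtk")
  write_vtk_assignment(mesh, assignment, path)
  got <- parse_vtk_ascii(path)
  expect_equal(got$points, mesh$nodes, ignore_attr = TRUE)
  conn <- matrix(match(mesh$elements, mesh$node_ids), ncol = 4)
  expect_equal(got$cells, conn, ignore_attr = TRUE)
  expect_equal(got$scalars$young_modulus, E)
  expect_equal(got$scalars$HU, E / 10)
})
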