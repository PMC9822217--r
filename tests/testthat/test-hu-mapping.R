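# Element HU averaging strategies and the full material-mapping step.

affine_setup <- function(coeffs = c(2, -1, 3, 7)) {
  spec <- phantom_spec("affine", dims = c(15, 15, 15), spacing = c(1, 1, 1),
                       origin = c(-2, -2, -2), coeffs = coeffs)
  list(spec = spec, vol = make_volume(spec),
       mesh = make_box_mesh(c(10, 10, 10), c(2, 2, 2)))
}

test_that("all strategies return the constant on a constant volume", {
  vol <- make_volume(phantom_spec("constant", dims = c(14, 14, 14),
                                  origin = c(-2, -2, -2), value = 500))
  mesh <- make_box_mesh(c(8, 8, 8), c(2, 2, 2))
  cfg <- mapping_config(chain = "pelvis_uniform_eq1_2")
  for (fn in list(element_hu_node_average, element_hu_voxel_average,
                  element_hu_integration)) {
    expect_equal(as.numeric(fn(mesh, vol, cfg)),
                 rep(500, nrow(mesh$elements)))
  }
  # integration at several refinements
  for (r in 1:3) {
    cfg_r <- mapping_config(chain = "pelvis_uniform_eq1_2", refinement = r)
    expect_equal(as.numeric(element_hu_integration(mesh, vol, cfg_r)),
                 rep(500, nrow(mesh$elements)))
  }
})

test_that("node average equals the centroid value on affine fields", {
  s <- affine_setup()
  cfg <- mapping_config(chain = "pelvis_uniform_eq1_2",
                        strategy = "node_average")
  got <- as.numeric(element_hu_node_average(s$mesh, s$vol, cfg))
  want <- as.numeric(phantom_field(s$spec, element_centroid(s$mesh)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("node average on a rough field equals four explicit interpolations", {
  set.seed(21)
  vol <- ct_volume(array(runif(12^3, 0, 1000), dim = c(12, 12, 12)))
  mesh <- random_tet_mesh(2, 9)
  cfg <- mapping_config(chain = "pelvis_uniform_eq1_2",
                        strategy = "node_average")
  got <- as.numeric(element_hu_node_average(mesh, vol, cfg))
  want <- mean(vapply(1:4, function(i)
    as.numeric(hu_at(vol, mesh$nodes[i, ])), numeric(1)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("voxel average matches exhaustive voxel enumeration", {
  spec <- phantom_spec("two_phase", dims = c(13, 13, 13),
                       origin = c(-1, -1, -1), period = 2,
                       hu_low = 100, hu_high = 1100)
  vol <- make_volume(spec)
  set.seed(31)
  mesh <- random_tet_mesh(0.5, 9.5, min_vol = 40)
  cfg <- mapping_config(chain = "pelvis_uniform_eq1_2",
                        strategy = "voxel_average")
  got <- as.numeric(element_hu_voxel_average(mesh, vol, cfg))
  # oracle: enumerate every voxel center in the volume
  idx <- as.matrix(expand.grid(0:12, 0:12, 0:12))
  centers <- voxel_to_world(vol, idx)
  inside <- point_in_tet(mesh, 1, centers)
  expect_gt(sum(inside), 10)
  want <- mean(vol$hu[idx[inside, 1] + 13 * (idx[inside, 2] +
                                               13 * idx[inside, 3]) + 1])
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("sub-voxel elements fall back to integration (or error on request)", {
  spec <- phantom_spec("affine", dims = c(8, 8, 8), spacing = c(2, 2, 2),
                       origin = c(-3, -3, -3), coeffs = c(5, 1, -2, 50))
  vol <- make_volume(spec)
  # a tet well inside one voxel cell, away from any voxel center
  nodes <- rbind(c(2.2, 2.2, 2.2), c(2.8, 2.2, 2.2),
                 c(2.2, 2.8, 2.2), c(2.2, 2.2, 2.8))
  mesh <- fe_mesh(nodes, matrix(1:4, nrow = 1))
  cfg <- mapping_config(chain = "pelvis_uniform_eq1_2",
                        strategy = "voxel_average")
  got <- element_hu_voxel_average(mesh, vol, cfg)
  expect_identical(attr(got, "fallback_eids"), 1L)
  expect_equal(as.numeric(got),
               as.numeric(element_hu_integration(mesh, vol, cfg)))
  cfg_err <- mapping_config(chain = "pelvis_uniform_eq1_2",
                            strategy = "voxel_average",
                            voxel_fallback = "error")
  expect_bonemapr_error(element_hu_voxel_average(mesh, vol, cfg_err),
                        "geometry", "no voxel center")
})

test_that("integration is exact for affine fields at every refinement", {
  s <- affine_setup()
  want <- as.numeric(phantom_field(s$spec, element_centroid(s$mesh)))
  got <- list()
  for (r in c(1, 3)) {
    cfg <- mapping_config(chain = "pelvis_uniform_eq1_2", refinement = r)
    got[[as.character(r)]] <-
      as.numeric(element_hu_integration(s$mesh, s$vol, cfg))
    expect_lt(max(abs(got[[as.character(r)]] - want) / abs(want)), 1e-9)
  }
  expect_equal(got[["1"]], got[["3"]], tolerance = 1e-9)
})

test_that("integration converges on a smooth nonlinear field", {
  # smooth field sampled finely enough that interpolation error is small
  d <- c(41, 41, 41)
  idx <- as.matrix(expand.grid(0:40, 0:40, 0:40)) * 0.25
  hu <- array(500 + 300 * sin(idx[, 1]) * cos(idx[, 2]) + 40 * idx[, 3]^2,
              dim = d)
  vol <- ct_volume(hu, spacing = c(0.25, 0.25, 0.25))
  set.seed(41)
  mesh <- random_tet_mesh(2, 8)
  err <- vapply(c(1, 2, 3), function(r) {
    cfg <- mapping_config(chain = "pelvis_uniform_eq1_2", refinement = r)
    ref <- mapping_config(chain = "pelvis_uniform_eq1_2", refinement = 6)
    abs(as.numeric(element_hu_integration(mesh, vol, cfg)) -
          as.numeric(element_hu_integration(mesh, vol, ref)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("map_materials is deterministic, bounded and strategy-consistent", {
  s <- affine_setup()
  for (st in c("node_average", "voxel_average", "volume_integration")) {
    cfg <- mapping_config(chain = "bonemat_test_eq11_13", strategy = st)
    a1 <- map_materials(s$mesh, s$vol, cfg)
    a2 <- map_materials(s$mesh, s$vol, cfg)
    expect_identical(a1, a2)                    # bitwise determinism
    expect_true(all(a1$hu_mean >= min(s$vol$hu) - 1e-9 &
                      a1$hu_mean <= max(s$vol$hu) + 1e-9))
  }
  # node_average and volume_integration coincide exactly on affine fields
  an <- map_materials(s$mesh, s$vol,
                      mapping_config(chain = "bonemat_test_eq11_13",
                                     strategy = "node_average"))
  ai <- map_materials(s$mesh, s$vol,
                      mapping_config(chain = "bonemat_test_eq11_13",
                                     strategy = "volume_integration"))
  expect_equal(an$young_modulus, ai$young_modulus, tolerance = 1e-12)
})

test_that("mapping a constant phantom gives every element the same modulus", {
  vol <- make_volume(phantom_spec("constant", dims = c(10, 10, 10),
                                  origin = c(-1, -1, -1), value = 800))
  mesh <- make_box_mesh(c(6, 6, 6), c(2, 2, 2))
  cfg <- mapping_config(chain = "pelvis_uniform_eq1_2")
  a <- map_materials(mesh, vol, cfg)
  want <- as.numeric(hu_to_modulus(builtin_chain("pelvis_uniform_eq1_2"),
                                   800))
  expect_equal(a$young_modulus, rep(want, nrow(mesh$elements)))
})

test_that("assignments are invariant under a simultaneous rigid motion", {
  s <- affine_setup()
  cfg0 <- mapping_config(chain = "bonemat_test_eq11_13")
  base <- map_materials(s$mesh, s$vol, cfg0)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t0 <- c(5, -3, 2)
  # move the volume with the rigid motion and tell the mapper to move the
  # mesh the same way
  vol_m <- ct_volume(s$vol$hu, spacing = s$vol$spacing,
                     origin = as.numeric(R %*% s$vol$origin + t0),
                     orientation = R %*% s$vol$orientation)
  cfg_m <- mapping_config(chain = "bonemat_test_eq11_13",
                          transform = rigid_transform(R, t0))
  moved <- map_materials(s$mesh, vol_m, cfg_m)
  expect_equal(moved$young_modulus, base$young_modulus, tolerance = 1e-9)
  expect_equal(moved$hu_mean, base$hu_mean, tolerance = 1e-9)
})

test_that("shell phantoms concentrate stiffness in the cortical layer", {
  # conforming cubic shell: interfaces on element faces, strict contrast
  sp <- phantom_spec("shell", dims = rep(27, 3), spacing = rep(1, 3),
                     origin = rep(-13, 3), center = c(0, 0, 0),
                     r_inner = 6, r_outer = 10, norm = "linf")
  vol <- make_volume(sp)
  mesh <- make_box_mesh(rep(20, 3), rep(10, 3), origin = rep(-10, 3))
  r <- apply(abs(element_centroid(mesh)), 1, max)
  shell <- r > 6
  cfg <- mapping_config(chain = "bonemat_test_eq11_13")
  a <- map_materials(mesh, vol, cfg)
  expect_gt(min(a$young_modulus[shell]), max(a$young_modulus[!shell]))
  # spherical shell: robust median contrast
  sp2 <- phantom_spec("shell", dims = rep(27, 3), spacing = rep(1, 3),
                      origin = rep(-13, 3), center = c(0, 0, 0),
                      r_inner = 6, r_outer = 10)
  a2 <- map_materials(mesh, make_volume(sp2), cfg)
  r2 <- sqrt(rowSums(element_centroid(mesh)^2))
  expect_gt(stats::median(a2$young_modulus[r2 > 6 & r2 <= 10]),
            3 * stats::median(a2$young_modulus[r2 <= 6]))
})

test_that("averaging order is configurable and differs on nonlinear laws", {
  s <- affine_setup()
  cfg_hu <- mapping_config(chain = "pelvis_uniform_eq1_2", average = "hu")
  cfg_e <- mapping_config(chain = "pelvis_uniform_eq1_2",
                          average = "modulus")
  a_hu <- map_materials(s$mesh, s$vol, cfg_hu)
  a_e <- map_materials(s$mesh, s$vol, cfg_e)
  # E(rho) is convex (b = 2.29 > 1): mean of E over samples >= E of mean HU
  expect_true(all(a_e$young_modulus >= a_hu$young_modulus - 1e-9))
  expect_gt(max(a_e$young_modulus - a_hu$young_modulus), 0)
})

test_that("poor mesh/volume overlap triggers the registration warning", {
  vol <- make_volume(phantom_spec("constant", dims = c(4, 4, 4), value = 0))
  mesh <- make_box_mesh(c(5, 5, 5), c(2, 2, 2), origin = c(50, 50, 50))
  cfg <- mapping_config(chain = "pelvis_uniform_eq1_2")
  expect_warning(map_materials(mesh, vol, cfg), "centroids")
})
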