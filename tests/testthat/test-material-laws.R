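# Law chains: published coefficients, floors, piecewise regimes, config I/O.

test_that("builtin chains carry the published coefficients digit for digit", {
  ch1 <- builtin_chain("pelvis_uniform_eq1_2")
  expect_identical(ch1$calibration$slope, 0.00063)
  expect_identical(ch1$calibration$intercept, -0.0067)
  expect_identical(ch1$calibration$output, "rho_ash")
  expect_identical(ch1$modulus[[1]]$a, 10500)
  expect_identical(ch1$modulus[[1]]$b, 2.29)

  ch2 <- builtin_chain("cortical_apparent_eq3_5")
  expect_identical(ch2$conversions[[1]]$scale, 0.877)
  expect_identical(ch2$conversions[[1]]$offset, 0.079)
  expect_identical(ch2$conversions[[2]]$scale, 1 / 0.6)
  expect_identical(ch2$conversions[[2]]$offset, 0)
  expect_identical(ch2$modulus[[1]]$a, 6850)
  expect_identical(ch2$modulus[[1]]$b, 1.49)

  ch3 <- builtin_chain("piecewise_eq6_10")
  expect_identical(ch3$calibration$slope, 0.0008)
  expect_identical(ch3$calibration$intercept, 0)
  expect_identical(ch3$conversions[[1]]$scale, 0.877)
  expect_identical(ch3$conversions[[1]]$pre_scale, 1.15)
  expect_identical(ch3$conversions[[1]]$offset, 0.08)
  segs <- ch3$modulus
  expect_identical(vapply(segs, function(s) s$hi, numeric(1)),
                   c(0.3, 0.486, Inf))
  expect_identical(segs[[1]]$a, 33900)
  expect_identical(segs[[1]]$b, 2.2)
  expect_identical(segs[[2]]$constant, 2398)
  expect_identical(segs[[3]]$a, 10200)
  expect_identical(segs[[3]]$b, 2.01)

  ch4 <- builtin_chain("bonemat_test_eq11_13")
  expect_identical(ch4$calibration$slope, 0.00079)
  expect_identical(ch4$calibration$intercept, -0.0039)
  expect_identical(ch4$conversions[[1]]$scale, 0.877)
  expect_identical(ch4$conversions[[1]]$offset, 0.079)
  expect_identical(ch4$modulus[[1]]$a, 14664)
  expect_identical(ch4$modulus[[1]]$b, 1.49)

  expect_bonemapr_error(builtin_chain("no_such_chain"), "config",
                        "pelvis_uniform_eq1_2")
})

test_that("HU converts to density through calibration, conversions and floor", {
  chb <- builtin_chain("bonemat_test_eq11_13")
  # hand evaluation: rho_ct = 0.00079*1000 - 0.0039 = 0.7861;
  # rho_ash = 0.877*0.7861 + 0.079
  expect_equal(as.numeric(hu_to_density(chb, 1000)),
               0.877 * 0.7861 + 0.079, tolerance = 1e-12)
  expect_equal(0.877 * 0.7861 + 0.079, 0.76841, tolerance = 1e-5)

  ch1 <- builtin_chain("pelvis_uniform_eq1_2")
  r0 <- hu_to_density(ch1, 0)  # raw -0.0067 floors
  expect_equal(as.numeric(r0), ch1$rho_floor)
  expect_identical(attr(r0, "n_floored"), 1L)
  # HU landing exactly on the floor is not counted as floored
  hu_exact <- (ch1$rho_floor + 0.0067) / 0.00063
  re <- hu_to_density(ch1, hu_exact)
  expect_equal(as.numeric(re), ch1$rho_floor)
  expect_identical(attr(re, "n_floored"), 0L)
})

test_that("density-to-modulus applies the correct piecewise regime", {
  ch <- builtin_chain("piecewise_eq6_10")
  expect_identical(as.numeric(density_to_modulus(ch, 0.4)), 2398)
  # half-open boundaries: 0.486 still constant, 0.3 still in the low power law
  expect_identical(as.numeric(density_to_modulus(ch, 0.486)), 2398)
  expect_equal(as.numeric(density_to_modulus(ch, 0.3)), 33900 * 0.3^2.2)
  expect_equal(as.numeric(density_to_modulus(ch, 0.6)), 10200 * 0.6^2.01)
  expect_equal(as.numeric(density_to_modulus(ch, 0.4861)),
               10200 * 0.4861^2.01)

  ch1 <- builtin_chain("pelvis_uniform_eq1_2")
  expect_identical(as.numeric(density_to_modulus(ch1, 1)), 10500)
})

test_that("piecewise regimes partition the density axis exactly once", {
  ch <- builtin_chain("piecewise_eq6_10")
  rho <- seq(1e-3, 3, by = 1e-3)
  E <- as.numeric(density_to_modulus(ch, rho))
  manual <- ifelse(rho > 0.486, 10200 * rho^2.01,
                   ifelse(rho > 0.3, 2398, 33900 * rho^2.2))
  manual <- pmax(manual, ch$e_floor)
  expect_equal(E, manual, tolerance = 1e-14)
})

test_that("HU-to-modulus composes the chain and floors small outputs", {
  chb <- builtin_chain("bonemat_test_eq11_13")
  rho <- 0.877 * (0.00079 * 1000 - 0.0039) + 0.079
  expect_equal(as.numeric(hu_to_modulus(chb, 1000)), 14664 * rho^1.49,
               tolerance = 1e-12)
  # HU placing rho_ash at 0.35 lands in the constant trabecular regime
  ch <- builtin_chain("piecewise_eq6_10")
  hu35 <- (0.35 - 0.08) / (0.877 * 1.15 * 0.0008)
  expect_identical(as.numeric(hu_to_modulus(ch, hu35)), 2398)
  # deeply negative HU floors the density, then the modulus law applies
  ch_lowfloor <- law_chain("tiny", builtin_chain("pelvis_uniform_eq1_2")$calibration,
                           modulus = list(modulus_segment(a = 1e-4, b = 1)),
                           rho_floor = 1e-3, e_floor = 0.01)
  e <- hu_to_modulus(ch_lowfloor, -3000)
  expect_identical(as.numeric(e), 0.01)
  expect_identical(attr(e, "n_floored_e"), 1L)
})

test_that("each builtin chain is monotone in HU up to 4000", {
  for (nm in c("pelvis_uniform_eq1_2", "cortical_apparent_eq3_5",
               "piecewise_eq6_10", "bonemat_test_eq11_13")) {
    ch <- builtin_chain(nm)
    E <- as.numeric(hu_to_modulus(ch, 0:4000))
    expect_true(all(diff(E) >= 0), info = nm)
  }
})

test_that("chain YAML round-trips field by field", {
  ch <- builtin_chain("piecewise_eq6_10")
  path <- file.path(withr::local_tempdir(), "chain.yaml")
  save_chain(ch, path)
  back <- load_chain(path)
  expect_equal(back, ch)
})

test_that("gapped and overlapping segment configs are rejected by interval", {
  cal <- list(slope = 0.001, intercept = 0, output = "rho_ash")
  gap <- list(name = "gap", calibration = cal,
              modulus = list(list(a = 1000, b = 2, lo = 0, hi = 0.3),
                             list(a = 2000, b = 2, lo = 0.35)))
  expect_bonemapr_error(load_chain(gap), "config", "0\\.3.*0\\.35")
  ovl <- list(name = "ovl", calibration = cal,
              modulus = list(list(a = 1000, b = 2, lo = 0, hi = 0.5),
                             list(a = 2000, b = 2, lo = 0.4)))
  expect_bonemapr_error(load_chain(ovl), "config", "overlap")
  # valid user chain reproducing a builtin compares equal
  ok <- load_chain(list(
    name = "piecewise_eq6_10",
    calibration = list(slope = 0.0008, intercept = 0, output = "rho_ct"),
    conversions = list(list(scale = 0.877, offset = 0.08, pre_scale = 1.15,
                            output = "rho_ash")),
    modulus = list(list(a = 33900, b = 2.2, lo = 0, hi = 0.3),
                   list(constant = 2398, lo = 0.3, hi = 0.486),
                   list(a = 10200, b = 2.01, lo = 0.486))))
  expect_equal(ok, builtin_chain("piecewise_eq6_10"))
})
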