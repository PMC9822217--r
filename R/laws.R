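# HU -> density -> Young's-modulus law chains.
#
# A chain is: one calibration line (HU to a density), zero or more linear
# density conversions (e.g. rho_CT -> rho_ash -> rho_app), and a piecewise
# modulus law whose segments are power laws E = a * rho^b or constants over
# half-open density intervals (lo, hi]. Units are fixed package-wide:
# densities in g/cm^3, moduli in MPa.

#' Calibration line from HU to density
#'
#' `rho = slope * HU + intercept`, the linear scanner-calibration
#' relationship. Calibration coefficients are configuration inputs; they
#' are never estimated by this package.
#'
#' @param slope g/cm^3 per HU, positive.
#' @param intercept g/cm^3.
#' @param output Which density the line produces: `"rho_ash"` or `"rho_ct"`.
#' @return An object of class `calibration_law`.
#' @export
calibration_law <- function(slope, intercept, output = c("rho_ash", "rho_ct")) {
  output <- match.arg(output)
  bm_assert(is.numeric(slope) && slope > 0, "validation",
            "calibration slope must be positive")
  bm_assert(is.numeric(intercept) && is.finite(intercept), "validation",
            "calibration intercept must be finite")
  structure(list(slope = slope, intercept = intercept, output = output),
            class = "calibration_law")
}

#' Linear conversion between density kinds
#'
#' `rho_out = scale * (pre_scale * rho_in) + offset`. `pre_scale` carries
#' multiplicative correction factors that the literature prints separately
#' from the main slope (e.g. a 1.15 scanner correction).
#'
#' @param scale Dimensionless, positive.
#' @param offset g/cm^3.
#' @param pre_scale Dimensionless (default 1).
#' @param output Density kind produced: `"rho_ash"` or `"rho_app"`.
#' @return An object of class `density_conversion`.
#' @export
density_conversion <- function(scale, offset, pre_scale = 1,
                               output = c("rho_ash", "rho_app")) {
  output <- match.arg(output)
  bm_assert(is.numeric(scale) && scale > 0, "validation",
            "conversion scale must be positive")
  structure(list(scale = scale, offset = offset, pre_scale = pre_scale,
                 output = output),
            class = "density_conversion")
}

#' One segment of a piecewise density-modulus law
#'
#' Over the half-open density interval `(lo, hi]`, the modulus is either
#' the power law `E = a * rho^b` or a constant.
#'
#' @param a Coefficient in MPa (power-law form).
#' @param b Dimensionless exponent.
#' @param lo,hi Interval bounds in g/cm^3, `lo < hi`; `hi` may be `Inf`.
#' @param constant Constant modulus in MPa (alternative to `a`/`b`).
#' @return An object of class `modulus_segment`.
#' @export
modulus_segment <- function(a = NULL, b = NULL, lo = 0, hi = Inf,
                            constant = NULL) {
  bm_assert(lo < hi, "validation",
            "segment interval must satisfy lo < hi (got (%g, %g])", lo, hi)
  if (is.null(constant)) {
    bm_assert(is.numeric(a) && a > 0 && is.numeric(b), "validation",
              "power-law segment needs a > 0 and an exponent b")
  } else {
    bm_assert(is.numeric(constant) && constant > 0, "validation",
              "constant segment modulus must be positive")
  }
  structure(list(a = a, b = b, lo = lo, hi = hi, constant = constant),
            class = "modulus_segment")
}

#' Assemble a HU-to-modulus law chain
#'
#' Validates that the modulus segments cover `(rho_floor, Inf)` exactly
#' once: sorted by lower bound, the first segment must start at or below
#' `rho_floor`, consecutive segments must abut, and the last must extend to
#' infinity. Gaps and overlaps are configuration errors reported with the
#' offending interval.
#'
#' @param name Chain name (reported in run logs and outputs).
#' @param calibration A [calibration_law].
#' @param conversions List of [density_conversion]s, applied in order.
#' @param modulus List of [modulus_segment]s.
#' @param rho_floor Density floor in g/cm^3 (default 1e-3): calibrated
#'   densities below it (e.g. from air or low-HU voxels, where calibration
#'   lines go negative) are raised to the floor, and every flooring event
#'   is counted.
#' @param e_floor Modulus floor in MPa (default 0.01); a zero or negative
#'   modulus would break any downstream solve.
#' @return An object of class `law_chain`.
#' @export
law_chain <- function(name, calibration, conversions = list(),
                      modulus, rho_floor = 1e-3, e_floor = 0.01) {
  bm_assert(inherits(calibration, "calibration_law"), "validation",
            "calibration must be a calibration_law")
  bm_assert(length(modulus) >= 1L &&
              all(vapply(modulus, inherits, logical(1), "modulus_segment")),
            "validation", "modulus must be a list of modulus_segment")
  bm_assert(rho_floor > 0 && e_floor > 0, "validation",
            "floors must be positive")
  ord <- order(vapply(modulus, function(s) s$lo, numeric(1)))
  modulus <- modulus[ord]
  bm_assert(modulus[[1]]$lo <= rho_floor, "config",
            "modulus segments leave the interval (%g, %g] uncovered",
            rho_floor, modulus[[1]]$lo)
  for (i in seq_along(modulus)[-1]) {
    prev_hi <- modulus[[i - 1L]]$hi
    lo <- modulus[[i]]$lo
    if (lo > prev_hi + 1e-12) {
      bm_stop("config", "gap between modulus segments: (%g, %g] is uncovered",
              prev_hi, lo)
    }
    if (lo < prev_hi - 1e-12) {
      bm_stop("config", "overlapping modulus segments on (%g, %g]",
              lo, min(prev_hi, modulus[[i]]$hi))
    }
  }
  bm_assert(is.infinite(modulus[[length(modulus)]]$hi), "config",
            "modulus segments leave (%g, Inf) uncovered",
            modulus[[length(modulus)]]$hi)
  structure(list(name = name, calibration = calibration,
                 conversions = conversions, modulus = modulus,
                 rho_floor = rho_floor, e_floor = e_floor),
            class = "law_chain")
}

#' @export
print.law_chain <- function(x, ...) {
  cat(sprintf("law_chain '%s': HU -> %s (slope %g, intercept %g)",
              x$name, x$calibration$output, x$calibration$slope,
              x$calibration$intercept), "\n")
  for (cv in x$conversions) {
    cat(sprintf("  -> %s = %g * (%g * rho) + %g\n", cv$output, cv$scale,
                cv$pre_scale, cv$offset))
  }
  for (s in x$modulus) {
    if (is.null(s$constant)) {
      cat(sprintf("  E = %g * rho^%g MPa on (%g, %g]\n", s$a, s$b, s$lo, s$hi))
    } else {
      cat(sprintf("  E = %g MPa on (%g, %g]\n", s$constant, s$lo, s$hi))
    }
  }
  cat(sprintf("  floors: rho %g g/cm^3, E %g MPa\n", x$rho_floor, x$e_floor))
  invisible(x)
}

#' Built-in law chains
#'
#' The four chains ship with their published coefficients:
#' \describe{
#'   \item{`pelvis_uniform_eq1_2`}{One relation for both bone types:
#'     `rho_ash = 0.00063 HU - 0.0067`, `E = 10500 rho_ash^2.29`.}
#'   \item{`cortical_apparent_eq3_5`}{Cortical-layer law via apparent
#'     density: `rho_ash = 0.877 rho_CT + 0.079`,
#'     `rho_app = rho_ash / 0.6`, `E = 6850 rho_app^1.49`. The source
#'     literature prints no HU calibration for this family, so the chain
#'     defaults to `rho_CT = 0.0008 HU`; replace it with your scanner's
#'     calibration line for real use.}
#'   \item{`piecewise_eq6_10`}{Three density regimes:
#'     `rho_CT = 0.0008 HU`, `rho_ash = 0.877 * 1.15 rho_CT + 0.08`;
#'     cortical `E = 10200 rho_ash^2.01` for `rho_ash > 0.486`, constant
#'     trabecular `E = 2398` MPa for `0.3 < rho_ash <= 0.486`, and
#'     trabecular `E = 33900 rho_ash^2.2` for `rho_ash <= 0.3`.}
#'   \item{`bonemat_test_eq11_13`}{The Bonemat test-case relations:
#'     `rho_CT = 0.00079 HU - 0.0039`, `rho_ash = 0.877 rho_CT + 0.079`,
#'     `E = 14664 rho_ash^1.49`.}
#' }
#'
#' @param name One of the chain names above.
#' @return A [law_chain].
#' @examples
#' density_to_modulus(builtin_chain("piecewise_eq6_10"), 0.4)  # 2398 MPa
#' @export
builtin_chain <- function(name) {
  chains <- c("pelvis_uniform_eq1_2", "cortical_apparent_eq3_5",
              "piecewise_eq6_10", "bonemat_test_eq11_13")
  if (!is.character(name) || length(name) != 1L || !name %in% chains) {
    bm_stop("config", "unknown law chain '%s'; available chains: %s",
            as.character(name)[1], paste(chains, collapse = ", "))
  }
  switch(name,
    pelvis_uniform_eq1_2 = law_chain(
      name,
      calibration_law(slope = 0.00063, intercept = -0.0067,
                      output = "rho_ash"),
      modulus = list(modulus_segment(a = 10500, b = 2.29))),
    cortical_apparent_eq3_5 = law_chain(
      name,
      calibration_law(slope = 0.0008, intercept = 0, output = "rho_ct"),
      conversions = list(
        density_conversion(scale = 0.877, offset = 0.079,
                           output = "rho_ash"),
        density_conversion(scale = 1 / 0.6, offset = 0,
                           output = "rho_app")),
      modulus = list(modulus_segment(a = 6850, b = 1.49))),
    piecewise_eq6_10 = law_chain(
      name,
      calibration_law(slope = 0.0008, intercept = 0, output = "rho_ct"),
      conversions = list(
        density_conversion(scale = 0.877, pre_scale = 1.15, offset = 0.08,
                           output = "rho_ash")),
      modulus = list(
        modulus_segment(a = 33900, b = 2.2, lo = 0, hi = 0.3),
        modulus_segment(constant = 2398, lo = 0.3, hi = 0.486),
        modulus_segment(a = 10200, b = 2.01, lo = 0.486, hi = Inf))),
    bonemat_test_eq11_13 = law_chain(
      name,
      calibration_law(slope = 0.00079, intercept = -0.0039,
                      output = "rho_ct"),
      conversions = list(
        density_conversion(scale = 0.877, offset = 0.079,
                           output = "rho_ash")),
      modulus = list(modulus_segment(a = 14664, b = 1.49))))
}

#' Convert HU to the chain's working density
#'
#' Applies the calibration line, then each density conversion in order, and
#' floors the result at `rho_floor`. The number of floored values is
#' returned in the `n_floored` attribute.
#'
#' @param chain A [law_chain].
#' @param hu Numeric vector of HU.
#' @return Densities in g/cm^3 (the kind the chain's modulus law consumes),
#'   with attribute `n_floored`.
#' @export
hu_to_density <- function(chain, hu) {
  rho <- chain$calibration$slope * hu + chain$calibration$intercept
  for (cv in chain$conversions) {
    rho <- cv$scale * (cv$pre_scale * rho) + cv$offset
  }
  floored <- rho < chain$rho_floor
  rho[floored] <- chain$rho_floor
  attr(rho, "n_floored") <- sum(floored)
  rho
}

#' Convert density to Young's modulus
#'
#' Applies the unique modulus segment whose half-open interval `(lo, hi]`
#' contains `rho`, and floors the result at `e_floor`.
#'
#' @param chain A [law_chain].
#' @param rho Numeric vector of densities in g/cm^3 (positive).
#' @return Moduli in MPa, with attribute `n_floored`.
#' @export
density_to_modulus <- function(chain, rho) {
  bm_assert(all(rho > 0), "validation", "densities must be positive")
  E <- rep(NA_real_, length(rho))
  for (s in chain$modulus) {
    sel <- rho > s$lo & rho <= s$hi
    if (!any(sel)) next
    E[sel] <- if (is.null(s$constant)) s$a * rho[sel]^s$b else s$constant
  }
  if (anyNA(E)) {
    bm_stop("config",
            "density %g g/cm^3 falls outside every modulus segment",
            rho[which(is.na(E))[1L]])
  }
  floored <- E < chain$e_floor
  E[floored] <- chain$e_floor
  attr(E, "n_floored") <- sum(floored)
  E
}

#' Convert HU directly to Young's modulus
#'
#' Composition of [hu_to_density()] and [density_to_modulus()].
#'
#' @param chain A [law_chain].
#' @param hu Numeric vector of HU.
#' @return Moduli in MPa, with attributes `n_floored_rho` and
#'   `n_floored_e`.
#' @export
hu_to_modulus <- function(chain, hu) {
  rho <- hu_to_density(chain, hu)
  E <- density_to_modulus(chain, as.numeric(rho))
  attr(E, "n_floored_rho") <- attr(rho, "n_floored")
  attr(E, "n_floored_e") <- attr(E, "n_floored")
  attr(E, "n_floored") <- NULL
  E
}

chain_to_list <- function(chain) {
  list(
    name = chain$name,
    calibration = list(slope = chain$calibration$slope,
                       intercept = chain$calibration$intercept,
                       output = chain$calibration$output),
    conversions = lapply(chain$conversions, function(cv)
      list(scale = cv$scale, offset = cv$offset, pre_scale = cv$pre_scale,
           output = cv$output)),
    modulus = lapply(chain$modulus, function(s) {
      out <- list(lo = s$lo, hi = s$hi)
      if (is.null(s$constant)) { out$a <- s$a; out$b <- s$b }
      else out$constant <- s$constant
      out
    }),
    rho_floor = chain$rho_floor,
    e_floor = chain$e_floor
  )
}

#' Load or save a law chain as YAML
#'
#' The YAML schema mirrors the [law_chain()] fields; segment coverage of
#' `(rho_floor, Inf)` is enforced at load time, so gapped or overlapping
#' user chains fail with an error naming the offending interval. `hi: .inf`
#' denotes an unbounded segment.
#'
#' @param config Path to a YAML file, or an already-parsed named list.
#' @return A [law_chain].
#' @export
load_chain <- function(config) {
  if (is.character(config)) {
    bm_assert(file.exists(config), "io", "chain config not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  bm_assert(is.list(config) && !is.null(config$calibration) &&
              !is.null(config$modulus), "config",
            "chain config must define 'calibration' and 'modulus'")
  cal <- config$calibration
  conversions <- lapply(config$conversions, function(cv)
    density_conversion(scale = cv$scale, offset = cv$offset,
                       pre_scale = cv$pre_scale %||% 1,
                       output = cv$output %||% "rho_ash"))
  segments <- lapply(config$modulus, function(s)
    modulus_segment(a = s$a, b = s$b,
                    lo = s$lo %||% 0,
                    hi = if (is.null(s$hi)) Inf else as.numeric(s$hi),
                    constant = s$constant))
  law_chain(name = config$name %||% "user_chain",
            calibration = calibration_law(cal$slope, cal$intercept,
                                          cal$output %||% "rho_ash"),
            conversions = conversions, modulus = segments,
            rho_floor = config$rho_floor %||% 1e-3,
            e_floor = config$e_floor %||% 0.01)
}

#' @rdname load_chain
#' @param chain A [law_chain] to serialize.
#' @param path Output YAML path.
#' @export
save_chain <- function(chain, path) {
  write_atomic(path, function(tmp)
    yaml::write_yaml(chain_to_list(chain), tmp))
  invisible(path)
}
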