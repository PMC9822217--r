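# Partition mapped elements into material sets of similar modulus (or HU)
# and compute the volume-fraction distribution over the sets.

#' Bin elements into material sets
#'
#' Splits the observed value range (Young's modulus by default, element HU
#' alternatively) into `n_bins` equal-width half-open intervals
#' `(lo, hi]`, with the minimum value closed into the first bin and the
#' maximum belonging to the last. Empty bins are dropped; surviving bins
#' keep their original interval index.
#'
#' @param assignment A [map_materials()] result.
#' @param n_bins Number of equal-width intervals (default 50).
#' @param space `"modulus"` (default) or `"hu"`.
#' @return List of `material_bin` objects: `index`, `lo`, `hi`,
#'   `element_ids`, plus `representative_modulus` and `volume_fraction`
#'   slots filled by [representative_modulus()] / [volume_fractions()] (or
#'   the [material_bins()] convenience wrapper).
#' @export
bin_elements <- function(assignment, n_bins = 50L, space = c("modulus", "hu")) {
  space <- match.arg(space)
  bm_assert(is.numeric(n_bins) && n_bins >= 1, "validation",
            "n_bins must be at least 1")
  bm_assert(nrow(assignment) > 0, "validation", "assignment is empty")
  n_bins <- as.integer(n_bins)
  v <- if (space == "modulus") assignment$young_modulus else assignment$hu_mean
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) {
    # all elements identical: a single bin carries everything
    idx <- rep(1L, length(v))
    breaks <- c(lo, hi)
    n_bins <- 1L
  } else {
    w <- (hi - lo) / n_bins
    idx <- pmin(pmax(ceiling((v - lo) / w), 1L), n_bins)
    breaks <- lo + w * (0:n_bins)
  }
  bins <- list()
  for (b in seq_len(n_bins)) {
    members <- assignment$eid[idx == b]
    if (length(members) == 0L) next
    bins[[length(bins) + 1L]] <- structure(
      list(index = b, lo = breaks[b], hi = breaks[b + 1L],
           element_ids = members,
           representative_modulus = NA_real_,
           volume_fraction = NA_real_),
      class = "material_bin")
  }
  bins
}

#' Fill in per-bin volume fractions
#'
#' `fraction_i = sum of member element volumes / total element volume`;
#' fractions over all bins sum to 1 within 1e-12 (asserted).
#'
#' @param bins Bin list from [bin_elements()].
#' @param mesh The [fe_mesh] the assignment was mapped on.
#' @return The bin list with `volume_fraction` filled.
#' @export
volume_fractions <- function(bins, mesh) {
  vols <- tet_volume(mesh)
  names(vols) <- mesh$elem_ids
  binned_ids <- unlist(lapply(bins, function(b) b$element_ids))
  total <- sum(vols[as.character(binned_ids)])
  bm_assert(total > 0, "validation", "total element volume is zero")
  bins <- lapply(bins, function(b) {
    b$volume_fraction <- sum(vols[as.character(b$element_ids)]) / total
    b
  })
  s <- sum(vapply(bins, function(b) b$volume_fraction, numeric(1)))
  bm_assert(abs(s - 1) <= 1e-12, "validation",
            "bin volume fractions sum to %.15g, expected 1", s)
  bins
}

#' Representative modulus of a bin
#'
#' Either the volume-weighted mean of the member moduli (default; it
#' preserves the mesh's volume-averaged stiffness better than the
#' midpoint) or the interval midpoint.
#'
#' @param bin A single `material_bin`.
#' @param assignment The [map_materials()] result the bins came from.
#' @param mesh The [fe_mesh] (needed for volume weighting).
#' @param mode `"volume_weighted_mean"` (default) or `"midpoint"`.
#' @return Modulus in MPa.
#' @export
representative_modulus <- function(bin, assignment = NULL, mesh = NULL,
                                   mode = c("volume_weighted_mean",
                                            "midpoint")) {
  mode <- match.arg(mode)
  bm_assert(length(bin$element_ids) > 0, "validation", "bin is empty")
  if (mode == "midpoint") {
    bm_assert(is.finite(bin$lo) && is.finite(bin$hi), "validation",
              "midpoint mode needs a finite interval")
    return((bin$lo + bin$hi) / 2)
  }
  bm_assert(!is.null(assignment) && !is.null(mesh), "validation",
            "volume_weighted_mean mode needs the assignment and mesh")
  E <- assignment$young_modulus[match(bin$element_ids, assignment$eid)]
  w <- tet_volume(mesh, bin$element_ids)
  sum(w * E) / sum(w)
}

#' Bin elements and fill representatives and volume fractions
#'
#' Convenience wrapper: [bin_elements()], then [representative_modulus()]
#' per bin, then [volume_fractions()].
#'
#' @inheritParams bin_elements
#' @param mesh The [fe_mesh] the assignment was mapped on.
#' @param statistic Representative-modulus mode, see
#'   [representative_modulus()].
#' @return Bin list with all fields filled.
#' @export
material_bins <- function(assignment, mesh, n_bins = 50L,
                          space = c("modulus", "hu"),
                          statistic = c("volume_weighted_mean", "midpoint")) {
  statistic <- match.arg(statistic)
  bins <- bin_elements(assignment, n_bins = n_bins, space = space)
  bins <- lapply(bins, function(b) {
    b$representative_modulus <-
      representative_modulus(b, assignment, mesh, mode = statistic)
    b
  })
  volume_fractions(bins, mesh)
}

#' Modulus / volume-fraction distribution table
#'
#' One row per non-empty bin, sorted by representative modulus — the
#' points of a modulus-distribution plot for the mapped model.
#'
#' @param bins Bin list with representatives and fractions filled.
#' @return `data.frame` with columns `bin`, `E_repr_MPa`,
#'   `volume_fraction`, `n_elements`.
#' @export
distribution_table <- function(bins) {
  df <- data.frame(
    bin = vapply(bins, function(b) b$index, integer(1)),
    E_repr_MPa = vapply(bins, function(b) b$representative_modulus,
                        numeric(1)),
    volume_fraction = vapply(bins, function(b) b$volume_fraction, numeric(1)),
    n_elements = vapply(bins, function(b) length(b$element_ids), integer(1)))
  df[order(df$E_repr_MPa), , drop = FALSE]
}

#' Plot the modulus distribution
#'
#' Reproduces the standard presentation of a mapped model's material
#' content: one point per element set, modulus on the abscissa, volume
#' fraction on the ordinate.
#'
#' @param bins Bin list with representatives and fractions filled.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_distribution <- function(bins, ...) {
  tab <- distribution_table(bins)
  graphics::plot(tab$E_repr_MPa, tab$volume_fraction, type = "p", pch = 19,
                 xlab = "Young's modulus, MPa", ylab = "volume fraction", ...)
}
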