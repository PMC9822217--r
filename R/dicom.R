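# Constrained DICOM series reader.
#
# Scope: uncompressed, explicit-VR little-endian, single-frame CT slices —
# the shape in which calibrated clinical CT is normally exported. Compressed
# transfer syntaxes, implicit VR, and multi-frame objects are rejected with
# an explicit error rather than guessed at.

dcm_tags <- list(
  transfer_syntax    = c(0x0002, 0x0010),
  rows               = c(0x0028, 0x0010),
  cols               = c(0x0028, 0x0011),
  pixel_spacing      = c(0x0028, 0x0030),
  bits_allocated     = c(0x0028, 0x0100),
  pixel_rep          = c(0x0028, 0x0103),
  rescale_intercept  = c(0x0028, 0x1052),
  rescale_slope      = c(0x0028, 0x1053),
  position           = c(0x0020, 0x0032),
  orientation        = c(0x0020, 0x0037),
  pixel_data         = c(0x7fe0, 0x0010)
)

dcm_u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
dcm_u32 <- function(raw4) {
  as.numeric(raw4[1]) + 256 * as.numeric(raw4[2]) +
    65536 * as.numeric(raw4[3]) + 16777216 * as.numeric(raw4[4])
}

# Parse one DICOM file, returning the tags in `dcm_tags` that are present.
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  bm_assert(length(raw) > 132L &&
              rawToChar(raw[129:132]) == "DICM", "format",
            "%s is not a DICOM part-10 file (missing DICM magic)", path)
  out <- list()
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  while (pos + 8L <= length(raw) + 1L) {
    group <- dcm_u16(raw[pos:(pos + 1L)])
    elem <- dcm_u16(raw[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      bm_stop("format",
              "%s: implicit-VR or corrupted element at offset %d (tag %04x,%04x); only explicit-VR little-endian DICOM is supported",
              path, pos - 1L, group, elem)
    }
    if (vr %in% long_vrs) {
      len <- dcm_u32(raw[(pos + 8L):(pos + 11L)])
      body <- pos + 12L
    } else {
      len <- dcm_u16(raw[(pos + 6L):(pos + 7L)])
      body <- pos + 8L
    }
    if (len == 4294967295) {
      bm_stop("format",
              "%s: undefined-length element (tag %04x,%04x); encapsulated/compressed DICOM is not supported",
              path, group, elem)
    }
    value_raw <- if (len > 0) raw[body:(body + len - 1L)] else raw(0)
    key <- NULL
    for (nm in names(dcm_tags)) {
      t <- dcm_tags[[nm]]
      if (group == t[1] && elem == t[2]) key <- nm
    }
    if (!is.null(key)) {
      # strings are space/NUL padded to even length
      as_str <- function(v) trimws(rawToChar(v[v != as.raw(0)]))
      out[[key]] <- switch(vr,
        US = dcm_u16(value_raw),
        DS = as.numeric(strsplit(as_str(value_raw), "\\\\")[[1]]),
        OW = value_raw, OB = value_raw,
        as_str(value_raw))
    }
    pos <- body + len
  }
  ts <- out$transfer_syntax
  if (!is.null(ts) && !ts %in% "1.2.840.10008.1.2.1") {
    bm_stop("format", "%s: unsupported transfer syntax %s", path, ts)
  }
  out
}

#' Read a DICOM CT series
#'
#' Reads a directory of uncompressed explicit-VR little-endian single-frame
#' CT slices, honours the rescale slope/intercept, sorts the slices along
#' the stack normal, and verifies uniform slice spacing.
#'
#' @param dir Directory containing the `.dcm` slices (any extension; every
#'   regular file in the directory is read).
#' @param spacing_tol Maximum allowed deviation of inter-slice spacing from
#'   uniform, in mm.
#' @return A [ct_volume].
#' @export
read_dicom_series <- function(dir, spacing_tol = 1e-3) {
  bm_assert(dir.exists(dir), "io", "DICOM directory not found: %s", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  bm_assert(length(files) >= 2L, "format",
            "DICOM directory %s holds %d file(s); need at least 2 slices",
            dir, length(files))
  slices <- lapply(files, read_dicom_file)
  required <- c(rows = "Rows (0028,0010)", cols = "Columns (0028,0011)",
                pixel_spacing = "PixelSpacing (0028,0030)",
                position = "ImagePositionPatient (0020,0032)",
                orientation = "ImageOrientationPatient (0020,0037)",
                rescale_slope = "RescaleSlope (0028,1053)",
                rescale_intercept = "RescaleIntercept (0028,1052)",
                bits_allocated = "BitsAllocated (0028,0100)",
                pixel_data = "PixelData (7FE0,0010)")
  for (i in seq_along(slices)) {
    missing <- setdiff(names(required), names(slices[[i]]))
    if (length(missing) > 0) {
      bm_stop("format", "%s is missing required DICOM field %s",
              files[i], required[[missing[1]]])
    }
  }
  s1 <- slices[[1]]
  row_dir <- s1$orientation[1:3]   # direction of increasing column index
  col_dir <- s1$orientation[4:6]   # direction of increasing row index
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  z <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  files <- files[ord]
  z <- z[ord]
  dz <- diff(z)
  bm_assert(all(dz > 0), "format",
            "DICOM series %s has coincident slice positions", dir)
  if (max(dz) - min(dz) > spacing_tol) {
    bm_stop("format",
            "DICOM series %s has non-uniform slice spacing (%.4g to %.4g mm); a slice may be missing",
            dir, min(dz), max(dz))
  }
  nx <- s1$cols
  ny <- s1$rows
  nz <- length(slices)
  hu <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    bm_assert(s$rows == ny && s$cols == nx, "format",
              "%s: slice dimensions differ within the series", files[k])
    bm_assert(s$bits_allocated == 16L, "format",
              "%s: only 16-bit DICOM pixel data is supported", files[k])
    signed <- !is.null(s$pixel_rep) && s$pixel_rep == 1L
    vals <- readBin(s$pixel_data, "integer", n = nx * ny, size = 2L,
                    signed = signed, endian = "little")
    bm_assert(length(vals) == nx * ny, "format",
              "%s: pixel data truncated", files[k])
    # PixelData is stored row by row: column index varies fastest
    hu[, , k] <- s$rescale_slope * vals + s$rescale_intercept
  }
  ps <- s1$pixel_spacing  # (row spacing, column spacing) per the standard
  spacing <- c(ps[2], ps[1], mean(dz))
  orientation <- cbind(row_dir, col_dir, normal, deparse.level = 0)
  ct_volume(hu, spacing = spacing, origin = slices[[1]]$position,
            orientation = orientation)
}
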