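# Fixtures are built in code at test time: tiny meshes, synthetic DICOM
# slices, and an independent VTK parser used as a re-read oracle.

unit_tet_mesh <- function() {
  fe_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          matrix(1:4, nrow = 1))
}

# A random well-shaped tet inside [lo, hi]^3 (seeded by the caller).
random_tet_mesh <- function(lo = 1, hi = 9, min_vol = 0.5) {
  repeat {
    v <- matrix(stats::runif(12, lo, hi), 4, 3)
    vol <- abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ],
                         v[4, ] - v[1, ]))) / 6
    if (vol > min_vol) return(fe_mesh(v, matrix(1:4, nrow = 1)))
  }
}

write_minimal_inp <- function(path, element_type = "C3D4") {
  writeLines(c(
    "*HEADING", "minimal tet",
    "*NODE",
    "1, 0., 0., 0.", "2, 1., 0., 0.", "3, 0., 1., 0.", "4, 0., 0., 1.",
    sprintf("*ELEMENT, TYPE=%s", element_type),
    if (element_type == "C3D10") "1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10"
    else "1, 1, 2, 3, 4"
  ), path)
  path
}

# --- minimal DICOM writer (explicit VR little endian, part 10) ------------

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                    endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr))
  header <- if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"))
  } else {
    c(head, dcm_raw_u16(length(value_raw)))
  }
  c(header, value_raw)
}

dcm_ds <- function(group, elem, values) {
  dcm_element(group, elem, "DS",
              charToRaw(paste(formatC(values, format = "g", digits = 10),
                              collapse = "\\")))
}

# One axial slice: `pixels` is an nx x ny integer matrix (column index
# fastest), stored values; HU = slope * stored + intercept.
write_test_dicom_slice <- function(path, pixels, position,
                                   pixel_spacing = c(1, 1),
                                   slope = 1, intercept = -1024,
                                   drop_tags = character()) {
  nx <- nrow(pixels)
  ny <- ncol(pixels)
  els <- list(
    transfer = dcm_element(0x0002, 0x0010, "UI",
                           charToRaw("1.2.840.10008.1.2.1")),
    position = dcm_ds(0x0020, 0x0032, position),
    orientation = dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    rows = dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(ny)),
    cols = dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(nx)),
    pixel_spacing = dcm_ds(0x0028, 0x0030, pixel_spacing),
    bits = dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(16L)),
    pixel_rep = dcm_element(0x0028, 0x0103, "US", dcm_raw_u16(1L)),
    intercept = dcm_ds(0x0028, 0x1052, intercept),
    slope = dcm_ds(0x0028, 0x1053, slope),
    pixel_data = dcm_element(0x7fe0, 0x0010, "OW",
                             writeBin(as.integer(pixels), raw(), size = 2L,
                                      endian = "little"))
  )
  els[drop_tags] <- NULL
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  for (e in els) writeBin(e, con)
  path
}

# Write an n x n x nz DICOM series of an affine-in-z constant-in-plane field.
write_test_dicom_series <- function(dir, n = 4L, nz = 5L, dz = 2.5,
                                    slope = 2, intercept = -1000) {
  dir.create(dir, showWarnings = FALSE)
  for (k in seq_len(nz)) {
    stored <- matrix(500L + k, n, n)
    write_test_dicom_slice(
      file.path(dir, sprintf("slice%02d.dcm", k)), stored,
      position = c(-10, -20, (k - 1) * dz), pixel_spacing = c(0.5, 0.75),
      slope = slope, intercept = intercept)
  }
  dir
}

# --- independent legacy-VTK parser (re-read oracle) -----------------------

parse_vtk_ascii <- function(path) {
  lines <- readLines(path)
  toks_after <- function(i, n) {
    vals <- numeric(0)
    j <- i + 1L
    while (length(vals) < n) {
      vals <- c(vals, as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
      j <- j + 1L
    }
    vals
  }
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- matrix(toks_after(ip, 3L * np), ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  nc <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cell_rows <- matrix(toks_after(ic, 5L * nc), ncol = 5L, byrow = TRUE)
  stopifnot(all(cell_rows[, 1] == 4))
  scalars <- list()
  for (is in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[is], "\\s+")[[1]][2]
    # values start after the LOOKUP_TABLE line
    scalars[[nm]] <- toks_after(is + 1L, nc)
  }
  list(points = pts, cells = cell_rows[, 2:5, drop = FALSE] + 1L,
       scalars = scalars)
}

# Constant-E assignment for solver tests.
uniform_assignment <- function(mesh, E) {
  data.frame(eid = mesh$elem_ids,
             young_modulus = rep(E, length(mesh$elem_ids)))
}

# Dirichlet table prescribing u = A x + b on a set of node ids.
affine_dirichlet <- function(mesh, node_ids, A, b = c(0, 0, 0)) {
  rows <- match(node_ids, mesh$node_ids)
  u <- sweep(tcrossprod(mesh$nodes[rows, , drop = FALSE], A), 2L, b, `+`)
  data.frame(node = node_ids, ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

expect_bonemapr_error <- function(expr, class, pattern = NULL) {
  testthat::expect_error(expr, regexp = pattern,
                         class = paste0("bonemapr_", class))
}
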