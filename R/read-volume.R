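# Volume readers and writers: NIfTI-1, raw + JSON sidecar, DICOM series.

#' Read a CT volume
#'
#' Reads a CT volume carrying Hounsfield units from one of the supported
#' on-disk formats, applying any rescale slope/intercept the format declares
#' so that the returned values are HU regardless of the stored integer type.
#'
#' Formats:
#' \describe{
#'   \item{`nifti`}{NIfTI-1 file; the sform/qform affine is converted to the
#'     internal origin/orientation/spacing decomposition.}
#'   \item{`raw`}{Raw binary array with a JSON sidecar at `<path>.json` (or
#'     `path` may point at the sidecar itself) declaring `dims`, `spacing`,
#'     `origin`, `dtype`, and optionally `orientation` (9 numbers,
#'     column-major), `byte_order`, `rescale_slope`, `rescale_intercept`,
#'     `data` (data filename).}
#'   \item{`dicom_dir`}{Directory of uncompressed explicit-VR little-endian
#'     single-frame DICOM slices; see [read_dicom_series()].}
#' }
#'
#' @param path File (or directory, for DICOM) to read.
#' @param format One of `"auto"`, `"nifti"`, `"raw"`, `"dicom_dir"`. `"auto"`
#'   picks by extension/type: directories are DICOM, `.nii`/`.nii.gz` is
#'   NIfTI, `.json`/`.raw` is raw.
#' @return A [ct_volume].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "raw", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else if (grepl("\\.(json|raw|bin)$", path, ignore.case = TRUE)) "raw"
    else bm_stop("format", "cannot infer volume format from path: %s", path)
  }
  switch(format,
         nifti = read_nifti_volume(path),
         raw = read_raw_volume(path),
         dicom_dir = read_dicom_series(path))
}

read_nifti_volume <- function(path) {
  bm_assert(file.exists(path), "io", "volume file not found: %s", path)
  img <- RNifti::readNifti(path)  # applies scl_slope/scl_inter on read
  A <- unclass(RNifti::xform(img))
  M <- A[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(M^2))
  bm_assert(all(spacing > 0), "format",
            "NIfTI affine has a zero-length axis: %s", path)
  orientation <- sweep(M, 2L, spacing, `/`)
  bm_assert(is_orthonormal(orientation, tol = 1e-5), "format",
            "NIfTI affine of %s is not rigid-plus-spacing (sheared axes)", path)
  # re-orthonormalize exactly so downstream code sees a clean rotation
  sv <- svd(orientation)
  orientation <- sv$u %*% t(sv$v)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) {
    bm_assert(all(dim(arr)[-(1:3)] == 1L), "format",
              "NIfTI volume %s has more than 3 non-trivial dimensions", path)
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  ct_volume(arr, spacing = spacing, origin = A[1:3, 4],
            orientation = orientation)
}

#' Write a volume as NIfTI-1
#'
#' Stores HU as float32 with the voxel-to-world affine in the sform/qform.
#'
#' @param vol A [ct_volume].
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$hu, datatype = "float")
  A <- structure(volume_affine(vol), code = 2L)
  img <- RNifti::`sform<-`(img, A)
  img <- RNifti::`qform<-`(img, A)
  write_atomic(path, function(tmp) RNifti::writeNifti(img, tmp))
  invisible(path)
}

raw_dtypes <- list(
  int16   = list(what = "integer", size = 2L, signed = TRUE),
  uint16  = list(what = "integer", size = 2L, signed = FALSE),
  int32   = list(what = "integer", size = 4L, signed = TRUE),
  uint8   = list(what = "integer", size = 1L, signed = FALSE),
  float32 = list(what = "double",  size = 4L, signed = TRUE),
  float64 = list(what = "double",  size = 8L, signed = TRUE)
)

read_raw_volume <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    sidecar <- path
  } else {
    sidecar <- paste0(path, ".json")
  }
  bm_assert(file.exists(sidecar), "io", "raw volume sidecar not found: %s",
            sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("dims", "spacing", "origin", "dtype")) {
    bm_assert(!is.null(meta[[field]]), "format",
              "raw sidecar %s is missing required field '%s'", sidecar, field)
  }
  data_file <- if (!is.null(meta$data)) {
    file.path(dirname(sidecar), meta$data)
  } else if (!identical(sidecar, path)) {
    path
  } else {
    sub("\\.json$", "", sidecar)
  }
  bm_assert(file.exists(data_file), "io", "raw volume data not found: %s",
            data_file)
  dt <- raw_dtypes[[meta$dtype]]
  bm_assert(!is.null(dt), "format", "unsupported raw dtype '%s'", meta$dtype)
  n <- prod(meta$dims)
  endian <- if (is.null(meta$byte_order)) "little"
  else match.arg(meta$byte_order, c("little", "big"))
  con <- file(data_file, "rb")
  on.exit(close(con))
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  bm_assert(length(vals) == n, "format",
            "raw data %s holds %d values, expected %d", data_file,
            length(vals), n)
  slope <- if (is.null(meta$rescale_slope)) 1 else meta$rescale_slope
  inter <- if (is.null(meta$rescale_intercept)) 0 else meta$rescale_intercept
  orientation <- if (is.null(meta$orientation)) diag(3)
  else matrix(as.numeric(meta$orientation), 3L, 3L)
  ct_volume(array(as.double(vals) * slope + inter, dim = meta$dims),
            spacing = meta$spacing, origin = meta$origin,
            orientation = orientation)
}

#' Write a volume as raw binary + JSON sidecar
#'
#' @param vol A [ct_volume].
#' @param path Output path for the raw data; the sidecar goes to
#'   `<path>.json`.
#' @param dtype On-disk type, `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_raw_volume <- function(vol, path, dtype = c("float32", "float64")) {
  dtype <- match.arg(dtype)
  size <- if (dtype == "float32") 4L else 8L
  write_atomic(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeBin(as.double(vol$hu), con, size = size, endian = "little")
  })
  meta <- list(dims = vol$dims, spacing = vol$spacing, origin = vol$origin,
               orientation = as.numeric(vol$orientation), dtype = dtype,
               byte_order = "little")
  write_atomic(paste0(path, ".json"), function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = FALSE, digits = NA)
  })
  invisible(path)
}
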