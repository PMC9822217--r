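# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed error so the CLI can map failures to machine-parsable classes.
# class: short token such as "io", "validation", "format", "geometry",
# "config", "solver".
bm_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("bonemapr_", class), "bonemapr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

bm_assert <- function(cond, class, fmt, ...) {
  if (!isTRUE(cond)) bm_stop(class, fmt, ...)
  invisible(TRUE)
}

# Coerce a point or set of points to an n x 3 numeric matrix.
as_points <- function(p) {
  if (is.null(dim(p))) {
    bm_assert(length(p) == 3L, "validation", "expected a length-3 point")
    p <- matrix(as.numeric(p), nrow = 1L)
  } else {
    p <- as.matrix(p)
    bm_assert(ncol(p) == 3L, "validation", "expected an n x 3 matrix of points")
    storage.mode(p) <- "double"
  }
  p
}

is_orthonormal <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) <= tol
}

# Atomic write: run `writer(tmp)` then rename onto `path`, so a failure never
# leaves a partial output behind.
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  bm_assert(dir.exists(dir), "io", "output directory does not exist: %s", dir)
  # keep the real extension so format-sniffing writers behave
  ext <- sub("^[^.]*", "", basename(path))
  tmp <- tempfile(pattern = ".partial", tmpdir = dir, fileext = ext)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    bm_stop("io", "failed to move temporary output onto %s", path)
  }
  invisible(path)
}

# Format numbers for text output without losing double precision.
fmt_num <- function(x) formatC(x, format = "g", digits = 17)
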