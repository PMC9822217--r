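# Abaqus .inp subset: *NODE, *ELEMENT (C3D4 family), *ELSET, *NSET,
# *MATERIAL/*ELASTIC/*DENSITY, *SOLID SECTION. Keyword lines are
# case-insensitive and comma-separated, ids 1-based as in the format.
# Unrecognized keyword blocks are preserved verbatim and passed through on
# write so a mapped deck stays usable downstream.

abq_keyword <- function(line) {
  toupper(trimws(strsplit(sub("^\\*", "", line), ",")[[1]][1]))
}

abq_params <- function(line) {
  parts <- trimws(strsplit(line, ",")[[1]][-1])
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=")[[1]]
    key <- toupper(trimws(kv[1]))
    out[[key]] <- if (length(kv) > 1) trimws(kv[2]) else TRUE
  }
  out
}

supported_tet_types <- c("C3D4", "C3D4H", "C3D4T", "DC3D4")

#' Read a tet4 mesh from an Abaqus input deck
#'
#' Supports the `*NODE`, `*ELEMENT` (C3D4 family only), `*ELSET`, `*NSET`,
#' `*MATERIAL`/`*ELASTIC`/`*DENSITY` and `*SOLID SECTION` keywords; any
#' other keyword block is kept verbatim in the mesh's `extra` field and
#' re-emitted on write. Material and section cards, when present, are parsed
#' into `attr(mesh, "materials")` and `attr(mesh, "sections")` so a mapped
#' deck can be re-read for verification solves.
#'
#' @param path Path to the `.inp` file.
#' @return An [fe_mesh].
#' @export
read_abaqus_inp <- function(path) {
  bm_assert(file.exists(path), "io", "mesh file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\*\\*", lines)]          # comments
  lines <- lines[nzchar(trimws(lines))]
  is_kw <- grepl("^\\*", lines)
  starts <- which(is_kw)
  bm_assert(length(starts) > 0, "format", "%s has no Abaqus keyword lines",
            path)
  nodes <- list(); node_ids <- list()
  elems <- list(); elem_ids <- list()
  elsets <- list(); nsets <- list()
  materials <- list(); sections <- list()
  extra <- character()
  ends <- c(starts[-1] - 1L, length(lines))
  current_material <- NULL
  for (b in seq_along(starts)) {
    kw_line <- lines[starts[b]]
    data <- if (ends[b] > starts[b]) lines[(starts[b] + 1L):ends[b]]
    else character()
    kw <- abq_keyword(kw_line)
    params <- abq_params(kw_line)
    if (kw == "NODE") {
      for (ln in data) {
        f <- as.numeric(strsplit(ln, ",")[[1]])
        node_ids[[length(node_ids) + 1L]] <- as.integer(f[1])
        nodes[[length(nodes) + 1L]] <- f[2:4]
      }
    } else if (kw == "ELEMENT") {
      type <- toupper(params[["TYPE"]] %||% "")
      if (!type %in% supported_tet_types) {
        bm_stop("format",
                "unsupported element type '%s' in %s (only 4-node tetrahedra %s are supported)",
                type, path, paste(supported_tet_types, collapse = "/"))
      }
      for (ln in data) {
        f <- as.integer(strsplit(ln, ",")[[1]])
        bm_assert(length(f) == 5L, "format",
                  "malformed C3D4 element line in %s: '%s'", path, ln)
        elem_ids[[length(elem_ids) + 1L]] <- f[1]
        elems[[length(elems) + 1L]] <- f[2:5]
      }
      set_name <- params[["ELSET"]]
      if (!is.null(set_name) && !isTRUE(set_name)) {
        ids <- vapply(data, function(ln)
          as.integer(strsplit(ln, ",")[[1]][1]), integer(1),
          USE.NAMES = FALSE)
        elsets[[set_name]] <- c(elsets[[set_name]], ids)
      }
    } else if (kw %in% c("ELSET", "NSET")) {
      name <- params[[kw]]
      bm_assert(is.character(name), "format",
                "%s block without a set name in %s", kw, path)
      ids <- integer()
      if (isTRUE(params[["GENERATE"]])) {
        for (ln in data) {
          f <- as.integer(strsplit(ln, ",")[[1]])
          step <- if (length(f) >= 3L && !is.na(f[3])) f[3] else 1L
          ids <- c(ids, seq.int(f[1], f[2], by = step))
        }
      } else {
        for (ln in data) {
          f <- strsplit(ln, ",")[[1]]
          f <- trimws(f)
          ids <- c(ids, as.integer(f[nzchar(f)]))
        }
      }
      if (kw == "ELSET") elsets[[name]] <- c(elsets[[name]], ids)
      else nsets[[name]] <- c(nsets[[name]], ids)
    } else if (kw == "MATERIAL") {
      current_material <- params[["NAME"]]
      materials[[current_material]] <- list()
    } else if (kw == "ELASTIC" && !is.null(current_material)) {
      f <- as.numeric(strsplit(data[1], ",")[[1]])
      materials[[current_material]]$young_modulus <- f[1]
      materials[[current_material]]$poisson_ratio <- f[2]
    } else if (kw == "DENSITY" && !is.null(current_material)) {
      materials[[current_material]]$density <-
        as.numeric(strsplit(data[1], ",")[[1]][1])
    } else if (kw == "HEADING") {
      # title block; the writer emits its own
    } else if (kw == "SOLID SECTION") {
      sections[[length(sections) + 1L]] <-
        list(elset = params[["ELSET"]], material = params[["MATERIAL"]])
    } else {
      extra <- c(extra, kw_line, data)
    }
  }
  bm_assert(length(nodes) > 0, "format", "%s contains no *NODE block", path)
  bm_assert(length(elems) > 0, "format", "%s contains no *ELEMENT block", path)
  mesh <- fe_mesh(do.call(rbind, nodes), do.call(rbind, elems),
                  node_ids = unlist(node_ids), elem_ids = unlist(elem_ids),
                  elsets = elsets, nsets = nsets, extra = extra)
  attr(mesh, "materials") <- materials
  attr(mesh, "sections") <- sections
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_id_lines <- function(ids, per_line = 16L) {
  n <- length(ids)
  vapply(split(ids, ceiling(seq_len(n) / per_line)),
         paste, character(1), collapse = ", ", USE.NAMES = FALSE)
}

#' Write a tet4 mesh (optionally with mapped materials) as an Abaqus deck
#'
#' With `bins` supplied, emits one `*ELSET`, `*MATERIAL`/`*ELASTIC` (and
#' `*DENSITY`) card and `*SOLID SECTION` per non-empty material bin; every
#' element must belong to exactly one bin. Young's modulus is written in
#' MPa, density in g/cm^3. Without `bins`, only the geometry (and any
#' pass-through keyword blocks) is written.
#'
#' @param mesh An [fe_mesh].
#' @param path Output path.
#' @param assignment Optional [map_materials()] result (used for per-bin
#'   mean densities).
#' @param bins Optional list of material bins from [bin_elements()].
#' @param poisson_ratio Poisson ratio written on each `*ELASTIC` card.
#' @return `path`, invisibly.
#' @export
write_abaqus_inp <- function(mesh, path, assignment = NULL, bins = NULL,
                             poisson_ratio = 0.3) {
  out <- c("*HEADING", "Mapped bone FE model (bonemapr)")
  out <- c(out, "*NODE")
  out <- c(out, sprintf("%d, %s, %s, %s", mesh$node_ids,
                        fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                        fmt_num(mesh$nodes[, 3])))
  out <- c(out, "*ELEMENT, TYPE=C3D4")
  out <- c(out, sprintf("%d, %d, %d, %d, %d", mesh$elem_ids,
                        mesh$elements[, 1], mesh$elements[, 2],
                        mesh$elements[, 3], mesh$elements[, 4]))
  if (!is.null(bins)) {
    all_binned <- unlist(lapply(bins, function(b) b$element_ids))
    bm_assert(!anyDuplicated(all_binned), "validation",
              "element(s) assigned to more than one bin: %s",
              paste(utils::head(all_binned[duplicated(all_binned)], 10),
                    collapse = ", "))
    missing <- setdiff(mesh$elem_ids, all_binned)
    if (length(missing) > 0) {
      bm_stop("validation", "element(s) not assigned to any bin: %s",
              paste(utils::head(missing, 10), collapse = ", "))
    }
    for (b in bins) {
      nm <- sprintf("MAT_%03d", b$index)
      out <- c(out, sprintf("*ELSET, ELSET=%s", nm),
               format_id_lines(sort(b$element_ids)))
    }
    for (b in bins) {
      nm <- sprintf("MAT_%03d", b$index)
      out <- c(out, sprintf("*SOLID SECTION, ELSET=%s, MATERIAL=%s", nm, nm))
    }
    for (b in bins) {
      nm <- sprintf("MAT_%03d", b$index)
      out <- c(out, sprintf("*MATERIAL, NAME=%s", nm), "*ELASTIC",
               sprintf("%s, %s", fmt_num(b$representative_modulus),
                       fmt_num(poisson_ratio)))
      if (!is.null(assignment)) {
        rho <- mean(assignment$rho[match(b$element_ids, assignment$eid)])
        out <- c(out, "*DENSITY", fmt_num(rho))
      }
    }
  }
  if (length(mesh$extra) > 0) out <- c(out, mesh$extra)
  write_atomic(path, function(tmp) writeLines(out, tmp))
  invisible(path)
}
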