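# STL / PLY mesh I/O.
#
# STL (ASCII and binary) stores free-standing triangles; shared vertices are
# rebuilt by exact coordinate matching on read. PLY (ASCII) keeps indexed
# faces and can carry boolean per-face label properties, the primary channel
# for exporting triangle classifications. STL labels travel in a sidecar CSV
# keyed by face index.

#' Read a surface mesh (STL or PLY)
#'
#' Dispatches on file extension. Degenerate (zero-area) faces are dropped with
#' a message rather than erroring, since screened-Poisson reconstructions
#' often carry slivers. PLY integer/uchar face properties are restored as
#' boolean labels.
#'
#' @param path mesh file (`.stl` ASCII or binary, `.ply` ASCII).
#' @param compartment compartment tag for the resulting mesh.
#' @param labels_csv optional sidecar CSV of per-face labels (column
#'   `triangle` plus one column per label), used with STL.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, compartment = "OMM", labels_csv = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    abort(paste0("unsupported mesh format: .", ext))
  )
  if (nrow(m$faces) == 0) abort("mesh file contains no faces")
  mesh <- triangle_mesh(m$vertices, m$faces, compartment = compartment,
                        labels = m$labels %||% list(), drop_degenerate = TRUE)
  if (!is.null(labels_csv)) {
    lab <- readr::read_csv(labels_csv, show_col_types = FALSE, progress = FALSE)
    for (nm in setdiff(names(lab), "triangle")) {
      v <- logical(n_triangles(mesh))
      v[lab$triangle] <- as.logical(lab[[nm]])
      mesh <- mesh_set_label(mesh, nm, v)
    }
  }
  mesh
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  ntri_guess <- readBin(con, "integer", 1, size = 4, endian = "little")
  close(con)
  sz <- file.info(path)$size
  is_binary <- length(ntri_guess) == 1 && !is.na(ntri_guess) &&
    sz == 84 + 50 * as.numeric(ntri_guess)
  if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vlines)) return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  nums <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  stl_index(nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", 50 * ntri)
  m <- matrix(rec, nrow = 50)
  floats <- matrix(readBin(as.raw(m[1:48, ]), "numeric", size = 4,
                           n = 12L * ntri, endian = "little"),
                   ncol = 12, byrow = TRUE)
  verts <- rbind(floats[, 4:6, drop = FALSE], floats[, 7:9, drop = FALSE],
                 floats[, 10:12, drop = FALSE])
  # interleave back to per-triangle order
  ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3)))
  stl_index(verts[ord, , drop = FALSE])
}

# collapse duplicated vertices, build faces from consecutive triplets
stl_index <- function(verts) {
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = uverts, faces = faces)
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a [triangle_mesh()].
#' @param path output `.stl` path.
#' @param labels_csv optional path; when given, per-triangle labels are
#'   written there as a sidecar CSV (STL itself cannot carry them).
#' @return The path, invisibly.
#' @export
write_mesh_stl <- function(mesh, path, labels_csv = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- mesh$normals
  fmt <- function(m) apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 9), collapse = " "))
  out <- c(sprintf("solid %s", mesh$compartment))
  blocks <- sprintf(
    "facet normal %s\n  outer loop\n    vertex %s\n    vertex %s\n    vertex %s\n  endloop\nendfacet",
    fmt(n), fmt(v[f[, 1], , drop = FALSE]), fmt(v[f[, 2], , drop = FALSE]),
    fmt(v[f[, 3], , drop = FALSE])
  )
  writeLines(c(out, blocks, sprintf("endsolid %s", mesh$compartment)), path)
  if (!is.null(labels_csv) && length(mesh$labels)) {
    lab <- tibble(triangle = seq_len(n_triangles(mesh)))
    for (nm in names(mesh$labels)) lab[[nm]] <- mesh$labels[[nm]]
    readr::write_csv(lab, labels_csv, progress = FALSE)
  }
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) abort("not a PLY file")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) abort("PLY header not terminated")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format ascii", hdr))) abort("only ASCII PLY is supported")

  elems <- list()
  cur <- NULL
  for (l in hdr) {
    p <- strsplit(l, "\\s+")[[1]]
    if (p[1] == "element") {
      cur <- p[2]
      elems[[cur]] <- list(count = as.integer(p[3]), props = list())
    } else if (p[1] == "property" && !is.null(cur)) {
      if (p[2] == "list") {
        elems[[cur]]$props <- c(elems[[cur]]$props,
                                list(list(name = p[5], list = TRUE)))
      } else {
        elems[[cur]]$props <- c(elems[[cur]]$props,
                                list(list(name = p[3], list = FALSE, type = p[2])))
      }
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face)) {
    abort("PLY must contain vertex and face elements")
  }

  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  nv <- elems$vertex$count
  nf <- elems$face$count
  if (length(body) < nv + nf) abort("PLY body shorter than declared")

  vprops <- vapply(elems$vertex$props, `[[`, "", "name")
  vdat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                as.numeric))
  vertices <- vdat[, match(c("x", "y", "z"), vprops), drop = FALSE]

  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  fprops <- elems$face$props
  faces <- matrix(0L, nf, 3)
  extra_names <- vapply(Filter(function(p) !p$list, fprops), `[[`, "", "name")
  extras <- matrix(NA_real_, nf, length(extra_names))
  for (i in seq_len(nf)) {
    row <- as.numeric(fl[[i]])
    cnt <- row[1]
    if (cnt != 3) abort("only triangular PLY faces are supported")
    faces[i, ] <- row[2:4] + 1L
    if (length(extra_names)) extras[i, ] <- row[5:(4 + length(extra_names))]
  }
  labels <- list()
  for (j in seq_along(extra_names)) labels[[extra_names[j]]] <- extras[, j] != 0
  list(vertices = vertices, faces = faces, labels = labels)
}

#' Write a mesh as ASCII PLY with per-face label properties
#'
#' Boolean per-triangle labels are written as `uchar` face properties and
#' restored verbatim by [read_mesh()].
#'
#' @param mesh a [triangle_mesh()].
#' @param path output `.ply` path.
#' @return The path, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  lab <- mesh$labels
  hdr <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    sprintf("property uchar %s", names(lab)),
    "end_header"
  )
  vrows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 9), collapse = " "))
  frows <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  for (nm in names(lab)) frows <- paste(frows, as.integer(lab[[nm]]))
  writeLines(c(hdr, vrows, frows), path)
  invisible(path)
}
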