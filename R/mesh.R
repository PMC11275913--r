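#' Triangle mesh of a membrane compartment
#'
#' Container for a membrane surface reconstruction: vertex coordinates in
#' Angstrom, faces as 1-based vertex-index triplets, plus derived per-triangle
#' centroids, areas and unit normals. Meshes carry a compartment tag
#' (`"OMM"`, `"IMM"`, `"ER"`, ...) and named boolean per-triangle labels used
#' by the patch and overlap analyses.
#'
#' @param vertices numeric matrix (n x 3), Angstrom.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param compartment compartment tag, e.g. `"OMM"` or `"IMM"`.
#' @param labels named list of logical vectors, one value per triangle.
#' @param drop_degenerate drop zero-area faces (with a message) instead of
#'   erroring; surface reconstructions often carry sliver triangles.
#'
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `centroids`, `areas`, `normals`, `compartment`, `labels`.
#' @export
triangle_mesh <- function(vertices, faces, compartment = "OMM",
                          labels = list(), drop_degenerate = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    abort("vertices and faces must have 3 columns")
  }
  if (nrow(faces) == 0L) abort("mesh has no faces")
  if (any(!is.finite(vertices))) abort("vertices must be finite")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    abort("face indices out of range")
  }

  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  areas <- 0.5 * vnorm(cr)
  if (any(areas <= 0)) {
    if (!drop_degenerate) abort("mesh contains zero-area faces")
    keep <- areas > 0
    message(sum(!keep), " degenerate (zero-area) face(s) dropped")
    faces <- faces[keep, , drop = FALSE]
    labels <- lapply(labels, function(l) l[keep])
    return(triangle_mesh(vertices, faces, compartment, labels))
  }
  normals <- cr / (2 * areas)
  centroids <- (v1 + v2 + v3) / 3

  labels <- lapply(labels, function(l) {
    l <- as.logical(l)
    if (length(l) != nrow(faces)) abort("label length must equal triangle count")
    l
  })

  structure(
    list(
      vertices = vertices, faces = faces,
      centroids = centroids, areas = areas, normals = normals,
      compartment = compartment, labels = labels
    ),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh> %s: %d vertices, %d triangles, area %.4g A^2\n",
    x$compartment, nrow(x$vertices), nrow(x$faces), sum(x$areas)
  ))
  if (length(x$labels)) {
    cat("labels:",
        paste(sprintf("%s (%d)", names(x$labels),
                      vapply(x$labels, sum, integer(1))),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of triangles in a mesh
#' @param mesh a [triangle_mesh()].
#' @return Integer triangle count.
#' @export
n_triangles <- function(mesh) nrow(mesh$faces)

#' Per-triangle view of a mesh
#'
#' @param x a [triangle_mesh()].
#' @param ... unused.
#' @return A tibble with one row per triangle: id, centroid, area, normal and
#'   any boolean labels.
#' @export
tidy.triangle_mesh <- function(x, ...) {
  mesh <- x
  out <- tibble(
    triangle = seq_len(n_triangles(mesh)),
    x = mesh$centroids[, 1], y = mesh$centroids[, 2], z = mesh$centroids[, 3],
    area = mesh$areas,
    nx = mesh$normals[, 1], ny = mesh$normals[, 2], nz = mesh$normals[, 3]
  )
  for (nm in names(mesh$labels)) out[[nm]] <- mesh$labels[[nm]]
  out
}

#' Attach or replace a boolean per-triangle label
#'
#' @param mesh a [triangle_mesh()].
#' @param name label name.
#' @param values logical vector, one per triangle.
#' @return The mesh with the label set.
#' @export
mesh_set_label <- function(mesh, name, values) {
  values <- as.logical(values)
  if (length(values) != n_triangles(mesh)) {
    abort("label length must equal triangle count")
  }
  mesh$labels[[name]] <- values
  mesh
}

mesh_label <- function(mesh, label) {
  if (is.character(label)) {
    if (!label %in% names(mesh$labels)) {
      abort(paste0("mesh has no label '", label, "'"))
    }
    mesh$labels[[label]]
  } else {
    l <- as.logical(label)
    if (length(l) != n_triangles(mesh)) abort("label length must equal triangle count")
    l
  }
}

#' Signed volume enclosed by a mesh
#'
#' Positive for a closed mesh whose face winding gives outward normals;
#' used as the orientation check for synthetic scenes.
#'
#' @param mesh a [triangle_mesh()].
#' @return Signed volume in cubic Angstrom.
#' @export
mesh_signed_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  # sum of tetrahedron signed volumes against the origin
  sum(
    v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
    v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
    v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  ) / 6
}

#' Sample points uniformly by area on a mesh surface
#'
#' Faces are drawn with probability proportional to area and points placed
#' uniformly inside each face by barycentric sampling. This is the complete
#' spatial randomness (CSR) generator used by the clustering null model.
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of points.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return List with `points` (n x 3 matrix, Angstrom) and `triangle`
#'   (face index each point lies on).
#' @export
sample_on_mesh <- function(mesh, n, seed = NULL) {
  local_seed(seed, {
    if (n == 0) {
      return(list(points = matrix(numeric(0), 0, 3), triangle = integer(0)))
    }
    f <- sample.int(n_triangles(mesh), n, replace = TRUE, prob = mesh$areas)
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
    a <- mesh$vertices[mesh$faces[f, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[f, 2], , drop = FALSE]
    c_ <- mesh$vertices[mesh$faces[f, 3], , drop = FALSE]
    pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
    list(points = pts, triangle = f)
  })
}

# ---- sphere / ellipsoid generation ------------------------------------------

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c(1,  t,  0), c(-1, -t,  0), c(1, -t,  0),
    c( 0, -1,  t), c(0,  1,  t), c( 0, -1, -t), c(0,  1, -t),
    c( t,  0, -1), c(t,  0,  1), c(-t,  0, -1), c(-t, 0,  1)
  )
  v <- v / sqrt(1 + t^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

subdivide_tri <- function(v, f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * 2^26 + pmax(e[, 1], e[, 2])
  ukey <- unique(key)
  mid_id <- match(key, ukey) + nrow(v)
  ue <- e[!duplicated(key), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  v2 <- rbind(v, mids)
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  f2 <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(vertices = v2, faces = f2)
}

#' Unit icosphere
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected to the
#' unit sphere. Watertight, outward-wound.
#'
#' @param subdivisions number of 4-fold subdivision rounds (faces = 20 * 4^s).
#' @return List with `vertices`, `faces`.
#' @export
icosphere <- function(subdivisions = 3) {
  m <- icosahedron()
  for (i in seq_len(subdivisions)) {
    m <- subdivide_tri(m$vertices, m$faces)
    m$vertices <- m$vertices / vnorm(m$vertices)
  }
  # enforce outward winding (sphere is centred at the origin)
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
  cr <- cbind(
    (v2[, 2] - v1[, 2]) * (v3[, 3] - v1[, 3]) - (v2[, 3] - v1[, 3]) * (v3[, 2] - v1[, 2]),
    (v2[, 3] - v1[, 3]) * (v3[, 1] - v1[, 1]) - (v2[, 1] - v1[, 1]) * (v3[, 3] - v1[, 3]),
    (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) - (v2[, 2] - v1[, 2]) * (v3[, 1] - v1[, 1])
  )
  flip <- rowSums(cr * (v1 + v2 + v3)) < 0
  if (any(flip)) m$faces[flip, ] <- m$faces[flip, c(1, 3, 2)]
  m
}

#' Triangulated ellipsoid surface
#'
#' @param semi_axes length-3 vector of semi-axes (Angstrom).
#' @param edge_target approximate triangle edge length (Angstrom); sets the
#'   icosphere subdivision level from the largest semi-axis.
#' @param compartment compartment tag.
#' @return A [triangle_mesh()].
#' @export
ellipsoid_mesh <- function(semi_axes = c(2000, 2000, 2000), edge_target = 100,
                           compartment = "OMM") {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), edge_target > 0)
  # icosahedron edge on the unit sphere is ~1.0515; each round halves it
  lev <- max(0L, ceiling(log2(1.0515 * max(semi_axes) / edge_target)))
  s <- icosphere(lev)
  v <- sweep(s$vertices, 2, semi_axes, `*`)
  triangle_mesh(v, s$faces, compartment = compartment)
}
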