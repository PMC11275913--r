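#' Classification thresholds for membrane-associated ribosomes
#'
#' @param d_exit_max maximum peptide-exit-to-membrane distance for the
#'   import-oriented class, Angstrom (default 95; boundary inclusive).
#' @param d_near_max maximum centre-to-membrane distance for the
#'   near-but-unoriented class, Angstrom (default 250; boundary inclusive).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(d_exit_max = 95, d_near_max = 250) {
  stopifnot(d_exit_max > 0, d_near_max > 0)
  structure(list(d_exit_max = d_exit_max, d_near_max = d_near_max),
            class = "classifier_config")
}

#' Annotate particles against the outer membrane mesh
#'
#' Fills, for every particle: the nearest OMM triangle id and centre distance
#' (`d_center`), the peptide-exit distance (`d_exit`, the distance from the
#' exit-tunnel point obtained by [apply_frame_offset()] to its nearest OMM
#' triangle centroid), and the three relative angles between the particle
#' axes and the normal of the nearest triangle (degrees, in `[0, 90]`).
#' Idempotent: re-running overwrites the same columns.
#'
#' @param particles particle tibble with `x, y, z, rot, tilt, psi`.
#' @param omm OMM [triangle_mesh()].
#' @param exit_offset [frame_offset()] with role `exit_tunnel`.
#' @param invert passed to [euler_to_matrix()].
#' @return The particle tibble with columns `nearest_omm_triangle, d_center,
#'   d_exit, theta_x, theta_y, theta_z` added.
#' @export
annotate_particles <- function(particles, omm, exit_offset = default_offsets()$exit_tunnel,
                               invert = FALSE) {
  if (n_triangles(omm) == 0) abort("empty OMM mesh")
  stopifnot(inherits(exit_offset, "frame_offset"))
  if (nrow(particles) == 0) {
    particles$nearest_omm_triangle <- integer(0)
    particles$d_center <- numeric(0)
    particles$d_exit <- numeric(0)
    particles$theta_x <- particles$theta_y <- particles$theta_z <- numeric(0)
    return(particles)
  }
  near <- nearest_triangle(particles, omm, mode = "centroid")
  exit_pts <- apply_frame_offset(particles, exit_offset, invert = invert)
  near_exit <- nearest_triangle(exit_pts, omm, mode = "centroid")

  Rs <- euler_to_matrix(particles$rot, particles$tilt, particles$psi,
                        invert = invert)
  if (is.matrix(Rs)) Rs <- list(Rs)
  ang <- t(vapply(seq_len(nrow(particles)), function(i) {
    relative_angles(Rs[[i]], omm$normals[near$triangle[i], ])
  }, numeric(3)))

  particles$nearest_omm_triangle <- near$triangle
  particles$d_center <- near$distance
  particles$d_exit <- near_exit$distance
  particles$theta_x <- ang[, 1]
  particles$theta_y <- ang[, 2]
  particles$theta_z <- ang[, 3]
  particles
}

check_annotated <- function(particles) {
  need <- c("d_center", "d_exit")
  if (!all(need %in% names(particles))) {
    abort("particles must be annotated first (see annotate_particles())")
  }
}

#' Flag particles optimally oriented for protein import
#'
#' A particle is import-oriented when its peptide-exit distance is at most
#' `d_exit_max` (boundary inclusive).
#'
#' @param particles annotated particle tibble.
#' @param cfg a [classifier_config()].
#' @return Logical vector, one per particle.
#' @export
classify_import_oriented <- function(particles, cfg = classifier_config()) {
  check_annotated(particles)
  particles$d_exit <= cfg$d_exit_max
}

#' Flag particles near the membrane but not oriented for import
#'
#' A particle is near-unoriented when its centre distance is at most
#' `d_near_max` and it is not import-oriented; the two classes are disjoint
#' by construction.
#'
#' @inheritParams classify_import_oriented
#' @return Logical vector, one per particle.
#' @export
classify_near_unoriented <- function(particles, cfg = classifier_config()) {
  check_annotated(particles)
  particles$d_center <= cfg$d_near_max & !classify_import_oriented(particles, cfg)
}

#' Assign the analysis class label to every particle
#'
#' @inheritParams classify_import_oriented
#' @return The tibble with a `class_label` column
#'   (`import_oriented` / `near_unoriented` / `other`).
#' @export
classify_particles <- function(particles, cfg = classifier_config()) {
  imp <- classify_import_oriented(particles, cfg)
  near <- classify_near_unoriented(particles, cfg)
  lab <- rep("other", nrow(particles))
  lab[near] <- "near_unoriented"
  lab[imp] <- "import_oriented"
  particles$class_label <- lab
  particles
}
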