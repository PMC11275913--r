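#' Convert subtomogram Euler angles to a rotation matrix
#'
#' Default convention is intrinsic ZYZ, `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)`,
#' the common convention for the `rlnAngleRot/Tilt/Psi` columns. The matrix
#' maps particle reference-frame vectors into the tomogram frame. Because the
#' active/passive reading of the angle triplet differs between refinement
#' packages, `invert = TRUE` returns the transpose.
#'
#' @param rot,tilt,psi Euler angles in degrees (vectorized).
#' @param invert return the transposed (inverse) rotation.
#' @return A 3x3 rotation matrix, or a list of matrices for vector input.
#' @export
euler_to_matrix <- function(rot, tilt, psi, invert = FALSE) {
  n <- max(length(rot), length(tilt), length(psi))
  if (n > 1) {
    rot <- rep_len(rot, n); tilt <- rep_len(tilt, n); psi <- rep_len(psi, n)
    return(lapply(seq_len(n), function(i) {
      euler_to_matrix(rot[i], tilt[i], psi[i], invert = invert)
    }))
  }
  stopifnot(is.finite(rot), is.finite(tilt), is.finite(psi))
  R <- rot_z(rot) %*% rot_y(tilt) %*% rot_z(psi)
  if (invert) t(R) else R
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Recover ZYZ Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()] (default convention). At the gimbal lock
#' `tilt = 0` or `180`, `psi` is set to 0 and the in-plane rotation folded
#' into `rot`.
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct)
  if (abs(ct) > 1 - 1e-12) {
    rot <- if (ct > 0) atan2(R[2, 1], R[1, 1]) else atan2(-R[2, 1], -R[1, 1])
    psi <- 0
  } else {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  }
  c(rot = rot, tilt = tilt, psi = psi) * 180 / pi
}

#' Rotation matrix from axis and angle (Rodrigues)
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Images of the particle reference axes in the tomogram frame
#'
#' The three columns are the images of x, y, z under `R` — the three-colour
#' orientation arrows of subtomogram viewers.
#'
#' @param R rotation matrix from [euler_to_matrix()].
#' @return 3x3 matrix whose columns are the rotated axes.
#' @export
particle_axes <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  R
}

#' A fixed offset in the particle reference frame
#'
#' Marks a functional site on the particle — the peptide exit tunnel or the
#' mRNA entry/exit ports — as a vector from the particle centre in its
#' reference frame (Angstrom).
#'
#' @param role one of `"exit_tunnel"`, `"mrna_entry_3p"`, `"mrna_exit_5p"`.
#' @param vector length-3 numeric, Angstrom.
#' @return A `frame_offset` object.
#' @export
frame_offset <- function(role = c("exit_tunnel", "mrna_entry_3p", "mrna_exit_5p"),
                         vector) {
  role <- match.arg(role)
  vector <- as.numeric(vector)
  if (length(vector) != 3 || any(!is.finite(vector))) {
    abort("offset vector must be a finite length-3 numeric")
  }
  structure(list(role = role, vector = vector), class = "frame_offset")
}

#' Default functional-site offsets for the 80S ribosome
#'
#' Synthetic defaults (the true vectors come from masking a consensus map and
#' are a required input for real data): peptide exit tunnel 120 A below the
#' particle centre along -z; mRNA exit (5') and entry (3') ports +-105 A along
#' x, so neighbouring particles in a chain can abut port-to-port.
#'
#' @return Named list of [frame_offset()] objects.
#' @export
default_offsets <- function() {
  list(
    exit_tunnel  = frame_offset("exit_tunnel",  c(0, 0, -120)),
    mrna_exit_5p = frame_offset("mrna_exit_5p", c(105, 0, 0)),
    mrna_entry_3p = frame_offset("mrna_entry_3p", c(-105, 0, 0))
  )
}

offset_lookup <- function(offsets, role) {
  if (inherits(offsets, "frame_offset")) offsets <- list(offsets)
  for (o in offsets) {
    if (inherits(o, "frame_offset") && o$role == role) return(o)
  }
  abort(paste0("no frame_offset with role '", role, "' supplied"))
}

#' Map a particle-frame offset to tomogram coordinates for every particle
#'
#' Computes `position + R %*% offset` per particle; a rigid-body operation, so
#' every displacement has the norm of the offset vector.
#'
#' @param particles particle tibble with columns `x, y, z, rot, tilt, psi`.
#' @param offset a [frame_offset()].
#' @param invert passed to [euler_to_matrix()].
#' @return Tibble with columns `x, y, z` (Angstrom, tomogram frame), one row
#'   per particle.
#' @export
apply_frame_offset <- function(particles, offset, invert = FALSE) {
  stopifnot(inherits(offset, "frame_offset"))
  if (nrow(particles) == 0) return(tibble(x = numeric(0), y = numeric(0), z = numeric(0)))
  Rs <- euler_to_matrix(particles$rot, particles$tilt, particles$psi, invert = invert)
  if (is.matrix(Rs)) Rs <- list(Rs)
  disp <- t(vapply(Rs, function(R) as.numeric(R %*% offset$vector), numeric(3)))
  tibble(
    x = particles$x + disp[, 1],
    y = particles$y + disp[, 2],
    z = particles$z + disp[, 3]
  )
}

#' Nearest mesh triangle for a set of points
#'
#' `centroid` mode returns the triangle whose centroid is closest (a kd-tree
#' over centroids, the convention of the morphometrics distance scripts);
#' `exact_surface` returns the true point-to-surface minimum, which is never
#' larger than the centroid distance.
#'
#' @param points n x 3 matrix or a tibble with `x, y, z` columns (Angstrom).
#' @param mesh a [triangle_mesh()].
#' @param mode `"centroid"` or `"exact_surface"`.
#' @return Tibble with `triangle` (id) and `distance` (Angstrom) per point;
#'   `exact_surface` mode adds the closest surface point `cx, cy, cz`.
#' @export
nearest_triangle <- function(points, mesh, mode = c("centroid", "exact_surface")) {
  mode <- match.arg(mode)
  pts <- as_points_matrix(points)
  if (nrow(pts) == 0) {
    return(tibble(triangle = integer(0), distance = numeric(0)))
  }
  if (mode == "centroid") {
    res <- cpp_nearest_point(pts, mesh$centroids)
    tibble(triangle = res$index, distance = res$distance)
  } else {
    res <- cpp_nearest_triangle_exact(pts, mesh$vertices, mesh$faces)
    tibble(
      triangle = res$index, distance = res$distance,
      cx = res$closest[, 1], cy = res$closest[, 2], cz = res$closest[, 3]
    )
  }
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    pts <- cbind(points$x, points$y, points$z)
  } else {
    pts <- as.matrix(points)
  }
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) abort("points must have 3 columns")
  pts
}

#' Relative angles between particle axes and a surface normal
#'
#' For each of the three particle axes `v_i` (columns of `R`), the angle
#' `acos(|v_i . n|)` in degrees — folded into `[0, 90]` so the result does not
#' depend on the sign of either vector.
#'
#' @param R rotation matrix of the particle.
#' @param normal unit surface normal.
#' @return Numeric length-3 vector of angles in degrees.
#' @export
relative_angles <- function(R, normal) {
  normal <- as.numeric(normal)
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6) {
    abort("normal must be a unit vector")
  }
  d <- abs(as.numeric(crossprod(R, normal)))
  acos(pmin(1, d)) * 180 / pi
}
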