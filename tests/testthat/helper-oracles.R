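# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths: quaternion composition for rotations,
# exhaustive double loops for nearest-neighbour and pair-count queries,
# enumeration/permutation for the rank test.

# ---- quaternion oracle for ZYZ rotations ------------------------------------

quat_mul <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_about <- function(axis, deg) {
  h <- deg * pi / 360
  c(cos(h), sin(h) * axis)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

euler_zyz_quat_oracle <- function(rot, tilt, psi) {
  q <- quat_mul(quat_about(c(0, 0, 1), rot),
                quat_mul(quat_about(c(0, 1, 0), tilt),
                         quat_about(c(0, 0, 1), psi)))
  quat_to_matrix(q)
}

# ---- exhaustive nearest-site scan -------------------------------------------

brute_nearest <- function(points, sites) {
  idx <- integer(nrow(points))
  dst <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- colSums((t(sites) - points[i, ])^2)
    idx[i] <- which.min(d2)
    dst[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, distance = dst)
}

# ---- exhaustive pair counts -------------------------------------------------

brute_pair_count <- function(points, r_ang) {
  n <- nrow(points)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((points[i, ] - points[j, ])^2)) <= r_ang) cnt <- cnt + 1L
    }
  }
  cnt
}

# ---- Mann-Whitney permutation oracle ----------------------------------------

mw_perm_oracle <- function(a, b, n_perm = 4000, seed = 1) {
  set.seed(seed)
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(rank(pooled)[seq_len(na)]) - (length(pooled) + 1) / 2)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    stat <- abs(mean(rank(pooled)[idx]) - (length(pooled) + 1) / 2)
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# ---- connected components of a triangle label (shared-vertex adjacency) -----

label_components <- function(mesh, label) {
  ids <- which(label)
  if (!length(ids)) return(0L)
  f <- mesh$faces[ids, , drop = FALSE]
  comp <- rep(NA_integer_, length(ids))
  vert_owner <- list()
  for (r in seq_along(ids)) {
    for (v in f[r, ]) {
      key <- as.character(v)
      vert_owner[[key]] <- c(vert_owner[[key]], r)
    }
  }
  nc <- 0L
  for (r in seq_along(ids)) {
    if (!is.na(comp[r])) next
    nc <- nc + 1L
    queue <- r
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- nc
      for (v in f[cur, ]) {
        nb <- vert_owner[[as.character(v)]]
        queue <- c(queue, nb[is.na(comp[nb])])
      }
    }
  }
  nc
}

# ---- fixture builders -------------------------------------------------------

# flat rectangular grid mesh in the z = 0 plane, edge spacing `h`
flat_grid_mesh <- function(nx = 10, ny = 10, h = 50, compartment = "OMM") {
  gx <- seq(0, (nx - 1) * h, by = h)
  gy <- seq(0, (ny - 1) * h, by = h)
  v <- as.matrix(expand.grid(x = gx, y = gy))
  v <- cbind(v, 0)
  id <- function(i, j) (j - 1) * nx + i
  faces <- list()
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      faces[[length(faces) + 1]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
      faces[[length(faces) + 1]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
    }
  }
  triangle_mesh(v, do.call(rbind, faces), compartment = compartment)
}

# particle tibble from raw columns
make_particles <- function(pos, eulers = NULL, tomogram = "tomogram_1") {
  n <- nrow(pos)
  if (is.null(eulers)) eulers <- matrix(0, n, 3)
  tibble::tibble(
    tomogram_id = tomogram, particle_id = seq_len(n),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    rot = eulers[, 1], tilt = eulers[, 2], psi = eulers[, 3]
  )
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_matrix(q)
}
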