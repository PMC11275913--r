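# Parametric double-membrane scenes with ground truth.
#
# The generator emulates the geometry the morphometrics pipeline measures on
# real mitochondria: a closed OMM mesh, an IMM offset ~135 A inside it
# (the inner boundary membrane spacing), cristae invaginations whose necks
# put IMM triangles in the 180-300 A distance band, and optional local
# OMM-IMM constrictions. Particle placement adds ribosomes hovering above
# the OMM with controllable orientation, clustering and polysome chains.

#' Configuration for a synthetic double-membrane scene
#'
#' @param semi_axes OMM ellipsoid semi-axes, Angstrom.
#' @param mesh_edge target triangle edge length, Angstrom.
#' @param ibm_gap baseline OMM-to-IMM spacing, Angstrom (default 135, the
#'   inner-boundary-membrane distance away from cristae).
#' @param n_cristae number of cristae invaginations.
#' @param crista_neck_radius neck radius, Angstrom; the invagination's lateral
#'   influence extends to twice this radius.
#' @param crista_depth maximum inward displacement of the IMM at a crista
#'   centre, Angstrom. Must exceed 165 A for the neck to sweep the whole
#'   cristae-junction distance band.
#' @param constrictions list of local OMM-IMM constrictions, each a list with
#'   `point` (3-vector on/near the OMM), `amplitude` (A, how far the IMM is
#'   pulled toward the OMM) and `radius` (A, Gaussian falloff scale).
#' @param seed integer RNG seed for crista site placement.
#' @return A `scene_config` list.
#' @export
scene_config <- function(semi_axes = c(2000, 2000, 2000), mesh_edge = 100,
                         ibm_gap = 135, n_cristae = 0,
                         crista_neck_radius = 300, crista_depth = 600,
                         constrictions = list(), seed = NULL) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), mesh_edge > 0,
            ibm_gap > 0, n_cristae >= 0, crista_neck_radius > 0,
            crista_depth > 0)
  if (any(semi_axes <= 10 * mesh_edge)) {
    abort("semi-axes must exceed 10x the mesh edge length")
  }
  if (n_cristae > 0 && crista_depth >= min(semi_axes) - ibm_gap) {
    abort("infeasible geometry: crista_depth exceeds the available interior")
  }
  for (cs in constrictions) {
    if (!all(c("point", "amplitude", "radius") %in% names(cs))) {
      abort("each constriction needs point, amplitude, radius")
    }
    if (cs$amplitude >= ibm_gap) {
      abort("infeasible geometry: constriction amplitude >= ibm_gap")
    }
    if (cs$amplitude <= 0 || cs$radius <= 0) {
      abort("constriction amplitude and radius must be positive")
    }
  }
  structure(
    list(semi_axes = semi_axes, mesh_edge = mesh_edge, ibm_gap = ibm_gap,
         n_cristae = n_cristae, crista_neck_radius = crista_neck_radius,
         crista_depth = crista_depth, constrictions = constrictions,
         seed = seed),
    class = "scene_config"
  )
}

# unit-sphere direction -> point on the IMM base surface (offset ibm_gap
# inward from the OMM along the ellipsoid normal)
imm_base_point <- function(u, semi_axes, gap) {
  p <- sweep(u, 2, semi_axes, `*`)
  nrm <- unitize(sweep(u, 2, semi_axes, `/`))
  p - gap * nrm
}

#' Generate a synthetic double-membrane scene
#'
#' Builds watertight, outward-wound OMM and IMM meshes. The IMM sits
#' `ibm_gap` inside the OMM along the surface normal; cristae displace IMM
#' vertices inward with a smooth cosine-cap profile (their necks sweep the
#' 180-300 A cristae-junction band), and constrictions displace IMM vertices
#' toward the OMM with a Gaussian falloff.
#'
#' @param config a [scene_config()].
#' @return List with `omm` and `imm` ([triangle_mesh()]) and `truth`, a list
#'   recording crista sites and constriction sites.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  lev <- max(0L, ceiling(log2(1.0515 * max(config$semi_axes) / config$mesh_edge)))
  sph <- icosphere(lev)
  u <- sph$vertices
  omm_v <- sweep(u, 2, config$semi_axes, `*`)
  nrm <- unitize(sweep(u, 2, config$semi_axes, `/`))
  imm_v <- omm_v - config$ibm_gap * nrm

  # crista sites: unit directions with enough angular separation that the
  # invaginations (influence radius 2 * neck_radius) never merge, and clear
  # of any requested constriction
  crista_sites <- matrix(numeric(0), 0, 3)
  if (config$n_cristae > 0) {
    min_sep <- 5 * config$crista_neck_radius
    avoid <- do.call(rbind, lapply(config$constrictions, function(cs) {
      unitize(matrix(as.numeric(cs$point) / config$semi_axes, 1))
    }))
    crista_sites <- local_seed(config$seed, {
      pick_separated_directions(config$n_cristae, min_sep, config$semi_axes,
                                avoid = avoid, avoid_sep = min_sep)
    })
    for (i in seq_len(nrow(crista_sites))) {
      site <- imm_base_point(crista_sites[i, , drop = FALSE],
                             config$semi_axes, config$ibm_gap)
      d <- vnorm(sweep(imm_v, 2, as.numeric(site)))
      reach <- 2 * config$crista_neck_radius
      w <- ifelse(d < reach, 0.5 * (1 + cos(pi * d / reach)), 0)
      imm_v <- imm_v - (config$crista_depth * w) * nrm
    }
  }

  constr_sites <- matrix(numeric(0), 0, 3)
  for (cs in config$constrictions) {
    u_s <- as.numeric(cs$point) / config$semi_axes
    u_s <- u_s / sqrt(sum(u_s^2))
    site <- imm_base_point(matrix(u_s, 1), config$semi_axes, config$ibm_gap)
    d <- vnorm(sweep(imm_v, 2, as.numeric(site)))
    imm_v <- imm_v + (cs$amplitude * exp(-(d / cs$radius)^2)) * nrm
    constr_sites <- rbind(constr_sites, u_s * config$semi_axes)
  }

  omm <- triangle_mesh(omm_v, sph$faces, compartment = "OMM")
  imm <- triangle_mesh(imm_v, sph$faces, compartment = "IMM")
  truth <- list(
    crista_sites = sweep(crista_sites, 2, config$semi_axes, `*`),
    constriction_sites = constr_sites,
    config = config
  )
  list(omm = omm, imm = imm, truth = truth)
}

# rejection-sample unit directions with pairwise chord separation (on the
# scaled surface) above min_sep
pick_separated_directions <- function(n, min_sep, semi_axes, avoid = NULL,
                                      avoid_sep = min_sep, max_tries = 2000) {
  sites <- matrix(numeric(0), 0, 3)
  tries <- 0
  while (nrow(sites) < n && tries < max_tries) {
    tries <- tries + 1
    u <- rnorm(3)
    u <- matrix(u / sqrt(sum(u^2)), 1)
    p <- u * semi_axes
    ok <- TRUE
    if (nrow(sites) > 0) {
      ps <- sweep(sites, 2, semi_axes, `*`)
      ok <- all(vnorm(sweep(ps, 2, as.numeric(p))) > min_sep)
    }
    if (ok && !is.null(avoid) && nrow(avoid) > 0) {
      pa <- sweep(avoid, 2, semi_axes, `*`)
      ok <- all(vnorm(sweep(pa, 2, as.numeric(p))) > avoid_sep)
    }
    if (ok) sites <- rbind(sites, u)
  }
  if (nrow(sites) < n) {
    abort("could not place the requested number of separated surface sites")
  }
  sites
}

#' Configuration for particle placement on a synthetic scene
#'
#' @param n_particles total particles, including polysome chain members.
#' @param hover_height particle centre height above the OMM surface along the
#'   local normal, Angstrom.
#' @param frac_import_oriented fraction of non-chain particles whose exit
#'   tunnel faces the membrane; assignment is deterministic (first
#'   `floor(f * n)` particles) before a seeded shuffle.
#' @param cluster_process `"none"` (uniform by area) or `"thomas"`
#'   (parent-offspring clustering).
#' @param n_parents,offspring_spread Thomas-process parent count and maximum
#'   tangential offspring displacement (Angstrom; draws are Gaussian with
#'   sd = spread/2, truncated at spread).
#' @param polysome_chains list of `c(length, spacing)` pairs: chain member
#'   count and centre-to-centre spacing in Angstrom. Chain members are always
#'   import-oriented.
#' @param orientation_noise degrees; each particle is additionally rotated
#'   about a random axis by an angle uniform in `[0, orientation_noise]`.
#' @param min_separation minimum centre-to-centre distance between non-chain
#'   particles, Angstrom (0 disables the check).
#' @param seed integer RNG seed.
#' @return A `placement_config` list.
#' @export
placement_config <- function(n_particles = 100, hover_height = 150,
                             frac_import_oriented = 1,
                             cluster_process = c("none", "thomas"),
                             n_parents = 10, offspring_spread = 150,
                             polysome_chains = list(),
                             orientation_noise = 0,
                             min_separation = 0, seed = NULL) {
  cluster_process <- match.arg(cluster_process)
  stopifnot(n_particles >= 0, hover_height >= 0,
            frac_import_oriented >= 0, frac_import_oriented <= 1,
            orientation_noise >= 0, n_parents >= 1, offspring_spread >= 0,
            min_separation >= 0)
  structure(
    list(n_particles = n_particles, hover_height = hover_height,
         frac_import_oriented = frac_import_oriented,
         cluster_process = cluster_process, n_parents = n_parents,
         offspring_spread = offspring_spread,
         polysome_chains = polysome_chains,
         orientation_noise = orientation_noise,
         min_separation = min_separation, seed = seed),
    class = "placement_config"
  )
}

#' Place particles on a synthetic membrane scene
#'
#' Samples surface sites (uniform by area, Thomas clustered, or at caller
#' supplied sites), lifts particle centres `hover_height` along the local
#' normal, and orients them: import-oriented particles have the exit-tunnel
#' offset anti-parallel to the local outward normal (so the exit sits
#' `hover_height - |offset|` above the membrane), all others have it flipped
#' outward. Polysome chains walk along the surface with ports aligned
#' head-to-tail.
#'
#' @param omm OMM [triangle_mesh()].
#' @param pconfig a [placement_config()].
#' @param offsets list of [frame_offset()]s; must include `exit_tunnel`, and
#'   the two mRNA ports when chains are requested. See [default_offsets()].
#' @param sites optional k x 3 matrix of surface points; the first k
#'   non-chain particles are placed there (import-oriented first).
#' @return List with `particles` (particle tibble) and `truth` (tibble with
#'   `particle_id, true_class, parent_id, chain_id, chain_order`).
#' @export
place_particles <- function(omm, pconfig, offsets = default_offsets(),
                            sites = NULL) {
  stopifnot(inherits(pconfig, "placement_config"))
  exit_off <- offset_lookup(offsets, "exit_tunnel")

  chain_len <- vapply(pconfig$polysome_chains, function(ch) as.integer(ch[1]),
                      integer(1))
  n_chain <- sum(chain_len)
  n_free <- pconfig$n_particles - n_chain
  if (n_free < 0) abort("polysome chains exceed n_particles")

  local_seed(pconfig$seed, {
    recs <- list()

    # --- free (non-chain) particles ---
    if (n_free > 0) {
      if (pconfig$cluster_process == "thomas") {
        par_s <- sample_on_mesh(omm, pconfig$n_parents)
        parent_id <- sample.int(pconfig$n_parents, n_free, replace = TRUE)
        base <- par_s$points[parent_id, , drop = FALSE]
        disp <- tangential_displacement(base, omm, pconfig$offspring_spread)
        near <- cpp_nearest_triangle_exact(base + disp, omm$vertices, omm$faces)
        pts <- near$closest
        tri <- near$index
      } else {
        s <- sample_on_mesh(omm, n_free)
        pts <- s$points
        tri <- s$triangle
        parent_id <- rep(NA_integer_, n_free)
      }
      if (!is.null(sites)) {
        sites <- as_points_matrix(sites)
        k <- min(nrow(sites), n_free)
        near <- cpp_nearest_triangle_exact(sites[seq_len(k), , drop = FALSE],
                                           omm$vertices, omm$faces)
        pts[seq_len(k), ] <- near$closest
        tri[seq_len(k)] <- near$index
        parent_id[seq_len(k)] <- NA_integer_
      }
      if (pconfig$min_separation > 0 && n_free > 1) {
        dd <- as.matrix(stats::dist(pts))
        diag(dd) <- Inf
        if (min(dd) <= pconfig$min_separation) {
          abort("could not satisfy the minimum particle separation; reduce n_particles")
        }
      }
      n_imp <- floor(pconfig$frac_import_oriented * n_free)
      imp <- c(rep(TRUE, n_imp), rep(FALSE, n_free - n_imp))
      if (!is.null(sites)) {
        # keep the site-pinned particles import-oriented, shuffle the rest
        k <- min(nrow(sites), n_imp)
        rest <- if (n_free > k) sample(imp[(k + 1):n_free]) else logical(0)
        imp <- c(rep(TRUE, k), rest)
      } else {
        imp <- sample(imp)
      }

      normals <- omm$normals[tri, , drop = FALSE]
      for (i in seq_len(n_free)) {
        R <- orient_particle(normals[i, ], exit_off, import = imp[i],
                             noise = pconfig$orientation_noise)
        recs[[length(recs) + 1]] <- list(
          pos = pts[i, ] + pconfig$hover_height * normals[i, ],
          R = R, import = imp[i], parent = parent_id[i],
          chain = NA_integer_, order = NA_integer_
        )
      }
    }

    # --- polysome chains ---
    if (n_chain > 0) {
      exit5 <- offset_lookup(offsets, "mrna_exit_5p")
      entry3 <- offset_lookup(offsets, "mrna_entry_3p")
      w <- entry3$vector - exit5$vector
      gap_target <- function(spacing) {
        max(spacing - sqrt(sum(w[1:2]^2)), 0)
      }
      for (ci in seq_along(pconfig$polysome_chains)) {
        len <- as.integer(pconfig$polysome_chains[[ci]][1])
        spacing <- as.numeric(pconfig$polysome_chains[[ci]][2])
        start <- sample_on_mesh(omm, 1)
        p <- as.numeric(start$points[1, ])
        nrm <- as.numeric(omm$normals[start$triangle[1], ])
        tdir <- rnorm(3)
        tdir <- tdir - sum(tdir * nrm) * nrm
        tdir <- tdir / sqrt(sum(tdir^2))
        prev_exit5 <- NULL
        for (k in seq_len(len)) {
          R <- chain_orientation(tdir, nrm, w, exit_off,
                                 noise = pconfig$orientation_noise)
          pos <- p + pconfig$hover_height * nrm
          if (!is.null(prev_exit5)) {
            # pin the port gap exactly: shift the member so its 3' entry sits
            # gap_target along the walk direction from the previous 5' exit
            want <- prev_exit5 + gap_target(spacing) * tdir
            pos <- pos + (want - (pos + as.numeric(R %*% entry3$vector)))
          }
          prev_exit5 <- pos + as.numeric(R %*% exit5$vector)
          recs[[length(recs) + 1]] <- list(
            pos = pos, R = R, import = TRUE, parent = NA_integer_,
            chain = ci, order = k
          )
          if (k < len) {
            step <- p + spacing * tdir
            near <- cpp_nearest_triangle_exact(matrix(step, 1),
                                               omm$vertices, omm$faces)
            newp <- as.numeric(near$closest[1, ])
            nrm <- as.numeric(omm$normals[near$index[1], ])
            tdir <- newp - p
            tdir <- tdir - sum(tdir * nrm) * nrm
            tdir <- tdir / sqrt(sum(tdir^2))
            p <- newp
          }
        }
      }
    }

    pos <- t(vapply(recs, `[[`, numeric(3), "pos"))
    eul <- t(vapply(recs, function(r) matrix_to_euler(r$R), numeric(3)))
    n <- length(recs)
    particles <- tibble(
      tomogram_id = "tomogram_1",
      particle_id = seq_len(n),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      rot = eul[, 1], tilt = eul[, 2], psi = eul[, 3]
    )
    cls <- rep(if (pconfig$hover_height <= 250) "near_unoriented" else "other", n)
    cls[vapply(recs, `[[`, logical(1), "import")] <- "import_oriented"
    truth <- tibble(
      particle_id = seq_len(n),
      true_class = cls,
      parent_id = vapply(recs, `[[`, integer(1), "parent"),
      chain_id = vapply(recs, `[[`, integer(1), "chain"),
      chain_order = vapply(recs, `[[`, integer(1), "order")
    )
    list(particles = particles, truth = truth)
  })
}

# Gaussian tangential displacement, truncated at `spread`
tangential_displacement <- function(base, mesh, spread) {
  n <- nrow(base)
  near <- cpp_nearest_point(base, mesh$centroids)
  nrm <- mesh$normals[near$index, , drop = FALSE]
  out <- matrix(0, n, 3)
  if (spread <= 0) return(out)
  for (i in seq_len(n)) {
    repeat {
      d <- rnorm(3, sd = spread / 2)
      d <- d - sum(d * nrm[i, ]) * nrm[i, ]
      if (sqrt(sum(d^2)) <= spread) break
    }
    out[i, ] <- d
  }
  out
}

# orientation with the exit-tunnel direction anti-parallel (import) or
# parallel (non-import) to the outward normal, random spin about the normal,
# optional noise rotation
orient_particle <- function(normal, exit_off, import, noise = 0) {
  u <- exit_off$vector / sqrt(sum(exit_off$vector^2))
  target <- if (import) -normal else normal
  R0 <- rotation_between(u, target)
  spin <- axis_angle_matrix(target, runif(1, 0, 360))
  R <- spin %*% R0
  if (noise > 0) {
    ax <- rnorm(3)
    R <- axis_angle_matrix(ax, runif(1, 0, noise)) %*% R
  }
  R
}

# chain member orientation: exit tunnel down (import) and the in-plane
# component of (entry3 - exit5) mapped onto -tangent so consecutive ports
# abut. Assumes the exit-tunnel offset runs along -z of the reference frame
# (the package default); other axes lose the import-orientation guarantee.
chain_orientation <- function(tdir, normal, w, exit_off, noise = 0) {
  u <- exit_off$vector / sqrt(sum(exit_off$vector^2))
  if (max(abs(u - c(0, 0, -1))) > 1e-6) {
    warn("chain generation assumes an exit-tunnel offset along -z; chain members may not be import-oriented")
  }
  s <- pracma_cross(normal, tdir)
  # basis columns (tdir, s, normal); spin so that w's in-plane angle maps to pi
  B <- cbind(tdir, s, normal)
  alpha <- atan2(w[2], w[1])
  R <- B %*% rot_z((pi - alpha) * 180 / pi)
  if (noise > 0) {
    ax <- rnorm(3)
    R <- axis_angle_matrix(ax, runif(1, 0, noise)) %*% R
  }
  R
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# minimal rotation taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  v <- pracma_cross(a, b)
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- pracma_cross(a, c(1, 0, 0))
    if (sum(ax^2) < 1e-12) ax <- pracma_cross(a, c(0, 1, 0))
    return(axis_angle_matrix(ax, 180))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}
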