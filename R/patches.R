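# Membrane patches, cristae-junction classification, overlap fractions,
# randomized nulls and patchwise intermembrane distances.

#' Patch-analysis configuration
#'
#' @param patch_radius membrane patch radius around a seed triangle, Angstrom
#'   (default 150, the ribosome footprint radius).
#' @param cj_min,cj_max IMM-to-OMM distance band defining cristae junctions,
#'   Angstrom (defaults 180 and 300, i.e. 18-30 nm).
#' @param crista_expand expansion radius around cristae-junction-projected
#'   OMM triangles, Angstrom (default 150 = half a cristae body width).
#' @param er_contact_max membrane-contact threshold for inter-organelle
#'   proximity regions, Angstrom (default 250 = 25 nm).
#' @param random_min_sep minimum centre separation between randomized patch
#'   seeds, Angstrom (default 150).
#' @param seed RNG seed for randomized patches.
#' @return A `patch_config` list.
#' @export
patch_config <- function(patch_radius = 150, cj_min = 180, cj_max = 300,
                         crista_expand = 150, er_contact_max = 250,
                         random_min_sep = 150, seed = NULL) {
  stopifnot(patch_radius >= 0, cj_min > 0, cj_max > cj_min,
            crista_expand > 0, er_contact_max > 0, random_min_sep > 0)
  structure(
    list(patch_radius = patch_radius, cj_min = cj_min, cj_max = cj_max,
         crista_expand = crista_expand, er_contact_max = er_contact_max,
         random_min_sep = random_min_sep, seed = seed),
    class = "patch_config"
  )
}

#' Build membrane patches around seed triangles
#'
#' A patch is the seed triangle plus every triangle whose centroid lies
#' within `radius` (Euclidean) of the seed centroid.
#'
#' @param mesh a [triangle_mesh()].
#' @param seed_ids integer vector of seed triangle ids.
#' @param radius patch radius, Angstrom.
#' @return A `patch_set`: tibble with columns `seed_triangle, member`, one
#'   row per (patch, member triangle); attributes `radius` and `mesh_size`.
#' @export
build_patches <- function(mesh, seed_ids, radius) {
  seed_ids <- as.integer(seed_ids)
  if (length(seed_ids) && (min(seed_ids) < 1 || max(seed_ids) > n_triangles(mesh))) {
    abort("invalid seed triangle id")
  }
  pieces <- lapply(seed_ids, function(s) {
    d2 <- rowSums(sweep(mesh$centroids, 2, mesh$centroids[s, ])^2)
    tibble(seed_triangle = s, member = which(d2 <= radius^2))
  })
  out <- if (length(pieces)) dplyr::bind_rows(pieces) else
    tibble(seed_triangle = integer(0), member = integer(0))
  structure(out, radius = radius, mesh_size = n_triangles(mesh),
            class = c("patch_set", class(out)))
}

#' Union boolean label of a patch set
#'
#' @param patches a `patch_set` from [build_patches()] or
#'   [randomize_patches()].
#' @param n_tri triangle count of the mesh (defaults to the recorded size).
#' @return Logical vector marking every triangle belonging to any patch.
#' @export
patch_label <- function(patches, n_tri = attr(patches, "mesh_size")) {
  lab <- logical(n_tri)
  lab[patches$member] <- TRUE
  lab
}

#' Classify cristae junctions and crista-associated outer membrane
#'
#' Three derived labels: `cj_imm` marks IMM triangles whose nearest-OMM
#' centroid distance falls in the cristae-junction band (minus an optional
#' exclusion mask standing in for manual cleanup); `cj_projected_omm` marks
#' the nearest OMM triangle of each such IMM triangle; `crista_associated_omm`
#' marks OMM triangles within `crista_expand` of any projected triangle (so
#' the projection is always contained in the expansion).
#'
#' @param imm,omm IMM and OMM [triangle_mesh()]es in the same frame.
#' @param cfg a [patch_config()].
#' @param exclusion_mask optional logical vector over IMM triangles to drop
#'   from the junction band.
#' @return List of logical vectors `cj_imm` (over IMM triangles),
#'   `cj_projected_omm` and `crista_associated_omm` (over OMM triangles).
#' @export
classify_crista_associated_omm <- function(imm, omm, cfg = patch_config(),
                                           exclusion_mask = NULL) {
  if (n_triangles(imm) == 0 || n_triangles(omm) == 0) abort("empty mesh")
  near <- cpp_nearest_point(imm$centroids, omm$centroids)
  cj_imm <- near$distance >= cfg$cj_min & near$distance <= cfg$cj_max
  if (!is.null(exclusion_mask)) {
    cj_imm <- cj_imm & !mesh_label(imm, exclusion_mask)
  }
  cj_proj <- logical(n_triangles(omm))
  cj_proj[near$index[cj_imm]] <- TRUE

  crista <- logical(n_triangles(omm))
  if (any(cj_proj)) {
    nn <- cpp_nearest_point(omm$centroids,
                            omm$centroids[cj_proj, , drop = FALSE])
    crista <- nn$distance <= cfg$crista_expand
  }
  list(cj_imm = cj_imm, cj_projected_omm = cj_proj,
       crista_associated_omm = crista)
}

#' Area overlap fraction between two triangle labels
#'
#' `sum(area[a & b]) / sum(area[a])`. Undefined (NA, not 0) when label `a`
#' has zero total area.
#'
#' @param mesh a [triangle_mesh()].
#' @param label_a,label_b label names or logical vectors over triangles.
#' @return Numeric scalar in `[0, 1]`, or `NA` when undefined.
#' @export
overlap_fraction <- function(mesh, label_a, label_b) {
  a <- mesh_label(mesh, label_a)
  b <- mesh_label(mesh, label_b)
  denom <- sum(mesh$areas[a])
  if (denom <= 0) return(NA_real_)
  sum(mesh$areas[a & b]) / denom
}

#' Randomized membrane patches
#'
#' Draws `n` seed triangles (uniform over triangles, or area-weighted) whose
#' pairwise centroid separations exceed `min_center_sep`, by rejection
#' sampling with an attempt budget. The matched-count randomization used as
#' the null for overlap and patch-distance comparisons.
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of patches.
#' @param radius patch radius, Angstrom.
#' @param min_center_sep minimum pairwise seed-centroid separation, Angstrom.
#' @param seed RNG seed.
#' @param area_weighted draw seeds proportional to triangle area.
#' @param max_attempts rejection-sampling budget.
#' @return A `patch_set` (see [build_patches()]).
#' @export
randomize_patches <- function(mesh, n, radius, min_center_sep = 150,
                              seed = NULL, area_weighted = FALSE,
                              max_attempts = 200 * max(n, 1)) {
  stopifnot(n >= 0)
  if (n == 0) return(build_patches(mesh, integer(0), radius))
  local_seed(seed, {
    prob <- if (area_weighted) mesh$areas else NULL
    seeds <- integer(0)
    tries <- 0
    while (length(seeds) < n && tries < max_attempts) {
      tries <- tries + 1
      cand <- sample.int(n_triangles(mesh), 1, prob = prob)
      if (length(seeds)) {
        d <- sqrt(rowSums(sweep(mesh$centroids[seeds, , drop = FALSE], 2,
                                mesh$centroids[cand, ])^2))
        if (any(d <= min_center_sep)) next
      }
      seeds <- c(seeds, cand)
    }
    if (length(seeds) < n) {
      abort(sprintf(
        "randomize_patches placed only %d of %d patches at separation > %g A",
        length(seeds), n, min_center_sep))
    }
    build_patches(mesh, seeds, radius)
  })
}

#' Triangles of one mesh within a distance of another mesh
#'
#' Labels triangles of `mesh_a` whose nearest `mesh_b` centroid lies within
#' `threshold` — e.g. OMM regions within 25 nm of an ER membrane.
#'
#' @param mesh_a,mesh_b [triangle_mesh()]es in the same frame.
#' @param threshold contact distance, Angstrom.
#' @return Logical vector over `mesh_a` triangles.
#' @export
proximity_region <- function(mesh_a, mesh_b, threshold) {
  if (is.null(mesh_b) || n_triangles(mesh_b) == 0) {
    warn("empty reference mesh; proximity region is empty")
    return(logical(n_triangles(mesh_a)))
  }
  nn <- cpp_nearest_point(mesh_a$centroids, mesh_b$centroids)
  nn$distance <= threshold
}

#' Intermembrane distances split by patch membership
#'
#' For every OMM triangle, the distance to the nearest IMM centroid, returned
#' split into in-patch and out-of-patch groups. The two groups partition the
#' OMM exactly (their areas sum to the total OMM area).
#'
#' @param omm,imm OMM and IMM [triangle_mesh()]es.
#' @param label label name or logical vector over OMM triangles marking the
#'   patch region.
#' @return A `patch_distances` object: list with numeric vectors `in_patch`
#'   and `out_of_patch` (Angstrom), areas of both groups, and the label.
#' @export
patch_imm_distances <- function(omm, imm, label) {
  if (n_triangles(imm) == 0) abort("empty IMM mesh")
  lab <- mesh_label(omm, label)
  nn <- cpp_nearest_point(omm$centroids, imm$centroids)
  structure(
    list(
      in_patch = nn$distance[lab],
      out_of_patch = nn$distance[!lab],
      area_in = sum(omm$areas[lab]),
      area_out = sum(omm$areas[!lab]),
      label = lab
    ),
    class = "patch_distances"
  )
}

#' @export
print.patch_distances <- function(x, ...) {
  cat(sprintf(
    "<patch_distances> %d in-patch / %d out-of-patch triangles\n",
    length(x$in_patch), length(x$out_of_patch)))
  if (length(x$in_patch)) {
    cat(sprintf("  in-patch peak:     %.1f A\n", histogram_peak(x$in_patch)))
  }
  if (length(x$out_of_patch)) {
    cat(sprintf("  out-of-patch peak: %.1f A\n", histogram_peak(x$out_of_patch)))
  }
  invisible(x)
}

#' @export
tidy.patch_distances <- function(x, ...) {
  dplyr::bind_rows(
    tibble(group = "in_patch", distance = x$in_patch),
    tibble(group = "out_of_patch", distance = x$out_of_patch)
  )
}
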