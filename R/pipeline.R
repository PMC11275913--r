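# End-to-end orchestration: annotate -> classify -> patches -> clustering ->
# intermembrane distances -> polysomes, per tomogram, with per-tomogram
# failure isolation, seeding, and a JSON manifest.

#' Run configuration for the full pipeline
#'
#' Each tomogram entry is either file-based (`star`, `omm`, `imm` paths, an
#' optional `er` path, plus `voxel_size`/`units` for the STAR table) or
#' synthetic (`scene` = [scene_config()] and `placement` =
#' [placement_config()]).
#'
#' @param tomograms named list of per-tomogram input lists (see above).
#' @param out_dir output directory.
#' @param seed global RNG seed; per-tomogram seeds are derived from it.
#' @param offsets functional-site offsets, see [default_offsets()].
#' @param classifier a [classifier_config()].
#' @param patches a [patch_config()].
#' @param kripley a [k_config()].
#' @param polysomes a [polysome_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(tomograms, out_dir, seed = 1,
                       offsets = default_offsets(),
                       classifier = classifier_config(),
                       patches = patch_config(),
                       kripley = k_config(),
                       polysomes = polysome_config(offsets = offsets)) {
  if (!length(tomograms)) abort("at least one tomogram entry is required")
  if (is.null(names(tomograms)) || any(!nzchar(names(tomograms)))) {
    names(tomograms) <- paste0("tomogram_", seq_along(tomograms))
  }
  for (nm in names(tomograms)) {
    tm <- tomograms[[nm]]
    if (!is.null(tm$star)) {
      for (p in c(tm$star, tm$omm, tm$imm, tm$er)) {
        if (!file.exists(p)) abort(paste0("input path does not exist: ", p))
      }
    } else if (is.null(tm$scene) || is.null(tm$placement)) {
      abort(paste0("tomogram '", nm,
                   "' needs either file inputs or scene + placement configs"))
    }
  }
  structure(
    list(tomograms = tomograms, out_dir = out_dir, seed = seed,
         offsets = offsets, classifier = classifier, patches = patches,
         kripley = kripley, polysomes = polysomes),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields of the module configs (classifier thresholds, patch radii,
#' K radii, polysome thresholds, offset vectors) map directly onto the
#' constructor arguments of [run_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  offsets <- default_offsets()
  if (!is.null(y$offsets)) {
    for (role in names(y$offsets)) {
      offsets[[role]] <- frame_offset(role, as.numeric(y$offsets[[role]]))
    }
  }
  args <- list(
    tomograms = y$tomograms,
    out_dir = y$out_dir %||% ".",
    seed = y$seed %||% 1,
    offsets = offsets
  )
  if (!is.null(y$classifier)) args$classifier <- do.call(classifier_config, y$classifier)
  if (!is.null(y$patches)) args$patches <- do.call(patch_config, y$patches)
  if (!is.null(y$kripley)) args$kripley <- do.call(k_config, y$kripley)
  if (!is.null(y$polysomes)) {
    args$polysomes <- do.call(polysome_config, c(y$polysomes, list(offsets = offsets)))
  }
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Per tomogram: load or generate the scene, annotate and classify particles,
#' compute cristae/crista-associated labels and overlap fractions (observed
#' and randomized), K ratio curves and interval maxima per particle class,
#' patchwise intermembrane distances with histogram peaks (observed and
#' randomized), and polysome chains. Group-level Mann-Whitney summaries
#' compare per-tomogram values, never pooled triangles or particles. All
#' results land as per-tomogram CSVs plus a JSON manifest; re-running with
#' the same config reproduces every stochastic output.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  tomo_names <- names(config$tomograms)
  tomo_seeds <- config$seed * 1000L + seq_along(tomo_names)
  results <- list()
  failures <- list()

  for (ti in seq_along(tomo_names)) {
    nm <- tomo_names[ti]
    res <- tryCatch(
      run_one_tomogram(nm, config$tomograms[[nm]], config, tomo_seeds[ti], out),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[nm]] <- conditionMessage(res)
      warn(paste0("tomogram '", nm, "' failed: ", conditionMessage(res)))
    } else {
      results[[nm]] <- res
    }
  }
  if (!length(results)) abort("all tomograms failed")

  summary_tbl <- dplyr::bind_rows(lapply(results, `[[`, "summary"))
  readr::write_csv(summary_tbl, file.path(out, "tomogram_summary.csv"),
                   progress = FALSE)

  tests <- group_level_tests(summary_tbl)
  readr::write_csv(tests, file.path(out, "group_tests.csv"), progress = FALSE)

  manifest <- list(
    package = "ribosurf",
    version = as.character(utils::packageVersion("ribosurf")),
    seed = config$seed,
    tomogram_seeds = as.list(setNames(tomo_seeds, tomo_names)),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    files = c(
      unlist(lapply(results, `[[`, "files"), use.names = FALSE),
      file.path(out, "tomogram_summary.csv"),
      file.path(out, "group_tests.csv")
    ),
    failures = failures
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

run_one_tomogram <- function(nm, tm, config, seed, out) {
  if (!is.null(tm$star)) {
    particles <- read_particle_star(tm$star, voxel_size = tm$voxel_size %||% 1,
                                    units = tm$units %||% "angstrom")
    particles$tomogram_id <- nm
    omm <- read_mesh(tm$omm, compartment = "OMM")
    imm <- read_mesh(tm$imm, compartment = "IMM")
    er <- if (!is.null(tm$er)) read_mesh(tm$er, compartment = "ER") else NULL
  } else {
    sc <- tm$scene
    if (!inherits(sc, "scene_config")) sc <- do.call(scene_config, sc)
    pc <- tm$placement
    if (!inherits(pc, "placement_config")) pc <- do.call(placement_config, pc)
    sc$seed <- sc$seed %||% seed
    pc$seed <- pc$seed %||% (seed + 1L)
    scene <- generate_scene(sc)
    placed <- place_particles(scene$omm, pc, offsets = config$offsets)
    particles <- placed$particles
    particles$tomogram_id <- nm
    omm <- scene$omm
    imm <- scene$imm
    er <- NULL
  }

  particles <- particles |>
    annotate_particles(omm, offset_lookup(config$offsets, "exit_tunnel")) |>
    classify_particles(config$classifier)
  files <- write_annotations_csv(particles, out, prefix = "particles")

  crista <- classify_crista_associated_omm(imm, omm, config$patches)
  omm <- mesh_set_label(omm, "crista_associated_omm", crista$crista_associated_omm)

  classes <- list(
    import_oriented = dplyr::filter(particles, .data$class_label == "import_oriented"),
    near_unoriented = dplyr::filter(particles, .data$class_label == "near_unoriented")
  )

  summary_row <- tibble(tomogram_id = nm)
  kmax_rows <- list()
  for (cl in names(classes)) {
    tbl <- classes[[cl]]
    # membrane patches for this class
    seeds <- unique(tbl$nearest_omm_triangle)
    lab_name <- paste0(cl, "_patch")
    if (length(seeds)) {
      ps <- build_patches(omm, seeds, config$patches$patch_radius)
      omm <- mesh_set_label(omm, lab_name, patch_label(ps))
      summary_row[[paste0("overlap_", cl)]] <-
        overlap_fraction(omm, lab_name, "crista_associated_omm")
    } else {
      summary_row[[paste0("overlap_", cl)]] <- NA_real_
    }
    # clustering
    if (nrow(tbl) >= 2) {
      kcfg <- config$kripley
      kcfg$seed <- seed + 17L
      curve <- k_ratio_curve(tbl, omm, kcfg)
      p <- file.path(out, paste0("kcurve_", cl, "_", nm, ".csv"))
      readr::write_csv(tidy(curve), p, progress = FALSE)
      files <- c(files, p)
      im <- max_ratio_by_interval(curve, config$kripley$interval_width)
      kmax_rows[[cl]] <- dplyr::mutate(im, tomogram_id = nm, class_label = cl)
      sel <- dplyr::filter(im, .data$r_lo == 30)
      summary_row[[paste0("kmax30_", cl)]] <-
        if (nrow(sel)) sel$max_ratio[1] else NA_real_
    } else {
      summary_row[[paste0("kmax30_", cl)]] <- NA_real_
    }
  }
  if (length(kmax_rows)) {
    p <- file.path(out, paste0("interval_maxima_", nm, ".csv"))
    readr::write_csv(dplyr::bind_rows(kmax_rows), p, progress = FALSE)
    files <- c(files, p)
  }

  # intermembrane distances at co-translation patches + randomized null
  if ("import_oriented_patch" %in% names(omm$labels)) {
    pd <- patch_imm_distances(omm, imm, "import_oriented_patch")
    summary_row$peak_in_patch <- histogram_peak(pd$in_patch)
    summary_row$peak_out_patch <- histogram_peak(pd$out_of_patch)
    summary_row$peak_all <- histogram_peak(c(pd$in_patch, pd$out_of_patch))
    n_patch <- length(unique(classes$import_oriented$nearest_omm_triangle))
    rnd <- randomize_patches(omm, n_patch, config$patches$patch_radius,
                             config$patches$random_min_sep, seed = seed + 31L)
    pd_r <- patch_imm_distances(omm, imm, patch_label(rnd))
    summary_row$peak_random_patch <- histogram_peak(pd_r$in_patch)
    summary_row$overlap_random <- overlap_fraction(omm, patch_label(rnd),
                                                   "crista_associated_omm")
    p <- file.path(out, paste0("patch_distances_", nm, ".csv"))
    readr::write_csv(tidy(pd), p, progress = FALSE)
    files <- c(files, p)
  }

  # ER contact regions, when an ER mesh is present
  if (!is.null(er)) {
    summary_row$er_contact_area <- sum(
      omm$areas[proximity_region(omm, er, config$patches$er_contact_max)])
  }

  # polysomes among import-oriented particles
  poly <- find_polysomes(classes$import_oriented, config$polysomes)
  summary_row$n_chains <- nrow(poly$metrics)
  p <- file.path(out, paste0("polysomes_", nm, ".csv"))
  readr::write_csv(poly$metrics, p, progress = FALSE)
  files <- c(files, p)

  list(summary = summary_row, files = files)
}

group_level_tests <- function(s) {
  rows <- list()
  add <- function(name, a, b) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) && length(b)) {
      mw <- mann_whitney(a, b)
      rows[[length(rows) + 1]] <<- tibble(
        comparison = name, n_a = length(a), n_b = length(b),
        u = mw$u, p_value = mw$p_value
      )
    }
  }
  if (all(c("kmax30_import_oriented", "kmax30_near_unoriented") %in% names(s))) {
    add("kmax30 import vs near", s$kmax30_import_oriented, s$kmax30_near_unoriented)
  }
  if (all(c("overlap_import_oriented", "overlap_near_unoriented") %in% names(s))) {
    add("overlap import vs near", s$overlap_import_oriented, s$overlap_near_unoriented)
  }
  if (all(c("overlap_import_oriented", "overlap_random") %in% names(s))) {
    add("overlap import vs random", s$overlap_import_oriented, s$overlap_random)
  }
  if (all(c("peak_in_patch", "peak_out_patch") %in% names(s))) {
    add("intermembrane peak in vs out of patch", s$peak_in_patch, s$peak_out_patch)
  }
  if (all(c("peak_in_patch", "peak_random_patch") %in% names(s))) {
    add("intermembrane peak in vs randomized patch", s$peak_in_patch,
        s$peak_random_patch)
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble(comparison = character(0), n_a = integer(0), n_b = integer(0),
           u = numeric(0), p_value = numeric(0))
}
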