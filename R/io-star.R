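# STAR-dialect particle tables.
#
# A minimal reader/writer for the loop_ table dialect used by subtomogram
# refinement packages: one data block, one loop, _rln-prefixed column names.
# All public coordinates are Angstrom; voxel-unit files are scaled on read by
# the (mandatory, never guessed) voxel size.

# internal column map: STAR name <-> tibble name
star_column_map <- function() {
  tibble(
    star = c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
             "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
             "rsNearestTriangle", "rsDistCenter", "rsDistExit",
             "rsAngleX", "rsAngleY", "rsAngleZ", "rsClassLabel"),
    name = c("x", "y", "z", "rot", "tilt", "psi",
             "nearest_omm_triangle", "d_center", "d_exit",
             "theta_x", "theta_y", "theta_z", "class_label"),
    numeric = c(rep(TRUE, 12), FALSE)
  )
}

#' Read a particle table from a STAR file
#'
#' Parses the first `loop_` block containing the six required columns
#' (`rlnCoordinateX/Y/Z`, `rlnAngleRot/Tilt/Psi`). Tomogram identity is read
#' from `rlnMicrographName`, with `rlnTomoName` as fallback; if neither is
#' present all particles are assigned `"tomogram_1"`. Annotation columns
#' written by [write_particle_star()] are restored when present.
#'
#' @param path STAR file path.
#' @param voxel_size Angstrom per voxel (e.g. 9.98); used when
#'   `units = "voxels"`.
#' @param units `"angstrom"` (coordinates passed through) or `"voxels"`
#'   (coordinates multiplied by `voxel_size`).
#' @return A particle tibble with columns `tomogram_id, particle_id, x, y, z`
#'   (Angstrom), `rot, tilt, psi` (degrees) and any annotation columns.
#' @export
read_particle_star <- function(path, voxel_size = 1,
                               units = c("angstrom", "voxels")) {
  units <- match.arg(units)
  stopifnot(voxel_size > 0)
  lines <- readLines(path, warn = FALSE)
  blk <- parse_star_loop(lines)
  cols <- blk$columns
  required <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
                "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")
  missing <- setdiff(required, cols)
  if (length(missing)) {
    abort(paste0("STAR file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  rows <- blk$rows
  n <- length(rows)
  cells <- if (n) do.call(rbind, strsplit(trimws(rows), "\\s+")) else
    matrix(character(0), 0, length(cols))
  if (n && ncol(cells) != length(cols)) {
    abort("STAR rows do not match the declared column count")
  }

  get_num <- function(star_name) {
    if (!star_name %in% cols) return(NULL)
    v <- suppressWarnings(as.numeric(cells[, match(star_name, cols)]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(paste0("non-numeric value in column ", star_name,
                   " at data row ", bad[1]))
    }
    v
  }

  tomo <- if ("rlnMicrographName" %in% cols) {
    cells[, match("rlnMicrographName", cols)]
  } else if ("rlnTomoName" %in% cols) {
    cells[, match("rlnTomoName", cols)]
  } else {
    rep("tomogram_1", n)
  }

  scale <- if (units == "voxels") voxel_size else 1
  out <- tibble(
    tomogram_id = as.character(tomo),
    particle_id = seq_len(n),
    x = (get_num("rlnCoordinateX") %||% numeric(0)) * scale,
    y = (get_num("rlnCoordinateY") %||% numeric(0)) * scale,
    z = (get_num("rlnCoordinateZ") %||% numeric(0)) * scale,
    rot = get_num("rlnAngleRot") %||% numeric(0),
    tilt = get_num("rlnAngleTilt") %||% numeric(0),
    psi = get_num("rlnAnglePsi") %||% numeric(0)
  )
  map <- star_column_map()
  extras <- map[!map$star %in% required & map$star %in% cols, ]
  for (i in seq_len(nrow(extras))) {
    col <- extras$star[i]
    out[[extras$name[i]]] <- if (extras$numeric[i]) get_num(col) else
      cells[, match(col, cols)]
  }
  if ("nearest_omm_triangle" %in% names(out)) {
    out$nearest_omm_triangle <- as.integer(out$nearest_omm_triangle)
  }
  out
}

parse_star_loop <- function(lines) {
  lines <- sub("#.*$", "", lines)  # strip trailing comments outside loops is safe here
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      cols <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        nm <- sub("^\\s*_(\\S+).*$", "\\1", lines[j])
        cols <- c(cols, nm)
        j <- j + 1L
      }
      k <- j
      rows <- character(0)
      while (k <= n && !grepl("^\\s*$", lines[k]) &&
             !grepl("^\\s*(data_|loop_)", lines[k])) {
        rows <- c(rows, lines[k])
        k <- k + 1L
      }
      return(list(columns = cols, rows = rows))
    }
    i <- i + 1L
  }
  abort("no loop_ block found in STAR file")
}

#' Write a particle table as a STAR file
#'
#' Inverse of [read_particle_star()]: annotation columns are written under
#' documented `rs*` names and survive a round trip.
#'
#' @param particles particle tibble (see [read_particle_star()]).
#' @param path output path.
#' @param voxel_size Angstrom per voxel, used when `units = "voxels"`.
#' @param units write coordinates in `"angstrom"` or `"voxels"`.
#' @return The path, invisibly.
#' @export
write_particle_star <- function(particles, path, voxel_size = 1,
                                units = c("angstrom", "voxels")) {
  units <- match.arg(units)
  stopifnot(voxel_size > 0)
  scale <- if (units == "voxels") voxel_size else 1
  map <- star_column_map()
  present <- map[map$name %in% names(particles), ]
  header <- c("", "data_particles", "", "loop_")
  star_cols <- c(present$star, "rlnMicrographName")
  header <- c(header, sprintf("_%s #%d", star_cols, seq_along(star_cols)))
  fmt_num <- function(v) formatC(v, format = "g", digits = 15)
  cols <- lapply(seq_len(nrow(present)), function(i) {
    v <- particles[[present$name[i]]]
    if (present$name[i] %in% c("x", "y", "z")) v <- v / scale
    if (present$numeric[i]) fmt_num(as.numeric(v)) else as.character(v)
  })
  cols <- c(cols, list(as.character(particles$tomogram_id %||%
                                      rep("tomogram_1", nrow(particles)))))
  rows <- if (nrow(particles)) do.call(paste, c(cols, sep = "\t")) else character(0)
  writeLines(c(header, rows, ""), path)
  invisible(path)
}

#' Write per-tomogram annotation CSV files
#'
#' One CSV per tomogram with a stable column order, the per-tomogram record
#' the downstream statistics read.
#'
#' @param records tibble with a `tomogram_id` column (particle annotations or
#'   per-triangle records).
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; files are `<prefix>_<tomogram_id>.csv`.
#' @return Character vector of written paths, invisibly.
#' @export
write_annotations_csv <- function(records, dir, prefix = "annotations") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!"tomogram_id" %in% names(records)) {
    records$tomogram_id <- "tomogram_1"
  }
  ids <- unique(records$tomogram_id)
  paths <- character(0)
  for (id in ids) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", id)
    p <- file.path(dir, paste0(prefix, "_", safe, ".csv"))
    readr::write_csv(dplyr::filter(records, .data$tomogram_id == id), p,
                     progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
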