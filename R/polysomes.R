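# Polysome detection from mRNA entry/exit port geometry.

#' Polysome linking configuration
#'
#' @param nn_max maximum centre-to-centre distance between neighbouring
#'   ribosomes, Angstrom (default 300 = 30 nm).
#' @param adj_max maximum 5' exit to 3' entry port gap for "directly
#'   adjacent" ports, Angstrom (default 60, about three marker-sphere radii;
#'   the original judgement was visual, so this is explicit and reported).
#' @param offsets list of [frame_offset()]s including `mrna_exit_5p` and
#'   `mrna_entry_3p`.
#' @return A `polysome_config` list.
#' @export
polysome_config <- function(nn_max = 300, adj_max = 60,
                            offsets = default_offsets()) {
  stopifnot(nn_max > adj_max, adj_max > 0)
  # fail fast if the port roles are missing
  offset_lookup(offsets, "mrna_exit_5p")
  offset_lookup(offsets, "mrna_entry_3p")
  structure(list(nn_max = nn_max, adj_max = adj_max, offsets = offsets),
            class = "polysome_config")
}

#' Compute mRNA entry/exit port coordinates per particle
#'
#' Rigid-body mapping of the two port offsets into the tomogram frame; the
#' port pair of every particle keeps the reference-frame pair distance.
#'
#' @param particles particle tibble with `x, y, z, rot, tilt, psi`.
#' @param cfg a [polysome_config()].
#' @param invert passed to [euler_to_matrix()].
#' @return The tibble with columns `exit5_x/y/z` and `entry3_x/y/z` added.
#' @export
compute_ports <- function(particles, cfg = polysome_config(), invert = FALSE) {
  ex <- apply_frame_offset(particles, offset_lookup(cfg$offsets, "mrna_exit_5p"),
                           invert = invert)
  en <- apply_frame_offset(particles, offset_lookup(cfg$offsets, "mrna_entry_3p"),
                           invert = invert)
  particles$exit5_x <- ex$x; particles$exit5_y <- ex$y; particles$exit5_z <- ex$z
  particles$entry3_x <- en$x; particles$entry3_y <- en$y; particles$entry3_z <- en$z
  particles
}

#' Link particles into polysome chains
#'
#' A directed candidate edge i -> j exists when the centre distance is at
#' most `nn_max` and the 5' exit port of i lies within `adj_max` of the 3'
#' entry port of j. Edges are accepted in order of increasing port gap,
#' subject to in-degree and out-degree at most 1 and no cycles (so a cycle is
#' broken at its largest port gap); chains are the resulting maximal simple
#' paths with at least two members, ordered 5'-most first.
#'
#' @param particles tibble from [compute_ports()].
#' @param cfg a [polysome_config()].
#' @return A `polysome_chains` tibble: `chain_id, chain_order, particle_id`
#'   plus the member port coordinates.
#' @export
link_chains <- function(particles, cfg = polysome_config()) {
  need <- c("exit5_x", "entry3_x")
  if (!all(need %in% names(particles))) {
    abort("particles lack port coordinates; run compute_ports() first")
  }
  n <- nrow(particles)
  empty <- tibble(chain_id = integer(0), chain_order = integer(0),
                  particle_id = particles$particle_id[0])
  if (n < 2) return(structure(empty, class = c("polysome_chains", class(empty))))

  pos <- cbind(particles$x, particles$y, particles$z)
  ex <- cbind(particles$exit5_x, particles$exit5_y, particles$exit5_z)
  en <- cbind(particles$entry3_x, particles$entry3_y, particles$entry3_z)

  cd <- as.matrix(stats::dist(pos))
  adj <- cd <= cfg$nn_max
  diag(adj) <- FALSE
  edges <- which(adj, arr.ind = TRUE)
  if (nrow(edges)) {
    gap <- sqrt(rowSums((ex[edges[, 1], , drop = FALSE] -
                         en[edges[, 2], , drop = FALSE])^2))
    keep <- gap <= cfg$adj_max
    edges <- edges[keep, , drop = FALSE]
    gap <- gap[keep]
  } else {
    gap <- numeric(0)
  }
  if (!nrow(edges)) {
    return(structure(empty, class = c("polysome_chains", class(empty))))
  }

  ord <- order(gap)
  succ <- rep(NA_integer_, n)
  pred <- rep(NA_integer_, n)
  comp <- seq_len(n)  # union-find to veto cycles
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (e in ord) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if (!is.na(succ[i]) || !is.na(pred[j])) next
    ri <- find(i); rj <- find(j)
    if (ri == rj) next  # would close a cycle: drop this (largest-gap) edge
    succ[i] <- j
    pred[j] <- i
    comp[ri] <- rj
  }

  heads <- which(!is.na(succ) & is.na(pred))
  rows <- list()
  cid <- 0L
  for (h in heads) {
    cid <- cid + 1L
    k <- h
    ordr <- 0L
    while (!is.na(k)) {
      ordr <- ordr + 1L
      rows[[length(rows) + 1]] <- tibble(
        chain_id = cid, chain_order = ordr,
        particle_id = particles$particle_id[k],
        x = pos[k, 1], y = pos[k, 2], z = pos[k, 3],
        exit5_x = ex[k, 1], exit5_y = ex[k, 2], exit5_z = ex[k, 3],
        entry3_x = en[k, 1], entry3_y = en[k, 2], entry3_z = en[k, 3]
      )
      k <- succ[k]
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("polysome_chains", class(out)))
}

#' Per-chain mRNA path metrics
#'
#' `path_length` is the length of the putative mRNA polyline from the 5' exit
#' of the first member to the 3' entry of the last: the rods connecting each
#' member's 5' exit to the next member's 3' entry, plus the within-member
#' traverse between the two ports of every interior member (zero whenever
#' consecutive ports coincide). `end_to_end` is the straight-line distance
#' between the terminal ports, so `path_length >= end_to_end` always. Both
#' are emitted because an end-to-end measurement admits either reading.
#'
#' @param chains a `polysome_chains` tibble from [link_chains()].
#' @return Tibble with one row per chain: `chain_id, n_members, path_length,
#'   end_to_end` (Angstrom).
#' @export
chain_metrics <- function(chains) {
  if (!nrow(chains)) {
    return(tibble(chain_id = integer(0), n_members = integer(0),
                  path_length = numeric(0), end_to_end = numeric(0)))
  }
  chains |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::arrange(.data$chain_order, .by_group = TRUE) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      path_length = {
        k <- dplyr::n()
        if (k < 2) abort("chains must have at least 2 members")
        # polyline exit5(1), entry3(2), exit5(2), ..., entry3(k)
        px <- as.numeric(rbind(.data$entry3_x, .data$exit5_x))[2:(2 * k - 1)]
        py <- as.numeric(rbind(.data$entry3_y, .data$exit5_y))[2:(2 * k - 1)]
        pz <- as.numeric(rbind(.data$entry3_z, .data$exit5_z))[2:(2 * k - 1)]
        sum(sqrt(diff(px)^2 + diff(py)^2 + diff(pz)^2))
      },
      end_to_end = sqrt(
        (.data$entry3_x[dplyr::n()] - .data$exit5_x[1])^2 +
        (.data$entry3_y[dplyr::n()] - .data$exit5_y[1])^2 +
        (.data$entry3_z[dplyr::n()] - .data$exit5_z[1])^2
      ),
      .groups = "drop"
    )
}

#' Detect polysomes among particles
#'
#' Convenience wrapper: [compute_ports()], [link_chains()] and
#' [chain_metrics()] in one call.
#'
#' @param particles particle tibble.
#' @param cfg a [polysome_config()].
#' @param invert passed to [euler_to_matrix()].
#' @return List with `chains` (member table) and `metrics` (per-chain table).
#' @export
find_polysomes <- function(particles, cfg = polysome_config(), invert = FALSE) {
  chains <- link_chains(compute_ports(particles, cfg, invert = invert), cfg)
  list(chains = chains, metrics = chain_metrics(chains))
}
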