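# Second-order clustering statistics on the membrane: Ripley's K ratio
# against a Monte Carlo CSR null, interval maxima, histogram-peak summaries
# and the nonparametric group comparison.

#' Ripley's K analysis configuration
#'
#' @param r_min,r_max radius range in nm (defaults 27 and 166).
#' @param r_step radius grid step, nm.
#' @param interval_width summary interval width, nm (default 10).
#' @param n_null number of CSR null replicates.
#' @param seed RNG seed for the null placements.
#' @return A `k_config` list.
#' @export
k_config <- function(r_min = 27, r_max = 166, r_step = 1,
                     interval_width = 10, n_null = 20, seed = NULL) {
  stopifnot(r_min > 0, r_max > r_min, r_step > 0, interval_width > 0,
            n_null >= 1)
  structure(list(r_min = r_min, r_max = r_max, r_step = r_step,
                 interval_width = interval_width, n_null = n_null,
                 seed = seed),
            class = "k_config")
}

# mean pair count within each radius (radii in Angstrom): (2/n) * #pairs
mean_pair_counts <- function(points, radii_ang) {
  n <- nrow(points)
  d <- sort(as.numeric(stats::dist(points)))
  counts <- findInterval(radii_ang, d)
  2 * counts / n
}

#' Ripley's K ratio curve against a CSR null on the membrane
#'
#' `K_obs(r)` is the mean pair count within `r` over the observed points;
#' `K_csr(r)` is the same statistic averaged over `n_null` placements of
#' equally many points uniformly by area on the domain mesh. Because both
#' are computed at equal n on the identical domain, intensity and
#' edge-correction factors cancel in the ratio, whose CSR value is 1.
#'
#' @param points n x 3 matrix or tibble with `x, y, z` (Angstrom); needs
#'   at least 2 points.
#' @param domain_mesh the membrane [triangle_mesh()] carrying the points.
#' @param cfg a [k_config()].
#' @return A `k_curve` object: tibble with `r` (nm), `k_obs`, `k_csr`,
#'   `ratio` (NA where the null count is zero); attributes record `n_points`,
#'   `n_null` and the seed.
#' @export
k_ratio_curve <- function(points, domain_mesh, cfg = k_config()) {
  pts <- as_points_matrix(points)
  if (nrow(pts) < 2) abort("need at least 2 points for a K curve")
  if (n_triangles(domain_mesh) == 0) abort("empty domain mesh")
  radii <- seq(cfg$r_min, cfg$r_max, by = cfg$r_step)
  radii_ang <- radii * 10
  k_obs <- mean_pair_counts(pts, radii_ang)
  null_sum <- numeric(length(radii))
  local_seed(cfg$seed, {
    for (i in seq_len(cfg$n_null)) {
      s <- sample_on_mesh(domain_mesh, nrow(pts))
      null_sum <- null_sum + mean_pair_counts(s$points, radii_ang)
    }
  })
  k_csr <- null_sum / cfg$n_null
  ratio <- ifelse(k_csr > 0, k_obs / k_csr, NA_real_)
  out <- tibble(r = radii, k_obs = k_obs, k_csr = k_csr, ratio = ratio)
  structure(out, n_points = nrow(pts), n_null = cfg$n_null, seed = cfg$seed,
            class = c("k_curve", class(out)))
}

#' Per-interval maxima of a K ratio curve
#'
#' Splits the radius axis into half-open intervals `[a, a + w)` anchored at
#' multiples of the interval width (so the 30-40 nm interval exists even when
#' the grid starts at 27 nm) and takes the maximum ratio over grid radii in
#' each. Intervals holding no grid radius get `NA`, not 0.
#'
#' @param curve a `k_curve` from [k_ratio_curve()].
#' @param interval_width interval width in nm.
#' @return Tibble with `r_lo, r_hi, max_ratio`.
#' @export
max_ratio_by_interval <- function(curve, interval_width = 10) {
  stopifnot(interval_width > 0)
  r <- curve$r
  lo <- floor(min(r) / interval_width) * interval_width
  starts <- seq(lo, max(r), by = interval_width)
  purrr::map_dfr(starts, function(a) {
    sel <- r >= a & r < a + interval_width
    tibble(
      r_lo = a, r_hi = a + interval_width,
      max_ratio = if (any(sel)) suppressWarnings(max(curve$ratio[sel], na.rm = TRUE)) else NA_real_
    )
  }) |>
    dplyr::mutate(max_ratio = ifelse(is.finite(.data$max_ratio),
                                     .data$max_ratio, NA_real_))
}

#' Peak of a 100-bin histogram
#'
#' Bins span the observed `[min, max]` range; returns the centre of the most
#' populated bin, taking the lower bin on ties. A degenerate input
#' (`min == max`) returns that value.
#'
#' @param values numeric vector (non-empty).
#' @param n_bins number of bins (default 100).
#' @return Numeric scalar: the peak bin centre.
#' @export
histogram_peak <- function(values, n_bins = 100) {
  values <- values[is.finite(values)]
  if (!length(values)) abort("histogram_peak needs at least one finite value")
  lo <- min(values)
  hi <- max(values)
  if (lo == hi) return(lo)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  # left-closed bins, with the maximum folded into the last bin
  bin <- pmin(findInterval(values, breaks), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  k <- which.max(counts)  # first (= lower) bin on ties
  (breaks[k] + breaks[k + 1]) / 2
}

#' Mann-Whitney U test (two-sided)
#'
#' Wraps [stats::wilcox.test()]: exact for small tie-free samples, normal
#' approximation with tie correction otherwise. The degenerate case where
#' the pooled values are all identical returns p = 1.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return Tibble with `u` (the U statistic) and `p_value`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) abort("both groups must be non-empty")
  if (length(unique(c(group_a, group_b))) == 1L) {
    return(tibble(u = length(group_a) * length(group_b) / 2, p_value = 1))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided")
  )
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  tibble(u = unname(ht$statistic), p_value = min(1, p))
}

#' @export
tidy.k_curve <- function(x, ...) {
  tibble(r = x$r, k_obs = x$k_obs, k_csr = x$k_csr, ratio = x$ratio)
}

#' @export
glance.k_curve <- function(x, ...) {
  tibble(
    n_points = attr(x, "n_points"),
    n_null = attr(x, "n_null"),
    mean_ratio = mean(x$ratio, na.rm = TRUE),
    max_ratio = suppressWarnings(max(x$ratio, na.rm = TRUE))
  )
}
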