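# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_histogram
#'   geom_violin geom_jitter labs facet_wrap
NULL

#' Plot a K ratio curve
#'
#' Ratio against radius with the CSR reference line at 1.
#'
#' @param object a `k_curve` from [k_ratio_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.k_curve <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$r, y = .data$ratio)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_line() +
    labs(x = "radius r (nm)", y = expression(K(r) / K[CSR](r)),
         title = sprintf("Clustering of %d particles (%d CSR replicates)",
                         attr(object, "n_points"), attr(object, "n_null")))
}

#' Plot intermembrane distance distributions by patch membership
#'
#' @param object a `patch_distances` from [patch_imm_distances()].
#' @param bins histogram bin count.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.patch_distances <- function(object, bins = 100, ...) {
  ggplot(tidy(object), aes(x = .data$distance)) +
    geom_histogram(bins = bins) +
    facet_wrap(~group, ncol = 1, scales = "free_y") +
    labs(x = "OMM-IMM distance (Å)", y = "triangles")
}

#' Violin-style plot of per-tomogram interval maxima
#'
#' @param interval_maxima long tibble with columns `r_lo`, `max_ratio` and
#'   optionally `class_label` (as written by [run_pipeline()]).
#' @return A ggplot.
#' @export
plot_interval_maxima <- function(interval_maxima) {
  d <- dplyr::filter(interval_maxima, is.finite(.data$max_ratio))
  d$interval <- factor(sprintf("%g-%g", d$r_lo, d$r_lo + (d$r_hi - d$r_lo)))
  p <- ggplot(d, aes(x = .data$interval, y = .data$max_ratio))
  if ("class_label" %in% names(d)) p <- p + aes(fill = .data$class_label)
  p + geom_violin() +
    geom_jitter(width = 0.1, alpha = 0.5, size = 0.8) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    labs(x = "radius interval (nm)", y = expression(max ~ K(r) / K[CSR](r)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot
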