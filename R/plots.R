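#' Histogram of fitted half-lives
#'
#' @param object A `decay_fits` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_fits <- function(object, ...) {
  d <- object %>% filter(.data$qc == "ok", is.finite(.data$half_life))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$half_life)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", color = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "half-life (min)", y = "isoforms",
                  title = "Fitted isoform half-lives") +
    ggplot2::theme_minimal()
}

#' Decay curve of one site with its fitted line
#'
#' Plots log normalized counts against time for a single poly(A) site,
#' with the fitted exponential decay overlaid per replicate.
#'
#' @param norm_counts Normalized count tibble.
#' @param fits `decay_fits` tibble.
#' @param chrom,pos,strand Site to plot.
#' @param condition Condition (default first present).
#' @return A ggplot.
#' @export
plot_decay_curve <- function(norm_counts, fits, chrom, pos, strand,
                             condition = NULL) {
  d <- norm_counts %>%
    filter(.data$chrom == !!chrom, .data$pos == !!pos,
           .data$strand == !!strand)
  if (!is.null(condition)) d <- d %>% filter(.data$condition == !!condition)
  f <- fits %>%
    filter(.data$chrom == !!chrom, .data$pos == !!pos,
           .data$strand == !!strand)
  if (nrow(d) == 0 || nrow(f) == 0) abort("site not found in counts or fits.")
  f <- f[1, ]
  t0 <- min(d$timepoint)
  a0 <- mean(d$norm_count[d$timepoint == t0])
  lab <- if (is.finite(f$half_life)) {
    sprintf("t1/2 = %.1f min", f$half_life)
  } else {
    "nondecaying"
  }
  ggplot2::ggplot(d %>% filter(.data$norm_count > 0),
                  ggplot2::aes(x = .data$timepoint, y = .data$norm_count,
                               color = .data$replicate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_function(
      fun = function(t) a0 * exp(-f$k * (t - t0)),
      inherit.aes = FALSE, color = "grey30"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time after transcriptional arrest (min)",
                  y = "normalized count",
                  title = sprintf("%s:%d:%s  (%s)", chrom, pos, strand, lab)) +
    ggplot2::theme_minimal()
}

#' Boxplot of decay rates by coverage category
#'
#' @param object An `isodecay_anova` from [category_anova()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.isodecay_anova <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$category, y = .data$k,
                               fill = .data$category)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "decay rate k (1/min)",
                  subtitle = sprintf("ANOVA p = %.2g", object$anova$p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Distance versus significance of isoform pairs
#'
#' @param pairs Output of [test_pairs()].
#' @return A ggplot of pair distance (log scale) against -log10 p.
#' @export
plot_pair_distance <- function(pairs) {
  prof <- pair_distance_profile(pairs)$profile
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$distance_nt,
                                     y = .data$neg_log10_p,
                                     color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance between isoform pair (nt)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}
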