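#' Filter internal-mispriming artifact sites
#'
#' Oligo-dT priming on genomic A-rich tracts produces false poly(A)-site
#' calls. A site is removed when its downstream genomic window (strand-aware,
#' starting at the nucleotide after the site, on the transcript sense strand)
#' is A-rich: A fraction above `max_a_frac`, or any run of `max_run` or more
#' consecutive A. Windows running past a chromosome end are truncated and the
#' site judged on the available bases.
#'
#' The filter is idempotent: the decision depends only on the genome, so
#' filtering twice equals filtering once.
#'
#' @param counts Long count tibble (see [read_site_counts()]).
#' @param genome `DNAStringSet` covering every chromosome in `counts`.
#' @param window Downstream window width in nt (default 18).
#' @param max_a_frac Maximum tolerated A fraction (default 0.67).
#' @param max_run Minimum consecutive-A run that triggers removal (default 6).
#' @return The count tibble with all rows of removed sites dropped. The
#'   removal report (site, reason, window sequence) is attached as attribute
#'   `"removal_report"` and retrievable with [mispriming_report()].
#' @export
filter_mispriming <- function(counts, genome, window = 18L,
                              max_a_frac = 0.67, max_run = 6L) {
  sites <- distinct(counts, .data$chrom, .data$pos, .data$strand)
  missing_chr <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chr) > 0) {
    abort(sprintf("genome lacks chromosome(s): %s.",
                  paste(missing_chr, collapse = ", ")))
  }
  check_strand(sites$strand)
  win <- map_chr(seq_len(nrow(sites)), function(i) {
    sense_window(genome, sites$chrom[i], sites$pos[i], sites$strand[i], window)
  })
  n_a <- vapply(strsplit(win, ""), function(x) sum(x == "A"), integer(1))
  wlen <- str_length(win)
  a_frac <- if_else(wlen > 0, n_a / wlen, 0)
  has_run <- str_detect(win, strrep("A", max_run))
  remove <- a_frac > max_a_frac | has_run
  report <- sites %>%
    mutate(
      window_seq = win,
      a_fraction = a_frac,
      reason = dplyr::case_when(
        a_frac > max_a_frac & has_run ~ "a_fraction,a_run",
        a_frac > max_a_frac ~ "a_fraction",
        has_run ~ "a_run",
        TRUE ~ NA_character_
      )
    ) %>%
    filter(remove)
  out <- counts %>%
    anti_join(report, by = c("chrom", "pos", "strand"))
  attr(out, "removal_report") <- report
  out
}

#' @rdname filter_mispriming
#' @param filtered Output of [filter_mispriming()].
#' @export
mispriming_report <- function(filtered) {
  attr(filtered, "removal_report")
}

# Extract the downstream window on the transcript sense strand.
# pos is 0-based; the window starts at the nucleotide after the site.
sense_window <- function(genome, chrom, pos, strand, window) {
  chr <- genome[[chrom]]
  len <- length(chr)
  if (strand == "+") {
    from <- pos + 2L            # 1-based base after the site
    to <- min(pos + 1L + window, len)
    if (from > to) return("")
    as.character(Biostrings::subseq(chr, from, to))
  } else {
    from <- max(pos - window + 1L, 1L)  # 1-based
    to <- pos
    if (from > to || to < 1L) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(chr, from, to)))
  }
}

#' Spike-in size factors
#'
#' The spike-in RNA represents the same number of molecules in every library,
#' so the total spike count measures each library's capture efficiency and
#' each library's size factor is proportional to its spike total:
#' `s = spike_total / anchor`, normalized count `= raw / s`.
#'
#' Two anchors are offered. `"reference"` (default) divides by the spike
#' total of the condition's first library (earliest timepoint, first
#' replicate), putting normalized counts on the scale of the time-zero
#' library; because the anchor does not depend on the other libraries,
#' rescaling any non-reference library's counts by a constant leaves every
#' normalized count exactly unchanged. `"geometric"` divides by the
#' geometric mean of the condition's spike totals, centering the factors at
#' 1; the anchor then couples the libraries, so the same rescaling shifts
#' all normalized counts of the condition by a common constant (slopes and
#' ratios are unaffected). Decay rates are identical under either anchor.
#'
#' @param counts Long count tibble containing spike-tagged sites.
#' @param spike_species Species tag of spike-in sites (default `"spike"`).
#' @param anchor `"reference"` or `"geometric"` (see above).
#' @return Tibble with one row per library: `condition`, `timepoint`,
#'   `replicate`, `spike_total`, `size_factor`.
#' @export
spike_size_factors <- function(counts, spike_species = "spike",
                               anchor = c("reference", "geometric")) {
  anchor <- match.arg(anchor)
  spikes <- counts %>% filter(.data$species == spike_species)
  if (nrow(spikes) == 0) {
    abort("no spike-tagged sites found; cannot normalize.")
  }
  libs <- counts %>% distinct(.data$condition, .data$timepoint, .data$replicate)
  totals <- libs %>%
    left_join(
      spikes %>%
        group_by(.data$condition, .data$timepoint, .data$replicate) %>%
        summarise(spike_total = sum(.data$count), .groups = "drop"),
      by = c("condition", "timepoint", "replicate")
    ) %>%
    mutate(spike_total = dplyr::coalesce(.data$spike_total, 0))
  if (any(totals$spike_total == 0)) {
    bad <- totals %>% filter(.data$spike_total == 0)
    abort(sprintf(
      "library with zero spike counts (%s): normalization impossible.",
      paste(paste(bad$condition, bad$timepoint, bad$replicate, sep = "_"),
            collapse = ", ")
    ))
  }
  totals %>%
    group_by(.data$condition) %>%
    arrange(.data$timepoint, .data$replicate, .by_group = TRUE) %>%
    mutate(size_factor = .data$spike_total /
             if (anchor == "geometric") gmean(.data$spike_total) else
               .data$spike_total[1]) %>%
    ungroup()
}

#' Apply size factors to a count table
#'
#' @param counts Long count tibble.
#' @param factors Size-factor tibble from [spike_size_factors()] (or
#'   [median_of_ratios()] for RIP data).
#' @return `counts` with an added `norm_count = count / size_factor` column.
#' @export
normalize_counts <- function(counts, factors) {
  by <- intersect(c("condition", "timepoint", "replicate"), names(factors))
  out <- counts %>%
    left_join(factors %>% select(dplyr::all_of(by), "size_factor"), by = by)
  if (anyNA(out$size_factor)) {
    abort("some libraries lack a size factor.")
  }
  out %>% mutate(norm_count = .data$count / .data$size_factor)
}

#' Estimate per-timepoint negative-binomial dispersion trends
#'
#' At each timepoint, per-site method-of-moments dispersions
#' `alpha_hat = max(0, (v - m) / m^2)` are computed from the normalized
#' replicate mean `m` and variance `v`, then the parametric trend
#' `alpha(mu) = a0 + a1 / mu` is fitted by least squares over sites with
#' `m > min_mean` (matching the mean of the skewed per-site estimates). Only the trend (never the noisy per-site estimate) feeds
#' the regression weights downstream.
#'
#' @param norm_counts Normalized count tibble (from [normalize_counts()]),
#'   sample species only or mixed (spike sites are excluded here).
#' @param min_mean Minimum normalized mean for a site to enter the trend fit
#'   (default 16).
#' @param alpha_floor Lower bound applied to fitted dispersions (default
#'   1e-4).
#' @param spike_species Tag of spike sites to exclude.
#' @return Tibble of class `dispersion_model` with one row per
#'   (condition, timepoint): trend coefficients `a0`, `a1`, the floor, and
#'   the number of sites used.
#' @export
estimate_dispersion <- function(norm_counts, min_mean = 16,
                                alpha_floor = 1e-4,
                                spike_species = "spike") {
  d <- norm_counts %>% filter(.data$species != spike_species)
  nrep <- d %>%
    distinct(.data$condition, .data$timepoint, .data$replicate) %>%
    count(.data$condition, .data$timepoint)
  if (any(nrep$n < 2)) {
    abort(paste(
      "dispersion estimation needs >= 2 replicates per timepoint;",
      "use a pooled-dispersion fallback for single-replicate designs."
    ))
  }
  per_site <- d %>%
    group_by(.data$condition, .data$timepoint, .data$chrom, .data$pos,
             .data$strand) %>%
    summarise(m = mean(.data$norm_count), v = var(.data$norm_count),
              .groups = "drop") %>%
    filter(.data$m > 0) %>%
    mutate(alpha_hat = pmax(0, (.data$v - .data$m) / .data$m^2))

  model <- per_site %>%
    group_by(.data$condition, .data$timepoint) %>%
    group_modify(function(df, key) {
      fit_df <- df %>% filter(.data$m > min_mean)
      co <- fit_dispersion_trend(fit_df$alpha_hat, fit_df$m)
      tibble(a0 = unname(co[1]), a1 = unname(co[2]),
             alpha_floor = alpha_floor, n_sites = nrow(fit_df))
    }) %>%
    ungroup()
  class(model) <- c("dispersion_model", class(model))
  model
}

# least-squares fit of alpha_hat ~ a0 + a1/m. With few replicates the
# per-site method-of-moments estimates are strongly right-skewed, so a
# median-type robust fit would sit well below the mean dispersion and
# understate the variance the weights need; least squares matches the mean.
# Falls back to a flat mean as data thins out.
fit_dispersion_trend <- function(alpha_hat, m) {
  if (length(alpha_hat) == 0) {
    return(c(a0 = 0, a1 = 0))
  }
  if (length(alpha_hat) < 5) {
    return(c(a0 = max(0, mean(alpha_hat)), a1 = 0))
  }
  x <- 1 / m
  co <- coef(lm(alpha_hat ~ x))
  c(a0 = max(0, unname(co[1])), a1 = unname(co[2]))
}

#' Predict dispersion from a fitted trend
#'
#' @param model A `dispersion_model` from [estimate_dispersion()].
#' @param condition,timepoint,mu Vectors (recycled to common length) at which
#'   to evaluate the per-timepoint trend `alpha(mu) = a0 + a1/mu`, floored at
#'   the model's `alpha_floor`.
#' @return Numeric vector of dispersions.
#' @export
predict_dispersion <- function(model, condition, timepoint, mu) {
  q <- tibble(condition = condition, timepoint = timepoint, mu = mu) %>%
    left_join(as_tibble(model), by = c("condition", "timepoint"))
  if (anyNA(q$a0)) {
    abort("dispersion model has no entry for some (condition, timepoint).")
  }
  pmax(q$a0 + q$a1 / pmax(q$mu, 1e-8), q$alpha_floor)
}

#' Keep reliably quantified sites
#'
#' A site is reliably quantified in a condition when its normalized count at
#' the first timepoint (mean over replicates) reaches `min_count` and at
#' least `min_timepoints` timepoints have nonzero counts. Spike sites are
#' dropped: they never enter decay fitting.
#'
#' @param norm_counts Normalized count tibble.
#' @param min_count Minimum normalized first-timepoint count (default 16).
#' @param min_timepoints Minimum number of timepoints with nonzero counts
#'   (default 3).
#' @param spike_species Tag of spike sites.
#' @return The normalized tibble restricted to passing (site, condition)
#'   combinations, sample species only.
#' @export
filter_reliable <- function(norm_counts, min_count = 16, min_timepoints = 3L,
                            spike_species = "spike") {
  d <- norm_counts %>% filter(.data$species != spike_species)
  t0 <- min(d$timepoint)
  keep <- d %>%
    group_by(.data$condition, .data$chrom, .data$pos, .data$strand) %>%
    summarise(
      t0_norm = mean(.data$norm_count[.data$timepoint == t0]),
      n_tp_nonzero = dplyr::n_distinct(
        .data$timepoint[.data$count > 0]),
      .groups = "drop"
    ) %>%
    filter(.data$t0_norm >= min_count, .data$n_tp_nonzero >= min_timepoints)
  d %>% semi_join(keep, by = c("condition", "chrom", "pos", "strand"))
}
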