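#' Median-of-ratios size factors
#'
#' For each library, the size factor is the median over sites of
#' `count / geometric mean of that site's counts across libraries`, using
#' only sites with nonzero counts in every library, then anchored so the
#' geometric mean of the factors is 1. This is the standard normalization
#' for count data without spike-ins, used for the IP/input comparison where
#' no spike-in anchor exists.
#'
#' @param counts Long count tibble; libraries are
#'   (condition, timepoint, replicate) combinations.
#' @return Size-factor tibble (`condition`, `timepoint`, `replicate`,
#'   `size_factor`).
#' @export
median_of_ratios <- function(counts) {
  wide <- counts %>%
    mutate(lib = paste(.data$condition, .data$timepoint, .data$replicate,
                       sep = "_")) %>%
    select("chrom", "pos", "strand", "lib", "count") %>%
    pivot_wider(names_from = "lib", values_from = "count", values_fill = 0)
  mat <- as.matrix(wide %>% select(-"chrom", -"pos", -"strand"))
  nz <- rowSums(mat == 0) == 0
  if (!any(nz)) {
    abort(paste("no site has nonzero counts in all libraries;",
                "consider a pseudo-reference fallback."))
  }
  m <- mat[nz, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  s <- apply(m / ref, 2, median)
  s <- s / gmean(s)
  counts %>%
    distinct(.data$condition, .data$timepoint, .data$replicate) %>%
    mutate(lib = paste(.data$condition, .data$timepoint, .data$replicate,
                       sep = "_")) %>%
    mutate(size_factor = unname(s[.data$lib])) %>%
    select(-"lib")
}

#' Negative-binomial IP-vs-input enrichment test
#'
#' Calls isoforms enriched in the immunoprecipitated (IP) fraction relative
#' to the input. The scheme: median-of-ratios size factors over all
#' libraries; per-site method-of-moments dispersion shrunk toward a trend
#' `alpha(mu) = a0 + a1/mu` fitted across sites (pooled over conditions);
#' a Wald test of the log2 fold change, whose standard error follows from
#' the NB variance `mu + alpha mu^2` by the delta method; Benjamini-Hochberg
#' adjustment; and a bound call at `q <= fdr_level` with fold change above
#' `fc_cutoff`. The dispersion term keeps low-count isoforms from producing
#' spuriously confident fold changes.
#'
#' Sites with zero counts everywhere are excluded. Sites with a zero mean in
#' either condition cannot yield a finite log2 fold change and are reported
#' with `NA` statistics and `bound = FALSE`.
#'
#' @param counts Long count tibble with conditions `input` and `IP` (>= 2
#'   replicates each).
#' @param fdr_level FDR level for the bound call (default 0.1).
#' @param fc_cutoff Minimum IP/input fold change, natural scale (default 4).
#'   Applied to the point estimate of fold change.
#' @param shrink_prior Prior weight (in pseudo-replicates) pulling the
#'   per-site dispersion toward the trend; with triplicates the trend
#'   dominates (default 4).
#' @param alpha_floor Dispersion floor (default 1e-4).
#' @return Tibble of class `enrichment_result`: per site `base_mean_input`,
#'   `base_mean_ip`, `log2fc`, `se_log2fc`, `alpha`, `p`, `q`, `bound`.
#' @export
nb_enrichment <- function(counts, fdr_level = 0.1, fc_cutoff = 4,
                          shrink_prior = 4, alpha_floor = 1e-4) {
  conds <- unique(counts$condition)
  if (!all(c("input", "IP") %in% conds)) {
    abort("`counts` must contain conditions 'input' and 'IP'.")
  }
  nrep <- counts %>%
    distinct(.data$condition, .data$replicate) %>%
    count(.data$condition)
  if (any(nrep$n < 2)) {
    abort("nb_enrichment needs >= 2 replicates per condition.")
  }
  lib_tot <- counts %>%
    group_by(.data$condition, .data$timepoint, .data$replicate) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  if (any(lib_tot$total == 0)) {
    abort("library with zero total counts.")
  }

  factors <- median_of_ratios(counts)
  d <- normalize_counts(counts, factors)

  per_site <- d %>%
    group_by(.data$chrom, .data$pos, .data$strand, .data$condition) %>%
    summarise(
      m = mean(.data$norm_count),
      v = var(.data$norm_count),
      n = dplyr::n(),
      inv_s = mean(1 / .data$size_factor),
      .groups = "drop"
    ) %>%
    pivot_wider(names_from = "condition",
                values_from = c("m", "v", "n", "inv_s"))
  all_zero <- per_site$m_input == 0 & per_site$m_IP == 0
  per_site <- per_site[!all_zero, ]

  # pooled method-of-moments dispersion per site, then trend + shrinkage
  mom <- function(m, v) if_else(m > 0, pmax(0, (v - m) / m^2), NA_real_)
  per_site <- per_site %>%
    mutate(
      alpha_in = mom(.data$m_input, .data$v_input),
      alpha_ip = mom(.data$m_IP, .data$v_IP),
      alpha_site = dplyr::coalesce(
        rowMeans(cbind(.data$alpha_in, .data$alpha_ip), na.rm = TRUE), 0),
      base_mean = (.data$m_input + .data$m_IP) / 2
    )
  trend_df <- per_site %>% filter(.data$base_mean > 5, !is.na(.data$alpha_site))
  co <- fit_dispersion_trend(trend_df$alpha_site, trend_df$base_mean)
  n_site <- per_site$n_input + per_site$n_IP
  w_site <- (n_site - 2) / (n_site - 2 + shrink_prior)
  per_site <- per_site %>%
    mutate(
      alpha_trend = pmax(co[1] + co[2] / pmax(.data$base_mean, 1e-8),
                         alpha_floor),
      alpha = pmax(w_site * .data$alpha_site +
                     (1 - w_site) * .data$alpha_trend, alpha_floor)
    )

  # delta-method Wald test on log2(m_IP / m_input):
  # Var(K_i/s_i) = m/s_i + alpha m^2  =>  Var(mean) = (m*mean(1/s)/n) + alpha m^2/n
  # Var(log2 m) = Var(mean) / (m^2 (ln 2)^2)
  ln2sq <- log(2)^2
  out <- per_site %>%
    mutate(
      testable = .data$m_input > 0 & .data$m_IP > 0,
      log2fc = if_else(.data$testable, log2(.data$m_IP / .data$m_input),
                       NA_real_),
      var_l2_in = (.data$m_input * .data$inv_s_input +
                     .data$alpha * .data$m_input^2) /
        (.data$n_input * .data$m_input^2 * ln2sq),
      var_l2_ip = (.data$m_IP * .data$inv_s_IP + .data$alpha * .data$m_IP^2) /
        (.data$n_IP * .data$m_IP^2 * ln2sq),
      se_log2fc = if_else(.data$testable,
                          sqrt(.data$var_l2_in + .data$var_l2_ip), NA_real_),
      p = if_else(.data$testable,
                  2 * pnorm(-abs(.data$log2fc / .data$se_log2fc)), NA_real_)
    )
  out$q <- NA_real_
  out$q[out$testable] <- p.adjust(out$p[out$testable], method = "BH")
  res <- out %>%
    transmute(
      chrom = .data$chrom, pos = .data$pos, strand = .data$strand,
      base_mean_input = .data$m_input, base_mean_ip = .data$m_IP,
      alpha = .data$alpha, log2fc = .data$log2fc,
      se_log2fc = .data$se_log2fc, p = .data$p, q = .data$q,
      bound = !is.na(.data$q) & .data$q <= fdr_level &
        2^.data$log2fc > fc_cutoff
    ) %>%
    arrange(.data$chrom, .data$pos, .data$strand)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_sites = nrow(x), n_tested = sum(!is.na(x$p)),
         n_bound = sum(x$bound))
}

#' Decay rates of bound versus unbound isoforms
#'
#' Within the genes that have at least one bound coding isoform, compares
#' decay rates of bound and unbound coding isoforms (means, medians, their
#' ratio, Welch t-test). This asks whether an RBP's binding targets decay
#' faster than the other isoforms of the same genes. All fitted rates enter
#' the group summaries, including non-positive estimates of slowly decaying
#' isoforms: truncating those would bias the slower (unbound) group upward
#' and attenuate the ratio.
#'
#' Three ratio summaries are reported: the ratio of group means, the ratio
#' of group medians, and a gene-paired ratio — the geometric mean over genes
#' (with isoforms in both groups) of that gene's bound/unbound mean-rate
#' ratio. The paired form cancels the gene-level baseline rate, which varies
#' over more than an order of magnitude between genes and otherwise
#' dominates the sampling noise of the group-level ratios.
#'
#' @param enrichment Output of [nb_enrichment()].
#' @param fits `decay_fits` (wild-type condition).
#' @param annotations Output of [classify_isoforms()].
#' @param min_group Minimum group size for the t-test (default 3).
#' @return One-row tibble: group sizes, mean/median k per group, the
#'   bound/unbound ratios (`mean_ratio`, `median_ratio`, `ratio_paired`),
#'   and the Welch p (NA when a group is too small).
#' @export
bound_vs_unbound_decay <- function(enrichment, fits, annotations,
                                   min_group = 3L) {
  coding <- annotations %>%
    filter(.data$coding, !is.na(.data$gene_id)) %>%
    distinct(.data$chrom, .data$pos, .data$strand, .data$gene_id)
  d <- fits %>%
    filter(.data$qc != "insufficient_points") %>%
    inner_join(coding, by = c("chrom", "pos", "strand")) %>%
    inner_join(enrichment %>% select("chrom", "pos", "strand", "bound"),
               by = c("chrom", "pos", "strand"))
  bound_genes <- d %>% filter(.data$bound) %>% distinct(.data$gene_id)
  d <- d %>% semi_join(bound_genes, by = "gene_id")
  b <- d %>% filter(.data$bound)
  u <- d %>% filter(!.data$bound)
  per_gene <- d %>%
    group_by(.data$gene_id) %>%
    summarise(
      mb = mean(.data$k[.data$bound]),
      mu = mean(.data$k[!.data$bound]),
      .groups = "drop"
    ) %>%
    filter(is.finite(.data$mb), is.finite(.data$mu), .data$mu > 0,
           .data$mb > 0)
  tibble(
    n_genes = nrow(bound_genes),
    n_bound = nrow(b), n_unbound = nrow(u),
    mean_k_bound = mean(b$k), mean_k_unbound = mean(u$k),
    median_k_bound = median(b$k), median_k_unbound = median(u$k),
    mean_ratio = mean(b$k) / mean(u$k),
    median_ratio = median(b$k) / median(u$k),
    n_genes_paired = nrow(per_gene),
    ratio_paired = if (nrow(per_gene) > 0) {
      exp(mean(log(per_gene$mb / per_gene$mu)))
    } else NA_real_,
    p = if (nrow(b) >= min_group && nrow(u) >= min_group) {
      t.test(b$k, u$k)$p.value
    } else NA_real_
  )
}

#' Group test of mutant/wild-type decay ratios by binding status
#'
#' Tests whether isoforms bound by an RBP in the wild type change their
#' decay rate differently upon loss of the protein than unbound isoforms,
#' using the per-isoform mutant/WT decay ratios. Coding and non-coding
#' isoforms are analyzed separately, since binding may be consequential for
#' one class only. The Welch t-test is applied to log ratios: decay-rate
#' ratios are positive multiplicative quantities whose estimation noise is
#' heavy-tailed on the natural scale (a slow isoform's rate ratio can be off
#' by severalfold), and the log transform symmetrizes it. Medians are
#' reported on the natural scale.
#'
#' @param ratios Output of [relative_decay_ratio()].
#' @param enrichment Output of [nb_enrichment()] (provides `bound`).
#' @param annotations Output of [classify_isoforms()] (provides `coding`).
#' @param min_group Minimum group size for a test (default 3).
#' @return Tibble with one row per coding class: group sizes, median ratios
#'   per group, Welch p (NA when a group is too small).
#' @export
ratio_group_test <- function(ratios, enrichment, annotations,
                             min_group = 3L) {
  lab <- annotations %>%
    filter(!.data$site_only) %>%
    group_by(.data$chrom, .data$pos, .data$strand) %>%
    summarise(coding = any(.data$coding), .groups = "drop")
  d <- ratios %>%
    inner_join(lab, by = c("chrom", "pos", "strand")) %>%
    inner_join(enrichment %>% select("chrom", "pos", "strand", "bound"),
               by = c("chrom", "pos", "strand"))
  d %>%
    group_by(.data$coding) %>%
    group_modify(function(df, key) {
      b <- df$ratio[df$bound]
      u <- df$ratio[!df$bound]
      tibble(
        n_bound = length(b), n_unbound = length(u),
        median_ratio_bound = if (length(b) > 0) median(b) else NA_real_,
        median_ratio_unbound = if (length(u) > 0) median(u) else NA_real_,
        p = if (length(b) >= min_group && length(u) >= min_group) {
          t.test(log(b), log(u))$p.value
        } else NA_real_
      )
    }) %>%
    ungroup()
}
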