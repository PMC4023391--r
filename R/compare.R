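#' ANOVA of decay rates across coverage categories
#'
#' One-way ANOVA of decay rates across categories with at least `min_n`
#' members, followed by pairwise Welch t-tests with Benjamini-Hochberg
#' adjustment. Categories below `min_n` are excluded from the test and from
#' the reported medians (the raw data are untouched, only the display rule
#' filters).
#'
#' @param fits_annot A `decay_fits` tibble joined with [classify_isoforms()]
#'   output (must carry `category` and `k`; rows with qc
#'   `"insufficient_points"` are dropped).
#' @param min_n Minimum category size (default 20).
#' @param pooled_sd Use pooled-variance t-tests instead of Welch (default
#'   FALSE).
#' @return List of class `isodecay_anova`: `summary` (per-category n,
#'   median k, median half-life), `anova` (F, dfs, p), `pairwise` (long
#'   tibble of adjusted pairwise p-values).
#' @export
category_anova <- function(fits_annot, min_n = 20L, pooled_sd = FALSE) {
  d <- fits_annot %>%
    filter(.data$qc != "insufficient_points", !is.na(.data$category))
  eligible <- d %>% count(.data$category) %>% filter(.data$n >= min_n)
  if (nrow(eligible) < 2) {
    abort(sprintf("need >= 2 categories with >= %d members.", min_n))
  }
  d <- d %>% semi_join(eligible, by = "category")
  d$category <- factor(d$category)

  fit <- aov(k ~ category, data = d)
  s <- summary(fit)[[1]]
  anova_row <- tibble(
    F = s$`F value`[1], df_between = s$Df[1], df_within = s$Df[2],
    p = s$`Pr(>F)`[1]
  )
  pw <- stats::pairwise.t.test(d$k, d$category, p.adjust.method = "BH",
                               pool.sd = pooled_sd)
  pairwise <- as_tibble(as.table(pw$p.value), .name_repair = ~c(
    "category_a", "category_b", "p_adj")) %>%
    filter(!is.na(.data$p_adj))
  summary_tbl <- d %>%
    group_by(.data$category) %>%
    summarise(
      n = dplyr::n(),
      median_k = median(.data$k),
      median_half_life = median(.data$half_life[is.finite(.data$half_life)]),
      .groups = "drop"
    )
  structure(
    list(summary = summary_tbl, anova = anova_row, pairwise = pairwise,
         data = d),
    class = "isodecay_anova"
  )
}

#' @export
print.isodecay_anova <- function(x, ...) {
  cat(sprintf("<isodecay_anova> F = %.3f (df %d, %d), p = %.3g\n",
              x$anova$F, x$anova$df_between, x$anova$df_within, x$anova$p))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.isodecay_anova <- function(x, ...) {
  x$pairwise
}

#' @export
glance.isodecay_anova <- function(x, ...) {
  x$anova
}

#' 3'UTR length versus decay rate
#'
#' Reports the Spearman correlation between decay rate and 3'UTR length over
#' all coding isoforms, and a per-gene proximal/distal pair table: for each
#' gene with >= 2 coding isoforms, the pair with the shortest and longest
#' 3'UTR, with the length difference, rate difference, and its z-test
#' significance.
#'
#' @param fits_annot `decay_fits` joined with annotations (`coding`,
#'   `utr3_length`, `gene_id` present); only qc-pass coding rows are used.
#' @param min_isoforms Minimum number of coding isoforms for the
#'   correlation (default 10).
#' @return List: `correlation` (one-row tibble rho / p / n) and `pairs`
#'   (per-gene tibble with `delta_length`, `delta_k`, `z`, `p`).
#' @export
utr_length_relation <- function(fits_annot, min_isoforms = 10L) {
  d <- fits_annot %>%
    filter(.data$qc != "insufficient_points", .data$coding,
           !is.na(.data$utr3_length))
  if (nrow(d) < min_isoforms) {
    abort(sprintf("need >= %d coding isoforms.", min_isoforms))
  }
  ct <- suppressWarnings(cor.test(d$k, d$utr3_length, method = "spearman"))
  correlation <- tibble(rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
  pairs <- d %>%
    group_by(.data$gene_id, .data$condition) %>%
    filter(dplyr::n() >= 2) %>%
    group_modify(function(df, key) {
      prox <- which.min(df$utr3_length)
      dist <- which.max(df$utr3_length)
      tibble(
        utr3_proximal = df$utr3_length[prox],
        utr3_distal = df$utr3_length[dist],
        delta_length = df$utr3_length[dist] - df$utr3_length[prox],
        k_proximal = df$k[prox],
        k_distal = df$k[dist],
        delta_k = df$k[dist] - df$k[prox],
        z = (df$k[dist] - df$k[prox]) /
          sqrt(df$se_k[dist]^2 + df$se_k[prox]^2)
      )
    }) %>%
    ungroup() %>%
    mutate(p = 2 * pnorm(-abs(.data$z)))
  list(correlation = correlation, pairs = pairs)
}

#' Distance profile of differential-stability pairs
#'
#' Relates the genomic distance between isoform pairs of a gene to the
#' statistical confidence of their stability difference, with significant
#' pairs counted in distance bins (1, 2-5, 6-10, 11-100, >100 nt).
#'
#' @param pairs Output of [test_pairs()].
#' @return List: `profile` (per pair: `distance_nt`, `neg_log10_p`,
#'   `significant`) and `bins` (counts of tested and significant pairs per
#'   distance bin).
#' @export
pair_distance_profile <- function(pairs) {
  profile <- pairs %>%
    filter(.data$distance_nt >= 1) %>%
    mutate(
      neg_log10_p = -log10(pmax(.data$p, .Machine$double.xmin)),
      bin = cut(.data$distance_nt, c(0, 1, 5, 10, 100, Inf),
                labels = c("1", "2-5", "6-10", "11-100", ">100"))
    )
  bins <- profile %>%
    group_by(.data$bin, .drop = FALSE) %>%
    summarise(n_pairs = dplyr::n(), n_significant = sum(.data$significant),
              .groups = "drop")
  list(profile = profile %>% select(-"bin"), bins = bins)
}

#' Scan 3'UTRs for RBP motifs
#'
#' Exact IUPAC matching on the transcript sense strand within each coding
#' isoform's 3'UTR (the region from the base after the stop codon to the
#' poly(A) site) plus `flank` nt downstream of the site. A hit is
#' `contained` when it ends at or upstream of the poly(A) site, i.e. lies
#' within the isoform's 3'UTR; hits in the downstream flank are reported
#' with `contained = FALSE`.
#'
#' @param genome `DNAStringSet`.
#' @param motifs Motif tibble (`motif_id`, `iupac`).
#' @param annotations Coding rows of [classify_isoforms()] output (rows with
#'   `coding = FALSE` or missing `utr3_length` are ignored).
#' @param genes Gene models (to locate each reference CDS's stop codon).
#' @param flank Downstream nt scanned beyond the poly(A) site (default 30).
#' @return Tibble of hits: `motif_id`, site key columns, `tif_id`,
#'   `gene_id`, `hit_pos` (genomic 0-based position of the hit's 5'-most
#'   sense base), `distance_to_3prime` (transcript nt from hit end to site;
#'   >= 0 inside the UTR), `contained`.
#' @export
scan_motifs <- function(genome, motifs, annotations, genes, flank = 30L) {
  validate_iupac(motifs$iupac)
  coding <- annotations %>%
    filter(.data$coding, !is.na(.data$utr3_length)) %>%
    left_join(genes %>% select("gene_id", cds_start = "start",
                               cds_end = "end"),
              by = "gene_id")
  hits <- list()
  for (i in seq_len(nrow(coding))) {
    r <- coding[i, ]
    chr <- genome[[r$chrom]]
    if (r$strand == "+") {
      from <- r$cds_end + 1L                 # 1-based base after stop
      to <- min(r$pos + 1L + flank, length(chr))
      if (from > to) next
      region <- Biostrings::subseq(chr, from, to)
    } else {
      from <- max(r$pos + 1L - flank, 1L)
      to <- r$cds_start                      # 1-based base after stop (sense)
      if (from > to) next
      region <- Biostrings::reverseComplement(Biostrings::subseq(chr, from, to))
    }
    # transcript coordinate 1 = base after the stop codon;
    # the poly(A) site sits at transcript coordinate utr3_length
    for (j in seq_len(nrow(motifs))) {
      m <- Biostrings::matchPattern(Biostrings::DNAString(motifs$iupac[j]),
                                    region, fixed = FALSE)
      if (length(m) == 0) next
      h1 <- BiocGenerics::start(m)
      h2 <- BiocGenerics::end(m)
      hit_pos <- if (r$strand == "+") r$cds_end + h1 - 1L else
        r$cds_start - h1
      hits[[length(hits) + 1]] <- tibble(
        motif_id = motifs$motif_id[j],
        chrom = r$chrom, pos = r$pos, strand = r$strand,
        tif_id = r$tif_id, gene_id = r$gene_id,
        hit_pos = hit_pos,
        distance_to_3prime = r$utr3_length - h2,
        contained = r$utr3_length - h2 >= 0
      )
    }
  }
  if (length(hits) == 0) {
    return(tibble(
      motif_id = character(), chrom = character(), pos = integer(),
      strand = character(), tif_id = character(), gene_id = character(),
      hit_pos = integer(), distance_to_3prime = numeric(),
      contained = logical()
    ))
  }
  list_rbind(hits)
}

#' Stability split by motif presence
#'
#' Within genes that have at least one isoform containing the motif, splits
#' coding isoforms into motif-containing and motif-free groups and compares
#' their decay rates (Welch t-test, group medians and their ratio). Also
#' returns, for contained isoforms, the distance from the motif to the 3'
#' end against the decay rate, to check for distance effects.
#'
#' @param fits_annot `decay_fits` joined with annotations (coding rows used).
#' @param hits Output of [scan_motifs()].
#' @param motif_id Motif to analyze.
#' @return List of class `motif_split`: `groups` (per-isoform table with
#'   `contained`), `test` (one-row tibble; NA p when a group is empty),
#'   `distance` (contained isoforms: motif distance vs k).
#' @export
motif_stability_split <- function(fits_annot, hits, motif_id) {
  mh <- hits %>%
    filter(.data$motif_id == !!motif_id, .data$contained) %>%
    distinct(.data$chrom, .data$pos, .data$strand) %>%
    mutate(contained = TRUE)
  d <- fits_annot %>%
    filter(.data$qc != "insufficient_points", .data$coding,
           !is.na(.data$gene_id)) %>%
    left_join(mh, by = c("chrom", "pos", "strand")) %>%
    mutate(contained = dplyr::coalesce(.data$contained, FALSE))
  motif_genes <- d %>% filter(.data$contained) %>% distinct(.data$gene_id)
  d <- d %>% semi_join(motif_genes, by = "gene_id")
  with_m <- d %>% filter(.data$contained)
  without_m <- d %>% filter(!.data$contained)
  test <- tibble(
    motif_id = motif_id,
    n_with = nrow(with_m), n_without = nrow(without_m),
    median_k_with = if (nrow(with_m) > 0) median(with_m$k) else NA_real_,
    median_k_without = if (nrow(without_m) > 0) median(without_m$k) else
      NA_real_,
    median_ratio = if (nrow(with_m) > 0 && nrow(without_m) > 0) {
      median(with_m$k) / median(without_m$k)
    } else NA_real_,
    p = if (nrow(with_m) >= 3 && nrow(without_m) >= 3) {
      t.test(with_m$k, without_m$k)$p.value
    } else NA_real_
  )
  dist_tbl <- with_m %>%
    inner_join(
      hits %>% filter(.data$motif_id == !!motif_id, .data$contained) %>%
        group_by(.data$chrom, .data$pos, .data$strand) %>%
        summarise(distance_to_3prime = min(.data$distance_to_3prime),
                  .groups = "drop"),
      by = c("chrom", "pos", "strand")
    ) %>%
    select("chrom", "pos", "strand", "gene_id", "k", "distance_to_3prime")
  structure(list(groups = d, test = test, distance = dist_tbl),
            class = "motif_split")
}

#' @export
print.motif_split <- function(x, ...) {
  print(x$test)
  invisible(x)
}

#' Decay-rate correlation of divergent gene pairs
#'
#' Identifies head-to-head gene pairs on opposite strands whose 5' starts
#' (shared promoter region) lie within `max_gap` nt — the minus-strand gene
#' upstream of the plus-strand gene, transcribing away from it — and
#' computes the Spearman correlation of their gene-level decay rates.
#' Convergent (tail-to-tail) pairs are excluded by the orientation rule.
#'
#' @param genes Gene-model tibble (ORFs used).
#' @param gene_k Output of [aggregate_gene_decay()].
#' @param max_gap Maximum distance in nt between the two 5' starts
#'   (default 200).
#' @param min_pairs Minimum number of pairs for a correlation (default 5).
#' @return List: `pairs` (tibble of divergent pairs with both k values) and
#'   `correlation` (rho / p / n, or NA when fewer than `min_pairs`).
#' @export
divergent_pair_correlation <- function(genes, gene_k, max_gap = 200L,
                                       min_pairs = 5L) {
  orfs <- genes %>% filter(.data$biotype == "ORF")
  minus <- orfs %>% filter(.data$strand == "-")
  plus <- orfs %>% filter(.data$strand == "+")
  pairs <- inner_join(
    minus %>% select(gene_minus = "gene_id", "chrom", end_minus = "end"),
    plus %>% select(gene_plus = "gene_id", "chrom", start_plus = "start"),
    by = "chrom", relationship = "many-to-many"
  ) %>%
    mutate(gap = .data$start_plus - (.data$end_minus - 1L)) %>%
    filter(.data$gap >= 1, .data$gap <= max_gap)
  kk <- gene_k %>% select("gene_id", "k_gene")
  pairs <- pairs %>%
    inner_join(kk %>% rename(k_minus = "k_gene"),
               by = c(gene_minus = "gene_id")) %>%
    inner_join(kk %>% rename(k_plus = "k_gene"),
               by = c(gene_plus = "gene_id"))
  correlation <- if (nrow(pairs) >= max(min_pairs, 3L)) {
    ct <- suppressWarnings(
      cor.test(pairs$k_minus, pairs$k_plus, method = "spearman"))
    tibble(rho = unname(ct$estimate), p = ct$p.value, n = nrow(pairs))
  } else {
    tibble(rho = NA_real_, p = NA_real_, n = nrow(pairs))
  }
  list(pairs = pairs, correlation = correlation)
}
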