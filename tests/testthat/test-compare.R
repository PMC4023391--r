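mk_fits_annot <- function(k_by_cat, se = 0.005, min_each = 25) {
  # build a decay_fits + annotation table with given per-category k vectors
  purrr::imap(k_by_cat, function(ks, cat) {
    n <- length(ks)
    tibble(chrom = "chr1", pos = seq_len(n) * 10L, strand = "+",
           condition = "WT", k = ks, se_k = se,
           half_life = log(2) / pmax(ks, 1e-9), n_points = 10L,
           abund_t0 = 100, qc = "ok", category = cat,
           coding = cat %in% c("coding_1orf", "coding_2plus_orf"),
           gene_id = paste0(cat, "_g", seq_len(n)),
           utr3_length = NA_real_)
  }) %>% bind_rows()
}

test_that("one-way ANOVA matches the textbook between/within computation", {
  g1 <- c(1, 2, 3); g2 <- c(11, 12, 13)
  d <- mk_fits_annot(list(coding_1orf = g1, sut = g2))
  res <- category_anova(d, min_n = 3)
  # hand computation: grand mean 7, SSB = 3*(2-7)^2 + 3*(12-7)^2 = 150,
  # SSW = 2 + 2 = 4, F = (150/1)/(4/4) = 150
  expect_equal(res$anova$F, 150, tolerance = 1e-10)
  expect_equal(res$anova$df_between, 1)
  expect_equal(res$anova$df_within, 4)
  # and agreement with the independent oneway.test oracle (equal variances)
  oracle <- stats::oneway.test(k ~ category, data = d, var.equal = TRUE)
  expect_equal(res$anova$F, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$anova$p, oracle$p.value, tolerance = 1e-10)
})

test_that("identical category distributions give F = 0 and pairwise p = 1", {
  d <- mk_fits_annot(list(coding_1orf = c(1, 2, 3), sut = c(1, 2, 3)))
  res <- category_anova(d, min_n = 3)
  expect_equal(res$anova$F, 0, tolerance = 1e-12)
  expect_equal(res$pairwise$p_adj, 1, tolerance = 1e-12)
})

test_that("categories below the display threshold are excluded", {
  d <- mk_fits_annot(list(coding_1orf = rnorm(25, 0.05, 0.001),
                          sut = rnorm(25, 0.08, 0.001),
                          intergenic = rnorm(5, 0.2, 0.001)))
  res <- category_anova(d, min_n = 20)
  expect_setequal(res$summary$category, c("coding_1orf", "sut"))
  expect_error(category_anova(d, min_n = 26), ">= 2 categories")
})

test_that("pairwise tests agree with Welch t-tests to high precision", {
  set.seed(3)
  d <- mk_fits_annot(list(coding_1orf = rnorm(30, 0.05, 0.01),
                          sut = rnorm(30, 0.07, 0.02)))
  res <- category_anova(d, min_n = 20)
  oracle <- t.test(d$k[d$category == "coding_1orf"],
                   d$k[d$category == "sut"])
  expect_equal(res$pairwise$p_adj, oracle$p.value, tolerance = 1e-10)
})

test_that("UTR length relation recovers constructed correlations", {
  # k strictly increasing with length -> rho = 1
  n <- 30
  d <- tibble(chrom = "chr1", pos = seq_len(n) * 10L, strand = "+",
              condition = "WT", k = seq(0.01, 0.1, length.out = n),
              se_k = 0.005, half_life = log(2) / seq(0.01, 0.1, length.out = n),
              n_points = 10L, abund_t0 = 100, qc = "ok", coding = TRUE,
              gene_id = rep(paste0("g", 1:15), each = 2),
              utr3_length = seq(10, 300, length.out = n))
  rel <- utr_length_relation(d)
  expect_equal(rel$correlation$rho, 1)
  # lengths independent of k -> |rho| small
  set.seed(9)
  d2 <- d %>% mutate(k = sample(k), utr3_length = sample(utr3_length))
  n_big <- 1000
  d3 <- tibble(chrom = "chr1", pos = seq_len(n_big) * 10L, strand = "+",
               condition = "WT", k = rlnorm(n_big, log(0.03), 0.5),
               se_k = 0.005, half_life = 1, n_points = 10L, abund_t0 = 100,
               qc = "ok", coding = TRUE,
               gene_id = rep(paste0("g", 1:500), each = 2),
               utr3_length = runif(n_big, 10, 300))
  rel3 <- utr_length_relation(d3)
  expect_lt(abs(rel3$correlation$rho), 0.1)
})

test_that("proximal/distal pairs capture sign and significance of stability differences", {
  # proximal t1/2 10 min, distal t1/2 40 min: distal more stable, delta_k < 0
  d <- tibble(chrom = "chr1", pos = c(100L, 200L), strand = "+",
              condition = "WT", k = c(log(2) / 10, log(2) / 40),
              se_k = 0.005, half_life = c(10, 40), n_points = 10L,
              abund_t0 = 100, qc = "ok", coding = TRUE, gene_id = "g1",
              utr3_length = c(50, 150))
  rel <- utr_length_relation(d, min_isoforms = 2)
  expect_equal(rel$pairs$delta_length, 100)
  expect_lt(rel$pairs$delta_k, 0)
  expect_lt(rel$pairs$p, 0.001)
})

test_that("pair distance profile bins pairs and excludes distance zero", {
  pairs <- tibble(
    gene_id = paste0("g", 1:6), condition = "WT",
    site_a = "a", site_b = "b",
    k_a = 0.1, k_b = 0.02, se_a = 0.005, se_b = 0.005,
    distance_nt = c(0, 1, 4, 8, 60, 300),
    delta_k = 0.08, z = 8, p = c(1e-15, 1e-15, 1e-15, 0.5, 1e-15, 1e-15),
    q = c(1e-14, 1e-14, 1e-14, 0.6, 1e-14, 1e-14),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  prof <- pair_distance_profile(pairs)
  expect_equal(nrow(prof$profile), 5)  # distance 0 excluded
  expect_equal(as.character(prof$bins$bin), c("1", "2-5", "6-10", "11-100", ">100"))
  expect_equal(prof$bins$n_pairs, c(1L, 1L, 1L, 1L, 1L))
  expect_equal(prof$bins$n_significant, c(1L, 1L, 0L, 1L, 1L))
})

test_that("null pair tests are uniformly significant at the nominal rate per bin", {
  set.seed(21)
  n <- 4000
  se <- 0.01
  k0 <- 0.05
  pairs <- tibble(
    gene_id = paste0("g", seq_len(n)), condition = "WT",
    site_a = "a", site_b = "b",
    k_a = rnorm(n, k0, se), k_b = rnorm(n, k0, se),
    se_a = se, se_b = se,
    distance_nt = sample(c(1, 3, 8, 50, 300), n, replace = TRUE)
  ) %>%
    mutate(delta_k = k_a - k_b, z = delta_k / sqrt(2 * se^2),
           p = 2 * pnorm(-abs(z)), q = p.adjust(p, "BH"),
           significant = p < 0.05)
  prof <- pair_distance_profile(pairs)
  rate <- prof$bins %>% mutate(rate = n_significant / n_pairs)
  expect_true(all(abs(rate$rate - 0.05) < 0.03))
})

test_that("IUPAC motif scanning finds planted and degenerate motifs in UTRs", {
  pipe <- default_pipeline()
  sim <- pipe$sim
  hits <- scan_motifs(sim$genome, sim$motifs, pipe$ann, sim$genes)
  found <- hits %>% filter(contained) %>% distinct(chrom, pos, strand)
  planted <- sim$truth %>% filter(motif) %>% select(chrom, pos, strand)
  expect_setequal(paste(found$chrom, found$pos, found$strand),
                  paste(planted$chrom, planted$pos, planted$strand))
  # all contained hits lie upstream of the poly(A) site within the UTR
  expect_true(all(hits$distance_to_3prime[hits$contained] >= 0))
})

test_that("motif scanner agrees with a brute-force IUPAC matcher", {
  set.seed(31)
  motifs <- c("TGTAAATA", "TGTAHMNTA", "RYSWKM")
  for (i in 1:25) {
    seq <- random_dna(500)
    for (m in motifs) {
      ours <- BiocGenerics::start(Biostrings::matchPattern(
        Biostrings::DNAString(m), Biostrings::DNAString(seq), fixed = FALSE))
      brute <- brute_iupac_match(m, seq)
      expect_identical(as.integer(ours), as.integer(brute))
    }
  }
  expect_error(scan_motifs(default_sim()$genome,
                           tibble(motif_id = "bad", iupac = "TGXA"),
                           default_pipeline()$ann, default_sim()$genes),
               "IUPAC")
})

test_that("motif split separates destabilized isoforms within motif genes", {
  pipe <- study_pipeline()
  sim <- pipe$sim
  hits <- scan_motifs(sim$genome, sim$motifs, pipe$ann, sim$genes)
  fits_annot <- pipe$fits %>%
    filter(condition == "WT") %>%
    inner_join(pipe$ann %>% filter(!site_only),
               by = c("chrom", "pos", "strand"))
  split <- motif_stability_split(fits_annot, hits, "PUF3")
  expect_gt(split$test$n_with, 20)
  expect_gt(split$test$n_without, 20)
  # planted effect: motif-bearing isoforms decay ~2x faster
  expect_gt(split$test$median_ratio, 1.5)
  expect_lt(split$test$median_ratio, 2.5)
  expect_lt(split$test$p, 0.01)
  expect_true(all(split$distance$distance_to_3prime >= 0))
})

test_that("motif split handles empty groups without a test", {
  fits_annot <- tibble(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                       condition = "WT", k = c(0.05, 0.06), se_k = 0.005,
                       half_life = 10, n_points = 10L, abund_t0 = 100,
                       qc = "ok", coding = TRUE, gene_id = "g1",
                       utr3_length = c(50, 100))
  hits <- tibble(motif_id = "PUF3", chrom = "chr1", pos = c(10L, 20L),
                 strand = "+", tif_id = "T", gene_id = "g1",
                 hit_pos = 5L, distance_to_3prime = 10, contained = TRUE)
  split <- motif_stability_split(fits_annot, hits, "PUF3")
  expect_equal(split$test$n_without, 0)
  expect_true(is.na(split$test$p))
})

test_that("divergent pair detection respects orientation and gap", {
  genes <- tibble::tribble(
    ~gene_id, ~chrom, ~start, ~end, ~strand, ~biotype,
    "m1", "chr1", 100L, 400L, "-", "ORF",   # 5' at 399
    "p1", "chr1", 500L, 800L, "+", "ORF",   # divergent with m1, gap 102
    "p2", "chr1", 900L, 1200L, "+", "ORF",  # convergent with m2 (tail-tail)
    "m2", "chr1", 1300L, 1600L, "-", "ORF",
    "p3", "chr1", 5000L, 5300L, "+", "ORF"  # isolated
  )
  gene_k <- tibble(gene_id = c("m1", "p1", "p2", "m2", "p3"),
                   condition = "WT",
                   k_gene = c(0.05, 0.05, 0.02, 0.08, 0.1),
                   n_isoforms = 1L)
  res <- divergent_pair_correlation(genes, gene_k, max_gap = 200)
  expect_equal(nrow(res$pairs), 1)
  expect_true(is.na(res$correlation$rho))
  expect_equal(res$pairs$gene_minus, "m1")
  expect_equal(res$pairs$gene_plus, "p1")
  # identical k within pairs -> rho = 1 over a constructed set
  genes2 <- purrr::map(0:9, function(i) {
    tibble(gene_id = c(paste0("m", i, "x"), paste0("p", i, "x")),
           chrom = "chr2", start = c(1000L, 1500L) + i * 5000L,
           end = c(1400L, 1900L) + i * 5000L,
           strand = c("-", "+"), biotype = "ORF")
  }) %>% bind_rows()
  kk <- seq(0.01, 0.1, length.out = 10)
  gene_k2 <- tibble(gene_id = c(paste0("m", 0:9, "x"), paste0("p", 0:9, "x")),
                    condition = "WT", k_gene = c(kk, kk), n_isoforms = 1L)
  res2 <- divergent_pair_correlation(genes2, gene_k2, max_gap = 200)
  expect_equal(res2$correlation$n, 10)
  expect_equal(res2$correlation$rho, 1)
})
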