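test_that("mispriming filter removes A-rich downstream windows, strand-aware", {
  # chr1: site at pos 9 ('+') sees bases 10..27; build three scenarios
  a18 <- strrep("A", 18)
  acgt <- strrep("ACGT", 5)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("C", 10), a18, strrep("C", 30)),
    chr2 = paste0(strrep("C", 10), substr(acgt, 1, 18), strrep("C", 30)),
    chr3 = paste0(strrep("C", 10), strrep("T", 18), strrep("C", 30))
  ))
  counts <- bind_rows(
    tibble(chrom = "chr1", pos = 9L, strand = "+"),    # all-A window
    tibble(chrom = "chr2", pos = 9L, strand = "+"),    # mixed window
    tibble(chrom = "chr3", pos = 28L, strand = "-")    # plus-strand T => sense A
  ) %>%
    mutate(species = "sample", condition = "WT", timepoint = 0,
           replicate = "R1", count = 10)
  out <- filter_mispriming(counts, genome)
  kept <- distinct(out, chrom)
  expect_identical(kept$chrom, "chr2")
  rep <- mispriming_report(out)
  expect_setequal(rep$chrom, c("chr1", "chr3"))
  expect_true(all(grepl("a_", rep$reason)))
})

test_that("a 6-A run triggers removal even at moderate A fraction", {
  win <- paste0("AAAAAA", strrep("CGT", 4))  # run of 6, A-frac 1/3
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0("CC", win, "CC")))
  counts <- tibble(chrom = "chr1", pos = 1L, strand = "+", species = "sample",
                   condition = "WT", timepoint = 0, replicate = "R1",
                   count = 5)
  out <- filter_mispriming(counts, genome)
  expect_equal(nrow(out), 0)
  expect_equal(mispriming_report(out)$reason, "a_run")
})

test_that("windows past the chromosome end are truncated, not fatal", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "CCCCCCCCCCGT"))
  counts <- tibble(chrom = "chr1", pos = 9L, strand = "+", species = "sample",
                   condition = "WT", timepoint = 0, replicate = "R1",
                   count = 5)
  expect_equal(nrow(filter_mispriming(counts, genome)), 1)
})

test_that("mispriming filter is idempotent on simulated data", {
  sim <- default_sim()
  counts <- simulate_decay_counts(sim)
  once <- filter_mispriming(counts, sim$genome)
  twice <- filter_mispriming(once, sim$genome)
  expect_equal(as.data.frame(once), as.data.frame(twice), ignore_attr = TRUE)
  expect_equal(nrow(mispriming_report(twice)), 0)
})

test_that("spike size factors: geometric anchoring matches the hand computation", {
  mat <- rbind(c(50, 80), c(1000, 2000))
  colnames(mat) <- c("WT_0_R1", "WT_5_R1")
  counts <- counts_from_matrix(mat, pos = c(100L, 900L)) %>%
    mutate(species = if_else(pos == 900L, "spike", "sample"))
  sf <- spike_size_factors(counts, anchor = "geometric")
  expect_equal(sort(sf$size_factor), c(1 / sqrt(2), sqrt(2)))
  # reference anchoring: first library is the anchor
  sf_ref <- spike_size_factors(counts, anchor = "reference")
  expect_equal(sf_ref$size_factor[order(sf_ref$timepoint)], c(1, 2))
  # equal totals -> all factors 1 under either anchor
  eq <- counts %>% mutate(count = if_else(species == "spike", 1000, count))
  expect_equal(spike_size_factors(eq, anchor = "geometric")$size_factor,
               c(1, 1))
})

test_that("a library with zero spike counts is a hard error", {
  mat <- rbind(c(50, 80), c(1000, 0))
  colnames(mat) <- c("WT_0_R1", "WT_5_R1")
  counts <- counts_from_matrix(mat, pos = c(100L, 900L)) %>%
    mutate(species = if_else(pos == 900L, "spike", "sample"))
  expect_error(spike_size_factors(counts), "zero spike")
})

test_that("rescaling one library leaves normalized counts invariant (reference anchor)", {
  sim <- default_sim()
  counts <- simulate_decay_counts(sim)
  norm1 <- normalize_counts(counts, spike_size_factors(counts))
  scaled <- counts %>%
    mutate(count = if_else(timepoint == 10 & replicate == "R2",
                           count * 3, count))
  norm3 <- normalize_counts(scaled, spike_size_factors(scaled))
  key <- c("chrom", "pos", "strand", "condition", "timepoint", "replicate")
  j <- inner_join(norm1 %>% select(all_of(key), n1 = norm_count),
                  norm3 %>% select(all_of(key), n3 = norm_count),
                  by = key)
  expect_lt(max(abs(j$n1 - j$n3)), 1e-12)
})

test_that("under geometric anchoring, rescaling shifts all libraries by one common factor", {
  sim <- default_sim()
  counts <- simulate_decay_counts(sim)
  norm1 <- normalize_counts(counts, spike_size_factors(counts,
                                                       anchor = "geometric"))
  scaled <- counts %>%
    mutate(count = if_else(timepoint == 10 & replicate == "R2",
                           count * 3, count))
  norm3 <- normalize_counts(scaled, spike_size_factors(scaled,
                                                       anchor = "geometric"))
  key <- c("chrom", "pos", "strand", "condition", "timepoint", "replicate")
  j <- inner_join(norm1 %>% select(all_of(key), n1 = norm_count),
                  norm3 %>% select(all_of(key), n3 = norm_count),
                  by = key) %>%
    filter(n1 > 0)
  ratios <- j$n3 / j$n1
  n_lib <- 10
  expect_lt(diff(range(ratios)), 1e-12)
  expect_equal(unique(round(ratios, 10)), round(3^(1 / n_lib), 10))
})

test_that("per-site method-of-moments dispersion matches the hand computation", {
  # replicate counts (100, 140): m = 120, v = 800, alpha = 680/14400
  counts <- tibble(chrom = "chr1", pos = 100L, strand = "+",
                   species = "sample", condition = "WT", timepoint = 0,
                   replicate = c("R1", "R2"), count = c(100, 140),
                   norm_count = c(100, 140), size_factor = 1)
  m <- estimate_dispersion(counts, min_mean = 16)
  expect_equal(m$a0, 680 / 14400, tolerance = 1e-12)
  expect_equal(m$a1, 0)
})

test_that("equal replicate counts clamp dispersion at the floor", {
  counts <- tibble(chrom = "chr1", pos = 100L, strand = "+",
                   species = "sample", condition = "WT", timepoint = 0,
                   replicate = c("R1", "R2"), count = c(100, 100),
                   norm_count = c(100, 100), size_factor = 1)
  m <- estimate_dispersion(counts)
  expect_equal(m$a0, 0)
  expect_equal(predict_dispersion(m, "WT", 0, 100), m$alpha_floor[1])
})

test_that("Poisson data yield a near-zero dispersion intercept", {
  set.seed(11)
  n_sites <- 300
  mu <- exp(runif(n_sites, log(50), log(2000)))
  counts <- purrr::map(c("R1", "R2", "R3", "R4"), function(r) {
    tibble(chrom = "chr1", pos = seq_len(n_sites) * 10L, strand = "+",
           species = "sample", condition = "WT", timepoint = 0,
           replicate = r, count = rpois(n_sites, mu))
  }) %>%
    bind_rows() %>%
    mutate(norm_count = count, size_factor = 1)
  m <- estimate_dispersion(counts)
  expect_gte(m$a0, 0)
  expect_lte(m$a0, 0.01)
  # and dispersion recovery: constant NB alpha is found at large mu
  alpha_true <- 0.1
  counts_nb <- counts %>%
    mutate(count = isodecay:::draw_nb(rep(mu, 4), alpha_true),
           norm_count = count)
  m2 <- estimate_dispersion(counts_nb)
  fitted <- predict_dispersion(m2, "WT", 0, 1000)
  expect_lt(abs(fitted - alpha_true) / alpha_true, 0.35)
})

test_that("single-replicate timepoints refuse dispersion estimation", {
  counts <- tibble(chrom = "chr1", pos = 100L, strand = "+",
                   species = "sample", condition = "WT", timepoint = 0,
                   replicate = "R1", count = 100, norm_count = 100,
                   size_factor = 1)
  expect_error(estimate_dispersion(counts), "2 replicates")
})

test_that("reliability filter applies the first-timepoint and nonzero-timepoint rules", {
  mk <- function(counts_vec) {
    tibble(chrom = "chr1", pos = 100L, strand = "+", species = "sample",
           condition = "WT", timepoint = c(0, 5, 10, 20, 40),
           replicate = "R1", count = counts_vec, norm_count = counts_vec)
  }
  expect_equal(nrow(filter_reliable(mk(c(100, 50, 25, 12, 6)))), 5)
  expect_equal(nrow(filter_reliable(mk(c(100, 0, 0, 0, 0)))), 0)
  expect_equal(nrow(filter_reliable(mk(c(10, 5, 2, 1, 0)), min_count = 16)), 0)
  # spike sites never pass through
  spike <- mk(c(100, 100, 100, 100, 100)) %>% mutate(species = "spike")
  expect_equal(nrow(filter_reliable(bind_rows(mk(c(100, 50, 25, 12, 6)),
                                              spike))), 5)
})
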