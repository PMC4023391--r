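# Shared fixtures, built in code. The default simulation is cached per
# session so several test files can reuse it without re-generating.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
  library(tidyr)
})

.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_genome_and_annotation(
      n_genes = 40, seed = 7, config = run_config(seed = 7))
  }
  .fixture_env$sim
}

# full decay pipeline on the default simulation (WT + mutant), cached
default_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    sim <- default_sim()
    counts <- simulate_decay_counts(sim, conditions = c("WT", "mutant"))
    filt <- filter_mispriming(counts, sim$genome)
    norm <- normalize_counts(filt, spike_size_factors(filt))
    disp <- estimate_dispersion(norm)
    rel <- filter_reliable(norm)
    fits <- fit_decay(rel, disp)
    ann <- classify_isoforms(
      match_tifs(distinct(filt, chrom, pos, strand) %>%
                   filter(chrom == "chrS"), sim$tifs),
      sim$genes
    )
    .fixture_env$pipe <- list(sim = sim, counts = counts, norm = norm,
                              disp = disp, rel = rel, fits = fits, ann = ann)
  }
  .fixture_env$pipe
}

# larger study-scale pipeline (~500 isoforms), cached; also used by the
# acceptance suite
study_pipeline <- function() {
  if (is.null(.fixture_env$study)) {
    sim <- simulate_genome_and_annotation(
      n_genes = 170, seed = 11, config = run_config(seed = 11))
    counts <- simulate_decay_counts(sim, conditions = c("WT", "mutant"))
    filt <- filter_mispriming(counts, sim$genome)
    norm <- normalize_counts(filt, spike_size_factors(filt))
    disp <- estimate_dispersion(norm)
    rel <- filter_reliable(norm)
    fits <- fit_decay(rel, disp)
    ann <- classify_isoforms(
      match_tifs(distinct(filt, chrom, pos, strand) %>%
                   filter(chrom == "chrS"), sim$tifs),
      sim$genes
    )
    .fixture_env$study <- list(sim = sim, counts = counts, norm = norm,
                               disp = disp, rel = rel, fits = fits, ann = ann)
  }
  .fixture_env$study
}

# a long count tibble from a site x library matrix; library names follow the
# <condition>_<timepoint>_<replicate> convention
counts_from_matrix <- function(mat, chrom = "chr1", pos = NULL,
                               strand = "+", species = "sample") {
  if (is.null(pos)) pos <- seq_len(nrow(mat)) * 100L
  tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
         species = species) %>%
    dplyr::bind_cols(as_tibble(mat)) %>%
    pivot_longer(-(1:4), names_to = c("condition", "timepoint", "replicate"),
                 names_sep = "_", values_to = "count") %>%
    mutate(timepoint = as.numeric(timepoint))
}

# one-site decay series with one replicate; optionally a parallel spike site
# with constant counts so that normalization is the identity
single_site_counts <- function(counts, timepoints, replicate = "R1",
                               condition = "WT", spike = TRUE) {
  site <- tibble(chrom = "chr1", pos = 100L, strand = "+",
                 species = "sample", condition = condition,
                 timepoint = timepoints, replicate = replicate,
                 count = counts)
  if (!spike) return(site)
  bind_rows(site, site %>% mutate(pos = 900L, species = "spike",
                                  count = 1000))
}

# size factors that are exactly 1 for the libraries present
unit_size_factors <- function(counts) {
  distinct(counts, condition, timepoint, replicate) %>%
    mutate(size_factor = 1)
}

# a flat dispersion model covering the (condition, timepoint) combinations
flat_dispersion <- function(counts, a0 = 0, floor = 1e-8) {
  m <- distinct(counts, condition, timepoint) %>%
    mutate(a0 = a0, a1 = 0, alpha_floor = floor, n_sites = 0L)
  class(m) <- c("dispersion_model", class(m))
  m
}

# brute-force weighted normal equations: shared slope, per-replicate
# intercepts; the independent oracle for fit_decay
oracle_wls <- function(y, t, rep_label, w) {
  reps <- unique(rep_label)
  X <- cbind(sapply(reps, function(r) as.numeric(rep_label == r)), t)
  XtW <- t(X) %*% diag(w, nrow = length(w))
  cov_b <- solve(XtW %*% X)
  b <- cov_b %*% XtW %*% y
  p <- ncol(X)
  list(k = unname(-b[p, 1]), se_k = unname(sqrt(cov_b[p, p])))
}

# naive IUPAC matcher: expands the pattern position by position and checks
# every window of the subject
brute_iupac_match <- function(pattern, subject) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  np <- length(p); ns <- length(s)
  if (ns < np) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(ns - np + 1)) {
    ok <- TRUE
    for (j in seq_len(np)) {
      if (!(s[i + j - 1] %in% iupac[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hand-labeled classification fixture (see test-annotate.R for use)
# Gene layout on a 3000-nt chromosome (0-based half-open CDS intervals):
#   GA: + CDS [100, 400)     GB: + CDS [600, 900)   (tandem pair)
#   GC: - CDS [1300, 1600)
#   SUTX: + SUT [1800, 1900)
#   GD: - CDS [2200, 2500)
fixture_genes <- function() {
  tibble::tribble(
    ~gene_id, ~chrom, ~start, ~end, ~strand, ~biotype,
    "GA", "chrF", 100L, 400L, "+", "ORF",
    "GB", "chrF", 600L, 900L, "+", "ORF",
    "GC", "chrF", 1300L, 1600L, "-", "ORF",
    "SUTX", "chrF", 1800L, 1900L, "+", "SUT",
    "GD", "chrF", 2200L, 2500L, "-", "ORF"
  )
}

# each case: a TIF (start5/end3 in transcript orientation) and its expected
# category / coding flag / 3'UTR length
fixture_cases <- function() {
  tibble::tribble(
    ~tif_id, ~strand, ~start5, ~end3, ~category, ~coding, ~utr3,
    # --- coding, one ORF, plus strand --------------------------------------
    "c01", "+", 80L, 519L, "coding_1orf", TRUE, 120,   # 120 nt past stop
    "c02", "+", 90L, 450L, "coding_1orf", TRUE, 51,
    "c03", "+", 100L, 399L, "coding_1orf", TRUE, 0,    # ends at stop base
    "c04", "+", 50L, 420L, "coding_1orf", TRUE, 21,
    # --- coding, one ORF, minus strand (GC stop codon at 1300) -------------
    "c05", "-", 1650L, 1200L, "coding_1orf", TRUE, 100,
    "c06", "-", 1620L, 1300L, "coding_1orf", TRUE, 0,
    "c07", "-", 1700L, 1250L, "coding_1orf", TRUE, 50,
    # --- coding, two ORFs --------------------------------------------------
    "c08", "+", 80L, 950L, "coding_2plus_orf", TRUE, 51,
    "c09", "+", 50L, 899L, "coding_2plus_orf", TRUE, 0,
    "c10", "+", 99L, 1000L, "coding_2plus_orf", TRUE, 101,
    # --- partial over two ORFs ---------------------------------------------
    "c11", "+", 200L, 700L, "partial_2orf", FALSE, NA,
    "c12", "+", 399L, 600L, "partial_2orf", FALSE, NA,  # touches both ends
    "c13", "+", 150L, 850L, "partial_2orf", FALSE, NA,
    # --- intragenic --------------------------------------------------------
    "c14", "+", 150L, 350L, "intragenic", FALSE, NA,
    "c15", "+", 101L, 398L, "intragenic", FALSE, NA,   # inside, misses both ends
    "c16", "-", 1550L, 1350L, "intragenic", FALSE, NA,
    "c17", "-", 2400L, 2300L, "intragenic", FALSE, NA,
    # --- overlap of the 3' portion only ------------------------------------
    "c18", "+", 200L, 520L, "overlap_3prime", FALSE, NA,
    "c19", "+", 399L, 450L, "overlap_3prime", FALSE, NA, # contains stop base
    "c20", "-", 1500L, 1250L, "overlap_3prime", FALSE, NA,
    "c21", "-", 2300L, 2100L, "overlap_3prime", FALSE, NA,
    # --- overlap of the 5' portion only ------------------------------------
    "c22", "+", 50L, 200L, "overlap_5prime", FALSE, NA,
    "c23", "+", 100L, 300L, "overlap_5prime", FALSE, NA, # contains start base
    "c24", "-", 1700L, 1400L, "overlap_5prime", FALSE, NA,
    "c25", "-", 2600L, 2350L, "overlap_5prime", FALSE, NA,
    # --- SUT (>= 50% reciprocal overlap with SUTX [1800,1900)) -------------
    "c26", "+", 1790L, 1910L, "sut", FALSE, NA,
    "c27", "+", 1810L, 1890L, "sut", FALSE, NA,
    # --- intergenic --------------------------------------------------------
    "c28", "+", 2600L, 2700L, "intergenic", FALSE, NA,
    "c29", "-", 1150L, 1000L, "intergenic", FALSE, NA,
    "c30", "+", 450L, 550L, "intergenic", FALSE, NA
  )
}

fixture_matched <- function(cases) {
  cases %>%
    mutate(chrom = "chrF", pos = end3, support = 1L, matched = TRUE) %>%
    select(chrom, pos, strand, tif_id, start5, end3, support, matched)
}

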