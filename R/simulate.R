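#' Simulate a genome, gene models, full-length isoforms and ground truth
#'
#' Builds a synthetic chromosome with protein-coding genes on both strands,
#' each expressing 1-4 alternative 3' isoforms, plus constructs that realize
#' every coverage category the classifier distinguishes: tandem gene pairs
#' spanned by a bicistronic isoform, an isoform partially covering two
#' adjacent CDSs, intragenic and 5'/3'-overlap isoforms, SUT-assigned
#' isoforms, intergenic isoforms, and a bare internal-priming artifact site
#' whose downstream window is an A tract. A PUF3-like destabilizing motif
#' (default `TGTAAATA`) is planted in a configurable fraction of genes such
#' that only the distal isoform contains it; chance occurrences of the motif
#' elsewhere in the random genome are scrubbed so motif truth is exact.
#'
#' A separate spike-in chromosome carries sites whose total expected
#' abundance is 1/9 of the total sample abundance at time zero, emulating a
#' 1:9 spike-in mass ratio.
#'
#' Every poly(A) site except the artifact gets a fixed low-A downstream
#' window, so the mispriming filter's ground truth is exact by construction.
#'
#' @param n_genes Number of protein-coding genes (>= 20 to realize all eight
#'   coverage categories; fewer triggers a warning naming the missing ones).
#' @param seed Integer seed; the whole output is a deterministic function of
#'   it.
#' @param config A [run_config()].
#' @param motif IUPAC string of the planted destabilizing motif.
#' @param motif_frac Fraction of multi-isoform genes whose distal isoform
#'   carries the motif (default 0.5).
#' @param halflife_range Range in minutes of true baseline half-lives, drawn
#'   log-uniformly per gene (default `c(4, 180)`, the span observed in
#'   yeast). Isoforms of a gene share the gene's baseline rate — multiplied
#'   by `iso_sdlog` jitter when requested — so that within-gene rate
#'   differences come only from planted effects (and jitter), giving the
#'   differential-stability tests a well-defined null.
#' @param iso_sdlog Log-sd of per-isoform multiplicative jitter around the
#'   gene baseline rate (default 0: isoforms of a gene share k exactly).
#' @param depth_meanlog,depth_sdlog Log-normal parameters of the true t0
#'   abundance per isoform; defaults give a median depth of 200.
#' @param n_spike Number of spike-in sites.
#' @param noncoding_bound_frac Fraction of non-coding isoforms flagged as
#'   RBP-bound without any planted decay effect (mirrors binding of
#'   non-coding isoforms that does not alter their stability).
#'
#' @return A list of class `isodecay_sim` with elements `genome`
#'   (`DNAStringSet`), `genes`, `tifs`, `motifs`, `truth` (tibbles) and the
#'   `config` used. `truth` holds, per site: identity, true category, motif /
#'   bound / destabilized flags, baseline decay rate `k_base` (1/min), the
#'   condition-specific rates `k_wt` and `k_mut`, and t0 abundance `A0`.
#' @export
simulate_genome_and_annotation <- function(n_genes = 40,
                                           seed = 1L,
                                           config = run_config(seed = seed),
                                           motif = "TGTAAATA",
                                           motif_frac = 0.5,
                                           halflife_range = c(4, 180),
                                           iso_sdlog = 0,
                                           depth_meanlog = log(200),
                                           depth_sdlog = 0.5,
                                           n_spike = 20,
                                           noncoding_bound_frac = 0.4) {
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  set.seed(seed)
  flank <- 420L   # room for 3'UTR isoform ladder + forced windows
  u5 <- 60L       # 5' side flank
  motif_k_mult <- 2

  specials <- rep(c("intragenic", "overlap_3prime", "overlap_5prime",
                    "sut", "intergenic", "artifact"), each = 3)
  kinds <- c("tandem1", "tandem2", specials)
  if (n_genes < length(kinds)) {
    realized <- unique(kinds[seq_len(n_genes)])
    missing_cats <- setdiff(
      c("coding_2plus_orf", "partial_2orf", specials),
      c(realized,
        if (all(c("tandem1", "tandem2") %in% realized))
          c("coding_2plus_orf", "partial_2orf"))
    )
    if (length(missing_cats) > 0) {
      warn(sprintf(
        "n_genes = %d is too small to realize all coverage categories; missing: %s",
        n_genes, paste(unique(missing_cats), collapse = ", ")
      ))
    }
    kinds <- kinds[seq_len(n_genes)]
  } else {
    kinds <- c(kinds, rep("standard", n_genes - length(kinds)))
  }

  genes <- list(); tifs <- list(); truth <- list()
  planted_motifs <- list()  # genomic plus-strand intervals carrying the motif
  forced_windows <- list()  # (start, width, sense_strand, type)
  tif_n <- 0L
  cursor <- 0L
  prev <- NULL  # info about previous gene, for the tandem constructs

  new_tif <- function() {
    tif_n <<- tif_n + 1L
    sprintf("TIF%04d", tif_n)
  }

  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    gid <- sprintf("GENE%03d", i)
    strand <- if (kind %in% c("tandem1", "tandem2")) "+" else
      if (i %% 2 == 0) "-" else "+"
    gap <- sample(200:300, 1)
    cds_len <- sample(300:600, 1)
    left <- if (strand == "+") u5 else flank
    right <- if (strand == "+") flank else u5
    cds_start <- cursor + gap + left
    cds_end <- cds_start + cds_len
    genes[[length(genes) + 1]] <- tibble(
      gene_id = gid, chrom = "chrS", start = cds_start, end = cds_end,
      strand = strand, biotype = "ORF"
    )

    # --- standard coding isoform ladder (every gene gets one) -------------
    n_iso <- sample(1:4, 1)
    offs <- cumsum(c(sample(30:60, 1), sample(55:85, n_iso)))[seq_len(n_iso)]
    has_motif <- n_iso >= 2 && runif(1) < motif_frac
    for (j in seq_len(n_iso)) {
      off <- offs[j]
      pos <- if (strand == "+") cds_end + off - 1L else cds_start - off
      tid <- new_tif()
      start5 <- if (strand == "+") cds_start - sample(20:40, 1) else
        cds_end - 1L + sample(20:40, 1)
      tifs[[length(tifs) + 1]] <- tibble(
        tif_id = tid, chrom = "chrS", strand = strand,
        start5 = start5, end3 = pos, support = sample(5:50, 1)
      )
      is_distal <- j == n_iso
      motif_here <- has_motif && is_distal
      truth[[length(truth) + 1]] <- tibble(
        chrom = "chrS", pos = pos, strand = strand, species = "sample",
        site_class = "isoform", gene_id = gid, tif_id = tid,
        category_true = "coding_1orf", coding_true = TRUE,
        utr3_true = off, motif = motif_here, artifact = FALSE
      )
      forced_windows[[length(forced_windows) + 1]] <-
        list(pos = pos, strand = strand, type = "neutral")
      if (motif_here) {
        d <- sample(20L:25L, 1)  # transcript distance from motif end to site
        if (strand == "+") {
          mstart <- pos - d - 7L  # 0-based first base of motif
        } else {
          mstart <- pos + d
        }
        planted_motifs[[length(planted_motifs) + 1]] <-
          list(start = mstart, strand = strand, pos = pos, d = d, tif = tid)
      }
    }
    max_off <- max(offs)

    # --- special constructs ----------------------------------------------
    add_site <- function(pos, strand, tid, gid2, category, coding, utr3) {
      truth[[length(truth) + 1]] <<- tibble(
        chrom = "chrS", pos = pos, strand = strand, species = "sample",
        site_class = "isoform", gene_id = gid2, tif_id = tid,
        category_true = category, coding_true = coding,
        utr3_true = utr3, motif = FALSE, artifact = FALSE
      )
      forced_windows[[length(forced_windows) + 1]] <<-
        list(pos = pos, strand = strand, type = "neutral")
    }
    add_tif <- function(tid, strand, start5, end3) {
      tifs[[length(tifs) + 1]] <<- tibble(
        tif_id = tid, chrom = "chrS", strand = strand,
        start5 = start5, end3 = end3, support = sample(2:20, 1)
      )
    }

    zone <- 0L
    if (kind == "tandem2" && !is.null(prev)) {
      # bicistronic isoform spanning both CDSs of the tandem '+' pair
      off2 <- max_off + 60L
      pos2 <- cds_end + off2 - 1L
      tid <- new_tif()
      add_tif(tid, "+", prev$cds_start - 35L, pos2)
      add_site(pos2, "+", tid, gid, "coding_2plus_orf", TRUE, off2)
      # isoform partially covering both CDSs, ends inside this CDS
      posp <- cds_start + 60L
      tid <- new_tif()
      add_tif(tid, "+", prev$cds_start + 50L, posp)
      add_site(posp, "+", tid, gid, "partial_2orf", FALSE, NA_real_)
    } else if (kind == "intragenic") {
      len <- sample(100:min(cds_len - 80L, 220L), 1)
      tid <- new_tif()
      if (strand == "+") {
        s5 <- cds_start + 30L; pos <- s5 + len
      } else {
        s5 <- cds_end - 31L; pos <- s5 - len
      }
      add_tif(tid, strand, s5, pos)
      add_site(pos, strand, tid, gid, "intragenic", FALSE, NA_real_)
    } else if (kind == "overlap_3prime") {
      off <- max_off + 60L
      tid <- new_tif()
      if (strand == "+") {
        s5 <- cds_start + round(cds_len / 2); pos <- cds_end + off - 1L
      } else {
        s5 <- cds_end - round(cds_len / 2); pos <- cds_start - off
      }
      add_tif(tid, strand, s5, pos)
      add_site(pos, strand, tid, gid, "overlap_3prime", FALSE, NA_real_)
    } else if (kind == "overlap_5prime") {
      inside <- sample(80:150, 1)
      tid <- new_tif()
      if (strand == "+") {
        s5 <- cds_start - 40L; pos <- cds_start + inside
      } else {
        s5 <- cds_end + 39L; pos <- cds_end - inside
      }
      add_tif(tid, strand, s5, pos)
      add_site(pos, strand, tid, gid, "overlap_5prime", FALSE, NA_real_)
    } else if (kind %in% c("sut", "intergenic", "artifact")) {
      zone <- 260L
      z <- cds_end + right  # start of the downstream feature zone
      if (kind == "sut") {
        sut_id <- sprintf("SUT%03d", i)
        genes[[length(genes) + 1]] <- tibble(
          gene_id = sut_id, chrom = "chrS", start = z + 50L, end = z + 170L,
          strand = "+", biotype = "SUT"
        )
        tid <- new_tif()
        add_tif(tid, "+", z + 55L, z + 165L)
        add_site(z + 165L, "+", tid, sut_id, "sut", FALSE, NA_real_)
      } else if (kind == "intergenic") {
        tid <- new_tif()
        add_tif(tid, "+", z + 60L, z + 160L)
        add_site(z + 160L, "+", tid, NA_character_, "intergenic", FALSE,
                 NA_real_)
      } else {  # artifact: bare A-tract mispriming site, no TIF
        pos <- z + 100L
        truth[[length(truth) + 1]] <- tibble(
          chrom = "chrS", pos = pos, strand = "+", species = "sample",
          site_class = "artifact", gene_id = NA_character_,
          tif_id = NA_character_, category_true = NA_character_,
          coding_true = FALSE, utr3_true = NA_real_, motif = FALSE,
          artifact = TRUE
        )
        forced_windows[[length(forced_windows) + 1]] <-
          list(pos = pos, strand = "+", type = "a_tract")
      }
    }

    prev <- list(cds_start = cds_start, cds_end = cds_end)
    cursor <- cds_end + right + zone
  }

  genes <- list_rbind(genes)
  tifs <- validate_tifs(list_rbind(tifs))
  truth <- list_rbind(truth)

  # --- genome sequence ------------------------------------------------------
  chr_len <- cursor + 500L
  base_probs <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  chr_seq <- paste(sample(names(base_probs), chr_len, replace = TRUE,
                          prob = base_probs), collapse = "")
  chr <- Biostrings::DNAString(chr_seq)

  neutral <- "CGTCGTCGACTGCATGCA"  # 18 nt, low A, no A run
  stopifnot(nchar(neutral) == 18)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  repl_at <- function(chr, start0, seq) {
    # start0: 0-based start of replacement
    Biostrings::replaceAt(chr,
                          IRanges::IRanges(start0 + 1L, start0 + nchar(seq)),
                          seq)
  }
  for (fw in forced_windows) {
    win <- if (fw$type == "a_tract") strrep("A", 18) else neutral
    if (fw$strand == "+") {
      chr <- repl_at(chr, fw$pos + 1L, win)
    } else {
      chr <- repl_at(chr, fw$pos - 18L, rc(win))
    }
  }
  for (pm in planted_motifs) {
    seq <- if (pm$strand == "+") motif else rc(motif)
    chr <- repl_at(chr, pm$start, seq)
  }

  # scrub chance motif occurrences so motif ground truth is exact
  planted_starts <- map_dbl(planted_motifs, function(p) p$start)
  for (pass in 1:3) {
    hits <- c(
      BiocGenerics::start(Biostrings::matchPattern(motif, chr, fixed = TRUE)),
      BiocGenerics::start(Biostrings::matchPattern(rc(motif), chr,
                                                   fixed = TRUE))
    ) - 1L
    stray <- setdiff(hits, planted_starts)
    if (length(stray) == 0) break
    for (s in stray) {
      old <- as.character(Biostrings::subseq(chr, s + 1L, s + 1L))
      chr <- repl_at(chr, s, if (old == "C") "G" else "C")
    }
  }

  spike_len <- 200L + n_spike * 120L
  spike_seq <- paste(sample(names(base_probs), spike_len, replace = TRUE,
                            prob = base_probs), collapse = "")
  spike_chr <- Biostrings::DNAString(spike_seq)
  spike_pos <- 50L + (seq_len(n_spike) - 1L) * 120L
  for (p in spike_pos) {
    spike_chr <- repl_at(spike_chr, p + 1L, neutral)
  }
  genome <- Biostrings::DNAStringSet(list(chrS = chr, spike_1 = spike_chr))

  # --- generative parameters ------------------------------------------------
  # gene-level baseline half-life; sites without a gene (artifact,
  # intergenic) draw their own baseline
  n_sites <- nrow(truth)
  unit <- if_else(is.na(truth$gene_id),
                  paste0("orphan_", seq_len(n_sites)), truth$gene_id)
  units <- unique(unit)
  t_half_unit <- setNames(
    exp(runif(length(units), log(halflife_range[1]),
              log(halflife_range[2]))),
    units
  )
  jitter <- if (iso_sdlog > 0) rlnorm(n_sites, 0, iso_sdlog) else rep(1, n_sites)
  truth$k_base <- log(2) / t_half_unit[unit] * jitter
  truth$A0 <- rlnorm(n_sites, depth_meanlog, depth_sdlog)

  # bound set: all destabilized (motif-carrying coding) isoforms, plus a
  # fraction of non-coding isoforms with no planted decay effect
  truth$destabilized <- truth$motif & truth$coding_true
  noncoding_iso <- which(!truth$coding_true & truth$site_class == "isoform")
  bound_nc <- noncoding_iso[runif(length(noncoding_iso)) < noncoding_bound_frac]
  truth$bound <- truth$destabilized
  truth$bound[bound_nc] <- TRUE
  truth$k_wt <- truth$k_base * ifelse(truth$destabilized, motif_k_mult, 1)
  truth$k_mut <- truth$k_base

  spike_truth <- tibble(
    chrom = "spike_1", pos = spike_pos, strand = "+", species = "spike",
    site_class = "spike", gene_id = NA_character_, tif_id = NA_character_,
    category_true = NA_character_, coding_true = FALSE, utr3_true = NA_real_,
    motif = FALSE, artifact = FALSE,
    k_base = 0, A0 = 0, destabilized = FALSE, bound = FALSE,
    k_wt = 0, k_mut = 0
  )
  w <- rlnorm(n_spike, 0, 0.5)
  spike_truth$A0 <- w / sum(w) * sum(truth$A0) / 9  # 1:9 spike:sample mass

  truth <- bind_rows(truth, spike_truth)

  structure(
    list(
      genome = genome,
      genes = genes,
      tifs = tifs,
      motifs = tibble(motif_id = "PUF3", iupac = motif),
      truth = truth,
      config = config,
      motif_k_mult = motif_k_mult
    ),
    class = "isodecay_sim"
  )
}

#' @export
print.isodecay_sim <- function(x, ...) {
  cat("<isodecay_sim>\n")
  cat(sprintf("  genome: %d sequences (%s nt)\n", length(x$genome),
              paste(Biostrings::width(x$genome), collapse = ", ")))
  cat(sprintf("  genes: %d (%d ORF, %d SUT)\n", nrow(x$genes),
              sum(x$genes$biotype == "ORF"), sum(x$genes$biotype == "SUT")))
  cat(sprintf("  TIFs: %d; sites: %d (%d spike, %d artifact)\n",
              nrow(x$tifs), nrow(x$truth), sum(x$truth$species == "spike"),
              sum(x$truth$artifact)))
  invisible(x)
}

#' Simulate decay time-course counts from ground truth
#'
#' Draws raw counts `K ~ NB(mean = s_jr * A0 * exp(-k * t_j), dispersion
#' alpha_j)` for every site, timepoint and replicate, in one or two
#' conditions. Spike-in sites keep a constant expected abundance across
#' timepoints (their molecular amount per sample is fixed), so only the
#' library size factor moves them. Isoforms carrying the planted motif decay
#' with an elevated rate in the wild type; in the mutant condition every
#' isoform reverts to its baseline rate, emulating deletion of the
#' destabilizing RBP.
#'
#' @param sim An `isodecay_sim` from [simulate_genome_and_annotation()].
#' @param config A [run_config()]; provides timepoints and replicate labels.
#' @param conditions Character vector, subset of `c("WT", "mutant")`.
#' @param alpha_range Per-timepoint NB dispersions, linearly increasing from
#'   `alpha_range[1]` at the first timepoint to `alpha_range[2]` at the last
#'   (technical noise rises as counts fall late in the time course). Use
#'   `c(0, 0)` for Poisson counts.
#' @param sf_sdlog Log-sd of the true library size factors (log-normal around
#'   1); nonzero values force the normalization stage to do real work.
#' @param seed Seed; defaults to `config$seed`.
#'
#' @return Long count tibble (`chrom`, `pos`, `strand`, `species`,
#'   `condition`, `timepoint`, `replicate`, `count`) with attribute
#'   `"libraries"`: a tibble of the true per-library size factors and
#'   per-timepoint dispersions.
#' @export
simulate_decay_counts <- function(sim,
                                  config = sim$config,
                                  conditions = "WT",
                                  alpha_range = c(0.02, 0.2),
                                  sf_sdlog = 0.15,
                                  seed = config$seed) {
  if (any(alpha_range < 0)) abort("dispersions must be >= 0.")
  stopifnot(all(conditions %in% c("WT", "mutant")))
  set.seed(seed)
  tp <- config$timepoints
  alpha_j <- seq(alpha_range[1], alpha_range[2], length.out = length(tp))

  libs <- crossing(condition = conditions,
                   timepoint = tp,
                   replicate = config$replicates) %>%
    mutate(s_true = rlnorm(dplyr::n(), 0, sf_sdlog)) %>%
    left_join(tibble(timepoint = tp, alpha_true = alpha_j), by = "timepoint")

  truth <- sim$truth
  out <- crossing(
    truth %>% select("chrom", "pos", "strand", "species", "site_class",
                     "k_wt", "k_mut", "A0"),
    libs
  ) %>%
    mutate(
      k_eff = dplyr::case_when(
        .data$species == "spike" ~ 0,
        .data$condition == "WT" ~ .data$k_wt,
        TRUE ~ .data$k_mut
      ),
      mu = .data$s_true * .data$A0 * exp(-.data$k_eff * .data$timepoint),
      count = draw_nb(.data$mu, .data$alpha_true)
    ) %>%
    select("chrom", "pos", "strand", "species", "condition", "timepoint",
           "replicate", "count") %>%
    arrange(.data$condition, .data$chrom, .data$pos, .data$strand,
            .data$timepoint, .data$replicate)
  attr(out, "libraries") <- libs
  out
}

# NB draw parameterized by mean and dispersion alpha (Var = mu + alpha*mu^2);
# alpha = 0 is the Poisson limit.
draw_nb <- function(mu, alpha) {
  n <- length(mu)
  alpha <- rep_len(alpha, n)
  out <- numeric(n)
  pois <- alpha == 0
  out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / alpha[!pois])
  }
  out
}

#' Simulate RNA-immunoprecipitation (RIP) counts
#'
#' Draws NB counts around steady-state abundances for matched `input` and
#' `IP` libraries. The IP mean of isoforms flagged `bound` in the ground
#' truth is multiplied by `enrichment`; unbound isoforms get a background
#' factor of 1. Library size factors are drawn log-normal so the
#' median-of-ratios normalization is exercised.
#'
#' @param sim An `isodecay_sim`.
#' @param enrichment IP/input mean ratio for bound isoforms (> 1).
#' @param n_reps Number of replicates per fraction (default 3, i.e.
#'   triplicate experiments).
#' @param alpha NB dispersion (default 0.05).
#' @param background IP/input ratio for unbound isoforms (default 1).
#' @param sf_sdlog Log-sd of true library size factors.
#' @param seed Seed.
#' @return Long count tibble with conditions `input` and `IP` (all at
#'   `timepoint = 0`), sample-species sites only, plus a `"libraries"`
#'   attribute with the true size factors.
#' @export
simulate_rip_counts <- function(sim,
                                enrichment = 8,
                                n_reps = 3,
                                alpha = 0.05,
                                background = 1,
                                sf_sdlog = 0.15,
                                seed = sim$config$seed) {
  if (enrichment <= 0) abort("`enrichment` must be > 0.")
  if (alpha < 0) abort("dispersion must be >= 0.")
  set.seed(seed)
  reps <- paste0("R", seq_len(n_reps))
  libs <- crossing(condition = c("input", "IP"), replicate = reps) %>%
    mutate(timepoint = 0, s_true = rlnorm(dplyr::n(), 0, sf_sdlog))

  truth <- sim$truth %>% filter(.data$species == "sample")
  out <- crossing(
    truth %>% select("chrom", "pos", "strand", "species", "bound", "A0"),
    libs
  ) %>%
    mutate(
      mu = .data$s_true * .data$A0 *
        if_else(.data$condition == "IP" & .data$bound, enrichment, background),
      count = draw_nb(.data$mu, alpha)
    ) %>%
    select("chrom", "pos", "strand", "species", "condition", "timepoint",
           "replicate", "count") %>%
    arrange(.data$condition, .data$replicate, .data$chrom, .data$pos)
  attr(out, "libraries") <- libs
  out
}

#' Write all simulated inputs to disk
#'
#' Emits exactly the file formats the readers consume: `genome.fa`,
#' `genes.gff3`, `tifs.tsv`, `motifs.tsv`, `truth.tsv` and, when count
#' tables are supplied, `counts_decay.tsv` / `counts_rip.tsv`.
#'
#' @param sim An `isodecay_sim`.
#' @param dir Output directory (created if needed).
#' @param decay_counts,rip_counts Optional count tibbles to write alongside.
#' @return `dir`, invisibly.
#' @export
write_simulated_data <- function(sim, dir, decay_counts = NULL,
                                 rip_counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gene_models(sim$genes, file.path(dir, "genes.gff3"))
  write_pipeline_table(sim$tifs, file.path(dir, "tifs.tsv"), sim$config)
  write_pipeline_table(sim$motifs, file.path(dir, "motifs.tsv"), sim$config)
  write_pipeline_table(sim$truth, file.path(dir, "truth.tsv"), sim$config)
  if (!is.null(decay_counts)) {
    write_site_counts(decay_counts, file.path(dir, "counts_decay.tsv"),
                      sim$config)
  }
  if (!is.null(rip_counts)) {
    write_site_counts(rip_counts, file.path(dir, "counts_rip.tsv"),
                      sim$config)
  }
  invisible(dir)
}
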