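#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline so that each stage can echo
#' the exact settings it ran with. Defaults encode the study design the
#' package targets: a transcription-arrest time course sampled at 0, 5, 10,
#' 20 and 40 minutes in two biological replicates, with foreign spike-in RNA
#' mixed at a 1:9 mass ratio into every sample.
#'
#' @param timepoints Numeric vector of sampling times in minutes, strictly
#'   increasing. Default `c(0, 5, 10, 20, 40)`.
#' @param replicates Character labels of the biological replicates; must not
#'   contain underscores (they delimit fields in count-table headers).
#' @param spike_species Species tag that marks spike-in sites. Spike counts
#'   drive normalization and never enter decay fitting.
#' @param mispriming_window Width in nt of the downstream window inspected by
#'   the internal-mispriming filter (default 18).
#' @param mispriming_max_a_frac Maximum tolerated A fraction in that window on
#'   the transcript sense strand (default 0.67).
#' @param mispriming_max_run Minimum length of a consecutive-A run that
#'   triggers removal (default 6).
#' @param min_count Minimum normalized count at the first timepoint for a site
#'   to be considered reliably quantified (default 16; below this the
#'   delta-method variance approximation used by the weights degrades).
#' @param min_timepoints Minimum number of timepoints with nonzero counts
#'   (default 3, the least that supports a slope and an error estimate).
#' @param fdr_level Benjamini-Hochberg FDR level for differential-stability
#'   and RIP-enrichment calls (default 0.1).
#' @param rip_fc_cutoff Minimum IP/input fold change (on the natural scale)
#'   for a bound call (default 4).
#' @param seed Integer seed recorded in all output headers and used by every
#'   stochastic operation.
#'
#' @return A list of class `isodecay_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 1)
#' cfg$timepoints
run_config <- function(timepoints = c(0, 5, 10, 20, 40),
                       replicates = c("R1", "R2"),
                       spike_species = "spike",
                       mispriming_window = 18L,
                       mispriming_max_a_frac = 0.67,
                       mispriming_max_run = 6L,
                       min_count = 16,
                       min_timepoints = 3L,
                       fdr_level = 0.1,
                       rip_fc_cutoff = 4,
                       seed = 1L) {
  if (length(timepoints) < 2 || any(diff(timepoints) <= 0)) {
    abort("`timepoints` must be a strictly increasing vector of length >= 2.")
  }
  if (any(grepl("_", replicates))) {
    abort("replicate labels must not contain underscores.")
  }
  if (!(fdr_level > 0 && fdr_level < 1)) {
    abort("`fdr_level` must lie in (0, 1).")
  }
  structure(
    list(
      timepoints = as.numeric(timepoints),
      replicates = as.character(replicates),
      spike_species = spike_species,
      mispriming_window = as.integer(mispriming_window),
      mispriming_max_a_frac = mispriming_max_a_frac,
      mispriming_max_run = as.integer(mispriming_max_run),
      min_count = min_count,
      min_timepoints = as.integer(min_timepoints),
      fdr_level = fdr_level,
      rip_fc_cutoff = rip_fc_cutoff,
      seed = as.integer(seed)
    ),
    class = "isodecay_config"
  )
}

#' @export
print.isodecay_config <- function(x, ...) {
  cat("<isodecay_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

# Shared internal helpers ----------------------------------------------------

# canonical site key "chrom:pos:strand" used to join tables
site_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = ":")
}

check_strand <- function(strand, where = "input") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf(
      "%s: invalid strand value(s) %s; strand must be '+' or '-'.",
      where, paste(unique(strand[bad]), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

gmean <- function(x) exp(mean(log(x)))
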