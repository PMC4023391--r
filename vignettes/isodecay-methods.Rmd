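---
title: "Measuring isoform-specific mRNA decay: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring isoform-specific mRNA decay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodecay)
library(dplyr)
```

## The measurement problem

Most yeast genes express several transcript isoforms that differ only in
their polyadenylation site, often by a handful of nucleotides. Because the
3' UTR carries destabilizing elements and RNA-binding-protein (RBP) sites,
these isoforms can have very different lifetimes, and a single per-gene
decay rate hides that structure. `isodecay` estimates a decay rate for
every individual poly(A) site — at single-nucleotide resolution, without
clustering adjacent sites — from a transcription-arrest time course read
out by 3'-end sequencing, and then asks how stability relates to coding
potential, 3'UTR length, motif content and direct RBP binding.

The experimental design the package assumes: transcription is arrested at
time zero (e.g. by shifting a temperature-sensitive polymerase mutant to
the restrictive temperature); samples are drawn at 0, 5, 10, 20 and 40
minutes in two biological replicates; a fixed mass of foreign RNA (1 part
per 9 parts sample RNA) is spiked into every sample before library
preparation; reads are assigned to poly(A) sites at the first aligned base,
the last templated nucleotide before the tail.

## Decay model and weighted fit

After arrest, each isoform's abundance decays exponentially,
$\mu_{j} = A_0 e^{-k t_j}$, and the observed count of isoform $i$ in
library $(j, r)$ is modeled as negative binomial,

$$K_{ijr} \sim \mathrm{NB}\!\left(\text{mean} = s_{jr}\, A_{0i}\,
e^{-k_i t_j},\ \text{Var} = \mu + \alpha_j \mu^2\right),$$

with a library size factor $s_{jr}$ and a timepoint-specific dispersion
$\alpha_j$. Taking logs of normalized counts gives a linear model in time,
and the delta method gives the variance of a log-count:

$$\mathrm{Var}(\ln K) \approx \frac{\mathrm{Var}(K)}{\mu^2}
  = \frac{1}{\mu} + \alpha.$$

`fit_decay()` fits $\ln(\text{normalized count})$ against time by weighted
least squares with weights $w = 1/(1/\mu + \alpha_j(\mu))$, a shared slope
$-k$ across replicates and replicate-specific intercepts. Late timepoints,
where counts are low and dispersion high, therefore count for less. This
matters most for fast-decaying isoforms: an unweighted fit chases the noisy
late points and mis-estimates $k$, while the weighted fit stays anchored to
the informative early points. The observed count stands in for $\mu$ in the
weights; iterating the weights from fitted means was evaluated and brought
no accuracy gain, so the simpler plug-in form is used.

Two reading notes on the weighting. First, "weights equal to the estimated
variance" can be read literally as up-weighting noisy points; only the
inverse-variance reading produces the conservative behavior described
above, so that is what is implemented. Second, standard errors are taken
from the known-variance WLS covariance $(X^\top W X)^{-1}$ — the weights
are absolute variance estimates, not relative ones, and the downstream
z-test assumes normal errors with known variance. Rescaling by a residual
variance estimated on ~7 degrees of freedom would make the z statistics
t-distributed and miscalibrated.

Zero counts are dropped rather than pseudocounted: $\ln 0$ is undefined,
pseudocounts bias slopes, and the weighting already down-weights points
with near-zero expectation. A consequence worth knowing: for fast decayers
the surviving late counts are right-truncated (only draws $\ge 1$ remain),
which lifts the late log-counts slightly, so the residual systematic error
of both weighted and unweighted fits is slightly *negative*; weighting
reduces its magnitude roughly twofold in simulation. Fits need at least 3
nonzero points (flag `insufficient_points` otherwise); a non-positive slope
is returned with flag `nondecaying` and an infinite half-life, which is
excluded from half-life summaries and mutant/wild-type ratios. Group
comparisons of decay *rates*, in contrast, keep non-positive estimates:
truncating them would bias slow groups upward.

## Spike-in normalization

The spike-in represents the same number of molecules in every library, so
each library's size factor is proportional to its total spike count.
`spike_size_factors()` offers two anchors for the proportionality
constant. The default divides by the spike total of the condition's first
library (earliest timepoint, first replicate): normalized counts sit on the
time-zero library's scale, and because the anchor involves no other
library, multiplying any other library's counts by a constant leaves every
normalized count exactly unchanged. The alternative `"geometric"` anchor
divides by the geometric mean of the condition's spike totals, centering
factors at 1; it couples the libraries, so the same rescaling moves all
normalized counts of the condition by a single common factor. Decay rates
and all downstream tests are identical under either anchor; only the
count-level invariance differs, which is why the reference anchor is the
default.

## Dispersion estimation

Per site and timepoint, a method-of-moments dispersion
$\hat\alpha = \max(0, (v - m)/m^2)$ is computed from the replicate mean
$m$ and variance $v$ of normalized counts, and per timepoint the trend
$\alpha_j(\mu) = a_0 + a_1/\mu$ is fitted across sites with $m$ above a
floor (default 16). Only the fitted trend feeds the weights — with two
replicates a per-site $\hat\alpha$ is far too noisy to use directly.

The trend is fitted by ordinary least squares, deliberately not by a
robust/median-type regression: with 2–3 replicates the sampling
distribution of $\hat\alpha$ is strongly right-skewed (the replicate
variance is roughly a scaled $\chi^2_1$), so a median fit sits well below
the mean dispersion. Using it deflates the variances behind the weights
and inflates every downstream z statistic, pushing the two-sided test's
type-I error visibly above its nominal level in null simulations. Least
squares matches the mean of the skewed estimates and restores calibration;
the test suite verifies the type-I error on a 2000-gene null simulation. Fitted
values are floored at `alpha_floor` (default 1e-4).

## Differential stability, gene aggregates, perturbation ratios

For every unordered pair of fitted isoforms of a gene,
$z = (k_A - k_B)/\sqrt{se_A^2 + se_B^2}$ with a two-sided normal p-value;
Benjamini–Hochberg adjustment is applied across all pairs genome-wide
(default FDR 10%). Per gene, `summarize_gene_pairs()` flags genes with at
least one significant pair and reports the largest half-life fold ratio.
Gene-level decay is the abundance-weighted mean of isoform rates
(`aggregate_gene_decay()`), abundance being the normalized count at the
first timepoint.

For a deletion strain versus wild type, `relative_decay_ratio()` forms
per-isoform ratios $k_\text{mut}/k_\text{wt}$, which cancel any global
shift in decay rates between strains. `ratio_group_test()` compares bound
and unbound isoforms with a Welch t-test on *log* ratios: ratios are
positive multiplicative quantities whose estimation noise is heavy-tailed
on the natural scale (a slow isoform's ratio can be off severalfold), and
the log transform symmetrizes it. Medians are reported on the natural
scale.

## Coverage classification

A poly(A) site is joined to full-length transcript isoforms (TIFs) whose
3' end lies within a tolerance (default 0 nt — nucleotide resolution) of
the site; one site can match several TIFs and inherits one label per TIF,
so a 3'UTR site can be simultaneously coding and non-coding across its
TIFs. Each (site, TIF) pair receives exactly one of eight categories by
testing the transcript interval against same-strand gene models, with
precedence

`coding > partial_2orf > sut > overlap_3' / overlap_5' > intragenic > intergenic`.

"Covers the CDS" is boundary-inclusive at the stop codon: a transcript
ending exactly at the stop codon's last base still covers. The 3'UTR
length of a coding assignment is counted in transcript orientation from
the base after the stop codon to the poly(A) site inclusive (a site at the
stop codon's last base has length 0); when a bicistronic transcript covers
several CDSs the reference is the covered gene whose stop codon lies
nearest upstream of the site. SUT (stable unannotated transcript)
assignment requires ≥ 50% reciprocal overlap between the TIF and the SUT
interval — no published rule exists, so the threshold is a documented,
configurable choice. Sites with no matched TIF are labeled by a site-only
heuristic (inside a CDS → intragenic, else intergenic) and flagged
`site_only` so TIF-level statistics can exclude them.

Category-level statistics (`category_anova()`) use a one-way ANOVA
followed by pairwise Welch t-tests with BH adjustment; only categories
with at least 20 members are displayed (the raw data are always
available). Welch rather than pooled-variance is the default because
category variances differ; the pooled variant sits behind `pooled_sd`.

## Internal-priming filter

Oligo-dT priming on genomic A tracts fakes poly(A) sites. A site is
removed when its downstream window (default 18 nt, strand-aware, starting
at the base after the site, read on the transcript sense strand) has an A
fraction above 0.67 or a run of ≥ 6 consecutive A. The window parameters
are exposed because published protocols vary in the exact rule; the filter
is idempotent and windows truncated at chromosome ends are judged on the
available bases.

## Motif scanning and RIP enrichment

Motifs are IUPAC consensus strings matched exactly (no position-weight
matrices) on the transcript sense strand within each coding isoform's
3'UTR plus a short downstream flank; a hit is `contained` when it ends at
or upstream of the poly(A) site. `motif_stability_split()` compares
isoforms with and without the motif *within genes that contain it at least
once*, so the contrast is isoform-specific rather than gene-specific.

`nb_enrichment()` calls isoforms enriched in an immunoprecipitated (IP)
fraction over the input with a self-contained negative-binomial scheme:
median-of-ratios size factors, per-site method-of-moments dispersion
shrunk toward a least-squares trend (prior weight 4 pseudo-replicates, so
with triplicates the trend dominates), and a delta-method Wald test on the
log2 fold change of normalized means; BH adjustment; a `bound` call at
q ≤ 0.1 and fold change > 4 applied to the raw point estimate of fold
change. The scheme is implemented in the package, not delegated; on a
fixed simulated dataset its fold changes agree closely with DESeq2's
(correlation > 0.98 in the test suite), which serves as an independent
cross-check, not as the implementation.

`bound_vs_unbound_decay()` restricts to coding isoforms of genes with at
least one bound isoform and reports three bound/unbound summaries: ratio
of group means, ratio of group medians, and a gene-paired ratio — the
geometric mean over genes of each gene's own bound/unbound mean-rate
ratio. Baseline decay rates vary over more than an order of magnitude
between genes; the paired form cancels that baseline and is the most
precise estimator of a planted within-gene effect.

## What the synthetic data emulate — and what they do not

`simulate_genome_and_annotation()` builds a genome in which every
assumption of the analysis is true by construction and every truth is
recorded: gene baseline half-lives log-uniform on 4–180 min; isoforms of a
gene share the baseline rate (optional lognormal jitter via `iso_sdlog`,
default 0, so the differential-stability null "equal rates within gene"
holds exactly except for planted effects); time-zero abundances log-normal
with median 200; NB dispersions rising linearly from 0.02 to 0.2 across
the five timepoints, mimicking the growth of technical noise late in the
arrest; library size factors log-normal around 1 (sd(log) 0.15, a
realistic depth variation that forces normalization to do real work);
spike-in sites on their own chromosome at 1/9 of the sample's expected
time-zero abundance; one A-tract artifact site per designated gene unit;
a PUF3-like motif (`TGTAAATA`) planted in half of the multi-isoform genes,
always and only in the distal isoform, with chance occurrences scrubbed
from the random genome so motif truth is exact; a bound set comprising all
motif-carrying coding isoforms (destabilized twofold in the wild type,
reverting to baseline in the mutant) plus a fraction of non-coding
isoforms bound with no rate effect. All eight coverage categories are
realized by dedicated constructs (tandem gene pairs, intragenic and
partial transcripts, SUTs, intergenic transcripts) on both strands.

What passing on these data shows: the estimator recovers known rates at
realistic depth and noise; the tests are calibrated under a true null; the
filters remove exactly what they claim. What it cannot show: robustness to
alignment and mapping artifacts other than A-tract mispriming, to
deviations from single-exponential decay (the arrest itself perturbs the
cell after ~40 min), to mis-annotated gene models, or to dispersion
structure unlike the assumed NB form. Conclusions about real libraries
still require the usual diagnostics (replicate concordance, removal
reports, qc flags).

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: libraries with zero spike counts
are a hard error (normalization impossible); single-replicate timepoints
refuse dispersion estimation rather than silently assuming Poisson;
empty categories or groups yield reports without tests rather than NAs in
disguise. Ties in TIF matching are kept as separate assignments, never
collapsed.

The validation suite runs the full pipeline on a 170-gene genome
(~500 isoform sites, ~430 reliable fits per condition), which keeps the
whole suite and the acceptance script within a couple of minutes while
leaving group sizes large enough for the planted effects to be estimated
with useful precision. Calibration checks use 2000 two-isoform genes.
One property sits at the edge of what the design can deliver: with the
stated dispersions, the final timepoint carries
$\mathrm{Var}(\ln K) \approx 0.21$, which bounds the standard error of
$k$ at about 0.007 regardless of depth, so the median relative half-life
error across the 4–180 min range hovers around 15% — the information
limit of five timepoints and two replicates, not an estimator defect.

## Limitations

* Single-exponential decay only; synthesis-plus-decay models for metabolic
  labeling designs are out of scope.
* Exact IUPAC motif matching; no PWM scores or de novo motif discovery.
* The RIP caller tests one condition contrast (IP vs input); complex
  designs belong in a dedicated GLM framework.
* BAM parsing is out of the core contract: counts arrive as per-site
  tables, keeping the package independent of aligner choices.
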