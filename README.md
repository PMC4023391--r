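# isodecay

Isoform-specific mRNA decay rates and RNA-binding-protein association from
3'-end sequencing time courses.

Most yeast genes express several transcript isoforms that differ only in
their polyadenylation site — sometimes by a single nucleotide — and those
isoforms can have very different lifetimes, because the 3'UTR carries the
destabilizing elements and RNA-binding-protein (RBP) sites. A per-gene decay
rate is therefore a composite that hides real regulation. `isodecay`
measures decay at the level of the individual poly(A) site: it takes
per-position 3'-end counts from a transcription-arrest time course,
normalizes them against a spiked-in foreign RNA, fits a variance-weighted
exponential decay per site, tests isoforms of a gene against each other,
classifies each isoform's coding potential against a full-length transcript
annotation, and relates stability to 3'UTR length, motif content and direct
RBP binding measured by isoform-resolved RNA immunoprecipitation (RIP).

## The model

After transcriptional arrest at $t = 0$, each isoform decays exponentially.
The raw count of isoform $i$ in the library at timepoint $t_j$, replicate
$r$ is modeled as negative binomial:

$$K_{ijr} \sim \mathrm{NB}\big(\text{mean} = s_{jr} A_{0i} e^{-k_i t_j},\;
\mathrm{Var} = \mu + \alpha_j \mu^2\big)$$

* $s_{jr}$ — library size factor from spike-in totals (the spike represents
  a constant number of molecules in every sample);
* $\alpha_j$ — per-timepoint NB dispersion, estimated as a trend
  $\alpha_j(\mu) = a_0 + a_1/\mu$ across sites;
* $k_i$ — the decay rate (1/min); half-life $t_{1/2} = \ln 2 / k$.

$\ln$(normalized count) is regressed on time by weighted least squares with
delta-method weights $w = 1/(1/\mu + \alpha_j(\mu))$, shared slope across
replicates, replicate-specific intercepts. Differential stability between
two isoforms of a gene is a two-sided z-test on
$(k_A - k_B)/\sqrt{se_A^2 + se_B^2}$ with Benjamini–Hochberg correction
genome-wide; RIP enrichment is a negative-binomial Wald test of IP vs input
with median-of-ratios normalization and trended dispersion shrinkage, and
isoforms are called bound at FDR ≤ 10% with more than fourfold enrichment.

Every stage is validated against a synthetic-data generator
(`simulate_genome_and_annotation()`) that plants known half-lives,
dispersions, spike-ins, internal-priming artifacts, a destabilizing
3'UTR motif and an RBP-bound set, so the whole pipeline can be checked
against ground truth. See the methods vignette
(`vignettes/isodecay-methods.Rmd`) for the statistical details and design
decisions.

## Worked example

Simulate an experiment (40 genes, 5 timepoints, 2 replicates, spike-ins),
run the pipeline, and integrate a RIP experiment:

```r
library(isodecay)
library(dplyr)

cfg <- run_config(seed = 7)
sim <- simulate_genome_and_annotation(n_genes = 40, seed = 7, config = cfg)
sim
#> <isodecay_sim>
#>   genome: 2 sequences (50648, 2600 nt)
#>   genes: 43 (40 ORF, 3 SUT)
#>   TIFs: 125; sites: 148 (20 spike, 3 artifact)

counts <- simulate_decay_counts(sim, cfg, conditions = "WT")
filtered <- filter_mispriming(counts, sim$genome)
mispriming_report(filtered)[, c("chrom", "pos", "strand", "reason")]
#> # A tibble: 3 × 4
#>   chrom   pos strand reason
#>   <chr> <int> <chr>  <chr>
#> 1 chrS  23062 +      a_fraction,a_run
#> 2 chrS  24600 +      a_fraction,a_run
#> 3 chrS  26069 +      a_fraction,a_run
```

The three planted A-tract artifact sites — and nothing else — are removed.
Normalize on spike-ins, estimate dispersions, fit decay:

```r
norm <- normalize_counts(filtered, spike_size_factors(filtered))
disp <- estimate_dispersion(norm)
fits <- fit_decay(filter_reliable(norm), disp)
glance(fits)
#> # A tibble: 1 × 5
#>   n_fits  n_ok n_nondecaying median_k median_half_life
#>    <int> <int>         <int>    <dbl>            <dbl>
#> 1    125   120             5   0.0275             25.2
```

125 sites are reliably quantified; the median fitted half-life is 25 min
(the generator draws half-lives log-uniformly between 4 and 180 min, whose
median is ~27 min). Classify isoforms against the full-length annotation
and test isoforms of a gene against each other:

```r
ann <- classify_isoforms(
  match_tifs(distinct(filtered, chrom, pos, strand) %>%
               filter(chrom == "chrS"), sim$tifs),
  sim$genes)
census(ann)$categories
#> # A tibble: 8 × 2
#>   category             n
#>   <chr>            <int>
#> 1 coding_1orf        108
#> 2 coding_2plus_orf     1
#> 3 partial_2orf         1
#> 4 sut                  3
#> 5 overlap_3prime       3
#> 6 overlap_5prime       3
#> 7 intragenic           3
#> 8 intergenic           3

fits_annot <- inner_join(fits, filter(ann, !site_only),
                         by = c("chrom", "pos", "strand"))
pairs <- test_pairs(filter(fits_annot, coding))
summarize_gene_pairs(pairs) %>% filter(any_significant) %>% head(3)
#> # A tibble: 3 × 7
#>   gene_id condition n_pairs n_significant any_significant max_fold_ratio
#>   <chr>   <chr>       <int>         <int> <lgl>                    <dbl>
#> 1 GENE007 WT              6             2 TRUE                      7.89
#> 2 GENE011 WT              6             2 TRUE                      6.37
#> 3 GENE013 WT              6             1 TRUE                      4.42
```

These genes carry the planted destabilizing motif in their distal isoform,
and the pair tests find the within-gene stability differences. Finally, a
RIP experiment at 8× enrichment for the bound set:

```r
enr <- nb_enrichment(simulate_rip_counts(sim, enrichment = 8, n_reps = 3))
glance(enr)
#> # A tibble: 1 × 3
#>   n_sites n_tested n_bound
#>     <int>    <int>   <int>
#> 1     128      128      26

bound_vs_unbound_decay(enr, fits, ann) %>%
  select(n_bound, n_unbound, ratio_paired, p)
#> # A tibble: 1 × 4
#>   n_bound n_unbound ratio_paired      p
#>     <int>     <int>        <dbl>  <dbl>
#> 1      19        40         1.85 0.0155
```

Within genes that have a bound isoform, bound coding isoforms decay ~1.9×
faster than their unbound siblings — recovering the planted twofold effect
(`ratio_paired` is the gene-paired geometric-mean ratio, which cancels
gene-level baseline differences).

Plot helpers: `autoplot(fits)` (half-life histogram),
`plot_decay_curve(norm, fits, "chrS", 826, "+")` (one site's fit),
`autoplot(category_anova(fits_annot))` (rates by category),
`plot_pair_distance(pairs)`.

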