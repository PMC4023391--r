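#' Fit per-isoform exponential decay rates by weighted regression
#'
#' For each poly(A) site and condition, fits the log-linear model
#' `ln(normalized count) = intercept_replicate - k * t` by weighted least
#' squares. The weight of each point is the inverse of the delta-method
#' variance of its log-count under the negative-binomial model,
#' `Var(ln K) ~= 1/mu + alpha_j(mu)`, with the raw count standing in for the
#' raw-scale mean and the per-timepoint dispersion taken from the fitted
#' trend. Points with higher technical noise (late, shallow timepoints)
#' therefore contribute less, which guards against the overestimation of
#' decay rates that an unweighted fit shows for fast-decaying isoforms.
#'
#' Zero counts are dropped (their log is undefined and a pseudocount would
#' bias the slope; the weighting already down-weights near-zero
#' expectations). Replicates share the slope and get separate intercepts.
#' Standard errors come from the weighted-least-squares covariance
#' `(X'WX)^-1` with the weights treated as true inverse variances, matching
#' the normal z-test applied downstream.
#'
#' @param norm_counts Normalized count tibble (ideally after
#'   [filter_reliable()]).
#' @param dispersion A `dispersion_model` from [estimate_dispersion()];
#'   required when `weighted = TRUE`.
#' @param weighted Use inverse-variance weights (default) or ordinary least
#'   squares.
#' @param replicate Optional single replicate label: fit that replicate
#'   alone (used for replicate-concordance analysis).
#' @param include_t0 Include the time-zero sample in fits (default TRUE).
#' @param min_points Minimum usable (nonzero) points for a fit (default 3).
#' @return A tibble of class `decay_fits`: one row per (site, condition)
#'   with `k` (1/min), `se_k`, `half_life` (min, `Inf` when `k <= 0`),
#'   `n_points`, `abund_t0` (mean normalized count at the first timepoint)
#'   and a `qc` flag (`"ok"`, `"nondecaying"`, `"insufficient_points"`).
#' @export
fit_decay <- function(norm_counts, dispersion = NULL, weighted = TRUE,
                      replicate = NULL, include_t0 = TRUE, min_points = 3L,
                      spike_species = "spike") {
  if (weighted && is.null(dispersion)) {
    abort("`dispersion` model is required for weighted fits.")
  }
  d <- norm_counts %>% filter(.data$species != spike_species)
  if (!is.null(replicate)) {
    d <- d %>% filter(.data$replicate %in% !!replicate)
  }
  t0 <- min(d$timepoint)
  if (!include_t0) {
    d <- d %>% filter(.data$timepoint > t0)
  }
  d <- d %>% mutate(
    alpha = if (weighted) {
      predict_dispersion(dispersion, .data$condition, .data$timepoint,
                         .data$norm_count)
    } else {
      0
    },
    w = if (weighted) 1 / (1 / pmax(.data$count, 1) + .data$alpha) else 1
  )

  fits <- d %>%
    group_by(.data$condition, .data$chrom, .data$pos, .data$strand) %>%
    group_modify(function(df, key) {
      abund_t0 <- mean(df$norm_count[df$timepoint == min(df$timepoint)])
      use <- df[df$count > 0, ]
      if (nrow(use) < min_points || length(unique(use$timepoint)) < 2) {
        return(tibble(k = NA_real_, se_k = NA_real_, half_life = NA_real_,
                      n_points = nrow(use), abund_t0 = abund_t0,
                      qc = "insufficient_points"))
      }
      fit <- wls_decay(log(use$norm_count), use$timepoint, use$replicate,
                       use$w)
      if (is.null(fit)) {
        return(tibble(k = NA_real_, se_k = NA_real_, half_life = NA_real_,
                      n_points = nrow(use), abund_t0 = abund_t0,
                      qc = "insufficient_points"))
      }
      tibble(
        k = fit$k, se_k = fit$se_k,
        half_life = if (fit$k > 0) log(2) / fit$k else Inf,
        n_points = nrow(use), abund_t0 = abund_t0,
        qc = if (fit$k <= 0) "nondecaying" else "ok"
      )
    }) %>%
    ungroup() %>%
    select("chrom", "pos", "strand", "condition", dplyr::everything())
  class(fits) <- c("decay_fits", class(fits))
  fits
}

# weighted least squares with replicate-specific intercepts and a shared
# slope; returns k = -slope and its known-variance standard error
wls_decay <- function(y, t, rep_label, w) {
  reps <- unique(rep_label)
  X <- cbind(
    vapply(reps, function(r) as.numeric(rep_label == r), numeric(length(y))),
    t
  )
  xtwx <- crossprod(X, w * X)
  ok <- tryCatch({
    cov_b <- solve(xtwx)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(NULL)
  b <- cov_b %*% crossprod(X, w * y)
  p <- ncol(X)
  list(k = unname(-b[p, 1]), se_k = unname(sqrt(cov_b[p, p])))
}

#' @export
print.decay_fits <- function(x, ...) {
  cat(sprintf("<decay_fits> %d fits (%d ok, %d nondecaying, %d insufficient)\n",
              nrow(x), sum(x$qc == "ok"), sum(x$qc == "nondecaying"),
              sum(x$qc == "insufficient_points")))
  NextMethod()
}

#' @export
glance.decay_fits <- function(x, ...) {
  ok <- x %>% filter(.data$qc == "ok")
  tibble(
    n_fits = nrow(x),
    n_ok = nrow(ok),
    n_nondecaying = sum(x$qc == "nondecaying"),
    median_k = median(ok$k),
    median_half_life = median(ok$half_life)
  )
}

#' Replicate concordance of independently fitted decay rates
#'
#' Fits from two single-replicate runs (see the `replicate` argument of
#' [fit_decay()]) are joined on site and condition, and the Spearman rank
#' correlation of the decay rates over sites fit in both replicates is
#' reported.
#'
#' @param fits_rep1,fits_rep2 `decay_fits` tibbles.
#' @param min_shared Minimum number of shared qc-pass sites (default 10).
#' @return One-row tibble: `n_shared`, `spearman`.
#' @export
replicate_concordance <- function(fits_rep1, fits_rep2, min_shared = 10L) {
  by <- c("chrom", "pos", "strand", "condition")
  shared <- inner_join(
    fits_rep1 %>% filter(.data$qc != "insufficient_points") %>%
      select(dplyr::all_of(by), k1 = "k"),
    fits_rep2 %>% filter(.data$qc != "insufficient_points") %>%
      select(dplyr::all_of(by), k2 = "k"),
    by = by
  )
  if (nrow(shared) < min_shared) {
    abort(sprintf("only %d sites fit in both replicates (need >= %d).",
                  nrow(shared), min_shared))
  }
  tibble(
    n_shared = nrow(shared),
    spearman = cor(shared$k1, shared$k2, method = "spearman")
  )
}

#' Differential-stability z-tests between isoforms of a gene
#'
#' Every unordered pair of fitted isoforms within a gene is tested with the
#' two-sided z statistic `z = (k_A - k_B) / sqrt(se_A^2 + se_B^2)`;
#' Benjamini-Hochberg adjustment is applied across all pairs genome-wide.
#'
#' @param fits A `decay_fits` tibble carrying a `gene_id` column (join the
#'   annotation first); rows with qc `"insufficient_points"` are ignored.
#' @param fdr_level FDR level defining `significant` (default 0.1).
#' @return Tibble with one row per pair: site keys A/B, `delta_k`, `z`, `p`,
#'   `q`, `distance_nt`, `significant`.
#' @export
test_pairs <- function(fits, fdr_level = 0.1) {
  if (!"gene_id" %in% names(fits)) {
    abort("`fits` must carry a `gene_id` column (join annotations first).")
  }
  usable <- fits %>%
    filter(.data$qc != "insufficient_points", !is.na(.data$gene_id))
  if (any(usable$se_k == 0)) {
    abort("degenerate fit with se_k = 0; refit upstream.")
  }
  pairs <- usable %>%
    group_by(.data$gene_id, .data$condition) %>%
    group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 2) return(tibble())
      idx <- utils::combn(n, 2)
      tibble(
        site_a = site_key(df$chrom[idx[1, ]], df$pos[idx[1, ]],
                          df$strand[idx[1, ]]),
        site_b = site_key(df$chrom[idx[2, ]], df$pos[idx[2, ]],
                          df$strand[idx[2, ]]),
        k_a = df$k[idx[1, ]], k_b = df$k[idx[2, ]],
        se_a = df$se_k[idx[1, ]], se_b = df$se_k[idx[2, ]],
        distance_nt = abs(df$pos[idx[1, ]] - df$pos[idx[2, ]])
      )
    }) %>%
    ungroup()
  if (nrow(pairs) == 0) {
    return(pairs %>% mutate(delta_k = numeric(0), z = numeric(0),
                            p = numeric(0), q = numeric(0),
                            significant = logical(0)))
  }
  pairs %>%
    mutate(
      delta_k = .data$k_a - .data$k_b,
      z = .data$delta_k / sqrt(.data$se_a^2 + .data$se_b^2),
      p = 2 * pnorm(-abs(.data$z)),
      q = p.adjust(.data$p, method = "BH"),
      significant = .data$q < fdr_level
    )
}

#' Per-gene summary of differential-stability pairs
#'
#' Marks genes with at least one significant isoform pair and computes the
#' largest fold ratio of half-lives among each gene's tested pairs (isoforms
#' with `k <= 0` are excluded from the ratio).
#'
#' @param pairs Output of [test_pairs()].
#' @return Tibble per (gene, condition): `n_pairs`, `n_significant`,
#'   `any_significant`, `max_fold_ratio`, `over_fourfold`.
#' @export
summarize_gene_pairs <- function(pairs) {
  pairs %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(
      n_pairs = dplyr::n(),
      n_significant = sum(.data$significant),
      any_significant = any(.data$significant),
      max_fold_ratio = {
        ok <- .data$k_a > 0 & .data$k_b > 0
        if (any(ok)) {
          max(exp(abs(log(.data$k_a[ok] / .data$k_b[ok]))))
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    ) %>%
    mutate(over_fourfold = .data$any_significant &
             !is.na(.data$max_fold_ratio) & .data$max_fold_ratio > 4)
}

#' Abundance-weighted gene-level decay rates
#'
#' The decay rate of a gene product is a composite of its isoforms' rates;
#' the aggregate is the mean of isoform decay rates weighted by isoform
#' abundance at the first timepoint.
#'
#' @param fits `decay_fits` with a `gene_id` column.
#' @return Tibble per (gene, condition): `k_gene`, `n_isoforms`.
#' @export
aggregate_gene_decay <- function(fits) {
  if (!"gene_id" %in% names(fits)) {
    abort("`fits` must carry a `gene_id` column.")
  }
  fits %>%
    filter(.data$qc != "insufficient_points", !is.na(.data$gene_id)) %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(
      k_gene = sum(.data$k * .data$abund_t0) / sum(.data$abund_t0),
      n_isoforms = dplyr::n(),
      .groups = "drop"
    )
}

#' Mutant/wild-type relative decay rates per isoform
#'
#' Ratios `k_mutant / k_wildtype` isolate isoform-specific effects of a
#' perturbation from any global shift in decay rates. Isoforms with a
#' non-positive or missing wild-type rate are excluded (ratio undefined) and
#' reported in the `"excluded"` attribute.
#'
#' @param fits_mutant,fits_wt `decay_fits` tibbles for the two strains.
#' @return Tibble per site: `k_mut`, `k_wt`, `ratio`.
#' @export
relative_decay_ratio <- function(fits_mutant, fits_wt) {
  by <- c("chrom", "pos", "strand")
  joined <- inner_join(
    fits_mutant %>% filter(.data$qc == "ok") %>%
      select(dplyr::all_of(by), k_mut = "k"),
    fits_wt %>% filter(.data$qc != "insufficient_points") %>%
      select(dplyr::all_of(by), k_wt = "k"),
    by = by
  )
  excluded <- joined %>% filter(.data$k_wt <= 0)
  out <- joined %>%
    filter(.data$k_wt > 0) %>%
    mutate(ratio = .data$k_mut / .data$k_wt)
  attr(out, "excluded") <- excluded
  out
}
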