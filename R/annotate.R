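#' Coverage categories
#'
#' The eight coverage categories a (site, full-length isoform) assignment
#' can receive, in classification precedence order.
#' @export
ISOFORM_CATEGORIES <- c(
  "coding_1orf", "coding_2plus_orf", "partial_2orf", "sut",
  "overlap_3prime", "overlap_5prime", "intragenic", "intergenic"
)

#' Match 3' sites to full-length transcript isoforms (TIFs)
#'
#' A site matches a TIF when the TIF's 3' end lies within `tolerance` nt of
#' the site on the same chromosome and strand. The default tolerance of 0
#' reflects nucleotide-resolution 3' end data. A site can match several TIFs
#' (one 3' end, several 5' starts); unmatched sites are kept with `NA`
#' `tif_id`.
#'
#' @param sites Tibble with (at least) `chrom`, `pos`, `strand`; extra
#'   columns pass through. Duplicate site rows are collapsed.
#' @param tifs TIF tibble (see [read_tif_annotation()]).
#' @param tolerance Maximum |TIF end3 - site pos| in nt (default 0).
#' @return Tibble with one row per (site, matched TIF), or one row with `NA`
#'   TIF fields for unmatched sites; `matched` flags the former.
#' @export
match_tifs <- function(sites, tifs, tolerance = 0L) {
  s <- distinct(sites, .data$chrom, .data$pos, .data$strand)
  hits <- s %>%
    inner_join(tifs, by = c("chrom", "strand"), relationship = "many-to-many") %>%
    filter(abs(.data$end3 - .data$pos) <= tolerance)
  unmatched <- s %>%
    anti_join(hits, by = c("chrom", "pos", "strand")) %>%
    mutate(tif_id = NA_character_, start5 = NA_integer_, end3 = NA_integer_,
           support = NA_integer_)
  bind_rows(hits, unmatched) %>%
    mutate(matched = !is.na(.data$tif_id)) %>%
    arrange(.data$chrom, .data$pos, .data$strand, .data$tif_id)
}

#' Classify (site, TIF) assignments by coverage of gene models
#'
#' Each matched full-length isoform's transcript interval is tested against
#' same-strand gene models:
#' * covers >= 1 complete CDS (boundary-inclusive at the stop codon) ->
#'   `coding_1orf` / `coding_2plus_orf`;
#' * overlaps the translated regions of two or more genes without covering
#'   both -> `partial_2orf`;
#' * reciprocally overlaps a SUT interval by >= `sut_min_overlap` ->
#'   `sut`;
#' * overlaps a single CDS only at its 3' (resp. 5') end ->
#'   `overlap_3prime` (`overlap_5prime`);
#' * lies entirely within one CDS -> `intragenic`;
#' * overlaps nothing -> `intergenic`.
#'
#' Precedence follows that order, so every (site, TIF) pair receives exactly
#' one category. A site matched to several TIFs keeps one row per TIF and
#' can be simultaneously coding and non-coding across them. For coding
#' assignments, `utr3_length` is the transcript-orientation distance from
#' the base after the stop codon to the poly(A) site, inclusive (a site at
#' the stop codon's last base has length 0); the reference CDS is the
#' covered gene whose stop codon lies nearest upstream of the site.
#'
#' Sites without any matched TIF are classified by a site-only heuristic
#' (inside a CDS -> `intragenic`, otherwise `intergenic`) and flagged
#' `site_only` so they can be excluded from TIF-level statistics.
#'
#' @param matched Output of [match_tifs()].
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param sut_min_overlap Minimum reciprocal overlap fraction for SUT
#'   assignment (default 0.5).
#' @return Tibble with one row per (site, TIF) assignment: `category`,
#'   `coding`, `gene_id`, `utr3_length`, `site_only`.
#' @export
classify_isoforms <- function(matched, genes, sut_min_overlap = 0.5) {
  orfs <- genes %>% filter(.data$biotype == "ORF")
  suts <- genes %>% filter(.data$biotype == "SUT")

  rows <- map(seq_len(nrow(matched)), function(i) {
    r <- matched[i, ]
    if (!r$matched) {
      cls <- classify_site_only(r$chrom, r$pos, r$strand, orfs)
      return(tibble(
        chrom = r$chrom, pos = r$pos, strand = r$strand,
        tif_id = NA_character_, gene_id = cls$gene_id,
        category = cls$category, coding = FALSE, utr3_length = NA_real_,
        site_only = TRUE
      ))
    }
    lo <- min(r$start5, r$end3)
    hi <- max(r$start5, r$end3)  # 0-based inclusive transcript interval
    cand <- orfs %>% filter(.data$chrom == r$chrom, .data$strand == r$strand)
    covered <- cand %>% filter(lo <= .data$start, hi >= .data$end - 1L)
    overlapped <- cand %>% filter(lo <= .data$end - 1L, hi >= .data$start)
    res <- if (nrow(covered) >= 1) {
      ref <- nearest_upstream_stop(covered, r$pos, r$strand)
      utr3 <- if (r$strand == "+") r$pos - ref$end + 1 else ref$start - r$pos
      list(
        category = if (nrow(covered) >= 2) "coding_2plus_orf" else
          "coding_1orf",
        coding = TRUE, gene_id = ref$gene_id, utr3 = utr3
      )
    } else if (nrow(overlapped) >= 2) {
      gid <- site_gene(overlapped, r$pos) %||% overlapped$gene_id[1]
      list(category = "partial_2orf", coding = FALSE, gene_id = gid,
           utr3 = NA_real_)
    } else if (nrow(s <- sut_match(suts, r$chrom, r$strand, lo, hi,
                                   sut_min_overlap)) >= 1) {
      list(category = "sut", coding = FALSE, gene_id = s$gene_id[1],
           utr3 = NA_real_)
    } else if (nrow(overlapped) == 1) {
      g <- overlapped[1, ]
      five_base <- if (g$strand == "+") g$start else g$end - 1L
      three_base <- if (g$strand == "+") g$end - 1L else g$start
      has5 <- lo <= five_base && five_base <= hi
      has3 <- lo <= three_base && three_base <= hi
      cat <- if (!has5 && !has3) "intragenic" else
        if (has3) "overlap_3prime" else "overlap_5prime"
      list(category = cat, coding = FALSE, gene_id = g$gene_id,
           utr3 = NA_real_)
    } else {
      list(category = "intergenic", coding = FALSE, gene_id = NA_character_,
           utr3 = NA_real_)
    }
    tibble(
      chrom = r$chrom, pos = r$pos, strand = r$strand, tif_id = r$tif_id,
      gene_id = res$gene_id, category = res$category, coding = res$coding,
      utr3_length = res$utr3, site_only = FALSE
    )
  })
  list_rbind(rows)
}

# among covered ORFs, the one whose stop codon is nearest upstream of the
# site in transcript orientation
nearest_upstream_stop <- function(covered, pos, strand) {
  d <- if (strand == "+") pos - (covered$end - 1L) else covered$start - pos
  covered[which.min(ifelse(d >= 0, d, Inf)), ]
}

# gene whose CDS contains the site position, if any
site_gene <- function(genes, pos) {
  inside <- genes %>% filter(.data$start <= pos, pos < .data$end)
  if (nrow(inside) > 0) inside$gene_id[1] else NULL
}

sut_match <- function(suts, chrom, strand, lo, hi, min_frac) {
  cand <- suts %>% filter(.data$chrom == !!chrom, .data$strand == !!strand)
  if (nrow(cand) == 0) return(cand)
  tif_len <- hi - lo + 1
  ov <- pmax(0, pmin(hi + 1, cand$end) - pmax(lo, cand$start))
  cand[ov / tif_len >= min_frac & ov / (cand$end - cand$start) >= min_frac, ]
}

classify_site_only <- function(chrom, pos, strand, orfs) {
  inside <- orfs %>%
    filter(.data$chrom == !!chrom, .data$strand == !!strand,
           .data$start <= pos, pos < .data$end)
  if (nrow(inside) > 0) {
    list(category = "intragenic", gene_id = inside$gene_id[1])
  } else {
    list(category = "intergenic", gene_id = NA_character_)
  }
}

#' Category census of classified isoforms
#'
#' @param annotations Output of [classify_isoforms()].
#' @return List with `categories` (count per category, all eight reported
#'   even when zero) and `genes` (per-gene number of coding isoform
#'   assignments, with tallies of genes having >= 2 and >= 3).
#' @export
census <- function(annotations) {
  cats <- tibble(category = ISOFORM_CATEGORIES) %>%
    left_join(
      annotations %>% filter(!.data$site_only) %>% count(.data$category),
      by = "category"
    ) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
  per_gene <- annotations %>%
    filter(.data$coding, !is.na(.data$gene_id)) %>%
    distinct(.data$gene_id, .data$chrom, .data$pos, .data$strand) %>%
    count(.data$gene_id, name = "n_coding_isoforms")
  list(
    categories = cats,
    genes = per_gene,
    n_genes_ge2 = sum(per_gene$n_coding_isoforms >= 2),
    n_genes_ge3 = sum(per_gene$n_coding_isoforms >= 3)
  )
}
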