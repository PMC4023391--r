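#' Read a poly(A)-site count table
#'
#' Reads a tab-separated table of per-position 3'-end counts. The first four
#' columns must be `chrom`, `pos` (0-based position of the last templated
#' nucleotide), `strand` (`+`/`-`) and `species` (sample vs spike-in tag);
#' every further column holds the counts of one library and must be named
#' `<condition>_<timepoint>_<replicate>`, e.g. `WT_0_R1` (condition and
#' replicate labels therefore must not contain underscores). Rows that repeat
#' a (chrom, pos, strand) key are summed, since read counts are additive.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @return A long tibble with columns `chrom`, `pos`, `strand`, `species`,
#'   `condition`, `timepoint`, `replicate`, `count`.
#' @export
read_site_counts <- function(path) {
  raw <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "strand", "species")
  if (!identical(names(raw)[seq_along(need)], need)) {
    abort(sprintf(
      "malformed header: first columns must be %s; got %s.",
      paste(need, collapse = ", "),
      paste(head(names(raw), 4), collapse = ", ")
    ))
  }
  lib_cols <- setdiff(names(raw), need)
  if (length(lib_cols) == 0 || nrow(raw) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), strand = character(),
      species = character(), condition = character(), timepoint = numeric(),
      replicate = character(), count = numeric()
    ))
  }
  parts <- str_split(lib_cols, "_")
  bad <- lib_cols[lengths(parts) != 3 | is.na(suppressWarnings(
    as.numeric(map_chr(parts, function(p) p[2]))))]
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed count column name(s): %s (expected <condition>_<timepoint>_<replicate>).",
      paste(bad, collapse = ", ")
    ))
  }
  check_strand(raw$strand, where = path)
  neg <- which(apply(raw[lib_cols] < 0, 1, any))
  if (length(neg) > 0) {
    abort(sprintf("negative count in row %d of %s.", neg[1], path))
  }
  long <- raw %>%
    as_tibble() %>%
    pivot_longer(dplyr::all_of(lib_cols),
                 names_to = c("condition", "timepoint", "replicate"),
                 names_sep = "_", values_to = "count") %>%
    mutate(timepoint = as.numeric(.data$timepoint),
           pos = as.integer(.data$pos)) %>%
    group_by(.data$chrom, .data$pos, .data$strand, .data$species,
             .data$condition, .data$timepoint, .data$replicate) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  long
}

#' Write a poly(A)-site count table
#'
#' Inverse of [read_site_counts()]: pivots the long count tibble back to the
#' wide one-column-per-library TSV dialect, with a commented header recording
#' the configuration and seed.
#'
#' @param counts Long count tibble as returned by [read_site_counts()] or
#'   [simulate_decay_counts()].
#' @param path Output path.
#' @param config Optional [run_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(counts, path, config = NULL) {
  wide <- counts %>%
    mutate(lib = paste(.data$condition, .data$timepoint, .data$replicate,
                       sep = "_")) %>%
    select("chrom", "pos", "strand", "species", "lib", "count") %>%
    pivot_wider(names_from = "lib", values_from = "count", values_fill = 0) %>%
    arrange(.data$chrom, .data$pos, .data$strand)
  write_pipeline_table(wide, path, config = config)
}

#' Read gene models from GFF3
#'
#' Imports `CDS` features as protein-coding gene models (biotype `ORF`) and
#' features of type `SUT` as stable-unannotated-transcript models. GFF3
#' 1-based inclusive coordinates are converted to the package's internal
#' 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `biotype`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "SUT")
  gr <- gr[keep]
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  biotype = character()))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    abort(sprintf("%s: feature without strand.", path))
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids)) {
    abort(sprintf("%s: CDS/SUT features must carry an ID attribute.", path))
  }
  out <- tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # 1-based incl -> 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand,
    biotype = if_else(as.character(gr$type) == "CDS", "ORF", "SUT")
  )
  if (any(out$end <= out$start)) {
    abort(sprintf("%s: feature with end <= start.", path))
  }
  out
}

#' Write gene models to GFF3
#'
#' @param genes Gene-model tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tisodecay\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
            genes$chrom,
            if_else(genes$biotype == "ORF", "CDS", "SUT"),
            genes$start + 1L, genes$end, genes$strand, genes$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a full-length transcript isoform (TIF) annotation
#'
#' A TIF is a transcript molecule class defined by a joint 5'-start / 3'-end
#' pair. Coordinates are in transcript orientation: on the minus strand
#' `start5 > end3` in genomic order.
#'
#' @param path TSV with columns `tif_id`, `chrom`, `strand`, `start5`,
#'   `end3`, `support` (read count supporting the TIF, >= 1).
#' @return Validated tibble of the same columns.
#' @export
read_tif_annotation <- function(path) {
  tifs <- as_tibble(read.delim(path, sep = "\t", comment.char = "#",
                               stringsAsFactors = FALSE))
  need <- c("tif_id", "chrom", "strand", "start5", "end3", "support")
  if (!all(need %in% names(tifs))) {
    abort(sprintf("TIF table must have columns %s.", paste(need, collapse = ", ")))
  }
  validate_tifs(tifs[need])
}

validate_tifs <- function(tifs) {
  check_strand(tifs$strand, where = "TIF annotation")
  if (any(tifs$support < 1)) {
    abort("TIF annotation: support must be >= 1.")
  }
  wrong <- (tifs$strand == "+" & tifs$start5 > tifs$end3) |
    (tifs$strand == "-" & tifs$start5 < tifs$end3)
  if (any(wrong)) {
    abort(sprintf(
      "TIF annotation: %d record(s) whose 5' end is not upstream of the 3' end in transcript orientation.",
      sum(wrong)
    ))
  }
  tifs
}

#' Read an RBP motif table
#'
#' @param path TSV with columns `motif_id` and `iupac` (IUPAC consensus
#'   string, e.g. `TGTAAATA` for the PUF3 element).
#' @return Tibble with validated IUPAC strings.
#' @export
read_motifs <- function(path) {
  m <- as_tibble(read.delim(path, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE))
  if (!all(c("motif_id", "iupac") %in% names(m))) {
    abort("motif table must have columns motif_id, iupac.")
  }
  validate_iupac(m$iupac)
  m
}

validate_iupac <- function(x) {
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", toupper(x))
  if (!all(ok)) {
    abort(sprintf("invalid IUPAC motif string(s): %s.",
                  paste(x[!ok], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions to bare sequence names.
#'
#' @param path FASTA path.
#' @return A `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a pipeline result table
#'
#' All result tables are written as TSV with `#`-prefixed header lines that
#' record the package version and, when given, every threshold of the run
#' configuration including the seed, so each file documents how it was made.
#'
#' @param tbl Data frame to write.
#' @param path Output path.
#' @param config Optional [run_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_pipeline_table <- function(tbl, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# isodecay %s", as.character(packageVersion("isodecay"))),
             con)
  writeLines(sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             con)
  if (!is.null(config)) {
    for (nm in names(config)) {
      writeLines(sprintf("# config %s: %s", nm,
                         paste(config[[nm]], collapse = ",")), con)
    }
  }
  suppressWarnings(write.table(tbl, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a pipeline result table
#'
#' @param path Path written by [write_pipeline_table()].
#' @return Tibble; the commented header lines are available in the
#'   `"header"` attribute.
#' @export
read_pipeline_table <- function(path) {
  all_lines <- readLines(path)
  hdr <- all_lines[startsWith(all_lines, "#")]
  tbl <- as_tibble(read.delim(path, sep = "\t", comment.char = "#",
                              stringsAsFactors = FALSE))
  attr(tbl, "header") <- hdr
  tbl
}
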