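#' Read a genome FASTA
#'
#' Loads sequences with `Biostrings` and tabulates per-sequence total and
#' non-N lengths. The non-N length is the conventional denominator for
#' genome-percent summaries of masked assemblies (ambiguous runs are not
#' annotatable, so they are excluded from the denominator).
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome_seq`: a list with `seq` (a
#'   `DNAStringSet`) and `info`, a tibble with columns `seq_name`, `length`
#'   and `non_n_length`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) abort("empty FASTA: no sequences")
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate sequence name in FASTA: %s",
                  nms[duplicated(nms)][1]))
  }
  names(seqs) <- nms
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  info <- tibble(
    seq_name = nms,
    length = Biostrings::width(seqs),
    non_n_length = as.integer(rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE]))
  )
  structure(list(seq = seqs, info = info), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", nrow(x$info), " sequence(s), ",
      sum(x$info$length), " bp (", sum(x$info$non_n_length), " non-N)\n",
      sep = "")
  print(x$info)
  invisible(x)
}

granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |>
    arrange(.data$chrom, .data$start)
}

tbl_to_granges <- function(tbl) {
  GenomicRanges::GRanges(
    tbl$chrom,
    IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
  )
}

#' Read gene annotation and derive the full genomic feature set
#'
#' Reads gene and exon features from GFF3 (or gene intervals from BED, which
#' carries no exon structure) and derives introns (gene minus exon) and
#' intergenic intervals (chromosome minus gene) by interval subtraction.
#' Exons extending outside their genes are clipped with a warning. All
#' output intervals are 0-based half-open and sorted.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param chrom_lengths Named integer vector of chromosome lengths, needed
#'   to close the intergenic track. When `NULL`, the rightmost annotated
#'   coordinate per chromosome is used, with a warning.
#' @return An object of class `gene_features`: a list of tibbles `genes`,
#'   `exons`, `introns`, `intergenic` (columns `chrom`, `start`, `end`) plus
#'   `chrom_lengths`.
#' @export
read_gene_features <- function(path, format = c("auto", "gff3", "bed"),
                               chrom_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[tolower(gr$type) == "gene"]
    exons <- gr[tolower(gr$type) == "exon"]
  } else {
    genes <- rtracklayer::import(path, format = "bed")
    exons <- GenomicRanges::GRanges()
  }
  # the feature tracks are strandless interval sets
  GenomicRanges::strand(genes) <- "*"
  if (length(exons)) GenomicRanges::strand(exons) <- "*"
  gene_red <- GenomicRanges::reduce(genes)
  exon_red <- GenomicRanges::reduce(exons)
  if (length(exon_red)) {
    outside <- GenomicRanges::setdiff(exon_red, gene_red)
    if (sum(GenomicRanges::width(outside)) > 0) {
      warn("exon intervals extend outside gene intervals; clipping to genes")
      exon_red <- GenomicRanges::intersect(exon_red, gene_red)
    }
  }
  introns <- GenomicRanges::setdiff(gene_red, exon_red)
  gene_tbl <- granges_to_tbl(gene_red)
  if (is.null(chrom_lengths)) {
    warn("no chromosome lengths supplied; using rightmost annotated coordinate")
    all_tbl <- bind_rows(gene_tbl, granges_to_tbl(exon_red))
    chrom_lengths <- vapply(split(all_tbl$end, all_tbl$chrom), max, numeric(1))
  }
  chroms <- tibble(chrom = names(chrom_lengths), start = 0L,
                   end = as.integer(chrom_lengths))
  intergenic <- GenomicRanges::setdiff(tbl_to_granges(chroms), gene_red)
  structure(
    list(
      genes = gene_tbl,
      exons = granges_to_tbl(exon_red),
      introns = granges_to_tbl(introns),
      intergenic = granges_to_tbl(intergenic),
      chrom_lengths = chrom_lengths
    ),
    class = "gene_features"
  )
}

#' @export
print.gene_features <- function(x, ...) {
  cat("<gene_features> genes:", nrow(x$genes), " exons:", nrow(x$exons),
      " introns:", nrow(x$introns), " intergenic:", nrow(x$intergenic), "\n")
  invisible(x)
}

#' Write insertions (or any interval table) as BED6
#'
#' @param x Tibble with columns `query_name` (or `chrom`), `start`, `end`,
#'   optionally `family` (or `repeat_name`) for the name field and `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  chrom <- x[["query_name"]] %||% x[["chrom"]]
  name <- x[["family"]] %||% x[["repeat_name"]] %||% rep(".", nrow(x))
  strand <- x[["strand"]] %||% rep(".", nrow(x))
  strand[strand == "C"] <- "-"
  lines <- if (nrow(x) == 0) character() else
    paste(chrom, x$start, x$end, name, ".", strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a simple gene/exon table as GFF3
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, and a list-column `exons` of tibbles
#'   with `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, paste(g$chrom, "retroscape", "gene", g$start + 1L, g$end,
                            ".", g$strand, ".",
                            sprintf("ID=%s", g$gene_id), sep = "\t"))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(g$chrom, "retroscape", "exon",
                              ex$start[j] + 1L, ex$end[j], ".", g$strand, ".",
                              sprintf("ID=%s.e%d;Parent=%s", g$gene_id, j, g$gene_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
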