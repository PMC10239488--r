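#' Extract annotated TE sequences from a genome
#'
#' Pulls the genomic sequence of each insertion; minus-strand loci are
#' reverse-complemented so every returned sequence reads in element
#' orientation. Names encode the locus as `chrom:start-end(strand)` with
#' 0-based half-open coordinates.
#'
#' @param genome A `genome_seq` from [read_genome_fasta()] or a named
#'   `DNAStringSet`.
#' @param insertions Tibble with columns `query_name`, `start`, `end`,
#'   `strand`.
#' @return A `DNAStringSet` of locus sequences.
#' @export
extract_te_sequences <- function(genome, insertions) {
  seqs <- if (inherits(genome, "genome_seq")) genome$seq else genome
  out <- vector("list", nrow(insertions))
  for (i in seq_len(nrow(insertions))) {
    r <- insertions[i, ]
    locus <- sprintf("%s:%d-%d(%s)", r$query_name, r$start, r$end, r$strand)
    if (!r$query_name %in% names(seqs)) {
      abort(sprintf("locus %s: unknown sequence '%s'", locus, r$query_name))
    }
    len <- length(seqs[[r$query_name]])
    if (r$start < 0 || r$end > len || r$start >= r$end) {
      abort(sprintf("locus %s: coordinates outside sequence bounds [0, %d)",
                    locus, len))
    }
    s <- Biostrings::subseq(seqs[[r$query_name]], start = r$start + 1L, end = r$end)
    if (r$strand %in% c("-", "C")) s <- Biostrings::reverseComplement(s)
    out[[i]] <- s
    names(out)[i] <- locus
  }
  do.call(c, lapply(out, Biostrings::DNAStringSet)) |>
    stats::setNames(names(out))
}

translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X" # codons containing N or partial
  unname(aa)
}

#' Find complete open reading frames in all six frames
#'
#' An ORF runs from an ATG to the next in-frame stop codon (the stop is
#' required: open-ended runs at a sequence edge are not complete ORFs).
#' Within each inter-stop region the first ATG defines the maximal ORF.
#' Frames 0-2 scan the forward strand, frames 3-5 the reverse complement;
#' reported coordinates are always on the forward strand of the input and
#' include the stop codon.
#'
#' @param sequence A `DNAString` or single character string.
#' @param min_aa Minimum peptide length in amino acids, stop excluded
#'   (default 300, below the length of a LINE ORF2 but above random noise).
#' @return Tibble: `frame` (0-5), `start`, `end` (0-based half-open,
#'   forward coordinates), `aa_length`, `aa_sequence`.
#' @export
find_orfs <- function(sequence, min_aa = 300) {
  seq_chr <- toupper(as.character(sequence))
  L <- nchar(seq_chr)
  if (L < 3L) abort("sequence shorter than one codon")
  rc <- revcomp_chr(seq_chr)
  res <- list()
  for (frame in 0:5) {
    s <- if (frame < 3L) seq_chr else rc
    off <- frame %% 3L
    n_codon <- (nchar(s) - off) %/% 3L
    if (n_codon < 2L) next
    starts <- off + 3L * (seq_len(n_codon) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    aa <- translate_codons(codons)
    stops <- which(aa == "*")
    region_start <- 1L
    for (st in stops) {
      if (st > region_start) {
        m_rel <- match("M", aa[region_start:(st - 1L)])
        if (!is.na(m_rel)) {
          m <- region_start + m_rel - 1L
          aa_len <- st - m
          if (aa_len >= min_aa) {
            nt_start <- off + (m - 1L) * 3L      # 0-based in scanned strand
            nt_end <- off + st * 3L              # past the stop codon
            if (frame < 3L) {
              fwd <- c(nt_start, nt_end)
            } else {
              fwd <- c(L - nt_end, L - nt_start)
            }
            res[[length(res) + 1L]] <- tibble(
              frame = frame, start = fwd[1], end = fwd[2],
              aa_length = aa_len,
              aa_sequence = paste(aa[m:(st - 1L)], collapse = "")
            )
          }
        }
      }
      region_start <- st + 1L
    }
  }
  if (length(res) == 0L) {
    return(tibble(frame = integer(), start = double(), end = double(),
                  aa_length = integer(), aa_sequence = character()))
  }
  bind_rows(res) |> arrange(.data$frame, .data$start)
}

#' Bundled reverse-transcriptase and endonuclease reference peptides
#'
#' Loads the packaged domain reference peptides used by [match_domain()].
#' These are synthetic stand-in profiles (fixed-seed constructs shipped as
#' `synthetic_l1_orf2_domains.faa`), not curated alignments: they define a
#' self-consistent screen — the simulator plants the same peptides — but
#' carry no information about real L1 ORF2p, so screening real genomes
#' requires substituting curated RT/EN consensus peptides via the `path`
#' argument.
#'
#' @param path Optional path to an alternative FASTA of peptides named
#'   `EN` and `RT`.
#' @return An `AAStringSet` with elements `EN` and `RT`.
#' @export
load_domain_profiles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "synthetic_l1_orf2_domains.faa",
                                package = "retroscape")
  prof <- Biostrings::readAAStringSet(path)
  names(prof) <- sub("\\s.*$", "", names(prof))
  if (!all(c("EN", "RT") %in% names(prof))) {
    abort("domain profile FASTA must contain peptides named 'EN' and 'RT'")
  }
  prof
}

#' Match a peptide against a domain reference
#'
#' Local (Smith-Waterman) alignment of an ORF peptide against a reference
#' domain peptide with BLOSUM62 scoring. Domain "completeness" is
#' operationalised as coverage: the aligned portion of the reference must
#' span at least `min_coverage` of its length (default 0.9). Similarity is
#' the fraction of aligned columns with a positive substitution score
#' (gaps count as failures).
#'
#' @param aa_sequence Peptide string.
#' @param domain `"RT"` or `"EN"`.
#' @param profiles An `AAStringSet` from [load_domain_profiles()].
#' @param min_coverage Minimum fraction of the reference covered.
#' @param min_similarity Minimum fraction of positive-scoring aligned
#'   columns (default 0.5).
#' @return One-row tibble: `domain`, `coverage`, `similarity`, `score`,
#'   `pass`.
#' @export
match_domain <- function(aa_sequence, domain = c("RT", "EN"),
                         profiles = load_domain_profiles(),
                         min_coverage = 0.9, min_similarity = 0.5) {
  domain <- match.arg(domain)
  if (!nzchar(aa_sequence)) abort("empty peptide")
  profile <- profiles[[domain]]
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_sequence), profile,
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5
  )
  sub_range <- Biostrings::subject(al)
  coverage <- (Biostrings::end(sub_range) - Biostrings::start(sub_range) + 1) /
    length(profile)
  p_chr <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s_chr <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  no_gap <- p_chr != "-" & s_chr != "-"
  B <- blosum62()
  positive <- no_gap
  positive[no_gap] <- B[cbind(p_chr[no_gap], s_chr[no_gap])] > 0
  similarity <- if (length(p_chr)) mean(positive) else 0
  tibble(
    domain = domain, coverage = coverage, similarity = similarity,
    score = Biostrings::score(al),
    pass = coverage >= min_coverage & similarity >= min_similarity
  )
}

blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Screen LINE loci for intact ORFs
#'
#' Extracts each annotated LINE locus, finds complete ORFs in all six
#' frames, and tests every ORF for both a complete reverse-transcriptase
#' and a complete endonuclease domain ([match_domain()]). An ORF is intact
#' when both domains pass in that single reading frame (as in LINE ORF2p,
#' where EN and RT reside on one peptide); a locus is intact when any of
#' its ORFs is; the species-level flag is the disjunction over loci.
#'
#' @inheritParams extract_te_sequences
#' @param min_aa Minimum ORF length in aa (default 300).
#' @param profiles,min_coverage,min_similarity Passed to [match_domain()].
#' @return Tibble of class `orf_screen`, one row per ORF (loci without
#'   ORFs get one all-NA row): `locus`, `frame`, `aa_length`,
#'   `rt_coverage`, `rt_similarity`, `en_coverage`, `en_similarity`,
#'   `intact`. `attr(, "has_intact_line")` and [glance()] give the
#'   species-level verdict.
#' @export
screen_lines <- function(genome, insertions, min_aa = 300,
                         profiles = load_domain_profiles(),
                         min_coverage = 0.9, min_similarity = 0.5) {
  seqs <- extract_te_sequences(genome, insertions)
  rows <- list()
  for (i in seq_along(seqs)) {
    locus <- names(seqs)[i]
    orfs <- find_orfs(seqs[[i]], min_aa = min_aa)
    if (nrow(orfs) == 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        locus = locus, frame = NA_integer_, aa_length = NA_integer_,
        rt_coverage = NA_real_, rt_similarity = NA_real_,
        en_coverage = NA_real_, en_similarity = NA_real_, intact = FALSE
      )
      next
    }
    for (j in seq_len(nrow(orfs))) {
      rt <- match_domain(orfs$aa_sequence[j], "RT", profiles,
                         min_coverage, min_similarity)
      en <- match_domain(orfs$aa_sequence[j], "EN", profiles,
                         min_coverage, min_similarity)
      rows[[length(rows) + 1L]] <- tibble(
        locus = locus, frame = orfs$frame[j], aa_length = orfs$aa_length[j],
        rt_coverage = rt$coverage, rt_similarity = rt$similarity,
        en_coverage = en$coverage, en_similarity = en$similarity,
        intact = rt$pass && en$pass
      )
    }
  }
  out <- bind_rows(rows)
  attr(out, "has_intact_line") <- any(out$intact)
  class(out) <- c("orf_screen", class(out))
  out
}

#' @export
glance.orf_screen <- function(x, ...) {
  tibble(
    n_loci = length(unique(x$locus)),
    n_orfs = sum(!is.na(x$frame)),
    n_intact_orfs = sum(x$intact),
    n_intact_loci = length(unique(x$locus[x$intact])),
    has_intact_line = isTRUE(attr(x, "has_intact_line"))
  )
}
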