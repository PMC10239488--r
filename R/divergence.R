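#' Count transitions and transversions in a pairwise alignment
#'
#' Scans equal-length gapped strings column by column. Columns with a gap
#' (`-`) or ambiguous base on either side are skipped entirely. Transitions
#' are A<->G and C<->T; every other mismatch is a transversion. With
#' `cpg_mode = "exclude"`, columns falling inside consensus CpG dinucleotides
#' (C immediately followed by G in the ungapped consensus) are removed from
#' the usable sites before counting, mirroring the CpG-adjusted divergence
#' RepeatMasker can report; hypermutable CpG transitions then no longer
#' inflate the distance.
#'
#' @param aligned_query,aligned_consensus Equal-length strings over
#'   `A,C,G,T,N,-` (other ambiguity codes are treated as N).
#' @param cpg_mode `"include"` (plain counts, default) or `"exclude"`.
#' @return One-row tibble: `n_sites`, `n_transitions`, `n_transversions`,
#'   `P`, `Q`, `n_cpg_sites` (CpG columns seen, whether or not excluded).
#' @export
#' @examples
#' count_substitutions("ACGT", "ACGA")
count_substitutions <- function(aligned_query, aligned_consensus,
                                cpg_mode = c("include", "exclude")) {
  cpg_mode <- match.arg(cpg_mode)
  if (nchar(aligned_query) != nchar(aligned_consensus)) {
    abort("aligned strings must have equal length")
  }
  q <- toupper(strsplit(aligned_query, "")[[1]])
  s <- toupper(strsplit(aligned_consensus, "")[[1]])
  bases <- c("A", "C", "G", "T")
  q[!(q %in% c(bases, "-"))] <- "N"
  s[!(s %in% c(bases, "-"))] <- "N"
  usable <- q %in% bases & s %in% bases

  # consensus CpG columns: C then G in the ungapped consensus sequence
  cons_pos <- which(s != "-")
  cpg_col <- rep(FALSE, length(s))
  if (length(cons_pos) >= 2L) {
    is_c <- s[cons_pos] == "C"
    next_g <- c(s[cons_pos][-1] == "G", FALSE)
    cpg_start <- cons_pos[is_c & next_g]
    cpg_col[cpg_start] <- TRUE
    cpg_col[cons_pos[match(cpg_start, cons_pos) + 1L]] <- TRUE
  }
  n_cpg_sites <- sum(usable & cpg_col)
  if (cpg_mode == "exclude") usable <- usable & !cpg_col

  n_sites <- sum(usable)
  if (n_sites == 0L) abort("no usable alignment columns")
  qq <- q[usable]
  ss <- s[usable]
  diff <- qq != ss
  transition <- diff & ((qq == "A" & ss == "G") | (qq == "G" & ss == "A") |
                          (qq == "C" & ss == "T") | (qq == "T" & ss == "C"))
  tibble(
    n_sites = n_sites,
    n_transitions = sum(transition),
    n_transversions = sum(diff & !transition),
    P = sum(transition) / n_sites,
    Q = sum(diff & !transition) / n_sites,
    n_cpg_sites = n_cpg_sites
  )
}

#' Kimura 2-parameter distance
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P` and `Q` are the
#' observed proportions of transitions and transversions. The distance is
#' the expected number of substitutions per site under a two-rate
#' substitution model, correcting the raw mismatch fraction for multiple
#' hits.
#'
#' @param P,Q Transition and transversion proportions (vectorised,
#'   recycled).
#' @return Numeric vector of distances (substitutions per site). Errors
#'   when the arguments leave the model's domain (`1 - 2P - Q <= 0` or
#'   `1 - 2Q <= 0`), i.e. the sequences are too divergent for the distance
#'   to be defined.
#' @export
#' @examples
#' kimura2p(0.2, 0.1) # = log(5) / 4
kimura2p <- function(P, Q) {
  if (any(P < 0) || any(Q < 0)) abort("P and Q must be non-negative")
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (any(a <= 0) || any(b <= 0)) {
    abort("Kimura 2-p distance undefined (too divergent): 1-2P-Q and 1-2Q must be positive")
  }
  -0.5 * log(a * sqrt(b))
}

#' Length-weighted divergence of a fragmented insertion
#'
#' Fragments of one interrupted insertion each carry their own divergence
#' estimate; the insertion-level value is the mean weighted by aligned
#' fragment length, so long fragments dominate as they should.
#'
#' @param K Numeric vector of per-fragment distances.
#' @param length Positive aligned lengths (same length as `K`).
#' @return Single merged divergence.
#' @export
insertion_divergence <- function(K, length) {
  if (length(K) == 0L) abort("at least one fragment is required")
  if (length(K) != length(length)) abort("K and length must have equal length")
  if (any(length <= 0)) abort("fragment lengths must be positive")
  sum(K * length) / sum(length)
}

#' Per-block Kimura divergence from alignment blocks
#'
#' Applies [count_substitutions()] and [kimura2p()] to each row of a table
#' of alignment blocks (as returned by [read_rmsk_align()]).
#'
#' @param blocks Tibble with columns `aligned_query`, `aligned_consensus`.
#' @param cpg_mode Passed to [count_substitutions()].
#' @return `blocks` with added columns `n_sites`, `P`, `Q` and `K`
#'   (substitutions per site).
#' @export
block_divergence <- function(blocks, cpg_mode = c("include", "exclude")) {
  cpg_mode <- match.arg(cpg_mode)
  counts <- map(seq_len(nrow(blocks)), function(i) {
    count_substitutions(blocks$aligned_query[[i]], blocks$aligned_consensus[[i]],
                        cpg_mode = cpg_mode)
  }) |> bind_rows()
  blocks |>
    mutate(
      n_sites = counts$n_sites, P = counts$P, Q = counts$Q,
      K = kimura2p(counts$P, counts$Q)
    )
}
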