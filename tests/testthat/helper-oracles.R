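# Independent oracles used across tests. Each re-derives the expected
# quantity by brute force, through a different code path than the
# implementation it checks.

# exact signed-rank p by enumerating all 2^n sign assignments
enumerate_signed_rank_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  W_all <- apply(signs, 1, function(pos) sum(r[unlist(pos)]))
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  switch(alternative,
    less = p_le,
    greater = p_ge,
    two_sided = min(1, 2 * min(p_le, p_ge))
  )
}

# per-column recount of substitutions, written as an explicit loop
brute_count_substitutions <- function(q, s) {
  qc <- strsplit(toupper(q), "")[[1]]
  sc <- strsplit(toupper(s), "")[[1]]
  n_sites <- 0L; ti <- 0L; tv <- 0L
  purine <- c("A", "G")
  for (i in seq_along(qc)) {
    a <- qc[i]; b <- sc[i]
    if (!a %in% c("A", "C", "G", "T")) next
    if (!b %in% c("A", "C", "G", "T")) next
    n_sites <- n_sites + 1L
    if (a != b) {
      same_type <- (a %in% purine) == (b %in% purine)
      if (same_type) ti <- ti + 1L else tv <- tv + 1L
    }
  }
  list(n_sites = n_sites, n_transitions = ti, n_transversions = tv)
}

# brute-force six-frame ORF scan: every ATG, walk to the first in-frame stop
brute_find_orfs <- function(seq_chr, min_aa) {
  seq_chr <- toupper(seq_chr)
  L <- nchar(seq_chr)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (frame in 0:5) {
    s <- if (frame < 3) seq_chr else rc
    off <- frame %% 3
    codon_starts <- seq(off + 1, nchar(s) - 2, by = 3)
    codons <- substring(s, codon_starts, codon_starts + 2)
    last_stop <- 0
    for (ci in seq_along(codons)) {
      if (codons[ci] %in% stops) {
        region <- codons[seq_len(ci - 1)][seq_len(ci - 1) > last_stop]
        m_idx <- which(region == "ATG")
        if (length(m_idx)) {
          m <- last_stop + m_idx[1]
          aa_len <- ci - m
          if (aa_len >= min_aa) {
            nt_start <- off + (m - 1) * 3
            nt_end <- off + ci * 3
            coords <- if (frame < 3) c(nt_start, nt_end) else c(L - nt_end, L - nt_start)
            out[[length(out) + 1]] <- data.frame(frame = frame,
                                                 start = coords[1], end = coords[2],
                                                 aa_length = aa_len)
          }
        }
        last_stop <- ci
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), start = numeric(), end = numeric(),
                      aa_length = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$frame, res$start), , drop = FALSE]
}

# all-pairs brute-force lifespan pairing
brute_make_pairs <- function(profiles, fold = 2) {
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    for (j in seq_len(nrow(profiles))) {
      if (i == j) next
      if (profiles$lifespan_years[i] >= fold * profiles$lifespan_years[j]) {
        out[[length(out) + 1]] <- data.frame(
          long_species = profiles$species[i],
          short_species = profiles$species[j]
        )
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(long_species = character(), short_species = character())
  res[order(res$long_species, res$short_species), , drop = FALSE]
}

# alternative algebraic form of the Kimura 2-p distance
kimura2p_alt <- function(P, Q) {
  0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
}

random_dna <- function(n, gc = 0.5) retroscape:::random_dna(n, gc)

# a small simulated genome shared by several tests
small_sim_config <- function(...) {
  sim_config(
    genome_length = 2e5,
    families = tibble::tibble(
      family = c("L1sim", "B1sim", "hATsim"),
      class_family = c("LINE/L1", "SINE/B1", "DNA/hAT"),
      cons_length = c(1500L, 300L, 400L),
      n = c(15L, 25L, 10L),
      w_recent = c(0.4, 0.4, 0)
    ),
    ...
  )
}

# run the full annotation -> divergence -> merge round trip on a te_sim
sim_to_insertions <- function(sim, dir = withr::local_tempdir(), use_align = TRUE) {
  paths <- emit_annotation(sim, dir)
  records <- read_rmsk_out(paths["out"])
  if (!use_align) {
    return(suppressWarnings(merge_fragments(records)))
  }
  blocks <- block_divergence(read_rmsk_align(paths["align"]))
  key <- paste(records$insertion_id, records$query_begin)
  bkey <- paste(blocks$insertion_id, blocks$query_begin)
  merge_fragments(records, divergence = blocks$K[match(key, bkey)])
}
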