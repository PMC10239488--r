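#' Simulation configuration
#'
#' Assembles the knobs of the ground-truthed TE genome simulator. Defaults
#' describe a desk-scale mammalian-like chromosome: a 1 Mb sequence at 41%
#' GC carrying five TE families whose copies age under a two-component
#' divergence mixture — an ancient peak at 25% +/- 3% divergence (the
#' ancestral accumulation seen in mammalian repeat landscapes) and a recent
#' component at 1% +/- 0.7% with per-family weight `w_recent`. Substitutions
#' are placed with transition:transversion odds `kappa`:1 (default 2);
#' annotation fragmentation mimics interrupted insertions.
#'
#' @param genome_length Chromosome length in bp.
#' @param gc Background GC content (0-1, exclusive).
#' @param kappa Transition:transversion odds ratio (> 0).
#' @param frag_prob Probability an insertion is annotated as several
#'   fragments sharing one identifier.
#' @param frag_max Maximum fragments per insertion (uniform on 2..frag_max).
#' @param families Tibble with columns `family`, `class_family`,
#'   `cons_length`, `n`, `w_recent`.
#' @param ancient_mean,ancient_sd,recent_mean,recent_sd Divergence mixture
#'   components, in percent.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, gc = 0.41, kappa = 2,
                       frag_prob = 0.2, frag_max = 3,
                       families = NULL,
                       ancient_mean = 25, ancient_sd = 3,
                       recent_mean = 1, recent_sd = 0.7) {
  if (gc <= 0 || gc >= 1) abort("gc must be strictly between 0 and 1")
  if (kappa <= 0) abort("kappa must be positive")
  families <- families %||% tibble(
    family = c("L1sim", "B1sim", "ERVsim", "hATsim", "Helsim"),
    class_family = c("LINE/L1", "SINE/B1", "LTR/ERVK", "DNA/hAT", "RC/Helitron"),
    cons_length = c(2000L, 300L, 600L, 500L, 600L),
    n = c(60L, 80L, 30L, 30L, 20L),
    w_recent = c(0.3, 0.3, 0.1, 0, 0)
  )
  stopifnot(all(families$n >= 0), all(families$cons_length > 0),
            all(families$w_recent >= 0 & families$w_recent <= 1))
  structure(
    list(genome_length = genome_length, gc = gc, kappa = kappa,
         frag_prob = frag_prob, frag_max = frag_max, families = families,
         ancient_mean = ancient_mean, ancient_sd = ancient_sd,
         recent_mean = recent_mean, recent_sd = recent_sd),
    class = "sim_config"
  )
}

#' Generate a random consensus sequence
#'
#' @param length Sequence length (> 0).
#' @param gc GC content, strictly between 0 and 1.
#' @param seed Optional seed for a reproducible sequence.
#' @return A character string of A/C/G/T.
#' @export
make_consensus <- function(length, gc = 0.5, seed = NULL) {
  if (length <= 0) abort("length must be positive")
  if (gc <= 0 || gc >= 1) abort("gc must be strictly between 0 and 1")
  with_seed_if(seed, random_dna(length, gc))
}

# per-site substitution probability whose expected (P, Q) hit target_K
solve_site_rate <- function(target_K, kappa) {
  if (target_K < 0) abort("target_K must be non-negative")
  if (target_K == 0) return(0)
  s_max <- (kappa + 1) / (2 * kappa + 1) # keeps 1 - 2P - Q > 0
  f <- function(s) {
    kimura2p(s * kappa / (kappa + 1), s / (kappa + 1)) - target_K
  }
  stats::uniroot(f, c(1e-12, s_max * (1 - 1e-9)), tol = 1e-12)$root
}

#' Mutate a consensus copy to a target Kimura divergence
#'
#' Each site substitutes independently with probability solving the
#' Kimura 2-parameter expectation for `target_K`; a substitution is a
#' transition with odds `kappa`:1 against a transversion (each of the two
#' transversion targets equally likely). Substitution-only, so the true
#' alignment is the identity: copy and consensus align column by column.
#'
#' @param consensus Consensus string.
#' @param target_K Target divergence in substitutions per site.
#' @param kappa Transition:transversion odds.
#' @param seed Optional seed.
#' @return List: `copy` (mutated string), `aligned_query`,
#'   `aligned_consensus` (the gapless truth alignment), `n_transitions`,
#'   `n_transversions`.
#' @export
mutate_copy <- function(consensus, target_K, kappa = 2, seed = NULL) {
  s_rate <- solve_site_rate(target_K, kappa)
  with_seed_if(seed, {
    base <- strsplit(consensus, "")[[1]]
    n <- length(base)
    hit <- runif(n) < s_rate
    is_ti <- hit & (runif(n) < kappa / (kappa + 1))
    is_tv <- hit & !is_ti
    ti_map <- c(A = "G", G = "A", C = "T", T = "C")
    tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                   C = c("A", "G"), T = c("A", "G"))
    copy <- base
    copy[is_ti] <- ti_map[base[is_ti]]
    if (any(is_tv)) {
      copy[is_tv] <- vapply(base[is_tv],
                            function(b) sample(tv_map[[b]], 1L), character(1))
    }
    list(
      copy = paste(copy, collapse = ""),
      aligned_query = paste(copy, collapse = ""),
      aligned_consensus = consensus,
      n_transitions = sum(is_ti),
      n_transversions = sum(is_tv)
    )
  })
}

draw_divergence_pct <- function(n, recent, config) {
  out <- numeric(n)
  if (any(recent)) {
    out[recent] <- rtrunc_norm(sum(recent), config$recent_mean,
                               config$recent_sd, 0.01, 4.5)
  }
  if (any(!recent)) {
    out[!recent] <- rtrunc_norm(sum(!recent), config$ancient_mean,
                                config$ancient_sd, 5, 45)
  }
  out
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

# split len into k parts, each >= min_part
split_lengths <- function(len, k, min_part = 30L) {
  if (k == 1L || len < k * min_part) return(len)
  repeat {
    cuts <- sort(sample(seq_len(len - 1L), k - 1L))
    parts <- diff(c(0L, cuts, len))
    if (all(parts >= min_part)) return(parts)
  }
}

#' Simulate a genome with ground-truthed TE insertions
#'
#' Draws consensus sequences, mutates copies to mixture-drawn target
#' divergences, optionally splits copies into annotation fragments with
#' unannotated spacer sequence between them, and places every insertion
#' uniformly at random without overlap in a random background chromosome
#' (`chr1`). Per-fragment truth records the realized alignment, raw
#' mismatch percent and Kimura divergence; per-insertion truth carries the
#' length-weighted merged divergence — the quantities the annotation
#' pipeline is supposed to recover.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; fixed seed gives byte-identical output.
#' @return List of class `te_sim`: `genome` (`DNAStringSet`), `consensus`
#'   (`DNAStringSet`), `truth_fragments`, `truth_insertions`, `config`.
#' @export
simulate_genome <- function(config = sim_config(), seed = NULL) {
  with_seed_if(seed, {
    fam <- config$families
    consensi <- setNames(
      map_chr(seq_len(nrow(fam)),
              function(i) random_dna(fam$cons_length[i], config$gc)),
      fam$family
    )
    ins <- fam |>
      tidyr::uncount(.data$n, .id = "copy_index") |>
      mutate(
        recent = runif(dplyr::n()) < .data$w_recent,
        div_pct = draw_divergence_pct(dplyr::n(), .data$recent, config),
        insertion_id = row_number()
      )
    n_ins <- nrow(ins)

    frag_rows <- vector("list", n_ins)
    block_seqs <- character(n_ins)
    for (i in seq_len(n_ins)) {
      fam_i <- ins$family[i]
      cons <- consensi[[fam_i]]
      mc <- mutate_copy(cons, ins$div_pct[i] / 100, config$kappa)
      len <- nchar(cons)
      k <- if (runif(1) < config$frag_prob && len >= 2L * 30L) {
        ks <- 2:config$frag_max
        ks[sample.int(length(ks), 1L)] # sample() would misread a scalar
      } else 1L
      parts <- split_lengths(len, k)
      k <- length(parts)
      cons_begin <- cumsum(c(0L, parts[-k])) # 0-based within consensus
      spacer_len <- if (k > 1L) sample(50:200, k - 1L, replace = TRUE) else integer()
      spacers <- map_chr(spacer_len, function(L) random_dna(L, config$gc))
      # block in copy orientation: frag1 spacer1 frag2 ...
      frag_seq <- substring(mc$copy, cons_begin + 1L, cons_begin + parts)
      pieces <- character(2L * k - 1L)
      pieces[seq(1L, 2L * k - 1L, by = 2L)] <- frag_seq
      if (k > 1L) pieces[seq(2L, 2L * k - 2L, by = 2L)] <- spacers
      block <- paste(pieces, collapse = "")
      ins_strand <- sample(c("+", "-"), 1L)
      block_seqs[i] <- if (ins_strand == "-") revcomp_chr(block) else block
      off_in_block <- cumsum(c(0L, head(parts, -1L) + spacer_len))
      this_block_len <- nchar(block)
      if (ins_strand == "-") {
        off_in_block <- this_block_len - off_in_block - parts
      }
      frag_rows[[i]] <- tibble(
        insertion_id = ins$insertion_id[i],
        family = fam_i,
        class_family = ins$class_family[i],
        strand = ins_strand,
        frag_index = seq_len(k),
        frag_len = parts,
        cons_begin = cons_begin,
        cons_length = len,
        off_in_block = off_in_block,
        aligned_query = substring(mc$aligned_query, cons_begin + 1L,
                                  cons_begin + parts),
        aligned_consensus = substring(mc$aligned_consensus, cons_begin + 1L,
                                      cons_begin + parts)
      )
    }

    block_len <- nchar(block_seqs)
    free <- config$genome_length - sum(block_len)
    if (free < 0) abort("insertions do not fit in the genome; increase genome_length")
    gap_points <- sort(runif(n_ins, 0, free))
    block_start <- floor(gap_points) + cumsum(c(0, head(block_len, -1)))
    block_start <- as.integer(block_start)

    ord <- order(block_start)
    segs <- character(2L * n_ins + 1L)
    prev_end <- 0L
    for (j in seq_len(n_ins)) {
      i <- ord[j]
      segs[2L * j - 1L] <- random_dna(block_start[i] - prev_end, config$gc)
      segs[2L * j] <- block_seqs[i]
      prev_end <- block_start[i] + block_len[i]
    }
    segs[2L * n_ins + 1L] <- random_dna(config$genome_length - prev_end, config$gc)
    genome <- Biostrings::DNAStringSet(paste(segs, collapse = ""))
    names(genome) <- "chr1"

    frags <- bind_rows(frag_rows) |>
      left_join(tibble(insertion_id = ins$insertion_id, block_start = block_start),
                by = "insertion_id") |>
      mutate(
        query_name = "chr1",
        start = .data$block_start + .data$off_in_block,
        end = .data$start + .data$frag_len
      )
    counts <- map(seq_len(nrow(frags)), function(i) {
      count_substitutions(frags$aligned_query[i], frags$aligned_consensus[i])
    }) |> bind_rows()
    frags <- frags |>
      mutate(
        n_mismatch = counts$n_transitions + counts$n_transversions,
        pct_div = 100 * .data$n_mismatch / .data$frag_len,
        K = kimura2p(counts$P, counts$Q),
        score = as.integer(round(2 * .data$frag_len * (1 - .data$pct_div / 100)))
      ) |>
      select("query_name", "start", "end", "strand", "family", "class_family",
             "insertion_id", "frag_index", "frag_len", "cons_begin",
             "cons_length", "pct_div", "K", "score",
             "aligned_query", "aligned_consensus") |>
      arrange(.data$start)

    truth_ins <- frags |>
      group_by(.data$insertion_id) |>
      summarise(
        query_name = first(.data$query_name),
        start = min(.data$start), end = max(.data$end),
        strand = first(.data$strand),
        family = first(.data$family), class_family = first(.data$class_family),
        total_bp = sum(.data$frag_len), n_fragments = dplyr::n(),
        divergence = insertion_divergence(.data$K, .data$frag_len),
        .groups = "drop"
      ) |>
      mutate(
        te_class = classify_te_family(.data$class_family),
        target_div_pct = ins$div_pct[match(.data$insertion_id, ins$insertion_id)],
        is_recent_nonltr = .data$te_class %in% c("LINE", "SINE") &
          .data$divergence < 0.03
      ) |>
      arrange(.data$start)

    structure(
      list(genome = genome,
           consensus = Biostrings::DNAStringSet(consensi),
           truth_fragments = frags, truth_insertions = truth_ins,
           config = config),
      class = "te_sim"
    )
  })
}

#' @export
print.te_sim <- function(x, ...) {
  cat("<te_sim> genome ", sum(Biostrings::width(x$genome)), " bp, ",
      nrow(x$truth_insertions), " insertions (",
      nrow(x$truth_fragments), " fragments)\n", sep = "")
  invisible(x)
}

#' Emit RepeatMasker-style annotation for a simulated genome
#'
#' Writes the per-fragment truth as `.out` (realized raw mismatch percents,
#' shared insertion identifiers, strand-dependent consensus coordinate
#' order) and/or `.align` (the true gapless alignments plus a
#' `Kimura (with divCpGMod) =` line with the realized Kimura percent).
#' Both files parse under [read_rmsk_out()] / [read_rmsk_align()].
#'
#' @param sim A `te_sim` from [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @param basename File stem (default `"sim"`).
#' @param style `"both"` (default), `"out"` or `"align"`.
#' @return Named character vector of written paths.
#' @export
emit_annotation <- function(sim, dir, basename = "sim",
                            style = c("both", "out", "align")) {
  style <- match.arg(style)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom_len <- sum(Biostrings::width(sim$genome))
  fr <- sim$truth_fragments
  records <- tibble(
    score = fr$score,
    pct_div = round(fr$pct_div, 1), pct_del = 0, pct_ins = 0,
    query_name = fr$query_name,
    query_begin = fr$start, query_end = fr$end,
    query_left = chrom_len - fr$end,
    strand = fr$strand,
    repeat_name = fr$family, class_family = fr$class_family,
    repeat_begin = fr$cons_begin + 1L,
    repeat_end = fr$cons_begin + fr$frag_len,
    repeat_left = fr$cons_length - (fr$cons_begin + fr$frag_len),
    insertion_id = fr$insertion_id,
    overlap_flag = FALSE
  )
  paths <- character()
  if (style %in% c("both", "out")) {
    out_path <- file.path(dir, paste0(basename, ".out"))
    write_rmsk_out(records, out_path)
    paths["out"] <- out_path
  }
  if (style %in% c("both", "align")) {
    align_path <- file.path(dir, paste0(basename, ".align"))
    con <- file(align_path, "w")
    on.exit(close(con), add = TRUE)
    for (i in seq_len(nrow(records))) {
      writeLines(format_out_row(records[i, ]), con)
      writeLines("", con)
      write_align_chunks(con, fr[i, ], chrom_len)
      writeLines(sprintf("Kimura (with divCpGMod) = %.2f", 100 * fr$K[i]), con)
      writeLines("", con)
    }
    paths["align"] <- align_path
  }
  paths
}

write_align_chunks <- function(con, frag, chrom_len, width = 60L) {
  q <- frag$aligned_query
  s <- frag$aligned_consensus
  n <- nchar(q)
  qpos <- frag$start + 1L # 1-based genomic (fragment orientation ignored here)
  spos <- frag$cons_begin + 1L
  for (chunk_start in seq(1L, n, by = width)) {
    chunk_end <- min(chunk_start + width - 1L, n)
    qc <- substr(q, chunk_start, chunk_end)
    sc <- substr(s, chunk_start, chunk_end)
    q_adv <- nchar(gsub("-", "", qc))
    s_adv <- nchar(gsub("-", "", sc))
    writeLines(sprintf("  %s %d %s %d", frag$query_name, qpos, qc,
                       qpos + q_adv - 1L), con)
    writeLines(sprintf("  %s %d %s %d", frag$family, spos, sc,
                       spos + s_adv - 1L), con)
    qpos <- qpos + q_adv
    spos <- spos + s_adv
  }
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes either uniformly or as a two-component
#' process in which a fraction `clustering` of genes falls inside one
#' cluster region spanning 10% of the chromosome (its location recorded in
#' `attr(, "cluster_region")`), emulating gene-rich neighbourhoods. Each
#' gene gets alternating exon/intron structure.
#'
#' @param genome_length Chromosome length (bp); chromosome is named `chr1`.
#' @param n_genes Number of genes (>= 0).
#' @param clustering Fraction of genes placed inside the cluster region
#'   (0 = uniform).
#' @param seed Optional seed.
#' @param gene_length Range of gene lengths (bp).
#' @param n_exons Range of exons per gene.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `strand`, `exons`
#'   (list-column of `start`/`end` tibbles). Write with [write_gff3()].
#' @export
make_genes <- function(genome_length, n_genes, clustering = 0, seed = NULL,
                       gene_length = c(2000, 6000), n_exons = 2:4) {
  stopifnot(n_genes >= 0, clustering >= 0, clustering <= 1)
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  exons = list())
  if (n_genes == 0L) return(empty)
  with_seed_if(seed, {
    cluster_w <- round(0.1 * genome_length)
    cluster_start <- sample.int(genome_length - cluster_w, 1L)
    lens <- sample(gene_length[1]:gene_length[2], n_genes, replace = TRUE)
    in_cluster <- runif(n_genes) < clustering
    starts <- integer(n_genes)
    taken <- tibble(start = integer(), end = integer())
    for (i in seq_len(n_genes)) {
      placed <- FALSE
      for (try in 1:1000) {
        # clustered placement falls back to uniform once the cluster is full
        use_cluster <- in_cluster[i] && try <= 200 &&
          cluster_w - lens[i] > 0
        s <- if (use_cluster) {
          cluster_start + sample.int(cluster_w - lens[i], 1L) - 1L
        } else {
          sample.int(genome_length - lens[i], 1L) - 1L
        }
        e <- s + lens[i]
        if (!any(s < taken$end & e > taken$start)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("could not place genes without overlap; reduce n_genes or gene_length")
      starts[i] <- s
      taken <- bind_rows(taken, tibble(start = s, end = e))
    }
    genes <- tibble(
      gene_id = sprintf("gene%03d", seq_len(n_genes)),
      chrom = "chr1", start = starts, end = starts + lens,
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    ) |>
      mutate(exons = map2(.data$start, .data$end, function(s, e) {
        k <- sample(n_exons, 1L)
        bounds <- round(seq(s, e, length.out = 2L * k))
        tibble(start = bounds[seq(1L, 2L * k - 1L, by = 2L)],
               end = bounds[seq(2L, 2L * k, by = 2L)])
      })) |>
      arrange(.data$start)
    attr(genes, "cluster_region") <- c(start = cluster_start,
                                       end = cluster_start + cluster_w)
    genes
  })
}
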