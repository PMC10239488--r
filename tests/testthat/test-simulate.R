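test_that("consensus generation is seeded and composition-controlled", {
  a <- make_consensus(1000, 0.5, seed = 1)
  b <- make_consensus(1000, 0.5, seed = 1)
  expect_identical(a, b)
  expect_error(make_consensus(1000, 1.0), "between 0 and 1")
  s <- make_consensus(1e5, 0.4, seed = 2)
  gc_obs <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  sd_gc <- sqrt(0.4 * 0.6 / 1e5)
  expect_lt(abs(gc_obs - 0.4), 3 * sd_gc)
})

test_that("mutate_copy hits its target divergence without bias", {
  cons <- make_consensus(5000, 0.45, seed = 3)
  ident <- mutate_copy(cons, 0, seed = 4)
  expect_identical(ident$copy, cons)
  withr::local_seed(5)
  k_hat <- replicate(80, {
    mc <- mutate_copy(cons, 0.10, kappa = 2)
    cnt <- count_substitutions(mc$copy, cons)
    kimura2p(cnt$P, cnt$Q)
  })
  se <- sd(k_hat) / sqrt(length(k_hat))
  expect_lt(abs(mean(k_hat) - 0.10), 2 * se + 1e-4)
})

test_that("large kappa suppresses transversions", {
  cons <- make_consensus(20000, 0.5, seed = 6)
  mc <- mutate_copy(cons, 0.05, kappa = 1e6, seed = 7)
  expect_equal(mc$n_transversions, 0)
  expect_gt(mc$n_transitions, 0)
})

test_that("simulation under a fixed seed is fully deterministic", {
  s1 <- simulate_genome(small_sim_config(), seed = 71)
  s2 <- simulate_genome(small_sim_config(), seed = 71)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth_fragments, s2$truth_fragments)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_annotation(s1, d1)
  p2 <- emit_annotation(s2, d2)
  expect_identical(readLines(p1["out"]), readLines(p2["out"]))
  expect_identical(readLines(p1["align"]), readLines(p2["align"]))
})

test_that("insertion placement and fragmentation keep the truth consistent", {
  cfg <- small_sim_config(frag_prob = 1, frag_max = 2)
  sim <- simulate_genome(cfg, seed = 72)
  expect_equal(nrow(sim$truth_insertions), 50L)
  expect_equal(nrow(sim$truth_fragments), 100L)
  expect_equal(length(unique(sim$truth_fragments$insertion_id)), 50L)
  expect_equal(sum(Biostrings::width(sim$genome)), 2e5)
  # planted fragments really sit at their recorded coordinates
  g <- as.character(sim$genome[[1]])
  fr <- sim$truth_fragments
  for (i in sample(nrow(fr), 10)) {
    seq_at <- substr(g, fr$start[i] + 1, fr$end[i])
    planted <- if (fr$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(fr$aligned_query[i])))
    } else {
      fr$aligned_query[i]
    }
    expect_identical(seq_at, planted)
  }
  # infeasible packing errors out
  toomany <- sim_config(genome_length = 1e4)
  expect_error(simulate_genome(toomany, seed = 73), "fit")
})

test_that("insertion starts are close to uniform across windows", {
  cfg <- sim_config(
    genome_length = 2e6,
    families = tibble::tibble(family = "B1sim", class_family = "SINE/B1",
                              cons_length = 200L, n = 400L, w_recent = 0.3),
    frag_prob = 0
  )
  pvals <- vapply(1:3, function(s) {
    sim <- simulate_genome(cfg, seed = 80 + s)
    counts <- table(cut(sim$truth_insertions$start, seq(0, 2e6, by = 2e5)))
    suppressWarnings(stats::chisq.test(as.vector(counts))$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("emitted annotation parses cleanly and matches the truth table", {
  sim <- simulate_genome(small_sim_config(), seed = 74)
  dir <- withr::local_tempdir()
  expect_no_warning(paths <- emit_annotation(sim, dir))
  expect_no_warning(rec <- read_rmsk_out(paths["out"]))
  fr <- dplyr::arrange(sim$truth_fragments, start)
  expect_equal(rec$query_begin, fr$start)
  expect_equal(rec$query_end, fr$end)
  expect_equal(rec$insertion_id, fr$insertion_id)
  expect_equal(rec$class_family, fr$class_family)
  expect_equal(rec$pct_div, round(fr$pct_div, 1))
  expect_equal(rec$repeat_begin, fr$cons_begin + 1L)
  # empty truth -> header-only file
  sim0 <- sim
  sim0$truth_fragments <- fr[0, ]
  p0 <- emit_annotation(sim0, dir, basename = "empty")
  expect_equal(nrow(read_rmsk_out(p0["out"])), 0L)
})

test_that("full divergence pipeline recovers per-insertion truth to high accuracy", {
  cfg <- sim_config(
    genome_length = 6e5,
    families = tibble::tibble(family = "L1sim", class_family = "LINE/L1",
                              cons_length = 5000L, n = 40L, w_recent = 0.3),
    frag_prob = 0.3
  )
  sim <- simulate_genome(cfg, seed = 75)
  ins <- sim_to_insertions(sim)
  m <- dplyr::inner_join(
    dplyr::select(ins, insertion_id, divergence),
    dplyr::select(sim$truth_insertions, insertion_id, truth = divergence),
    by = "insertion_id"
  )
  expect_equal(nrow(m), 40L)
  # .align carries the exact alignments, so recovery is exact
  expect_equal(m$divergence, m$truth, tolerance = 1e-12)
  # and both sit within binomial sampling error of the generator's target
  t2 <- dplyr::inner_join(
    m, dplyr::select(sim$truth_insertions, insertion_id, target_div_pct),
    by = "insertion_id"
  )
  expect_lt(max(abs(t2$divergence - t2$target_div_pct / 100)), 0.02)
})

test_that("LINE locus construction produces the promised ORF structure", {
  loc <- make_line_locus(TRUE, seed = 76)
  orfs <- find_orfs(loc$seq, min_aa = 300)
  expect_gte(nrow(orfs), 1L)
  expect_true(any(orfs$start == loc$orf_start & orfs$end == loc$orf_end))
  for (d in c("stop", "frameshift", "deletion")) {
    bad <- make_line_locus(FALSE, d, seed = 76)
    g <- Biostrings::DNAStringSet(c(chr1 = bad$seq))
    scr <- screen_lines(g, tibble::tibble(query_name = "chr1", start = 0L,
                                          end = nchar(bad$seq), strand = "+"))
    expect_false(attr(scr, "has_intact_line"))
  }
})

test_that("cohorts reproduce the configured DI contrast", {
  cohort <- default_cohort_spec()
  cc <- make_cohort(cohort, seed = 77)
  di <- cohort_di(cc)
  di <- dplyr::left_join(di, cohort, by = "species")
  short_di <- di$di[di$lifespan_phenotype == "short_lived"]
  long_di <- di$di[di$lifespan_phenotype == "long_lived"]
  expect_gt(min(short_di), max(long_di)) # 2x rate gap, large counts
  res <- pair_test(di, make_pairs(cohort), alternative = "less")
  expect_lt(res$p_value, 0.05)
  # single species: no pairs downstream
  expect_equal(nrow(make_pairs(cohort[1, ])), 0L)
})

test_that("sequence-mode cohorts plug into the annotation pipeline", {
  cohort <- default_cohort_spec()[c(1, 3), ]
  dir <- withr::local_tempdir()
  cc <- make_cohort(cohort, base_config = small_sim_config(),
                    sequences = TRUE, dir = dir, seed = 78)
  expect_length(cc$data, 2L)
  for (sp in cohort$species) {
    sim <- cc$data[[sp]]
    expect_s3_class(sim, "te_sim")
    ins <- sim_to_insertions(sim)
    truth_recent <- sum(sim$truth_insertions$is_recent_nonltr)
    expect_equal(nrow(select_recent(ins)), truth_recent)
  }
  # short-lived species got the higher recent weight
  expect_gt(sum(cc$data[["Mus musculus"]]$truth_insertions$is_recent_nonltr),
            sum(cc$data[["Heterocephalus glaber"]]$truth_insertions$is_recent_nonltr))
})
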