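out_header <- c(
  "   SW  perc perc perc  query    position in query     matching repeat",
  "score  div. del. ins.  sequence begin end (left)  repeat class/family begin end (left) ID",
  ""
)

test_that("a .out row parses into a record with internal coordinates", {
  f <- withr::local_tempfile(lines = c(
    out_header,
    "463 1.3 0.6 1.7 chr1 1001 1500 (500) + L1MdA LINE/L1 1 500 (0) 7",
    "300 5.0 0.0 0.0 chr1 2001 2200 (100) C B1 SINE/B1 (10) 190 1 8 *"
  ))
  rec <- read_rmsk_out(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$query_name[1], "chr1")
  expect_equal(rec$query_begin[1], 1000L) # 0-based half-open
  expect_equal(rec$query_end[1], 1500L)
  expect_equal(rec$class_family[1], "LINE/L1")
  expect_equal(rec$pct_div[1], 1.3)
  expect_equal(rec$insertion_id[1], 7L)
  expect_false(rec$overlap_flag[1])
  # complement-strand row: strand C -> "-", consensus coords normalised
  expect_equal(rec$strand[2], "-")
  expect_equal(rec$repeat_begin[2], 1L)
  expect_equal(rec$repeat_end[2], 190L)
  expect_equal(rec$repeat_left[2], 10L)
  expect_true(rec$overlap_flag[2])
})

test_that("header-only and malformed .out files behave as specified", {
  f <- withr::local_tempfile(lines = out_header)
  expect_equal(nrow(read_rmsk_out(f)), 0L)
  bad <- withr::local_tempfile(lines = c(out_header, "463 1.3 0.6"))
  expect_error(read_rmsk_out(bad), "line 4")
})

test_that(".out writer round-trips simulator output field-for-field", {
  sim <- simulate_genome(small_sim_config(), seed = 21)
  dir <- withr::local_tempdir()
  paths <- emit_annotation(sim, dir, style = "out")
  rec <- read_rmsk_out(paths["out"])
  expect_equal(nrow(rec), nrow(sim$truth_fragments))
  expect_equal(rec$query_begin, sort(sim$truth_fragments$start))
  # write back and re-read: parsed tables identical, files byte-identical
  f2 <- file.path(dir, "rt.out")
  write_rmsk_out(rec, f2)
  expect_identical(read_rmsk_out(f2), rec)
  expect_identical(readLines(f2)[-(1:3)], readLines(paths["out"])[-(1:3)])
})

test_that("coordinate conversion is an involution", {
  for (b in c(1L, 17L, 1000L)) {
    internal <- retroscape:::to_internal_coords(b, b + 99L)
    ext <- retroscape:::to_external_coords(internal$start, internal$end)
    expect_identical(ext$begin, b)
    expect_identical(ext$end, b + 99L)
  }
})

test_that(".align blocks reconstruct the simulator's true alignments", {
  sim <- simulate_genome(small_sim_config(), seed = 22)
  dir <- withr::local_tempdir()
  paths <- emit_annotation(sim, dir, style = "align")
  expect_no_warning(blocks <- read_rmsk_align(paths["align"]))
  fr <- dplyr::arrange(sim$truth_fragments, start)
  expect_equal(nrow(blocks), nrow(fr))
  expect_equal(blocks$aligned_query, fr$aligned_query)
  expect_equal(blocks$aligned_consensus, fr$aligned_consensus)
  expect_equal(blocks$kimura_reported, round(100 * fr$K, 2))
})

test_that("identical .align strings give zero differences and truncation errors", {
  f <- withr::local_tempfile(lines = c(
    "463 0.0 0.0 0.0 chr1 1 4 (0) + L1 LINE/L1 1 4 (0) 1",
    "  chr1 1 ACGT 4",
    "  L1 1 ACGT 4",
    "Kimura (with divCpGMod) = 0.00"
  ))
  blocks <- read_rmsk_align(f)
  expect_equal(blocks$aligned_query, blocks$aligned_consensus)
  expect_equal(count_substitutions(blocks$aligned_query,
                                   blocks$aligned_consensus)$n_transitions, 0L)
  trunc <- withr::local_tempfile(lines = c(
    "463 0.0 0.0 0.0 chr1 1 4 (0) + L1 LINE/L1 1 4 (0) 1",
    "  chr1 1 ACGT 4"
  ))
  expect_error(read_rmsk_align(trunc), "block 1")
})

test_that("classify_te_family covers the class set and is total", {
  expect_equal(classify_te_family("LINE/L1"), "LINE")
  expect_equal(classify_te_family("RC/Helitron"), "Helitron")
  expect_equal(classify_te_family("Simple_repeat"), "Other")
  expect_equal(classify_te_family("Unknown"), "Unknown")
  labels <- c("LINE/L1", "LINE/CR1", "SINE/Alu", "SINE/B1", "LTR/ERVK",
              "DNA/hAT-Charlie", "RC/Helitron", "Unknown", "Unclassified",
              "Satellite", "Low_complexity", "rRNA", "made-up/label")
  cls <- classify_te_family(labels)
  expect_true(all(cls %in% c("DNA", "Helitron", "SINE", "LINE", "LTR",
                             "Unknown", "Other")))
  expect_length(cls, length(labels))
})

test_that("genome FASTA reading reports exact and non-N lengths", {
  f <- withr::local_tempfile(lines = c(">s", "ACGTNNNN"))
  g <- read_genome_fasta(f)
  expect_equal(g$info$length, 8L)
  expect_equal(g$info$non_n_length, 4L)
  empty <- withr::local_tempfile(lines = character())
  expect_error(read_genome_fasta(empty))
  dup <- withr::local_tempfile(lines = c(">s", "ACGT", ">s", "GGCC"))
  expect_error(read_genome_fasta(dup), "duplicate")
  # simulator genome round trip
  sim <- simulate_genome(small_sim_config(), seed = 23)
  fa <- withr::local_tempfile()
  Biostrings::writeXStringSet(sim$genome, fa)
  expect_equal(read_genome_fasta(fa)$info$length, 2e5)
})

test_that("gene feature derivation performs the stated interval algebra", {
  gff <- withr::local_tempfile(lines = c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t1\t200\t.\t+\t.\tID=g1.e1;Parent=g1",
    "chr1\tsrc\texon\t801\t1000\t.\t+\t.\tID=g1.e2;Parent=g1"
  ))
  fs <- read_gene_features(gff, chrom_lengths = c(chr1 = 5000))
  expect_equal(fs$genes, tibble::tibble(chrom = "chr1", start = 0L, end = 1000L))
  expect_equal(fs$introns$start, 200L)
  expect_equal(fs$introns$end, 800L)
  expect_equal(fs$intergenic$start, 1000L)
  expect_equal(fs$intergenic$end, 5000L)
  # gene-less chromosome: intergenic covers it entirely
  fs2 <- read_gene_features(gff, chrom_lengths = c(chr1 = 5000, chr2 = 300))
  chr2 <- dplyr::filter(fs2$intergenic, chrom == "chr2")
  expect_equal(chr2$start, 0L)
  expect_equal(chr2$end, 300L)
})

test_that("simulated gene annotation round-trips through GFF3", {
  genes <- make_genes(1e5, 12, clustering = 0, seed = 5)
  gff <- withr::local_tempfile()
  write_gff3(genes, gff)
  fs <- read_gene_features(gff, chrom_lengths = c(chr1 = 1e5))
  expect_equal(nrow(fs$genes), 12L) # non-overlapping by construction
  expect_equal(fs$genes$start, genes$start)
  expect_equal(fs$genes$end, genes$end)
  expect_true(all(fs$introns$start >= min(genes$start)))
})

test_that("BED6 export writes 0-based half-open intervals and round-trips", {
  ins <- tibble::tibble(query_name = "chr1", start = 1000L, end = 1500L,
                        family = "L1MdA", strand = "C")
  f <- withr::local_tempfile()
  write_bed(ins, f)
  expect_equal(readLines(f), "chr1\t1000\t1500\tL1MdA\t.\t-")
  gr <- rtracklayer::import(f, format = "bed")
  expect_equal(GenomicRanges::start(gr), 1001L) # GRanges is 1-based
  expect_equal(GenomicRanges::end(gr), 1500L)
  empty <- withr::local_tempfile()
  write_bed(ins[0, ], empty)
  expect_equal(length(readLines(empty)), 0L)
})
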