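test_that("recent selection uses a strict 3% cut and the non-LTR class filter", {
  ins <- tibble::tibble(
    te_class = c("LINE", "LINE", "LTR", "SINE"),
    divergence = c(0.029, 0.030, 0.010, 0.0299999)
  )
  kept <- select_recent(ins)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$divergence < 0.03))
  expect_false("LTR" %in% kept$te_class)
})

test_that("DI arithmetic and scale consistency", {
  expect_equal(density_of_insertion(9000, 2), 4500)
  expect_equal(density_of_insertion(0, 2), 0)
  expect_error(density_of_insertion(10, 0), "positive")
  # doubling count and size leaves DI unchanged
  withr::local_seed(1)
  n <- sample(1:1e5, 20)
  gb <- runif(20, 0.5, 4)
  expect_equal(density_of_insertion(2 * n, 2 * gb),
               density_of_insertion(n, gb))
})

test_that("window counts assign insertions by start position", {
  ins <- tibble::tibble(query_name = "chr1",
                        start = c(0.1e6, 1.2e6, 1.3e6), end = start + 100)
  tr <- window_density(ins, c(chr1 = 3e6), 1e6)
  expect_equal(tr$n, c(1L, 2L, 0L))
  expect_equal(tr$density, c(1, 2, 0))
  # empty set -> all-zero track; totals always balance
  tr0 <- window_density(ins[0, ], c(chr1 = 3e6), 1e6)
  expect_true(all(tr0$n == 0L))
  expect_equal(sum(tr$n), nrow(ins))
  g <- glance(tr)
  expect_equal(g$mean_density, 1)
  expect_equal(g$total_insertions, 3L)
})

test_that("partial trailing windows are normalised per Mb", {
  ins <- tibble::tibble(query_name = "chr1", start = c(2.1e6), end = start + 10)
  tr <- window_density(ins, c(chr1 = 2.5e6), 1e6)
  expect_equal(tr$width_bp, c(1e6, 1e6, 0.5e6))
  expect_equal(tr$density[3], 1 / 0.5)
})

test_that("uniform placement yields window densities near the rate", {
  lambda <- 40 # per Mb
  withr::local_seed(9)
  n <- rpois(1, lambda * 10)
  ins <- tibble::tibble(query_name = "chr1",
                        start = sort(sample.int(1e7, n)), end = start + 1)
  tr <- window_density(ins, c(chr1 = 1e7), 1e6)
  expect_lt(abs(mean(tr$density) - lambda), 3 * sqrt(lambda / 10))
  expect_equal(sum(tr$n), n)
})

test_that("feature densities count starts per window", {
  feats <- structure(list(
    genes = tibble::tibble(chrom = "chr1", start = c(10L, 20L), end = c(500L, 600L)),
    exons = tibble::tibble(chrom = character(), start = integer(), end = integer()),
    introns = tibble::tibble(chrom = character(), start = integer(), end = integer()),
    intergenic = tibble::tibble(chrom = "chr1", start = 0L, end = 2e6),
    chrom_lengths = c(chr1 = 2e6)
  ), class = "gene_features")
  windows <- window_density(tibble::tibble(query_name = character(),
                                           start = integer()),
                            c(chr1 = 2e6), 1e6)
  fd <- feature_density(feats, windows)
  expect_equal(fd$gene_n, c(2L, 0L))
  expect_equal(fd$gene_density, c(2, 0))
  expect_equal(fd$intergenic_n, c(1L, 0L))
})

test_that("clustered simulated genes surface as gene-rich windows", {
  genes <- make_genes(2e6, 40, clustering = 0.8, seed = 6,
                      gene_length = c(1000, 2000))
  cluster <- attr(genes, "cluster_region")
  gff <- withr::local_tempfile()
  write_gff3(genes, gff)
  fs <- read_gene_features(gff, chrom_lengths = c(chr1 = 2e6))
  windows <- window_density(tibble::tibble(query_name = character(),
                                           start = integer()),
                            c(chr1 = 2e6), 1e5)
  fd <- feature_density(fs, windows)
  labels <- classify_windows(fd$gene_density)
  rich <- which(labels == "gene_rich")
  cluster_windows <- which(windows$start < cluster["end"] &
                             windows$end > cluster["start"])
  expect_true(any(cluster_windows %in% rich))
  expect_gt(max(fd$gene_density[cluster_windows]),
            max(fd$gene_density[-cluster_windows]))
})

test_that("spearman rho matches monotone expectations and cor.test", {
  x <- 1:10
  expect_equal(spearman_corr(x, x^2)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  withr::local_seed(14)
  for (rep in 1:5) {
    a <- rnorm(12)
    b <- rnorm(12)
    got <- spearman_corr(a, b)
    ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                            exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("permutation p-value equals full enumeration at n = 6", {
  x <- c(3.2, 1.1, 5.6, 2.2, 4.9, 0.7)
  y <- c(2.0, 1.5, 4.1, 4.4, 3.3, 0.2)
  got <- spearman_corr(x, y, p_method = "permutation")
  # independent full 6! enumeration via recursive index permutations
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perm_idx <- retroscape:::all_permutations(6L)
  rhos <- apply(perm_idx, 1, function(i) stats::cor(rx, ry[i]))
  expect_equal(nrow(perm_idx), factorial(6))
  expect_equal(got$p_value, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
  # hand rank-formula check (no ties): rho = 1 - 6*sum(d^2)/(n(n^2-1))
  expect_equal(got$rho, 1 - 6 * sum((rx - ry)^2) / (6 * 35))
})

test_that("gene-rich/poor classification follows the quantile rule", {
  labels <- classify_windows(1:8)
  expect_equal(quantile(1:8, 0.25, names = FALSE), 2.75)
  expect_equal(quantile(1:8, 0.75, names = FALSE), 6.25)
  expect_equal(labels, c("gene_poor", "gene_poor", "neither", "neither",
                         "neither", "neither", "gene_rich", "gene_rich"))
  expect_warning(lab2 <- classify_windows(rep(3, 6)), "degenerate")
  expect_true(all(lab2 == "neither"))
  # bimodal densities recover the two modes
  dens <- c(rep(1, 10), rep(9, 10))
  lab3 <- classify_windows(dens)
  expect_true(all(lab3[dens < 5] == "gene_poor"))
  expect_true(all(lab3[dens > 5] == "gene_rich"))
})

test_that("rank-sum contrast matches exact enumeration and detects shifts", {
  res <- compare_rich_poor(c(5, 6, 7), c(1, 2, 3))
  expect_equal(res$p_value, 0.1) # 2 / choose(6, 3)
  same <- compare_rich_poor(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_error(compare_rich_poor(numeric(), 1:3), "non-empty")
  # power: groups shifted by 2 sd, n = 50, rejected in >= 95% of replicates
  withr::local_seed(17)
  rej <- replicate(200, {
    compare_rich_poor(rnorm(50, 2), rnorm(50, 0))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.95)
})
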