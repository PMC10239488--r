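#' Select recent non-LTR retrotransposon insertions
#'
#' Young insertions are identified by divergence from consensus strictly
#' below a threshold (default 3%, a conventional proxy for recent activity)
#' among non-LTR retrotransposons (LINEs and SINEs).
#'
#' @param insertions Tibble from [merge_fragments()] (columns `te_class`,
#'   `divergence` as a proportion).
#' @param max_div Divergence threshold as a proportion (default 0.03);
#'   the comparison is strict (`divergence < max_div`).
#' @param classes TE classes retained (default `c("LINE", "SINE")`).
#' @return The filtered subset.
#' @export
select_recent <- function(insertions, max_div = 0.03,
                          classes = c("LINE", "SINE")) {
  filter(insertions, .data$te_class %in% classes, .data$divergence < max_div)
}

#' Density of insertion (DI)
#'
#' `DI = number of insertions / assembly size (Gb)`: the count of recent
#' non-LTR insertions normalised by assembly size, making species with
#' different genome sizes comparable.
#'
#' @param n_insertions Insertion count(s).
#' @param assembly_size_gb Assembly size(s) in gigabases; must be positive.
#' @return Numeric DI (insertions per Gb), vectorised.
#' @export
#' @examples
#' density_of_insertion(9000, 2) # 4500 per Gb
density_of_insertion <- function(n_insertions, assembly_size_gb) {
  if (any(assembly_size_gb <= 0)) abort("assembly_size_gb must be positive")
  n_insertions / assembly_size_gb
}

#' Recent non-LTR DI from merged insertions
#'
#' Convenience wrapper: applies [select_recent()] and [density_of_insertion()].
#'
#' @inheritParams select_recent
#' @param assembly_size_gb Assembly size in Gb.
#' @return One-row tibble: `n_recent`, `assembly_size_gb`, `di`.
#' @export
recent_di <- function(insertions, assembly_size_gb, max_div = 0.03,
                      classes = c("LINE", "SINE")) {
  n <- nrow(select_recent(insertions, max_div = max_div, classes = classes))
  tibble(n_recent = n, assembly_size_gb = assembly_size_gb,
         di = density_of_insertion(n, assembly_size_gb))
}

#' Windowed insertion density
#'
#' Tiles each chromosome with non-overlapping windows of fixed size and
#' counts insertions per window, assigning an insertion to the window
#' containing its start. Densities are per Mb, so the trailing partial
#' window is normalised by its actual width.
#'
#' @param insertions Tibble with columns `query_name` and `start`.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_size Window size in bp (e.g. `0.5e6`, `1e6`, `1.5e6`).
#' @return Tibble of class `window_track`: `chrom`, `start`, `end`,
#'   `width_bp`, `n`, `density` (insertions per Mb). [glance()] returns the
#'   mean and standard deviation of the per-window densities.
#' @export
window_density <- function(insertions, chrom_lengths, window_size) {
  assert_scalar_number(window_size, "window_size", positive = TRUE)
  windows <- make_windows(chrom_lengths, window_size)
  counts <- count_starts_in_windows(windows,
                                    insertions$query_name %||% insertions$chrom,
                                    insertions$start)
  out <- windows |>
    mutate(n = counts, density = .data$n / (.data$width_bp / 1e6))
  attr(out, "window_size") <- window_size
  class(out) <- c("window_track", class(out))
  out
}

make_windows <- function(chrom_lengths, window_size) {
  stopifnot(!is.null(names(chrom_lengths)))
  bind_rows(map(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    starts <- seq(0, len - 1, by = window_size)
    tibble(chrom = chrom, start = starts,
           end = pmin(starts + window_size, len)) |>
      mutate(width_bp = .data$end - .data$start)
  }))
}

count_starts_in_windows <- function(windows, chrom, start) {
  if (length(chrom) == 0L) return(integer(nrow(windows)))
  counts <- integer(nrow(windows))
  for (cm in unique(windows$chrom)) {
    wi <- which(windows$chrom == cm)
    s <- start[chrom == cm]
    s <- s[s >= windows$start[wi[1]] & s < windows$end[wi[length(wi)]]]
    if (length(s)) {
      idx <- findInterval(s, windows$start[wi])
      tab <- tabulate(idx, nbins = length(wi))
      counts[wi] <- tab
    }
  }
  counts
}

#' @export
glance.window_track <- function(x, ...) {
  tibble(
    n_windows = nrow(x), total_insertions = sum(x$n),
    mean_density = mean(x$density), sd_density = sd(x$density),
    window_size = attr(x, "window_size")
  )
}

#' Per-window genomic feature densities
#'
#' Counts genes, exons, introns and intergenic intervals per window (a
#' feature counts in the window containing its start) and converts counts
#' to densities per Mb.
#'
#' @param features A `gene_features` object from [read_gene_features()].
#' @param windows A `window_track` (or any tibble with `chrom`, `start`,
#'   `end`, `width_bp`).
#' @return `windows` with added columns `<feature>_n` and
#'   `<feature>_density` for `gene`, `exon`, `intron`, `intergenic`.
#' @export
feature_density <- function(features, windows) {
  stopifnot(inherits(features, "gene_features"))
  for (feat in c("genes", "exons", "introns", "intergenic")) {
    tbl <- features[[feat]]
    counts <- count_starts_in_windows(windows, tbl$chrom, tbl$start)
    nm <- sub("s$", "", feat)
    windows[[paste0(nm, "_n")]] <- counts
    windows[[paste0(nm, "_density")]] <- counts / (windows$width_bp / 1e6)
  }
  windows
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value uses the
#' t-distribution approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (two-sided); for `n <= 8` an exact permutation p-value over all `n!`
#' orderings can be requested.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @param p_method `"t"` (default) or `"permutation"` (only for `n <= 8`).
#' @return One-row tibble: `rho`, `p_value`, `n`, `p_method`.
#' @export
spearman_corr <- function(x, y, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3L) abort("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("rho undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (p_method == "permutation") {
    if (n > 8L) abort("permutation p-value limited to n <= 8")
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (abs(rho) >= 1) 0 else 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  tibble(rho = rho, p_value = p, n = n, p_method = p_method)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

#' Classify windows as gene-rich or gene-poor
#'
#' Windows at or below the 0.25 quantile of the gene density distribution
#' are gene-poor; windows at or above the 0.75 quantile are gene-rich
#' (quantiles by linear interpolation between order statistics,
#' [stats::quantile()] type 7; comparisons are `<=` and `>=`). When the two
#' quantiles coincide the distribution is degenerate: every window would be
#' both, so all windows are labelled `neither` with a warning.
#'
#' @param gene_density Numeric vector of per-window gene densities
#'   (length `>= 4`).
#' @param probs Lower and upper quantile probabilities (default 0.25/0.75).
#' @return Character vector over `{gene_poor, gene_rich, neither}`.
#' @export
#' @examples
#' classify_windows(1:8)
classify_windows <- function(gene_density, probs = c(0.25, 0.75)) {
  if (length(gene_density) < 4L) abort("need at least 4 windows")
  q <- quantile(gene_density, probs = probs, type = 7, names = FALSE)
  if (q[1] >= q[2]) {
    warn("degenerate gene density distribution (q25 >= q75); labelling all windows 'neither'")
    return(rep("neither", length(gene_density)))
  }
  dplyr::case_when(
    gene_density <= q[1] ~ "gene_poor",
    gene_density >= q[2] ~ "gene_rich",
    TRUE ~ "neither"
  )
}
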