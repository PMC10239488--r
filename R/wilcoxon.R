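#' Wilcoxon signed-rank test for paired differences
#'
#' Tests whether paired differences are symmetrically distributed around
#' zero. Zero differences are dropped before ranking; absolute differences
#' get average ranks. The statistic `W` is the sum of ranks of positive
#' differences. With no ties among absolute differences and `n <= 30` the
#' null distribution of `W` is enumerated exactly by dynamic programming
#' (convolution over rank inclusion, equivalent to enumerating all `2^n`
#' sign assignments); otherwise a normal approximation with continuity and
#' tie correction is used.
#'
#' For 25 differences that all share one sign with distinct magnitudes the
#' exact p-value is `1/2^25` one-sided and `2/2^25 ~= 5.96e-8` two-sided —
#' the resolution limit of the design.
#'
#' @param differences Numeric vector of paired differences.
#' @param alternative `"two_sided"`, `"less"` (differences tend negative)
#'   or `"greater"`.
#' @param method `"auto"` (exact when possible), `"exact"` or `"normal"`.
#' @return Object of class `signed_rank_test`: list with `statistic` (W),
#'   `p_value`, `n` (nonzero differences), `method` used, `alternative`,
#'   `ties` (logical). Supports [tidy()] and [glance()].
#' @export
#' @examples
#' wilcoxon_signed_rank(-(1:25), alternative = "two_sided")
wilcoxon_signed_rank <- function(differences,
                                 alternative = c("two_sided", "less", "greater"),
                                 method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("all differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  ties <- anyDuplicated(abs(d)) > 0L
  W <- sum(r[d > 0])
  if (method == "auto") {
    method <- if (!ties && n <= 30L) "exact" else "normal"
  }
  if (method == "exact" && ties) {
    abort("exact method unavailable with tied absolute differences; use method = 'normal'")
  }
  p <- if (method == "exact") {
    signed_rank_exact_p(W, n, alternative)
  } else {
    signed_rank_normal_p(W, r, alternative)
  }
  structure(
    list(statistic = W, p_value = p, n = n, method = method,
         alternative = alternative, ties = ties),
    class = "signed_rank_test"
  )
}

# Null counts of W = sum of included ranks over subsets of {1..n}:
# DP convolution, one pass per rank. Returns P(W <= w) and P(W >= w) exactly
# (in double precision; total mass 2^n).
signed_rank_exact_p <- function(W, n, alternative) {
  maxw <- n * (n + 1L) / 2L
  counts <- numeric(maxw + 1L)
  counts[1L] <- 1
  for (rk in seq_len(n)) {
    shifted <- c(numeric(rk), counts[seq_len(maxw + 1L - rk)])
    counts <- counts + shifted
  }
  total <- 2^n
  p_le <- sum(counts[seq_len(W + 1L)]) / total
  p_ge <- sum(counts[seq(W + 1L, maxw + 1L)]) / total
  switch(alternative,
    less = p_le,
    greater = p_ge,
    two_sided = min(1, 2 * min(p_le, p_ge))
  )
}

signed_rank_normal_p <- function(W, r, alternative) {
  n <- length(r)
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  sigma <- sqrt(sigma2)
  p_le <- pnorm((W - mu + 0.5) / sigma)
  p_ge <- pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
  switch(alternative,
    less = p_le,
    greater = p_ge,
    two_sided = min(1, 2 * min(p_le, p_ge))
  )
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat("Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  cat("  W = ", x$statistic, ", n = ", x$n, ", alternative = ",
      x$alternative, "\n  p-value = ", format(x$p_value, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.signed_rank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
         method = x$method, alternative = x$alternative, ties = x$ties)
}

#' @export
glance.signed_rank_test <- function(x, ...) tidy(x)

#' Wilcoxon rank-sum contrast between two groups of windows
#'
#' Two-sample Mann-Whitney / rank-sum test, used to contrast TE insertion
#' densities between gene-rich and gene-poor windows. Thin wrapper around
#' [stats::wilcox.test()] (exact for small samples without ties).
#'
#' @param x,y Numeric vectors (e.g. TE densities in gene-rich and gene-poor
#'   windows). Both must be non-empty.
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`.
#' @return One-row tibble: `statistic` (rank-sum U), `p_value`, `n_x`,
#'   `n_y`, `alternative`.
#' @export
compare_rich_poor <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = sub("_", ".", alternative)
  ))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n_x = length(x), n_y = length(y), alternative = alternative)
}
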