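# Coordinate conventions: everything internal is 0-based half-open [start, end).
# RepeatMasker .out / .align and GFF3 are 1-based inclusive; BED is already
# 0-based half-open. Conversion happens only at format boundaries.

to_internal_coords <- function(begin_1based, end_inclusive) {
  list(start = as.integer(begin_1based) - 1L, end = as.integer(end_inclusive))
}

to_external_coords <- function(start, end) {
  list(begin = as.integer(start) + 1L, end = as.integer(end))
}

# strip "(123)" -> 123L
unparen <- function(x) as.integer(gsub("[()]", "", x))

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive", name))
  }
  invisible(x)
}

# local RNG scope; seed = NULL leaves the caller's RNG stream untouched
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
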