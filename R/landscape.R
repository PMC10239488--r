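#' Merge annotation fragments into TE insertions
#'
#' RepeatMasker splits interrupted insertions into several fragments but
#' assigns them a shared identifier. Counting fragments would overestimate
#' insertion numbers, so fragments sharing an identifier are collapsed into
#' one insertion: total length is the sum of fragment lengths, the span is
#' the union of fragment intervals, class and family come from the longest
#' fragment (deterministic tie-break, conflicts logged), and divergence is
#' the length-weighted mean of per-fragment values
#' ([insertion_divergence()]).
#'
#' @param records Annotation tibble from [read_rmsk_out()].
#' @param divergence Optional numeric vector, one Kimura distance
#'   (proportion, not percent) per record, typically computed from `.align`
#'   blocks via [block_divergence()]. When `NULL` the `.out` `pct_div`
#'   column (raw mismatch percent, not a Kimura distance) is used instead,
#'   with a warning, and the result carries
#'   `attr(, "divergence_source") = "pct_div"`.
#' @param include_overlaps Keep rows flagged `*` (lower-scoring overlaps)?
#'   Default TRUE.
#' @return Tibble of class `te_insertions`, one row per insertion:
#'   `query_name`, `start`, `end` (span), `strand`, `total_bp`, `te_class`,
#'   `family`, `class_family`, `divergence` (proportion), `insertion_id`,
#'   `n_fragments`.
#' @export
merge_fragments <- function(records, divergence = NULL, include_overlaps = TRUE) {
  if (is.null(divergence)) {
    warn(paste("no per-fragment Kimura divergences supplied;",
               "falling back to the .out pct_div column (raw mismatch percent)"))
    divergence <- records$pct_div / 100
    src <- "pct_div"
  } else {
    if (length(divergence) != nrow(records)) {
      abort("`divergence` must have one value per record")
    }
    src <- "kimura"
  }
  records <- mutate(records, .div = divergence)
  if (!include_overlaps) records <- filter(records, !.data$overlap_flag)

  multi <- records |>
    dplyr::distinct(.data$insertion_id, .data$query_name) |>
    dplyr::count(.data$insertion_id) |>
    filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    abort(sprintf("insertion id %d has fragments on more than one query sequence",
                  multi$insertion_id[1]))
  }

  out <- records |>
    mutate(frag_len = .data$query_end - .data$query_begin) |>
    group_by(.data$query_name, .data$insertion_id) |>
    summarise(
      start = min(.data$query_begin),
      end = max(.data$query_end),
      strand = .data$strand[which.max(.data$frag_len)],
      total_bp = sum(.data$frag_len),
      class_family = .data$class_family[which.max(.data$frag_len)],
      family = .data$repeat_name[which.max(.data$frag_len)],
      divergence = insertion_divergence(.data$.div, .data$frag_len),
      n_fragments = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(te_class = classify_te_family(.data$class_family)) |>
    select("query_name", "start", "end", "strand", "total_bp", "te_class",
           "family", "class_family", "divergence", "insertion_id",
           "n_fragments") |>
    arrange(.data$query_name, .data$start)
  attr(out, "divergence_source") <- src
  class(out) <- c("te_insertions", class(out))
  out
}

#' Build a TE divergence landscape
#'
#' Bins merged insertions by divergence from consensus (percent, half-open
#' bins `[k, k+1)` over 0-50 plus an overflow bin) and accumulates base
#' pairs per (bin, TE class), expressed as percent of the assembly.
#'
#' @param insertions Tibble from [merge_fragments()].
#' @param denominator_bp Assembly length used as the percent denominator;
#'   conventionally the non-N length (see [read_genome_fasta()]).
#' @param bin_width Bin width in percent divergence (default 1).
#' @param assembly_name Optional label stored on the result.
#' @return Tibble of class `te_landscape` with columns `bin_lo`, `bin_hi`,
#'   `te_class`, `bp`, `percent`; attributes `denominator_bp` and
#'   `assembly_name`. The overflow bin has `bin_hi = Inf`.
#' @export
build_landscape <- function(insertions, denominator_bp, bin_width = 1,
                            assembly_name = NA_character_) {
  assert_scalar_number(denominator_bp, "denominator_bp", positive = TRUE)
  edges <- seq(0, 50, by = bin_width)
  div_pct <- insertions$divergence * 100
  over <- div_pct >= 50
  if (any(over)) {
    inform(sprintf("%d insertion(s) with divergence >= 50%% accumulated in the overflow bin",
                   sum(over)))
  }
  bin_lo <- ifelse(over, 50, edges[findInterval(pmin(div_pct, 50 - 1e-12), edges)])
  grid <- tidyr::expand_grid(
    bin_lo = c(edges[-length(edges)], 50),
    te_class = te_classes()
  )
  cells <- tibble(bin_lo = bin_lo, te_class = insertions$te_class,
                  bp = insertions$total_bp) |>
    group_by(.data$bin_lo, .data$te_class) |>
    summarise(bp = sum(.data$bp), .groups = "drop")
  out <- grid |>
    left_join(cells, by = c("bin_lo", "te_class")) |>
    mutate(
      bp = dplyr::coalesce(.data$bp, 0),
      bin_hi = ifelse(.data$bin_lo >= 50, Inf, .data$bin_lo + bin_width),
      percent = 100 * .data$bp / denominator_bp
    ) |>
    select("bin_lo", "bin_hi", "te_class", "bp", "percent") |>
    arrange(.data$bin_lo, .data$te_class)
  attr(out, "denominator_bp") <- denominator_bp
  attr(out, "assembly_name") <- assembly_name
  class(out) <- c("te_landscape", class(out))
  out
}

#' Summarise TE genome content by class
#'
#' Per-class occupied base pairs and genome percent, in the style of
#' per-genome TE content tables: DNA transposons, Helitrons, SINEs, LINEs,
#' LTRs and Unknown are reported separately, and `Other` (satellites,
#' simple repeats, ...) is listed but excluded from the total TE percent.
#'
#' @inheritParams build_landscape
#' @return Tibble of class `te_content` with columns `te_class`,
#'   `n_insertions`, `bp`, `percent`; use [glance()] for the total.
#' @export
summarize_content <- function(insertions, denominator_bp,
                              assembly_name = NA_character_) {
  assert_scalar_number(denominator_bp, "denominator_bp", positive = TRUE)
  out <- tibble(te_class = te_classes()) |>
    left_join(
      insertions |>
        group_by(.data$te_class) |>
        summarise(n_insertions = dplyr::n(), bp = sum(.data$total_bp),
                  .groups = "drop"),
      by = "te_class"
    ) |>
    mutate(
      n_insertions = dplyr::coalesce(.data$n_insertions, 0L),
      bp = dplyr::coalesce(.data$bp, 0),
      percent = 100 * .data$bp / denominator_bp
    )
  attr(out, "denominator_bp") <- denominator_bp
  attr(out, "assembly_name") <- assembly_name
  class(out) <- c("te_content", class(out))
  out
}

#' @export
glance.te_content <- function(x, ...) {
  te <- filter(as_tibble(x), .data$te_class != "Other")
  tibble(
    total_te_percent = sum(te$percent),
    total_te_bp = sum(te$bp),
    n_insertions = sum(te$n_insertions),
    denominator_bp = attr(x, "denominator_bp"),
    assembly_name = attr(x, "assembly_name")
  )
}

#' Export a landscape as TSV (and optionally a stacked-bar plot)
#'
#' The TSV is wide: one row per divergence bin, one column per TE class,
#' values in genome percent.
#'
#' @param landscape A `te_landscape` from [build_landscape()].
#' @param path TSV output path.
#' @param plot_path Optional image path (written with [ggplot2::ggsave()]).
#' @return `path`, invisibly.
#' @export
export_landscape <- function(landscape, path, plot_path = NULL) {
  wide <- as_tibble(landscape) |>
    select("bin_lo", "te_class", "percent") |>
    tidyr::pivot_wider(names_from = "te_class", values_from = "percent")
  readr::write_tsv(wide, path)
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, autoplot(landscape), width = 8, height = 4.5,
                    dpi = 150)
  }
  invisible(path)
}
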