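#' Read a RepeatMasker `.out` annotation table
#'
#' Parses the whitespace-delimited `.out` format (15 columns plus an optional
#' trailing `*` marking hits suppressed by a higher-scoring overlapping hit).
#' Query coordinates are converted from the file's 1-based inclusive
#' convention to the package-internal 0-based half-open convention; repeat
#' (consensus) coordinates are normalised so that `repeat_begin < repeat_end`
#' regardless of strand. RepeatMasker writes `C` for complement-strand hits;
#' these are reported as strand `"-"`.
#'
#' @param path Path to a `.out` file. The standard 3-line header is skipped
#'   if present; headerless files are accepted.
#' @return A tibble with one row per annotation fragment and columns
#'   `score`, `pct_div`, `pct_del`, `pct_ins`, `query_name`, `query_begin`,
#'   `query_end` (0-based half-open), `query_left`, `strand` (`+`/`-`),
#'   `repeat_name`, `class_family`, `repeat_begin`, `repeat_end`,
#'   `repeat_left`, `insertion_id`, `overlap_flag` (TRUE when the row was
#'   starred as a lower-scoring overlap).
#' @seealso [write_rmsk_out()], [read_rmsk_align()], [merge_fragments()]
#' @export
#' @examples
#' out <- tempfile(fileext = ".out")
#' writeLines(c(
#'   "   SW  perc perc perc  query     position in query",
#'   "score  div. del. ins.  sequence  begin end (left)",
#'   "",
#'   "463 1.3 0.6 1.7 chr1 1001 1500 (500) + L1MdA LINE/L1 1 500 (0) 7"
#' ), out)
#' read_rmsk_out(out)
read_rmsk_out <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  empty <- tibble(
    score = integer(), pct_div = double(), pct_del = double(),
    pct_ins = double(), query_name = character(), query_begin = integer(),
    query_end = integer(), query_left = integer(), strand = character(),
    repeat_name = character(), class_family = character(),
    repeat_begin = integer(), repeat_end = integer(), repeat_left = integer(),
    insertion_id = integer(), overlap_flag = logical()
  )
  is_data <- grepl("^\\s*\\d", lines)
  if (!any(is_data)) return(empty)
  data_idx <- which(is_data)
  rows <- map(data_idx, function(i) parse_out_row(lines[[i]], i))
  out <- bind_rows(rows)
  bad <- out$query_begin >= out$query_end
  if (any(bad)) {
    abort(sprintf("malformed .out row at line %d: begin >= end",
                  data_idx[which(bad)[1]]))
  }
  out
}

parse_out_row <- function(line, lineno) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) < 15L || length(f) > 16L) {
    abort(sprintf("malformed .out row at line %d: expected 15-16 fields, got %d",
                  lineno, length(f)))
  }
  strand_raw <- f[[9]]
  if (!strand_raw %in% c("+", "C")) {
    abort(sprintf("malformed .out row at line %d: bad strand '%s'",
                  lineno, strand_raw))
  }
  # consensus coordinates: "+" prints begin end (left); "C" prints (left) end begin
  if (strand_raw == "+") {
    rbegin <- suppressWarnings(as.integer(f[[12]]))
    rend <- suppressWarnings(as.integer(f[[13]]))
    rleft <- unparen(f[[14]])
  } else {
    rleft <- unparen(f[[12]])
    rend <- suppressWarnings(as.integer(f[[13]]))
    rbegin <- suppressWarnings(as.integer(f[[14]]))
  }
  qb <- suppressWarnings(as.integer(f[[6]]))
  qe <- suppressWarnings(as.integer(f[[7]]))
  id <- suppressWarnings(as.integer(f[[15]]))
  if (anyNA(c(qb, qe, rbegin, rend, rleft, id))) {
    abort(sprintf("malformed .out row at line %d: non-numeric coordinate field",
                  lineno))
  }
  tibble(
    score = as.integer(f[[1]]),
    pct_div = as.numeric(f[[2]]), pct_del = as.numeric(f[[3]]),
    pct_ins = as.numeric(f[[4]]),
    query_name = f[[5]],
    query_begin = qb - 1L, query_end = qe,
    query_left = unparen(f[[8]]),
    strand = if (strand_raw == "C") "-" else "+",
    repeat_name = f[[10]], class_family = f[[11]],
    repeat_begin = rbegin, repeat_end = rend, repeat_left = rleft,
    insertion_id = id,
    overlap_flag = length(f) == 16L && f[[16]] == "*"
  )
}

#' Write annotation records as a RepeatMasker `.out` file
#'
#' Inverse of [read_rmsk_out()]: internal 0-based half-open coordinates go
#' back to 1-based inclusive, strand `"-"` is written as `C`, and the
#' strand-dependent ordering of consensus coordinates is restored, so a
#' read/write round trip preserves every field.
#'
#' @param records Tibble as returned by [read_rmsk_out()].
#' @param path Output path.
#' @param header Write the standard 3-line header (default TRUE).
#' @return `path`, invisibly.
#' @export
write_rmsk_out <- function(records, path, header = TRUE) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end    (left)  repeat    class/family  begin end (left) ID",
    ""
  )
  body <- if (nrow(records) == 0) character() else
    map_chr(seq_len(nrow(records)), function(i) format_out_row(records[i, ]))
  writeLines(c(if (header) hdr, body), path)
  invisible(path)
}

format_out_row <- function(r) {
  ext <- to_external_coords(r$query_begin, r$query_end)
  if (r$strand == "+") {
    rc <- c(r$repeat_begin, r$repeat_end, sprintf("(%d)", r$repeat_left))
  } else {
    rc <- c(sprintf("(%d)", r$repeat_left), r$repeat_end, r$repeat_begin)
  }
  paste(
    r$score, sprintf("%.1f", r$pct_div), sprintf("%.1f", r$pct_del),
    sprintf("%.1f", r$pct_ins), r$query_name, ext$begin, ext$end,
    sprintf("(%d)", r$query_left), if (r$strand == "-") "C" else "+",
    r$repeat_name, r$class_family, rc[1], rc[2], rc[3], r$insertion_id,
    if (isTRUE(r$overlap_flag)) "*" else NULL
  )
}

#' Read a RepeatMasker-style `.align` alignment file
#'
#' Reads the alignment dialect emitted by [emit_annotation()]: each block is
#' a `.out`-style header row followed by indented, alternating
#' query/consensus sequence lines (wrapped at a fixed width, gap character
#' `-`, positions 1-based inclusive) and an optional
#' `Kimura (with divCpGMod) = x.xx` line giving the divergence RepeatMasker
#' itself reported for the block.
#'
#' @param path Path to a `.align` file.
#' @return A tibble with one row per block: `query_name`, `query_begin`,
#'   `query_end` (0-based half-open), `consensus_name`, `strand`,
#'   `insertion_id`, `aligned_query`, `aligned_consensus` (equal-length
#'   gapped strings, consensus orientation), and `kimura_reported`
#'   (percent; `NA` when the file carries no Kimura line).
#' @export
read_rmsk_align <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- which(grepl("^\\d", lines))
  blocks <- vector("list", length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (b in seq_along(hdr_idx)) {
    chunk <- lines[seq(bounds[b], bounds[b + 1L] - 1L)]
    blocks[[b]] <- parse_align_block(chunk, b)
  }
  bind_rows(blocks)
}

parse_align_block <- function(chunk, block_index) {
  hdr <- parse_out_row(chunk[[1]], 1L)
  seq_lines <- chunk[grepl("^\\s+\\S", chunk)]
  if (length(seq_lines) == 0L || length(seq_lines) %% 2L != 0L) {
    abort(sprintf("truncated alignment block %d: unpaired sequence lines",
                  block_index))
  }
  pull_seq <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) != 4L) {
      abort(sprintf("malformed sequence line in alignment block %d", block_index))
    }
    f[[3]]
  }
  qi <- seq(1L, length(seq_lines), by = 2L)
  aligned_query <- paste(map_chr(seq_lines[qi], pull_seq), collapse = "")
  aligned_consensus <- paste(map_chr(seq_lines[qi + 1L], pull_seq), collapse = "")
  if (nchar(aligned_query) != nchar(aligned_consensus)) {
    abort(sprintf("alignment block %d: query and consensus lengths differ",
                  block_index))
  }
  kim_line <- chunk[grepl("^Kimura", chunk)]
  kimura <- if (length(kim_line)) {
    as.numeric(sub(".*=\\s*", "", kim_line[[1]]))
  } else {
    NA_real_
  }
  tibble(
    query_name = hdr$query_name,
    query_begin = hdr$query_begin, query_end = hdr$query_end,
    consensus_name = hdr$repeat_name, strand = hdr$strand,
    insertion_id = hdr$insertion_id,
    aligned_query = aligned_query, aligned_consensus = aligned_consensus,
    kimura_reported = kimura
  )
}

#' Classify a RepeatMasker class/family string into a TE class
#'
#' The prefix before `/` decides the class. Rolling-circle elements
#' (`RC/Helitron`) are reported as their own `Helitron` class, separate from
#' cut-and-paste DNA transposons, matching the convention of per-genome TE
#' content tables. Satellites, simple repeats, low-complexity and other
#' non-TE annotation demote to `Other`, which content summaries exclude from
#' the TE total. Unrecognised labels also map to `Other` (repeat-library
#' labels vary across releases), so the function is total.
#'
#' @param class_family Character vector of class/family strings, e.g.
#'   `"LINE/L1"`, `"SINE/Alu"`, `"RC/Helitron"`.
#' @return Character vector over
#'   `{DNA, Helitron, SINE, LINE, LTR, Unknown, Other}`.
#' @export
#' @examples
#' classify_te_family(c("LINE/L1", "RC/Helitron", "Simple_repeat", "Unknown"))
classify_te_family <- function(class_family) {
  stopifnot(is.character(class_family), all(nzchar(class_family)))
  prefix <- toupper(sub("/.*$", "", class_family))
  dplyr::case_when(
    prefix == "DNA" ~ "DNA",
    prefix == "RC" ~ "Helitron",
    prefix == "SINE" ~ "SINE",
    prefix == "LINE" ~ "LINE",
    prefix == "LTR" ~ "LTR",
    prefix %in% c("UNKNOWN", "UNCLASSIFIED") ~ "Unknown",
    TRUE ~ "Other"
  )
}

te_classes <- function() c("DNA", "Helitron", "SINE", "LINE", "LTR", "Unknown", "Other")
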