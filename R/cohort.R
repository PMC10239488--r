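codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

back_translate <- function(aa_sequence) {
  tab <- codons_by_aa()
  aa <- strsplit(aa_sequence, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) abort(sprintf("cannot back-translate residue '%s'", a))
    sample(opts, 1L) # uniform synonymous codon choice
  }, character(1)), collapse = "")
}

random_peptide <- function(n) {
  paste(sample(setdiff(unique(Biostrings::GENETIC_CODE), "*"), n, replace = TRUE),
        collapse = "")
}

#' Construct a LINE locus with an intact or disrupted ORF
#'
#' Builds an ORF2-like reading frame — start codon, linkers, the
#' endonuclease reference peptide, then the reverse-transcriptase reference
#' peptide (EN before RT, as in LINE ORF2p) — back-translated with uniform
#' synonymous codons and embedded in random flanking sequence. Disruptions
#' break the element the way degenerate genomic copies are broken: `stop`
#' places a premature stop mid-RT, `frameshift` deletes one nucleotide
#' mid-RT, `deletion` removes the EN domain entirely.
#'
#' @param intact Build an unbroken ORF (TRUE) or apply `disruption`.
#' @param disruption One of `"stop"`, `"frameshift"`, `"deletion"`.
#' @param profiles Domain peptides ([load_domain_profiles()]).
#' @param flank Random flank length on each side (bp).
#' @param seed Optional seed.
#' @return List: `seq` (locus string), `orf_start`, `orf_end` (0-based
#'   half-open, stop codon included), `intact`, `disruption`.
#' @export
make_line_locus <- function(intact = TRUE,
                            disruption = c("stop", "frameshift", "deletion"),
                            profiles = load_domain_profiles(),
                            flank = 200, seed = NULL) {
  disruption <- if (intact) NA_character_ else match.arg(disruption)
  with_seed_if(seed, {
    en <- as.character(profiles[["EN"]])
    rt <- as.character(profiles[["RT"]])
    aa_orf <- paste0("M", random_peptide(20), en, random_peptide(30), rt,
                     random_peptide(10))
    nt <- paste0(back_translate(aa_orf), "TAA")
    if (!intact) {
      # midpoint of the RT segment, in nt within the ORF
      rt_aa_start <- 1L + 20L + nchar(en) + 30L
      mid_rt_nt <- (rt_aa_start + nchar(rt) %/% 2L) * 3L
      nt <- switch(disruption,
        stop = paste0(substr(nt, 1L, mid_rt_nt), "TAA",
                      substr(nt, mid_rt_nt + 4L, nchar(nt))),
        frameshift = paste0(substr(nt, 1L, mid_rt_nt),
                            substr(nt, mid_rt_nt + 2L, nchar(nt))),
        deletion = {
          en_nt_start <- (1L + 20L) * 3L # 0-based nt offset of EN
          en_nt_end <- en_nt_start + nchar(en) * 3L
          paste0(substr(nt, 1L, en_nt_start), substr(nt, en_nt_end + 1L, nchar(nt)))
        }
      )
    }
    locus <- paste0(random_dna(flank, 0.41), nt, random_dna(flank, 0.41))
    list(seq = locus, orf_start = flank, orf_end = flank + nchar(nt),
         intact = intact, disruption = disruption)
  })
}

#' Default cohort specification
#'
#' The bundled 10-species table augmented with recent-insertion rates that
#' reproduce the study's contrast: short-lived species accumulate recent
#' non-LTR insertions at roughly twice the per-Gb rate of long-lived ones
#' (9000 vs 4500 per Gb, the order of magnitude of published DI values),
#' plus a per-species recent-copy weight `w_recent` for full-sequence
#' simulation.
#'
#' @return [species_profiles()] with added columns `rate_recent` (expected
#'   recent non-LTR insertions per Gb) and `w_recent`.
#' @export
default_cohort_spec <- function() {
  species_profiles() |>
    mutate(
      rate_recent = ifelse(.data$lifespan_phenotype == "short_lived", 9000, 4500),
      w_recent = ifelse(.data$lifespan_phenotype == "short_lived", 0.4, 0.2)
    )
}

#' Simulate a multi-species cohort
#'
#' Generates per-species data whose recent non-LTR insertion load follows
#' the cohort specification, for testing the DI/pairing/signed-rank
#' pipeline end to end.
#'
#' Two fidelities: with `sequences = FALSE` (fast; the default) each
#' species gets a truth-level insertion table — recent and ancient non-LTR
#' counts drawn Poisson with mean `rate * assembly_size_gb`, divergences
#' from the usual recent/ancient mixture components — sufficient for DI and
#' the paired test. With `sequences = TRUE` each species gets a full
#' [simulate_genome()] bundle whose non-LTR families use the species'
#' `w_recent`, and (optionally) emitted `.out`/`.align` files under `dir`.
#'
#' @param cohort Tibble like [default_cohort_spec()]: columns `species`,
#'   `lifespan_years`, `assembly_size_gb`, and `rate_recent` (count mode)
#'   or `w_recent` (sequence mode). Needs >= 2 species.
#' @param base_config [sim_config()] used in sequence mode.
#' @param sequences Full-sequence simulation? Default FALSE.
#' @param dir If given (sequence mode), annotation files are emitted per
#'   species under this directory.
#' @param rate_ancient Expected ancient non-LTR insertions per Gb
#'   (count mode; default 3000).
#' @param seed Optional seed.
#' @return List of class `te_cohort`: `species` (the spec), `data` (named
#'   list per species: insertion tibble or `te_sim`), `paths` (annotation
#'   files, sequence mode with `dir`).
#' @export
make_cohort <- function(cohort = default_cohort_spec(),
                        base_config = sim_config(), sequences = FALSE,
                        dir = NULL, rate_ancient = 3000, seed = NULL) {
  if (nrow(cohort) < 2L) abort("a cohort needs at least 2 species")
  with_seed_if(seed, {
    data <- list()
    paths <- list()
    for (i in seq_len(nrow(cohort))) {
      sp <- cohort$species[i]
      if (!sequences) {
        gb <- cohort$assembly_size_gb[i]
        n_recent <- rpois(1L, cohort$rate_recent[i] * gb)
        n_ancient <- rpois(1L, rate_ancient * gb)
        recent <- c(rep(TRUE, n_recent), rep(FALSE, n_ancient))
        cfg <- base_config
        data[[sp]] <- tibble(
          te_class = sample(c("LINE", "SINE"), n_recent + n_ancient,
                            replace = TRUE),
          divergence = draw_divergence_pct(n_recent + n_ancient, recent, cfg) / 100,
          total_bp = 1L
        )
      } else {
        cfg <- base_config
        nonltr <- classify_te_family(cfg$families$class_family) %in% c("LINE", "SINE")
        cfg$families$w_recent[nonltr] <- cohort$w_recent[i]
        sim <- simulate_genome(cfg)
        data[[sp]] <- sim
        if (!is.null(dir)) {
          paths[[sp]] <- emit_annotation(sim, dir,
                                         basename = gsub("\\W+", "_", sp))
        }
      }
    }
    structure(list(species = cohort, data = data, paths = paths),
              class = "te_cohort")
  })
}

#' Per-species DI table for a simulated cohort
#'
#' Computes recent non-LTR DI per species from a [make_cohort()] result.
#' In count mode the insertion tables are filtered directly; in sequence
#' mode the truth insertion tables of each `te_sim` are used (run the
#' annotation round trip explicitly when testing the file pipeline).
#'
#' @param cohort_result A `te_cohort`.
#' @param max_div Divergence threshold (proportion, default 0.03).
#' @return Tibble: `species`, `n_recent`, `assembly_size_gb`, `di`.
#' @export
cohort_di <- function(cohort_result, max_div = 0.03) {
  sp <- cohort_result$species
  bind_rows(map(seq_len(nrow(sp)), function(i) {
    d <- cohort_result$data[[sp$species[i]]]
    ins <- if (inherits(d, "te_sim")) d$truth_insertions else d
    recent_di(ins, sp$assembly_size_gb[i], max_div = max_div) |>
      mutate(species = sp$species[i], .before = 1L)
  }))
}
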