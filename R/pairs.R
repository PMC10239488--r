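#' Bundled 10-species profile table
#'
#' The four rodents and six bats of the comparative design, with maximum
#' lifespans (years), adult body masses (g), assembly sizes (Gb) and
#' cancer/lifespan phenotype labels. The rodent and *M. molossus* lifespans
#' are the values printed in the study design; the remaining bat lifespans
#' and the body masses come from the AnAge longevity database
#' (`lifespan_source` records which). Assembly sizes are the published
#' per-genome values.
#'
#' @return Tibble with columns `species`, `common_name`, `order`,
#'   `lifespan_years`, `mass_g`, `assembly_size_gb`, `cancer_phenotype`,
#'   `lifespan_phenotype`, `lifespan_source`.
#' @export
#' @examples
#' species_profiles()
species_profiles <- function() {
  path <- system.file("extdata", "species_profiles.tsv", package = "retroscape")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Construct lifespan-contrast species pairs
#'
#' Returns every ordered pair (long-lived, short-lived) whose lifespan
#' ratio is at least `fold` (default two-fold, boundary included: "at
#' least"). Species may appear in many pairs; with the bundled 10-species
#' table this yields exactly 25 pairs. Output is sorted by
#' (long_species, short_species) for determinism.
#'
#' @param profiles Tibble with columns `species` and `lifespan_years`
#'   (e.g. [species_profiles()]).
#' @param fold Minimum lifespan ratio (default 2).
#' @return Tibble: `long_species`, `short_species`, `long_lifespan`,
#'   `short_lifespan`, `lifespan_ratio`.
#' @export
#' @examples
#' make_pairs(species_profiles())
make_pairs <- function(profiles, fold = 2) {
  if (nrow(profiles) < 2L) {
    return(tibble(long_species = character(), short_species = character(),
                  long_lifespan = double(), short_lifespan = double(),
                  lifespan_ratio = double()))
  }
  tidyr::expand_grid(
    long_species = profiles$species,
    short_species = profiles$species
  ) |>
    filter(.data$long_species != .data$short_species) |>
    left_join(
      select(profiles, long_species = "species", long_lifespan = "lifespan_years"),
      by = "long_species"
    ) |>
    left_join(
      select(profiles, short_species = "species", short_lifespan = "lifespan_years"),
      by = "short_species"
    ) |>
    mutate(lifespan_ratio = .data$long_lifespan / .data$short_lifespan) |>
    filter(.data$lifespan_ratio >= fold) |>
    arrange(.data$long_species, .data$short_species)
}

#' Paired DI contrast across lifespan pairs
#'
#' Joins a per-species DI table onto the lifespan pairs and runs the
#' signed-rank test on the differences `DI(long) - DI(short)`. Under the
#' hypothesis that long-lived species carry fewer recent insertions the
#' differences are negative, so `alternative = "less"` is the one-sided
#' test of interest; the two-sided alternative is also available. Note
#' that species recur across pairs, so the differences are not
#' independent — the test reproduces the published procedure and the
#' caveat is documented rather than corrected.
#'
#' @param di_table Tibble with columns `species` and `di`.
#' @param pairs Tibble from [make_pairs()].
#' @param alternative,method Passed to [wilcoxon_signed_rank()].
#' @return A `signed_rank_test` object with an added `pairs` element
#'   (the pair table with `di_long`, `di_short`, `difference`).
#' @export
pair_test <- function(di_table, pairs, alternative = "less", method = "auto") {
  joined <- pairs |>
    left_join(select(di_table, long_species = "species", di_long = "di"),
              by = "long_species") |>
    left_join(select(di_table, short_species = "species", di_short = "di"),
              by = "short_species") |>
    mutate(difference = .data$di_long - .data$di_short)
  if (anyNA(joined$difference)) {
    abort("di_table is missing a species present in `pairs`")
  }
  res <- wilcoxon_signed_rank(joined$difference, alternative = alternative,
                              method = method)
  res$pairs <- joined
  res
}
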