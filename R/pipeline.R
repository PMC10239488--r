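#' Read a species metadata table
#'
#' TSV with at least `species`, `lifespan_years`, `assembly_size_gb`;
#' extra columns (mass, phenotype labels) pass through.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_species_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("species", "lifespan_years", "assembly_size_gb")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(sprintf("species table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(tbl$lifespan_years <= 0) || any(tbl$assembly_size_gb <= 0)) {
    abort("lifespans and assembly sizes must be positive")
  }
  tbl
}

default_run_config <- function() {
  list(
    max_div = 0.03, pair_fold = 2, window_size = 1e6,
    quantiles = c(0.25, 0.75), orf_min_aa = 300,
    domain_coverage = 0.9, domain_similarity = 0.5,
    cpg_mode = "include", alternative = "less", plots = TRUE
  )
}

#' Run the full comparative TE analysis pipeline
#'
#' Orchestrates every stage over a multi-species input set: annotation
#' parsing, Kimura divergence (from `.align` when available, else the
#' `.out` mismatch column), fragment merging, landscape and content
#' summaries, recent non-LTR DI, lifespan pairing with the signed-rank
#' test, windowed TE/gene-feature densities with Spearman correlations and
#' the gene-rich/gene-poor rank-sum contrast, and the LINE ORF screen.
#' Writes one TSV per report into `out_dir` (plus stacked-bar landscape
#' images when `plots` is enabled and a graphics device is available);
#' every file carries the configuration hash as a comment line, and reruns
#' of one config are deterministic.
#'
#' @param config A list or path to a YAML file with entries: `out_dir`,
#'   `species_table` (path or tibble), `species` (list of per-species
#'   entries: `name`, `out`, optional `align`, `genome`, `genes`), plus
#'   optional threshold overrides `max_div`, `pair_fold`, `window_size`,
#'   `quantiles`, `orf_min_aa`, `domain_coverage`, `domain_similarity`,
#'   `cpg_mode`, `alternative`, `plots`.
#' @return (Invisibly) a list with elements `content`, `landscapes`, `di`,
#'   `pair_test`, `windows`, `correlations`, `rich_poor`, `orf_screen`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$out_dir)) abort("config must name an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])

  species_tbl <- if (is.character(cfg$species_table)) {
    read_species_table(cfg$species_table)
  } else {
    as_tibble(cfg$species_table)
  }

  landscapes <- list()
  content_rows <- list()
  di_rows <- list()
  window_rows <- list()
  corr_rows <- list()
  richpoor_rows <- list()
  orf_rows <- list()

  for (sp in cfg$species) {
    name <- sp$name
    inform(sprintf("[%s] parsing annotation", name))
    records <- read_rmsk_out(sp$out)
    divergence <- NULL
    if (!is.null(sp$align)) {
      blocks <- read_rmsk_align(sp$align) |>
        block_divergence(cpg_mode = cfg$cpg_mode)
      # .align blocks and .out rows are matched by insertion id + interval
      key <- paste(records$insertion_id, records$query_begin)
      bkey <- paste(blocks$insertion_id, blocks$query_begin)
      divergence <- blocks$K[match(key, bkey)]
      if (anyNA(divergence)) {
        abort(sprintf("[%s] %d .out rows lack a matching .align block",
                      name, sum(is.na(divergence))))
      }
    }
    insertions <- if (is.null(divergence)) {
      merge_fragments(records)
    } else {
      merge_fragments(records, divergence = divergence)
    }

    sp_meta <- filter(species_tbl, .data$species == name)
    if (nrow(sp_meta) != 1L) {
      abort(sprintf("species '%s' not found (exactly once) in species table", name))
    }
    genome <- NULL
    if (!is.null(sp$genome)) genome <- read_genome_fasta(sp$genome)
    denominator <- if (!is.null(genome)) {
      sum(genome$info$non_n_length)
    } else {
      sp_meta$assembly_size_gb * 1e9
    }

    land <- build_landscape(insertions, denominator, assembly_name = name)
    landscapes[[name]] <- land
    plot_path <- NULL
    if (isTRUE(cfg$plots) && capabilities("png")) {
      plot_path <- file.path(cfg$out_dir, sprintf("landscape_%s.png", name))
    }
    tsv <- file.path(cfg$out_dir, sprintf("landscape_%s.tsv", name))
    tryCatch(export_landscape(land, tsv, plot_path),
             error = function(e) {
               warn(sprintf("[%s] landscape image failed: %s", name, conditionMessage(e)))
               export_landscape(land, tsv, NULL)
             })

    content_rows[[name]] <- summarize_content(insertions, denominator) |>
      as_tibble() |>
      mutate(species = name, .before = 1L)
    di_rows[[name]] <- recent_di(insertions, sp_meta$assembly_size_gb,
                                 max_div = cfg$max_div) |>
      mutate(species = name, .before = 1L)

    chrom_lengths <- if (!is.null(genome)) {
      setNames(genome$info$length, genome$info$seq_name)
    } else {
      warn(sprintf("[%s] no genome given; window track spans the rightmost insertion", name))
      vapply(split(insertions$end, insertions$query_name), max, numeric(1))
    }
    recent <- select_recent(insertions, max_div = cfg$max_div)
    track <- window_density(recent, chrom_lengths, cfg$window_size)
    window_rows[[name]] <- mutate(glance(track), species = name, .before = 1L)

    if (!is.null(sp$genes)) {
      feats <- read_gene_features(sp$genes, chrom_lengths = chrom_lengths)
      track_f <- feature_density(feats, track)
      corr_rows[[name]] <- bind_rows(map(
        c("gene", "exon", "intron", "intergenic"),
        function(f) {
          dens <- track_f[[paste0(f, "_density")]]
          if (length(unique(dens)) == 1L || length(unique(track_f$density)) == 1L) {
            return(tibble(species = name, feature = f, rho = NA_real_,
                          p_value = NA_real_, n = nrow(track_f)))
          }
          spearman_corr(track_f$density, dens) |>
            mutate(species = name, feature = f, .before = 1L) |>
            select("species", "feature", "rho", "p_value", "n")
        }
      ))
      labels <- if (nrow(track_f) >= 4L) {
        classify_windows(track_f$gene_density, probs = cfg$quantiles)
      } else {
        warn(sprintf("[%s] fewer than 4 windows; skipping gene-rich/poor contrast", name))
        rep("neither", nrow(track_f))
      }
      rich <- track_f$density[labels == "gene_rich"]
      poor <- track_f$density[labels == "gene_poor"]
      richpoor_rows[[name]] <- if (length(rich) && length(poor)) {
        compare_rich_poor(rich, poor) |>
          mutate(species = name, .before = 1L)
      } else {
        tibble(species = name, statistic = NA_real_, p_value = NA_real_,
               n_x = length(rich), n_y = length(poor),
               alternative = "two_sided")
      }
    }

    if (!is.null(genome)) {
      lines <- filter(insertions, .data$te_class == "LINE")
      if (nrow(lines)) {
        scr <- screen_lines(genome, lines, min_aa = cfg$orf_min_aa,
                            min_coverage = cfg$domain_coverage,
                            min_similarity = cfg$domain_similarity)
        orf_rows[[name]] <- mutate(as_tibble(scr), species = name, .before = 1L)
      }
    }
  }

  di_tbl <- bind_rows(di_rows) |>
    left_join(select(species_tbl, "species", "lifespan_years"), by = "species")
  pairs <- make_pairs(rename_lifespan(species_tbl), fold = cfg$pair_fold)
  test <- pair_test(di_tbl, pairs, alternative = cfg$alternative)

  write_report <- function(tbl, file) {
    path <- file.path(cfg$out_dir, file)
    writeLines(sprintf("# config_hash: %s", hash), path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
    path
  }
  write_report(bind_rows(content_rows), "content.tsv")
  write_report(di_tbl, "di.tsv")
  write_report(
    tidy(test) |> mutate(n_pairs = nrow(pairs)),
    "pair_test.tsv"
  )
  write_report(bind_rows(window_rows), "window_density.tsv")
  write_report(
    if (length(corr_rows)) bind_rows(corr_rows) else
      tibble(species = character(), feature = character(), rho = double(),
             p_value = double(), n = integer()),
    "window_correlations.tsv"
  )
  write_report(
    if (length(richpoor_rows)) bind_rows(richpoor_rows) else
      tibble(species = character(), statistic = double(), p_value = double(),
             n_x = integer(), n_y = integer(), alternative = character()),
    "rich_poor.tsv"
  )
  write_report(
    if (length(orf_rows)) bind_rows(orf_rows) else
      tibble(species = character(), locus = character(), frame = integer(),
             aa_length = integer(), rt_coverage = double(),
             rt_similarity = double(), en_coverage = double(),
             en_similarity = double(), intact = logical()),
    "orf_screen.tsv"
  )

  invisible(list(
    content = bind_rows(content_rows), landscapes = landscapes, di = di_tbl,
    pair_test = test, windows = bind_rows(window_rows),
    correlations = if (length(corr_rows)) bind_rows(corr_rows) else NULL,
    rich_poor = if (length(richpoor_rows)) bind_rows(richpoor_rows) else NULL,
    orf_screen = if (length(orf_rows)) bind_rows(orf_rows) else NULL,
    config_hash = hash
  ))
}

rename_lifespan <- function(species_tbl) {
  select(species_tbl, "species", "lifespan_years")
}
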