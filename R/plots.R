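te_class_palette <- function() {
  c(DNA = "#3b6fb6", Helitron = "#7bc043", SINE = "#f2a104", LINE = "#1b9e77",
    LTR = "#d95f02", Unknown = "#999999", Other = "#d3d3d3")
}

#' Stacked-bar divergence landscape plot
#'
#' Genome percent (y) per divergence bin (x), stacked by TE class — the
#' conventional repeat-landscape view: recent activity piles up at low
#' divergence, ancient accumulation at high divergence.
#'
#' @param object A `te_landscape` from [build_landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_landscape <- function(object, ...) {
  dat <- as_tibble(object) |>
    filter(is.finite(.data$bin_hi)) |>
    mutate(te_class = factor(.data$te_class, levels = names(te_class_palette())))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_lo + 0.5, y = .data$percent,
                                    fill = .data$te_class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = te_class_palette(), name = "TE class") +
    ggplot2::labs(
      x = "Kimura divergence from consensus (%)",
      y = "Genome (%)",
      title = attr(object, "assembly_name")
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of per-species density of insertion
#'
#' Species ordered by increasing lifespan, coloured by phenotype, the
#' standard view of the recent non-LTR insertion density contrast.
#'
#' @param di_table Tibble with columns `species`, `di`, and optionally
#'   `lifespan_years` and `lifespan_phenotype`.
#' @return A ggplot object.
#' @export
plot_di <- function(di_table) {
  dat <- di_table
  if (!is.null(dat$lifespan_years)) {
    dat <- arrange(dat, .data$lifespan_years)
  }
  dat <- mutate(dat, species = factor(.data$species, levels = .data$species))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$species, y = .data$di))
  p <- if (is.null(dat$lifespan_phenotype)) {
    p + ggplot2::geom_col(fill = "#1b9e77")
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$lifespan_phenotype)) +
      ggplot2::scale_fill_manual(
        values = c(short_lived = "#d7301f", long_lived = "#1b9e77"),
        name = "phenotype"
      )
  }
  p + ggplot2::labs(x = NULL, y = "Recent non-LTR insertions per Gb") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Windowed density track plot
#'
#' @param object A `window_track` from [window_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_track <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Insertions per Mb") +
    ggplot2::theme_minimal()
}
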