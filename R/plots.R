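#' Dot plot of core-defensome prevalence per domain
#'
#' Circle size and colour scale with the fraction of genomes encoding each
#' system, the standard presentation for cross-domain prevalence surveys.
#'
#' @param cohort Cohort tibble from [summarize_cohort()].
#' @param k Systems per domain fed to [core_defensome()].
#' @return A ggplot object.
#' @export
plot_core_defensome <- function(cohort, k = 20L) {
  core <- core_defensome(cohort, k = k)
  prev <- system_prevalence(cohort) |>
    dplyr::filter(.data$system_name %in% core$union)
  ggplot2::ggplot(prev, ggplot2::aes(
    x = .data$domain,
    y = stats::reorder(.data$system_name, .data$prevalence),
    size = .data$prevalence, colour = .data$prevalence
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.0f", 100 * .data$prevalence)),
      size = 2.6, colour = "black", nudge_x = 0.25
    ) +
    ggplot2::scale_size_area(max_size = 8, labels = scales_percent) +
    ggplot2::scale_colour_viridis_c(labels = scales_percent) +
    ggplot2::labs(
      x = NULL, y = NULL, size = "Prevalence", colour = "Prevalence",
      title = "Core defensome prevalence by domain"
    ) +
    ggplot2::theme_minimal()
}

scales_percent <- function(x) paste0(round(100 * x), "%")

#' Bar chart of phylum prevalence contrasts
#'
#' Bars show per-phylum prevalence with confidence intervals; the dashed
#' line is the overall (unweighted) mean prevalence on the response scale,
#' and fill marks phyla significantly over- or under-represented after FDR
#' adjustment.
#'
#' @param contrasts A `prevalence_contrasts` tibble from
#'   [phylum_contrasts()].
#' @param system Optional system name used in the title.
#' @return A ggplot object.
#' @export
plot_prevalence_contrasts <- function(contrasts, system = NULL) {
  overall <- plogis(mean(qlogis(pmin(pmax(contrasts$estimate, 1e-12), 1 - 1e-12))))
  ggplot2::ggplot(contrasts, ggplot2::aes(
    x = stats::reorder(.data$phylum, .data$estimate),
    y = .data$estimate, fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = overall, linetype = "dashed", colour = "red") +
    ggplot2::scale_fill_manual(values = c(
      over = "#08519c", under = "#9ecae1", ns = "grey70"
    )) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Prevalence",
      title = if (is.null(system)) "Phylum prevalence vs overall mean" else {
        sprintf("%s: phylum prevalence vs overall mean", system)
      }
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_prevalence_contrasts
#' @param object A `prevalence_contrasts` tibble.
#' @param ... Passed to [plot_prevalence_contrasts()].
#' @export
autoplot.prevalence_contrasts <- function(object, ...) {
  plot_prevalence_contrasts(object, ...)
}

#' Defense abundance across thermal categories
#'
#' Violin/box plot of per-genome defense counts by OGT bin (see
#' [bin_ogt()]).
#'
#' @param cohort Cohort tibble with `ogt_c` and `total_systems`.
#' @return A ggplot object.
#' @export
plot_ogt_abundance <- function(cohort) {
  dat <- dplyr::mutate(cohort, ogt_bin = bin_ogt(.data$ogt_c))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$ogt_bin, y = .data$total_systems, fill = .data$ogt_bin
  )) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::labs(
      x = "Thermal category", y = "Defense systems per genome",
      title = "Defense abundance by growth temperature"
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
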