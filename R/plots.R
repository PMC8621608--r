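#' Plot dye-swap log2 ratios along a chromosome
#'
#' The classic aberration-track view: one point per probe and hybridisation,
#' optionally overlaying called intervals as horizontal segments at the
#' expected deletion/duplication levels.
#'
#' @param signals Signal tibble for one mouse (`probe_id`, `log2_a`,
#'   `log2_b`).
#' @param probe_map Probe map supplying coordinates.
#' @param chrom Chromosome to show.
#' @param xlim Optional bp range.
#' @param calls Optional call tibble (`chrom`, `start`, `end`, `kind`).
#' @return A ggplot object.
#' @export
plot_signal_track <- function(signals, probe_map, chrom, xlim = NULL,
                              calls = NULL) {
  d <- signals %>%
    inner_join(probe_map, by = "probe_id") %>%
    filter(.data$chrom == .env$chrom) %>%
    tidyr::pivot_longer(c("log2_a", "log2_b"),
                        names_to = "experiment", values_to = "log2_ratio") %>%
    mutate(experiment = if_else(.data$experiment == "log2_a",
                                "hybridisation A", "hybridisation B"))
  if (!is.null(xlim)) d <- filter(d, .data$pos >= xlim[1], .data$pos <= xlim[2])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$log2_ratio,
                                       colour = .data$experiment)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = paste0(chrom, " position (bp)"), y = "log2 ratio",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    cc <- filter(calls, .data$chrom == .env$chrom)
    if (nrow(cc) > 0) {
      cc <- mutate(cc, level = if_else(.data$kind == "deletion", -1, log2(1.5)))
      p <- p + ggplot2::geom_segment(
        data = cc,
        ggplot2::aes(x = .data$start, xend = .data$end,
                     y = .data$level, yend = .data$level),
        inherit.aes = FALSE, linewidth = 1.2, colour = "black")
    }
  }
  p
}

#' Histogram of CNV sizes on a log10 axis
#'
#' @param calls Call tibble with `size` and `kind`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(calls, bins = 20) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$size, fill = .data$kind)) +
    ggplot2::geom_histogram(bins = bins, position = "stack") +
    ggplot2::scale_x_log10(labels = scales_comma) +
    ggplot2::labs(x = "CNV size (bp)", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Genes per CNV against CNV size
#'
#' @param calls Call tibble with `size` and `gene_count` (see
#'   [annotate_genes()]).
#' @return A ggplot object.
#' @export
plot_gene_counts <- function(calls) {
  stopifnot("gene_count" %in% names(calls))
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$size, y = .data$gene_count)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10(labels = scales_comma) +
    ggplot2::labs(x = "CNV size (bp)", y = "genes overlapped") +
    ggplot2::theme_minimal()
}

scales_comma <- function(x) format(x, big.mark = ",", scientific = FALSE, trim = TRUE)

#' @rdname fit_standard_curve
#' @param object A `qpcr_curve`.
#' @export
autoplot.qpcr_curve <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("ct", "log10_mass")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_mass, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "log10 input mass (ng)", y = "Ct",
                  title = sprintf("slope %.3f, efficiency %.2f",
                                  object$slope, object$efficiency)) +
    ggplot2::theme_minimal()
}

#' @rdname cox_lifespan_fit
#' @param object A `cnv_coxfit`.
#' @export
autoplot.cnv_coxfit <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(lo = exp(.data$log_hr - 1.96 * .data$std_error),
           hi = exp(.data$log_hr + 1.96 * .data$std_error))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hazard_ratio, y = .data$factor)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
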