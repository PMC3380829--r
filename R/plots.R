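#' Plot a pipeline run
#'
#' ChIP versus input counts per cluster on log10 axes, colored by
#' classification, with reference lines at enrichment 1 and at the
#' configured selection threshold.
#'
#' @param object A `censat_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.censat_run <- function(object, ...) {
  rep <- object$report
  c_tot <- object$qc$chip$n_kept
  i_tot <- object$qc$input$n_kept
  df <- dplyr::mutate(rep,
                      chip_frac = pmax(.data$chip_count, 0.5) / c_tot,
                      input_frac = pmax(.data$input_count, 0.5) / i_tot)
  thr <- object$config$enrichment_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$input_frac,
                                   y = .data$chip_frac,
                                   colour = .data$classification,
                                   size = .data$genome_proportion_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = log10(thr),
                         linetype = "dotted", colour = "grey30") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "input read fraction", y = "ChIP read fraction",
                  colour = "classification", size = "genome %",
                  title = sprintf("Approach %s cluster enrichment",
                                  object$approach),
                  subtitle = sprintf(
                    "dotted line: %g-fold enrichment threshold", thr))
}

#' Plot an enrichment distribution
#'
#' Histogram of per-unit enrichment over log-spaced bins, with vertical
#' reference lines at enrichment 1 and 10.
#'
#' @param object A `censat_enrichment_summary` from [enrichment_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.censat_enrichment_summary <- function(object, ...) {
  h <- object$histogram
  finite <- h$bin_low > 0 & is.finite(h$bin_high)
  df <- h[finite, ]
  df$mid <- sqrt(df$bin_low * df$bin_high)
  extras <- tibble::tibble(
    label = c("0", "Inf"),
    n = c(h$n[h$bin_low == 0], h$n[is.infinite(h$bin_high)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$n)) +
    ggplot2::geom_col(width = 0.2, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = c(1, 10), linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "enrichment (log scale)", y = "units",
                  title = "Enrichment distribution",
                  subtitle = sprintf(
                    "%d units; %d at E = 0, %d at E = Inf; %.1f%% depleted",
                    object$n_units, extras$n[1], extras$n[2],
                    100 * object$frac_depleted))
}

#' Plot a dot-plot comparison
#'
#' Window-match dot plot from [dotplot()]; forward-strand matches in blue,
#' reverse in red, faceted by sequence pair when more than one pair is
#' present.
#'
#' @param object A `censat_dotplot` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.censat_dotplot <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos_a,
                                            y = .data$pos_b,
                                            colour = .data$strand)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c(`+` = "steelblue",
                                            `-` = "firebrick")) +
    ggplot2::labs(x = "position", y = "position",
                  title = sprintf(
                    "Dot plot (window %d, identity >= %.0f%%)",
                    attr(object, "window"),
                    100 * attr(object, "min_identity")))
  if (length(unique(paste(object$seq_a, object$seq_b))) > 1) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$seq_b), cols = ggplot2::vars(.data$seq_a),
      scales = "free")
  }
  p
}

#' Plot per-cluster enrichment as a ranked bar chart
#'
#' @param run A `censat_run`.
#' @param top_n Number of clusters to show (default 30).
#' @return A ggplot object.
#' @export
plot_enrichment_ranking <- function(run, top_n = 30) {
  df <- run$report |>
    dplyr::filter(is.finite(.data$enrichment)) |>
    dplyr::slice_head(n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$family_id, .data$enrichment),
    y = .data$enrichment, fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = run$config$enrichment_threshold,
                        linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "enrichment",
                  title = "Cluster enrichment ranking")
}
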