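#' Plot read depth around a candidate loss
#'
#' Diagnostic scatter of per-base depth across a candidate region and its
#' flanks: depth as purple dots, the reported loss boundaries as orange
#' vertical lines, array probe positions as pink dashed lines. A genuine
#' loss shows as a concave dip between the boundary lines.
#'
#' @param profile A `depth_profile` tibble covering at least the plotted
#'   window.
#' @param start,end Reported loss boundaries (0-based half-open).
#' @param probes Optional [probe_map()] tibble; probes inside the window are
#'   drawn.
#' @param window_factor Half-window drawn on each side of the call, as a
#'   multiple of the call length (default 1).
#' @param thin Plot every `thin`-th base to keep large windows light
#'   (default 1 = all bases).
#' @return A ggplot object.
#' @export
plot_depth_region <- function(profile, start, end, probes = NULL,
                              window_factor = 1, thin = 1) {
  L <- end - start
  lo <- max(profile$pos[1], start - round(window_factor * L))
  hi <- min(profile$pos[nrow(profile)] + 1, end + round(window_factor * L))
  df <- profile[profile$pos >= lo & profile$pos < hi, , drop = FALSE]
  if (thin > 1) df <- df[seq(1, nrow(df), by = thin), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_point(colour = "purple", size = 0.6, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(start, end), colour = "orange",
                        linewidth = 0.8) +
    ggplot2::labs(x = sprintf("position on %s", df$chrom[1] %||% ""),
                  y = "read depth") +
    ggplot2::coord_cartesian(xlim = c(lo, hi)) +
    ggplot2::theme_minimal()
  if (!is.null(probes)) {
    pp <- probes$pos[probes$pos >= lo & probes$pos < hi &
                       probes$chrom == (df$chrom[1] %||% probes$chrom[1])]
    if (length(pp) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = pp, colour = "pink",
                                   linetype = "dashed", linewidth = 0.4)
    }
  }
  p
}

#' @rdname plot_depth_region
#' @param out_path File to render the plot into (extension decides the
#'   device).
#' @param ... Passed to [plot_depth_region()].
#' @return `depth_plot()` returns `out_path` invisibly.
#' @export
depth_plot <- function(profile, start, end, out_path, ...) {
  p <- plot_depth_region(profile, start, end, ...)
  ggplot2::ggsave(out_path, p, width = 7, height = 3.5, dpi = 120)
  invisible(out_path)
}

#' Plot breakpoint evidence proportions
#'
#' The three-way evidence split of a validation run (direct break reads,
#' paired-end only, unsupported) as a pie chart.
#'
#' @param summary Output of [summarize_evidence()].
#' @return A ggplot object.
#' @export
plot_evidence_summary <- function(summary) {
  df <- tidyr::pivot_longer(
    summary[, c("break_read", "paired_end", "unsupported")],
    cols = dplyr::everything(), names_to = "evidence", values_to = "prop")
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$prop, fill = .data$evidence)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::scale_fill_manual(values = c(break_read = "#4daf4a",
                                          paired_end = "#377eb8",
                                          unsupported = "#e41a1c")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "evidence") +
    ggplot2::theme_void()
}
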