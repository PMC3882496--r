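#' Plot a metagene profile
#'
#' @param object A `meta_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position relative to TSS (bp)", y = "mean signal",
                  subtitle = sprintf("%d regions", object$n_regions[1])) +
    ggplot2::theme_minimal()
}

#' Plot a binned promoter signal heatmap
#'
#' Rows (anchors) are ordered by the upstream antisense score, mirroring the
#' usual divergent-transcription heatmap layout.
#'
#' @param object A `binned_signal`.
#' @param channel `"antisense"` (default) or `"sense"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binned_signal <- function(object,
                                   channel = c("antisense", "sense"), ...) {
  channel <- match.arg(channel)
  score <- antisense_score(object)
  ord <- order(score$antisense_score)
  df <- tidy(object) |> dplyr::filter(.data$channel == !!channel)
  df$region_id <- factor(df$region_id, levels = score$region_id[ord])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$region_id,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$transform) +
    ggplot2::labs(x = "position relative to TSS (bp)", y = NULL,
                  title = paste(channel, "signal")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Histogram of LUAT 5' offsets relative to the gene TSS
#'
#' @param calls Call tibble with a `luat_offset` column (from
#'   [assemble_luats()] or [scan_luats()]).
#' @param binwidth Histogram bin width in bp (default 100).
#' @return A ggplot.
#' @export
plot_offset_histogram <- function(calls, binwidth = 100) {
  df <- dplyr::filter(as_tibble(calls), !is.na(.data$luat_offset))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$luat_offset)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "LUAT 5' end relative to gene TSS (bp)", y = "LUATs") +
    ggplot2::theme_minimal()
}

#' Plot a splice-site accumulation curve
#' @param object An `accumulation_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accumulation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "nucleotides traversed from the TSS",
                  y = "fraction of genes with a site") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
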