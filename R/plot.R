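#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a threshold-sweep curve
#'
#' Cross- and self-mapping frequency against the identity threshold, one
#' line per direction, log-scaled y axis with the spurious-match tolerance
#' marked.
#'
#' @param object A `genopair_sweep` tibble from [threshold_sweep()].
#' @param max_spurious Horizontal reference line (default 0.01).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.genopair_sweep <- function(object, max_spurious = 0.01, ...) {
  df <- tibble::as_tibble(object)
  df$direction <- paste(df$source, "→", df$target)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$frequency,
                                   colour = .data$direction,
                                   linetype = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = max_spurious, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "identity threshold (%)", y = "mapping frequency",
                  colour = "direction", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot recruitment counts
#'
#' @param object A `genopair_recruitment` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.genopair_recruitment <- function(object, ...) {
  df <- dplyr::bind_rows(
    object$counts,
    tibble::tibble(reference = "unmapped", n_mapped = object$n_unmapped))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$n_mapped)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "reads",
                  title = sprintf("recruitment at %s%% identity",
                                  format(object$threshold))) +
    ggplot2::theme_minimal()
}

#' Histogram of reciprocal best-hit identities
#'
#' The distribution of per-gene-pair percent identities (2%-wide bins),
#' with the pair's ANI marked — the conventional view of how conserved a
#' genome pair is.
#'
#' @param rbh Reciprocal-pair tibble from [reciprocal_best_hits()].
#' @param ani Optional ANI to mark with a vertical line.
#' @param binwidth Bin width in identity points.
#' @return A ggplot object.
#' @export
plot_identity_histogram <- function(rbh, ani = NULL, binwidth = 2) {
  p <- ggplot2::ggplot(rbh, ggplot2::aes(x = .data$identity_ab)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "percent identity", y = "gene pairs") +
    ggplot2::theme_minimal()
  if (!is.null(ani))
    p <- p + ggplot2::geom_vline(xintercept = ani, colour = "red",
                                 linetype = "dashed")
  p
}
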