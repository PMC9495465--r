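#' Plot an rSNP call table
#'
#' Lollipop chart of the functional impact factor per (rSNP, TF) pair,
#' faceted by gene and coloured by call category. The dashed lines mark the
#' |FIF| = 10 reporting gate.
#'
#' @param object An `rsnp_calls` tibble.
#' @param fif_threshold Gate drawn as reference lines (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(fd_rsnp_calls())
#' @export
autoplot.rsnp_calls <- function(object, fif_threshold = 10, ...) {
  df <- as_tibble(object)
  df$label <- paste(df$rsid, df$tf, df$cell_line, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fif,
                                   y = stats::reorder(.data$label, .data$fif),
                                   colour = .data$category)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$fif,
                                       yend = stats::reorder(.data$label,
                                                             .data$fif)),
                          linewidth = 0.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = c(-fif_threshold, fif_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$gene),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "Functional impact factor (FIF)", y = NULL,
                  colour = "Category") +
    ggplot2::theme_minimal()
}

#' Plot a position weight matrix
#'
#' Heat map of the log2-odds weights by motif column and base — a quick
#' visual check of motif sharpness and of which columns dominate the
#' achievable score range.
#'
#' @param object A `pwm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pwm <- function(object, ...) {
  df <- as_tibble(as.data.frame(as.table(object$weights)),
                  .name_repair = "minimal")
  names(df) <- c("base", "column", "weight")
  df$column <- as.integer(df$column)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$base,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(title = paste(object$matrix_id, object$tf_name),
                  x = "Motif column", y = NULL, fill = "log2 odds") +
    ggplot2::theme_minimal()
}
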