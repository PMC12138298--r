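# ggplot2 views of the extracted measurement table.

#' Plot a measurement table
#'
#' Region rows become a tissue-volume bar panel per body site and mode; organ
#' rows a ranked bar chart of the largest structures.
#'
#' @param object A `boa_measurements` tibble from [extract_measurements()].
#' @param kind `"region"` (tissue volumes) or `"organ"` (top organ volumes).
#' @param top_n Number of organ rows shown when `kind = "organ"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot boa_measurements
#' @export
autoplot.boa_measurements <- function(object, kind = c("region", "organ"),
                                      top_n = 20, ...) {
  kind <- match.arg(kind)
  if (kind == "region") {
    df <- object[object$kind == "region-tissue", , drop = FALSE]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$volume_ml,
                                     fill = .data$mode)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(ggplot2::vars(.data$body_site)) +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "volume [mL]", fill = "measurement mode",
                    title = "Body composition by region") +
      ggplot2::theme_minimal()
  } else {
    df <- object[object$kind == "organ", , drop = FALSE]
    df <- df[order(-df$volume_ml), , drop = FALSE][seq_len(min(top_n, nrow(df))), ]
    ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$structure, .data$volume_ml),
                                     y = .data$volume_ml)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "volume [mL]",
                    title = sprintf("Largest %d structures", nrow(df))) +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.boa_measurements
#' @param rows A `boa_measurements` tibble.
#' @export
plot_measurements <- function(rows, kind = c("region", "organ"), top_n = 20) {
  autoplot.boa_measurements(rows, kind = kind, top_n = top_n)
}
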