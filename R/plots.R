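#' Plot a sequence logo as stacked letter frequencies
#'
#' Columns are repeat-unit positions; letter heights are residue frequency
#' scaled by the column's information content (bits), the conventional logo
#' scaling.
#'
#' @param object A `logo_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot logo_matrix
#' @export
autoplot.logo_matrix <- function(object, ...) {
  df <- tidy.logo_matrix(object)
  df <- mutate(group_by(arrange(df, .data$position, .data$freq),
                        .data$position),
               h = .data$freq * .data$ic,
               ymax = cumsum(.data$h), ymin = .data$ymax - .data$h)
  ggplot2::ggplot(ungroup(df)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$position - 0.45, xmax = .data$position + 0.45,
      ymin = .data$ymin, ymax = .data$ymax, fill = .data$residue),
      colour = "grey30", linewidth = 0.1, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(
      x = .data$position, y = (.data$ymin + .data$ymax) / 2,
      label = .data$residue, size = .data$h), show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 4)) +
    ggplot2::labs(x = "repeat-unit position", y = "bits") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot sliding-window composition along a protein
#'
#' @param protein Protein string or one-row sequence tibble.
#' @param window Window length.
#' @param residues Residues counted (default P, S, T).
#' @param region Optional `repeat_region` to shade.
#' @return A ggplot object.
#' @export
plot_composition <- function(protein, window = 50L,
                             residues = c("P", "S", "T"), region = NULL) {
  df <- sliding_composition(protein, window, residues)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start + window / 2,
                                        y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (aa)",
                  y = paste0("fraction ",
                             paste(residues, collapse = "/"),
                             " (window ", window, ")")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(region)) {
    p <- p + ggplot2::annotate("rect", xmin = region$start,
                               xmax = region$end, ymin = 0, ymax = 1,
                               alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Boxplot of a two-strain phenotype contrast
#'
#' @param data Long-form data frame.
#' @param value,group Column names (strings).
#' @return A ggplot object.
#' @export
plot_contrast <- function(data, value, group = "strain") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]],
                                     y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::theme_minimal()
}

#' Step survival curves from death times
#'
#' @param data Data frame with a death-time column and a group column.
#' @param time,group Column names (strings).
#' @return A ggplot object.
#' @export
plot_survival <- function(data, time, group = "strain") {
  df <- bind_rows(purrr::map(unique(data[[group]]), function(g) {
    t <- sort(data[[time]][data[[group]] == g])
    tibble(group = g, time = c(0, t),
           alive = c(1, 1 - seq_along(t) / length(t)))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$alive,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "fraction alive", colour = group) +
    ggplot2::theme_minimal()
}
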