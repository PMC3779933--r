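# ggplot2 displays for the main result types.

#' @export
autoplot.umatrix <- function(object, ...) {
  df <- tibble(
    row = as.integer(base::row(unclass(object))),
    col = as.integer(base::col(unclass(object))),
    height = as.numeric(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "U-height") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row",
                  title = "U-matrix (mean neighbor codebook distance)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.clone_binning <- function(object, ...) {
  um <- autoplot(object$umatrix)
  bins <- object$partition |> as_tibble() |> filter(.data$bin > 0)
  um +
    ggplot2::geom_point(
      data = bins,
      ggplot2::aes(x = .data$col, y = .data$row,
                   colour = factor(.data$bin)),
      inherit.aes = FALSE, size = 0.6) +
    ggplot2::scale_colour_brewer(palette = "Set1", name = "bin")
}

# Four-state fill mirroring the standard concordance shading: white =
# predicted only, light blue = confirmed only, dark blue = both, red =
# neither.
concordance_fill <- c(neither = "#d73027", predicted_only = "#ffffff",
                      confirmed_only = "#abd9e9", both = "#2c7bb6")

#' @export
autoplot.concordance <- function(object, drop_neither_clones = TRUE, ...) {
  df <- as_tibble(object)
  if (drop_neither_clones) {
    active <- df |>
      group_by(.data$clone_id) |>
      summarise(any = any(.data$state != "neither"), .groups = "drop") |>
      filter(.data$any)
    df <- df |> semi_join(active, by = "clone_id")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$substrate, y = .data$clone_id,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_manual(values = concordance_fill, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Predicted vs biochemically confirmed activities") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.bin_trait_table <- function(object, ...) {
  df <- as_tibble(object) |> mutate(bin = factor(.data$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$substrate, y = .data$clone_id,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_manual(values = concordance_fill, drop = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$bin), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Trait co-occurrence within genome bins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-substrate positive frequencies of a screen
#'
#' @param summary A `screen_summary` from [tally_screen()] or
#'   [summarize_screen_counts()].
#' @return A ggplot bar chart of positive-assay frequency per substrate.
#' @export
plot_substrate_frequencies <- function(summary) {
  stopifnot(inherits(summary, "screen_summary"))
  ggplot2::ggplot(summary$per_substrate,
                  ggplot2::aes(x = stats::reorder(.data$substrate,
                                                  .data$frequency_pct),
                               y = .data$frequency_pct)) +
    ggplot2::geom_col(fill = "#2c7bb6") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "positive assays (% of clones screened)") +
    ggplot2::theme_minimal()
}
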