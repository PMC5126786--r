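# ggplot2 views of the tabular result types.

#' Plot a family-by-species count matrix
#'
#' Tile heatmap of family member counts, faceted by high-order group.
#'
#' @param object A `family_matrix` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.family_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = -c("family", "group"),
                              names_to = "species", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$family,
                                     fill = .data$n)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 2.6) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "members") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot assignment statuses
#'
#' Bar chart of the cascade outcome per candidate, colored by status.
#'
#' @param object A `bhlh_assignments` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bhlh_assignments <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "cascade status", y = "candidates") +
    ggplot2::theme_minimal()
}

#' Plot intron locations across motif regions
#'
#' @param records Intron records ([classify_introns()] output bound over
#'   genes).
#' @return A ggplot object.
#' @export
plot_intron_locations <- function(records) {
  lv <- c("basic", "helix1", "loop", "helix2", "outside_motif")
  df <- dplyr::count(records, location = factor(.data$location, levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$location, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "motif region", y = "introns") +
    ggplot2::theme_minimal()
}
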