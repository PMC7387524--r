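#' Plot methods
#'
#' `autoplot.embedding_result()` draws the 2-D recognition space colored by
#' aaRS class with per-aaRS mean-position labels;
#' `autoplot.design_comparison()` draws the mean silhouette per fingerprint
#' design with per-seed points; `plot_occupancy()` draws an occupancy
#' profile as an atom-by-type tile map.
#'
#' @param object an `embedding_result` or `design_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @importFrom ggplot2 autoplot
#' @method autoplot embedding_result
#' @export
autoplot.embedding_result <- function(object, ...) {
  df <- tidy(object)
  df$aars_class <- aars_class(df$aars)
  centers <- df |>
    dplyr::group_by(.data$aars) |>
    dplyr::summarise(dim1 = mean(.data$dim1), dim2 = mean(.data$dim2),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$aars_class),
                        alpha = 0.6, size = 1.5) +
    ggplot2::geom_text(data = centers,
                       ggplot2::aes(label = .data$aars), size = 3) +
    ggplot2::labs(x = "dimension 1 (arbitrary units)",
                  y = "dimension 2 (arbitrary units)",
                  colour = "aaRS class") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot design_comparison
#' @export
autoplot.design_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$design <- factor(df$design, levels = unique(df$design))
  summ <- glance(object)
  summ$design <- factor(summ$design, levels = levels(df$design))
  ggplot2::ggplot(summ,
                  ggplot2::aes(.data$design, .data$mean_silhouette,
                               group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(.data$design, .data$silhouette),
                        alpha = 0.4) +
    ggplot2::labs(x = "fingerprint design", y = "mean silhouette") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param profile an `occupancy_profile` from [compute_occupancy()].
#' @export
plot_occupancy <- function(profile) {
  df <- tibble::as_tibble(profile)
  ggplot2::ggplot(df, ggplot2::aes(.data$scaffold_atom, .data$itype,
                                   fill = .data$occupancy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 1)) +
    ggplot2::labs(title = paste0(attr(profile, "aars"), " (n = ",
                                 attr(profile, "n_structures"), ")"),
                  x = "scaffold atom", y = "interaction type") +
    ggplot2::theme_minimal()
}
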