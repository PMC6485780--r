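# ggplot2 views of the result types.

#' Plot a genome comparison against the demarcation thresholds
#'
#' Bar chart of the AGIOS, AAI and dDDH percentages for one genome pair,
#' with the species-demarcation thresholds drawn as dashed lines.
#'
#' @param object A `comparison_result`.
#' @param t [thresholds()] to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot comparison_result
#' @export
autoplot.comparison_result <- function(object, t = thresholds(), ...) {
  dat <- tibble(metric = factor(c("AGIOS", "AAI", "dDDH"),
                                levels = c("AGIOS", "AAI", "dDDH")),
                value = c(object$agios, object$aai, object$ddh),
                threshold = c(NA, t$aai_species, t$ddh_species))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$threshold,
                                        ymax = .data$threshold),
                           linetype = "dashed", colour = "firebrick",
                           na.rm = TRUE) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(title = sprintf("%s vs %s", object$strain_a, object$strain_b),
                  y = "percent", x = NULL,
                  caption = "dashed: species-demarcation threshold") +
    ggplot2::theme_minimal()
}

#' Plot a distance matrix as a heatmap
#'
#' @param dm Square distance matrix (e.g. from [k2p_distance_matrix()]).
#' @return A ggplot.
#' @export
plot_distance_matrix <- function(dm) {
  long <- tidy_distance_matrix(dm)
  long <- bind_rows(long,
                    rename(long, taxon_a = "taxon_b", taxon_b = "taxon_a"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon_a, y = .data$taxon_b,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "K2P distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the evidence behind a species report
#'
#' Dot plot of every metric/threshold pair in the report's evidence table.
#'
#' @param object A `species_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot species_report
#' @export
autoplot.species_report <- function(object, ...) {
  ev <- mutate(object$evidence,
               label = paste(.data$call, .data$metric, sep = ": "))
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$value, y = .data$label,
                                   colour = .data$passed)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_point(ggplot2::aes(x = .data$threshold), shape = 124,
                        size = 5, colour = "black") +
    ggplot2::labs(title = sprintf("%s: %s", object$strain, object$overall),
                  x = "percent", y = NULL, colour = "supports call",
                  caption = "vertical bar: threshold") +
    ggplot2::theme_minimal()
}
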