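#' Plot a read-length histogram
#'
#' Reproduces the two-peak figure: miRNA reads at 20-24 nt and, when
#' multireads are reported, 5' tRNA halves at 30-33 nt. Facets by policy
#' combination and/or sample when those columns are present.
#'
#' @param histogram Output of [length_histogram()] (rows from several policy
#'   combinations can be stacked).
#' @return A ggplot object.
#' @export
plot_length_histogram <- function(histogram) {
  p <- ggplot2::ggplot(histogram,
                       ggplot2::aes(x = .data$length, y = .data$count,
                                    fill = .data$feature_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "read length (nt)", y = "reads", fill = "class") +
    ggplot2::theme_minimal()
  facets <- intersect(c("policy_combo", "sample"), names(histogram))
  if (length(facets)) {
    p <- p + ggplot2::facet_wrap(facets, scales = "free_y")
  }
  p
}

#' Plot anticodon-relative cleavage-site profiles
#'
#' @param profile Output of [cleavage_profile()].
#' @return A ggplot object: fraction of 5'-half reads by cleavage offset
#'   (nt upstream of the anticodon), per family.
#' @export
plot_cleavage_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$offset), y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap("family_id") +
    ggplot2::labs(x = "cleavage offset upstream of anticodon (nt)",
                  y = "fraction of 5' half reads") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a differential-abundance fit
#'
#' @param object A `trna_diff`.
#' @param contrast Which contrast to plot (default the first).
#' @param ... Unused.
#' @return A ggplot object of signed fold change vs -log10 p.
#' @export
autoplot.trna_diff <- function(object, contrast = names(object$contrasts)[1],
                               ...) {
  tab <- object$table
  fc <- tab[[paste0(contrast, "_fc")]]
  p <- tab[[paste0(contrast, "_p")]]
  q <- tab[[paste0(contrast, "_q")]]
  df <- tibble(fc = fc, p = p, sig = !is.na(q) & q <= 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fc, y = -log10(.data$p),
                                   colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = paste0("signed fold change (", contrast, ")"),
                  y = "-log10 p", colour = "BH q <= 0.05") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
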