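# ggplot2 displays for the main result types.

#' Plot core/pan-genome curves
#'
#' All subset points plus a mean line per curve, in the style of pan-genome
#' rarefaction figures.
#'
#' @param curve Tibble from [core_pan_curve()].
#' @return A ggplot object.
#' @export
plot_core_pan_curve <- function(curve) {
  long <- tidyr::pivot_longer(curve, c("core", "pan"),
                              names_to = "which", values_to = "families")
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$subset_size, .data$which),
    families = mean(.data$families), .groups = "drop"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subset_size,
                                     y = .data$families,
                                     colour = .data$which)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.35, size = 0.8) +
    ggplot2::geom_line(data = means, linewidth = 1) +
    ggplot2::scale_colour_manual(values = c(core = "#2166ac",
                                            pan = "#1b7837")) +
    ggplot2::labs(x = "Number of genomes", y = "Gene families",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an occurrence spectrum
#'
#' For each replicon class, the distribution of the number of strains a
#' family is found in.
#'
#' @param spectrum Tibble from [re_statistics()] / [tal_statistics()]
#'   (`$spectrum`).
#' @return A ggplot object.
#' @export
plot_occurrence_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$n_strains)) +
    ggplot2::geom_bar(fill = "#2166ac") +
    ggplot2::facet_wrap(~rep_class) +
    ggplot2::labs(x = "Number of strains", y = "Families") +
    ggplot2::theme_minimal()
}

#' Plot a family-count PCA
#'
#' Scatter of the first two components, coloured by replicon class.
#'
#' @param object A `pr_pca` from [pca_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_pca <- function(object, ...) {
  ev <- object$explained_variance
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$rep_class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = "Replicon class"
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a Mantel test result
#'
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @return One-row tibble `r`, `p`, `n_perm`, `alternative`.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n_perm = x$n_perm,
                 alternative = x$alternative)
}

#' @rdname tidy.mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x)

#' Tidy PCA scores
#'
#' @param x A `pr_pca`.
#' @param ... Unused.
#' @return The scores tibble.
#' @export
tidy.pr_pca <- function(x, ...) x$scores

#' @rdname tidy.pr_pca
#' @export
glance.pr_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    pc1_variance = x$explained_variance[1],
    pc2_variance = x$explained_variance[2]
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
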