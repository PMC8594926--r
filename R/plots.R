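# ggplot2 views of the main result types.

#' Plot a per-biotype size distribution
#'
#' @param sizes Tibble from [size_distribution()].
#' @return A ggplot.
#' @export
plot_size_distribution <- function(sizes) {
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$length, y = .data$mean_cpm,
                                      fill = .data$biotype)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~biotype, scales = "free_y") +
    ggplot2::labs(x = "fragment length (nt)", y = "mean cpm",
                  fill = "biotype") +
    ggplot2::theme_minimal()
}

#' Plot first-nucleotide bias per biotype
#'
#' @param bias Tibble from [first_nt_bias()].
#' @return A ggplot.
#' @export
plot_first_nt_bias <- function(bias) {
  ggplot2::ggplot(bias, ggplot2::aes(x = .data$biotype, y = .data$fraction,
                                     fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "cpm-weighted fraction", fill = "base") +
    ggplot2::theme_minimal()
}

#' Plot a per-reference coverage profile
#'
#' @param profile Tibble from [compute_coverage()].
#' @param subunits Optional tibble with `subunit_id`, `start`, `end` drawn
#'   as shaded intervals (e.g. mature rRNA subunits on a precursor).
#' @return A ggplot.
#' @export
plot_coverage <- function(profile, subunits = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position,
                                             y = .data$cpm))
  if (!is.null(subunits)) {
    p <- p + ggplot2::geom_rect(
      data = subunits,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$subunit_id),
      alpha = 0.15, inherit.aes = FALSE
    )
  }
  p + ggplot2::geom_area(alpha = 0.7) +
    ggplot2::labs(x = "reference position", y = "cpm coverage") +
    ggplot2::theme_minimal()
}

#' Plot cpm-weighted terminal-class fractions
#'
#' @param enrichment Tibble from [terminal_enrichment()]; the first column
#'   is used as the group axis.
#' @return A ggplot.
#' @export
plot_terminal_enrichment <- function(enrichment) {
  group_col <- names(enrichment)[1L]
  long <- tidyr::pivot_longer(
    enrichment, c("five_prime", "internal", "three_prime"),
    names_to = "terminal_class", values_to = "fraction"
  )
  long$terminal_class <- factor(long$terminal_class,
                                c("five_prime", "internal", "three_prime"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group_col]],
                                     y = .data$fraction,
                                     fill = .data$terminal_class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(y = "cpm fraction", fill = "terminal") +
    ggplot2::theme_minimal()
}

#' @rdname saturation_curve
#' @param object A `saturation_fit`.
#' @export
autoplot.saturation_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth,
                                        y = .data$richness)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "subsampled reads", y = "distinct sequences") +
    ggplot2::theme_minimal()
  if (object$converged) {
    df$fitted <- object$fitted
    p <- p +
      ggplot2::geom_line(data = df, ggplot2::aes(y = .data$fitted),
                         colour = "steelblue") +
      ggplot2::geom_hline(yintercept = object$Asym, linetype = "dashed")
  }
  p
}

#' @rdname correlation_cluster
#' @param object A `correlation_cluster`.
#' @param ... Unused.
#' @export
autoplot.correlation_cluster <- function(object, ...) {
  ord <- object$leaf_order
  df <- as.data.frame(as.table(object$correlation[ord, ord]))
  names(df) <- c("sample_a", "sample_b", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
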