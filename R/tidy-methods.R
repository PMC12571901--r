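#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ASO design result
#'
#' Returns the candidate table as a plain tibble (one row per candidate),
#' dropping the result class and attributes.
#'
#' @param x An `aso_design` from [design_asos()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.aso_design <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' Summarise an ASO design result
#'
#' @param x An `aso_design` from [design_asos()].
#' @param ... Unused.
#' @return One-row tibble: genome id, gene/candidate/passing counts, number
#'   of under-designed genes, and the main filter bounds.
#' @export
glance.aso_design <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(genome = attr(x, "genome_id") %||% NA_character_,
         n_genes = dplyr::n_distinct(x$gene),
         n_candidates = nrow(x),
         n_passing = sum(x$passes),
         n_under_designed = dplyr::n_distinct(x$gene[x$under_designed]),
         tm_min = cfg$tm_min, tm_max = cfg$tm_max,
         purine_min = cfg$purine_min, purine_max = cfg$purine_max,
         max_offtarget_tirs = cfg$max_offtarget_tirs)
}

#' Plot an ASO design result
#'
#' Candidate melting temperature against purine fraction, with the
#' acceptance box of the design filter drawn and passing candidates
#' highlighted.
#'
#' @param object An `aso_design` from [design_asos()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aso_design <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- as_tibble(unclass_result(object))
  df <- df[!is.na(df$tm_c), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tm_c, y = .data$purine_frac,
                                   colour = .data$passes)) +
    ggplot2::annotate("rect", xmin = cfg$tm_min, xmax = cfg$tm_max,
                      ymin = cfg$purine_min, ymax = cfg$purine_max,
                      alpha = 0.1, fill = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "predicted duplex Tm (°C)",
                  y = "purine fraction of oligomer",
                  colour = "passes filter") +
    ggplot2::theme_minimal()
}

#' Tidy a screen result
#'
#' @param x An `aso_screen` from [analyze_screen()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.aso_screen <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' Summarise a screen result
#'
#' @param x An `aso_screen` from [analyze_screen()].
#' @param ... Unused.
#' @return One-row tibble with the number of scored knockdowns and the count
#'   in each effect category.
#' @export
glance.aso_screen <- function(x, ...) {
  counts <- table(x$category)
  tibble(n = nrow(x),
         n_increase = counts[["-"]], n_none = counts[["none"]],
         n_weak = counts[["+"]], n_effective = counts[["++"]],
         n_very_effective = counts[["+++"]],
         n_censored = sum(x$censored))
}

#' Plot a screen result
#'
#' log10 PFU reduction per gene, coloured by effect category; censored
#' calls (target below detection) are marked with open triangles at their
#' bound.
#'
#' @param object An `aso_screen` from [analyze_screen()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aso_screen <- function(object, ...) {
  df <- as_tibble(unclass_result(object))
  df$gene <- stats::reorder(df$gene, df$delta_log10_pfu)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$delta_log10_pfu,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(data = df[df$censored, ], shape = 24) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log10 PFU reduction (control - targeting)",
                  fill = "effect") +
    ggplot2::theme_minimal()
}

#' Volcano plot of temporal transcript classes
#'
#' @param expr Output of [classify_temporal()].
#' @param lfc_cutoff,sig_cutoff Thresholds to draw (match the classifier).
#' @return A ggplot.
#' @export
plot_temporal_classes <- function(expr, lfc_cutoff = 2, sig_cutoff = 10) {
  stopifnot(all(c("log2fc", "padj", "class") %in% names(expr)))
  ggplot2::ggplot(expr, ggplot2::aes(x = .data$log2fc,
                                     y = -log10(.data$padj),
                                     colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = sig_cutoff, linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change (late vs early)",
                  y = "-log10 adjusted P", colour = "class") +
    ggplot2::theme_minimal()
}

unclass_result <- function(x) {
  attr(x, "config") <- NULL
  attr(x, "thresholds") <- NULL
  attr(x, "offtarget_by_genome") <- NULL
  attr(x, "genome_id") <- NULL
  attr(x, "window") <- NULL
  class(x) <- setdiff(class(x), c("aso_design", "aso_screen"))
  x
}
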