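#' @importFrom ggplot2 ggplot aes geom_tile geom_point geom_histogram
#'   geom_col labs scale_fill_gradient scale_fill_manual theme_minimal
#'   facet_grid autoplot
NULL

#' @export
ggplot2::autoplot

#' Heatmap of mean pairwise polymorphism by subgroup
#'
#' @param object A [all_pairs_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pair_summary
#' @export
autoplot.pair_summary <- function(object, ...) {
  gm <- object$group_matrix
  df <- as_tibble(as.data.frame(as.table(gm), stringsAsFactors = FALSE))
  names(df) <- c("group_a", "group_b", "mean_count")
  ggplot(df, aes(x = .data$group_a, y = .data$group_b,
                 fill = .data$mean_count)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        na.value = "grey90") +
    labs(x = NULL, y = NULL, fill = "mean polymorphic\nSNPs / pair") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Histogram of nearest-neighbor marker distances
#'
#' @param object A [spacing_stats()] result.
#' @param binwidth Histogram bin width in bp (default 20 kb).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spacing_stats
#' @export
autoplot.spacing_stats <- function(object, binwidth = 20e3, ...) {
  ggplot(object$nn, aes(x = .data$nn_bp)) +
    geom_histogram(binwidth = binwidth, fill = "steelblue",
                   colour = "white") +
    labs(x = "distance to nearest neighboring SNP (bp)", y = "SNPs") +
    theme_minimal()
}

#' Per-megabase informative-SNP density of a panel design
#'
#' @param object A `panel_design`.
#' @param ... Unused.
#' @return A ggplot: bins x chromosome tiles per cross, filled by
#'   informative-SNP count.
#' @method autoplot panel_design
#' @export
autoplot.panel_design <- function(object, ...) {
  cov <- object$coverage
  if (nrow(cov) == 0L) abort("design has no coverage table (no crosses)")
  cov$chromosome <- factor(cov$chromosome, levels = chrom_levels(cov$chromosome))
  ggplot(cov, aes(x = .data$bin, y = .data$chromosome,
                  fill = .data$n_informative)) +
    geom_tile() +
    facet_grid(rows = ggplot2::vars(.data$cross)) +
    scale_fill_gradient(low = "white", high = "darkgreen") +
    labs(x = "1 Mb bin", y = NULL, fill = "informative\nSNPs") +
    theme_minimal()
}

#' PCA score plot coloured by subpopulation
#'
#' @param object A [pca_genotypes()] result.
#' @param components Length-2 integer: which components to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot geno_pca
#' @export
autoplot.geno_pca <- function(object, components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  ev <- object$explained_variance[components]
  ggplot(object$scores,
         aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
             colour = .data$group)) +
    geom_point(size = 2) +
    labs(x = sprintf("%s (%.1f%%)", pcs[1], 100 * ev[1]),
         y = sprintf("%s (%.1f%%)", pcs[2], 100 * ev[2]),
         colour = "group") +
    theme_minimal()
}

#' Graphical genotypes of coded progeny along the genome
#'
#' Displays the A/B/H/NC codes of each line as coloured tiles ordered by
#' marker position, one facet per chromosome — the standard graphical
#' genotype display for introgression tracking.
#'
#' @param coded A [classify_progeny()] result.
#' @param progeny Ids of the lines to show (default: all).
#' @param chromosomes Optional chromosome subset.
#' @return A ggplot.
#' @export
plot_graphical_genotypes <- function(coded, progeny = NULL,
                                     chromosomes = NULL) {
  if (is.null(progeny)) progeny <- coded_progeny(coded)
  x <- as_tibble(coded)[, c("chromosome", "position", progeny)]
  if (!is.null(chromosomes)) x <- x[x$chromosome %in% chromosomes, ]
  long <- tidyr::pivot_longer(x, cols = all_of(progeny),
                              names_to = "line", values_to = "code")
  long$chromosome <- factor(long$chromosome,
                            levels = chrom_levels(long$chromosome))
  ggplot(long, aes(x = .data$position / 1e6, y = .data$line,
                   fill = .data$code)) +
    geom_tile() +
    facet_grid(cols = ggplot2::vars(.data$chromosome), scales = "free_x",
               space = "free_x") +
    scale_fill_manual(values = c(A = "white", H = "skyblue",
                                 B = "royalblue4", NC = "grey70")) +
    labs(x = "position (Mb)", y = NULL, fill = "code") +
    theme_minimal()
}
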