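# ggplot2 figures for the main result types.

#' Plot rarefaction curves
#'
#' Pan- and core-genome median sizes against the number of genomes, with the
#' fitted Heaps'-law and exponential curves overlaid when supplied.
#'
#' @param object A [rarefaction_curves()] result.
#' @param power_fit Optional [fit_power_law()] result.
#' @param core_fit Optional [fit_core_exponential()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rarefaction_series
#' @export
autoplot.rarefaction_series <- function(object, power_fit = NULL,
                                        core_fit = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"n",
                              names_to = "genome", values_to = "size")
  long$genome <- ifelse(long$genome == "pan_median", "pan-genome", "core genome")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$size,
                                          colour = .data$genome)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "genomes added", y = "gene families (median)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  grid <- tibble(n = seq(1, max(long$n), length.out = 200))
  if (!is.null(power_fit)) {
    grid$pan <- power_fit$kappa * grid$n^power_fit$gamma
    p <- p + ggplot2::geom_line(data = grid,
      ggplot2::aes(x = .data$n, y = .data$pan), inherit.aes = FALSE,
      linetype = 2)
  }
  if (!is.null(core_fit)) {
    grid$core <- core_fit$kappa_c * exp(-core_fit$decay * grid$n) +
      core_fit$omega
    p <- p + ggplot2::geom_line(data = grid,
      ggplot2::aes(x = .data$n, y = .data$core), inherit.aes = FALSE,
      linetype = 3)
  }
  p
}

#' Plot a substitution-saturation report
#'
#' Transition (`s`) and transversion (`v`) proportions of every sequence
#' pair against their TN93 distance — the standard visual saturation check:
#' an unsaturated alignment shows transitions above transversions.
#'
#' @param object A [saturation_assessment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saturation_report
#' @export
autoplot.saturation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$pairs, c("s", "v"),
                              names_to = "class", values_to = "proportion")
  long$class <- ifelse(long$class == "s", "transitions", "transversions")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d, y = .data$proportion,
                                     colour = .data$class,
                                     shape = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "TN93 distance", y = "proportion of sites",
                  colour = NULL, shape = NULL,
                  subtitle = sprintf("verdict: %s (%.0f%% of pairs saturated)",
                                     object$verdict,
                                     100 * object$saturated_fraction)) +
    ggplot2::theme_minimal()
}

#' Plot per-branch gene turnover on the tree
#'
#' Draws the reference tree with per-branch gain (+) / loss (-) counts and
#' ancestral gene totals at internal nodes.
#'
#' @param x A [gene_turnover()] result.
#' @param tree The rooted tree the result was computed on.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot_turnover <- function(x, tree, ...) {
  stopifnot(inherits(x, "turnover_result"), inherits(tree, "phylo"))
  ape::plot.phylo(tree, ...)
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) sprintf("n%02d", seq_len(tree$Nnode))
              else tree$node.label)
  br <- x$branches
  edge_lab <- paste0("+", br$gains, "/-", br$losses)[
    match(labels[tree$edge[, 2]], br$child_label)]
  ape::edgelabels(edge_lab, frame = "none", cex = 0.7, adj = c(0.5, -0.3))
  totals <- x$node_counts$total_genes[match(labels, x$node_counts$node_label)]
  ntip <- length(tree$tip.label)
  ape::nodelabels(totals[(ntip + 1):length(labels)], frame = "circle", cex = 0.6)
  invisible(x)
}
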