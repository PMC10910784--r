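# ggplot2 displays for the main result types.

#' Histogram of monomer identity to the consensus
#'
#' @param monomers Monomer tibble with `identity` (and optional
#'   `consensus_name` for fill).
#' @param binwidth Histogram bin width (identity units).
#' @return A ggplot.
#' @export
plot_identity_distribution <- function(monomers, binwidth = 0.005) {
  p <- ggplot2::ggplot(monomers, ggplot2::aes(x = .data$identity))
  if ("consensus_name" %in% names(monomers)) {
    p <- p + ggplot2::aes(fill = .data$consensus_name)
  }
  p +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = "identity to consensus", y = "monomers", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Enrichment track with centromere calls
#'
#' @param track [log2_ratio()] output.
#' @param calls Optional [call_centromere()] output (shaded).
#' @return A ggplot (facetted by chromosome).
#' @export
plot_enrichment_track <- function(track, calls = NULL) {
  p <- ggplot2::ggplot(track) +
    ggplot2::geom_step(ggplot2::aes(x = .data$start, y = .data$log2_ratio)) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "log2(ChIP/Input)") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_rect(
      data = calls,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "red", alpha = 0.15
    )
  }
  p
}

#' Within-monomer phase profile
#'
#' @param x A `pancent_phase` from [phase_profile()].
#' @return A ggplot with the smoothed density and the peak offset marked.
#' @export
plot_phase_profile <- function(x) {
  ggplot2::ggplot(x$profile, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density), width = 1,
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), color = "red") +
    ggplot2::geom_vline(xintercept = x$peak_offset, linetype = 2) +
    ggplot2::labs(x = "offset within monomer (bp)", y = "fragment density") +
    ggplot2::theme_minimal()
}

#' PCA projection of k-mer frequency vectors
#'
#' @param object A `pancent_pca`.
#' @param groups Optional vector of group labels (colour).
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 with explained-variance axis labels.
#' @method autoplot pancent_pca
#' @export
autoplot.pancent_pca <- function(object, groups = NULL, ...) {
  d <- object$scores
  if (!is.null(groups)) d$group <- factor(groups)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$prop_var[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$prop_var[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.6)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$group), alpha = 0.6)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Metaprofile of enrichment over features
#'
#' @param profile [metaprofile()] output.
#' @return A ggplot with body boundaries marked.
#' @export
plot_metaprofile <- function(profile) {
  b <- range(profile$position[profile$section == "body"])
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = b + c(-0.5, 0.5), linetype = 3) +
    ggplot2::labs(x = "scaled position (flank | body | flank)",
                  y = "mean log2(ChIP/Input)") +
    ggplot2::theme_minimal()
}
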