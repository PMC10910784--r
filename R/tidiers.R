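# broom-style accessors for the PCA fit.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the scores of a k-mer PCA
#'
#' @param x A `pancent_pca`.
#' @param ... Unused.
#' @return Long tibble: `row`, `PC`, `score`.
#' @method tidy pancent_pca
#' @export
tidy.pancent_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"row", names_to = "PC", values_to = "score")
}

#' One-row summary of a k-mer PCA
#'
#' @param x A `pancent_pca`.
#' @param ... Unused.
#' @return Tibble with `n_rows`, `n_components`, `var_pc1`, `var_pc2`,
#'   `var_first_100` (fraction of variance in the leading <= 100 components).
#' @method glance pancent_pca
#' @export
glance.pancent_pca <- function(x, ...) {
  tibble(
    n_rows = nrow(x$scores),
    n_components = x$n_components,
    var_pc1 = x$prop_var[1],
    var_pc2 = if (length(x$prop_var) > 1) x$prop_var[2] else NA_real_,
    var_first_100 = sum(x$prop_var[seq_len(min(100, x$n_components))])
  )
}
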