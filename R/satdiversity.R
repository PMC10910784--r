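# Satellite diversity statistics: exact-duplication sharing, 5-mer PCA with
# hierarchical clustering, subsampling and group comparisons. "Identical
# monomers" means exact string equality of the sequence as read on the
# annotated strand (strand-normalized at generation/extraction time).

#' Proportion of monomers with an exact duplicate
#'
#' A monomer counts as duplicated if its sequence occurs at least twice within
#' the scope: on the same chromosome (self excluded) or anywhere on another
#' chromosome.
#'
#' @param monomers Monomer tibble with `chrom` and `sequence` columns.
#' @param scope `"within_chromosome"` or `"between_chromosomes"`.
#' @return One-row tibble per chromosome (within) or overall per chromosome
#'   (between): `scope`, `chrom`, `n`, `n_duplicated`, `proportion`.
#' @export
duplication_proportion <- function(monomers,
                                   scope = c("within_chromosome",
                                             "between_chromosomes")) {
  scope <- match.arg(scope)
  if (NROW(monomers) == 0) abort("empty monomer set: proportion undefined")
  if (scope == "within_chromosome") {
    monomers |>
      group_by(.data$chrom) |>
      summarise(
        n = n(),
        n_duplicated = sum(duplicated(.data$sequence) |
                             duplicated(.data$sequence, fromLast = TRUE)),
        .groups = "drop"
      ) |>
      mutate(scope = scope, proportion = .data$n_duplicated / .data$n,
             .before = 1)
  } else {
    chroms <- unique(monomers$chrom)
    purrr::map_dfr(chroms, function(ch) {
      qry <- monomers$sequence[monomers$chrom == ch]
      tgt <- unique(monomers$sequence[monomers$chrom != ch])
      tibble(scope = scope, chrom = ch, n = length(qry),
             n_duplicated = sum(qry %in% tgt),
             proportion = sum(qry %in% tgt) / length(qry))
    })
  }
}

#' Proportion of monomers shared between two sets
#'
#' Fraction of set A monomers whose exact sequence occurs in set B, and vice
#' versa (e.g. homologous chromosome pairs, or the same chromosome in two
#' genomes).
#'
#' @param set_a,set_b Monomer tibbles (or character vectors of sequences).
#' @return Two-row tibble: `direction`, `n_query`, `n_shared`, `proportion`.
#' @export
shared_monomer_proportion <- function(set_a, set_b) {
  a <- if (is.data.frame(set_a)) set_a$sequence else set_a
  b <- if (is.data.frame(set_b)) set_b$sequence else set_b
  if (length(a) == 0 || length(b) == 0) abort("empty monomer set")
  tibble(
    direction = c("A_in_B", "B_in_A"),
    n_query = c(length(a), length(b)),
    n_shared = c(sum(a %in% b), sum(b %in% a)),
    proportion = c(mean(a %in% b), mean(b %in% a))
  )
}

#' PCA of a k-mer frequency matrix
#'
#' Columns are mean-centered (not variance-scaled: frequencies share a scale,
#' and scaling 1024 sparse columns amplifies noise) and projected onto up to
#' `n_components` principal components.
#'
#' @param x Numeric matrix (rows = sequences), e.g. from [kmer_table()].
#' @param n_components Maximum number of components (default 100); capped at
#'   the matrix rank.
#' @param scale. Standardize columns first (default `FALSE`).
#' @return A `pancent_pca` object: `scores` tibble (`row`, `PC1`, ...),
#'   `sdev`, `prop_var` (explained-variance fractions), `rotation`, `center`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
pca_project <- function(x, n_components = 100L, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("PCA needs at least 2 rows")
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  p <- prcomp(x, center = TRUE, scale. = scale., rank. = k)
  ev <- p$sdev^2
  scores <- as_tibble(p$x)
  scores <- mutate(scores, row = rownames(x) %||% as.character(seq_len(nrow(x))),
                   .before = 1)
  structure(
    list(scores = scores, sdev = p$sdev, prop_var = ev / sum(ev),
         rotation = p$rotation, center = p$center, n_components = k),
    class = "pancent_pca"
  )
}

#' @export
print.pancent_pca <- function(x, ...) {
  cat(sprintf("<pancent_pca> %d rows, %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), x$n_components,
              100 * x$prop_var[1], 100 * (x$prop_var[2] %||% NA)))
  invisible(x)
}

#' Hierarchical clustering of PC scores into groups
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' principal-component scores, cut into `n_groups` clusters. Labels are
#' deterministic given input order.
#'
#' @param scores A `pancent_pca` object, its `scores` tibble, or a numeric
#'   matrix of coordinates.
#' @param n_groups Number of groups (>= 2).
#' @return Integer vector of group labels.
#' @export
hca_groups <- function(scores, n_groups) {
  if (inherits(scores, "pancent_pca")) scores <- scores$scores
  if (is.data.frame(scores)) {
    scores <- as.matrix(scores[vapply(scores, is.numeric, logical(1))])
  }
  if (n_groups < 2) abort("n_groups must be >= 2")
  if (n_groups > nrow(scores)) abort("more groups than rows")
  hc <- hclust(dist(scores), method = "ward.D2")
  unname(cutree(hc, k = n_groups))
}

#' Random subsample of fragments
#'
#' Uniform sample without replacement, deterministic given the seed (used for
#' the per-genome 500-fragment PCA displays).
#'
#' @param fragments Fragment tibble (or any data frame).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return The sampled rows (original order preserved).
#' @export
subsample_fragments <- function(fragments, n = 500L, seed = 1L) {
  if (n > nrow(fragments)) abort("sample size exceeds population")
  idx <- withr::with_seed(seed, sort(sample.int(nrow(fragments), n)))
  fragments[idx, , drop = FALSE]
}

#' Welch two-sample comparison of score distributions
#'
#' Two-sided Welch t-test (unequal variances), as used for comparing PC-score
#' distributions between groups. If both groups are constant with equal means,
#' `t = 0`, `p = 1` by convention.
#'
#' @param scores_a,scores_b Numeric vectors (each length >= 2).
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
group_compare <- function(scores_a, scores_b) {
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    abort("each group needs at least 2 values")
  }
  if (sd(scores_a) == 0 && sd(scores_b) == 0) {
    if (mean(scores_a) == mean(scores_b)) {
      return(tibble(t = 0, df = NA_real_, p_value = 1,
                    mean_a = mean(scores_a), mean_b = mean(scores_b)))
    }
    return(tibble(t = sign(mean(scores_a) - mean(scores_b)) * Inf,
                  df = NA_real_, p_value = 0,
                  mean_a = mean(scores_a), mean_b = mean(scores_b)))
  }
  tt <- t.test(scores_a, scores_b, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(scores_a), mean_b = mean(scores_b))
}
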