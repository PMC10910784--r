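# Satellite-retrotransposon interplay: LTR-pair divergence and insertion-time
# dating, satellite identity near CRM insertions versus array interiors, and
# the per-window LTR-density vs satellite-identity relationship.

#' Divergence between the two LTRs of an element
#'
#' Global alignment of the 5' and 3' LTR; the raw p-distance is mismatches /
#' aligned (non-gap) columns. The JC69 correction
#' `K = -(3/4) * log(1 - (4/3) * p)` is the default, appropriate for young
#' elements and numerically close to raw below K ~ 0.05.
#'
#' @param ltr5,ltr3 LTR sequences (character vectors, recycled pairwise).
#' @param correction `"JC69"` (default) or `"none"`.
#' @return Numeric divergence K in substitutions/site.
#' @export
ltr_divergence <- function(ltr5, ltr3, correction = c("JC69", "none")) {
  correction <- match.arg(correction)
  n <- max(length(ltr5), length(ltr3))
  ltr5 <- rep_len(ltr5, n); ltr3 <- rep_len(ltr3, n)
  p <- vapply(seq_len(n), function(i) {
    st <- .aln_stats(ltr5[i], ltr3[i], type = "global",
                     gap_opening = 4, gap_extension = 1)
    st$mismatch / (st$match + st$mismatch)  # gaps excluded from p-distance
  }, double(1))
  if (correction == "none") return(p)
  if (any(p >= 0.75)) abort("p-distance >= 0.75: JC69 correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Insertion time of an LTR element
#'
#' The two LTRs are identical at insertion and diverge at `2 * rate` per
#' site-year, so `T = K / (2 * rate)`, reported in Mya. The default rate
#' 1.3e-8 substitutions/site/year is the standard grass clock used by
#' LTR-dating pipelines.
#'
#' @param K Divergence in substitutions/site (e.g. [ltr_divergence()]).
#' @param rate Substitution rate per site per year (> 0).
#' @return Age in millions of years.
#' @examples
#' insertion_time(0.013, 1.3e-8)  # 0.5 Mya
#' @export
insertion_time <- function(K, rate = 1.3e-8) {
  if (any(rate <= 0)) abort("rate must be > 0")
  K / (2 * rate) / 1e6
}

#' Satellite identity near CRM insertions vs array interiors
#'
#' Monomers overlapping any `[element_start - window, element_end + window)`
#' region are the "near" group; all others are "interior". Returns both
#' groups' identity values and a Welch t-test (near vs interior).
#'
#' @param monomers Monomer tibble with `chrom`, `start`, `end`, `identity`.
#' @param crms CRM annotation tibble with `chrom`, `start`, `end`.
#' @param window Adjacency window in bp on each side (default 5000).
#' @return `list(monomers, test)`: `monomers` gains a `crm_group` column
#'   (`"near"`/`"interior"`); `test` is a [group_compare()] row, or `NULL`
#'   (with a warning) if a group is empty.
#' @export
crm_adjacent_identity <- function(monomers, crms, window = 5000L) {
  monomers <- as_tibble(monomers)
  near <- rep(FALSE, nrow(monomers))
  for (i in seq_len(NROW(crms))) {
    near <- near | (monomers$chrom == crms$chrom[i] &
                      monomers$start < crms$end[i] + window &
                      monomers$end > crms$start[i] - window)
  }
  monomers <- mutate(monomers, crm_group = ifelse(near, "near", "interior"))
  a <- monomers$identity[near]
  b <- monomers$identity[!near]
  test <- if (length(a) >= 2 && length(b) >= 2) {
    group_compare(a, b)
  } else {
    warning("one adjacency group is empty or too small; statistics omitted")
    NULL
  }
  list(monomers = monomers, test = test)
}

#' Per-window LTR density versus satellite identity
#'
#' Tiles each chromosome into fixed windows, computes the fraction of window
#' bp covered by LTR annotations and the mean identity of monomers whose
#' midpoint falls in the window, keeps windows with at least `min_monomers`
#' monomers, and reports the Pearson correlation between density and
#' identity.
#'
#' @param monomers Monomer tibble (`chrom`, `start`, `end`, `identity`).
#' @param ltrs LTR annotation tibble (`chrom`, `start`, `end`).
#' @param window Window size in bp (default 100 kb).
#' @param min_monomers Minimum monomers per eligible window (default 10).
#' @return `list(windows, correlation)`: `windows` has `chrom`, `start`,
#'   `end`, `n_monomers`, `ltr_density`, `mean_identity`; `correlation` is a
#'   tibble (`r`, `p_value`, `n_windows`) or `NULL` when fewer than 3
#'   eligible windows or zero variance (with a warning).
#' @export
ltr_density_vs_identity <- function(monomers, ltrs, window = 1e5,
                                    min_monomers = 10L) {
  monomers <- as_tibble(monomers)
  out <- lapply(split(monomers, monomers$chrom), function(d) {
    ch <- d$chrom[1]
    lt <- if (NROW(ltrs)) ltrs[ltrs$chrom == ch, , drop = FALSE] else ltrs
    len <- max(d$end, if (NROW(lt)) lt$end else 0L)
    starts <- seq.int(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    cov <- if (NROW(lt)) {
      IRanges::coverage(IRanges::IRanges(lt$start + 1L, lt$end), width = len)
    } else {
      S4Vectors::Rle(0L, len)
    }
    covered <- IRanges::viewSums(IRanges::Views(
      cov > 0, start = starts + 1L, end = ends))
    mid <- (d$start + d$end) %/% 2L
    wi <- findInterval(mid, starts)
    tibble(chrom = ch, start = starts, end = ends,
           n_monomers = tabulate(wi, nbins = length(starts)),
           ltr_density = as.numeric(covered) / (ends - starts),
           mean_identity = as.numeric(tapply(d$identity, factor(wi, levels = seq_along(starts)), mean)))
  })
  windows <- dplyr::bind_rows(out)
  eligible <- filter(windows, .data$n_monomers >= min_monomers)
  correlation <- NULL
  if (nrow(eligible) < 3) {
    warning("fewer than 3 eligible windows; correlation omitted")
  } else if (sd(eligible$mean_identity) == 0 || sd(eligible$ltr_density) == 0) {
    warning("zero variance in density or identity; correlation undefined")
  } else {
    ct <- cor.test(eligible$ltr_density, eligible$mean_identity,
                   method = "pearson")
    correlation <- tibble(r = unname(ct$estimate), p_value = ct$p.value,
                          n_windows = nrow(eligible))
  }
  list(windows = windows, correlation = correlation)
}
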