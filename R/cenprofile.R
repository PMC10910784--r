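# CENH3 enrichment profiling: binned coverage, log2(ChIP/Input) tracks,
# centromere calling (threshold-and-merge, maximal summed signal), enrichment
# level, centromeric repeat-cluster classification, occupancy/identity
# quantile groups, metaprofiles, and within-monomer phasing.

#' Bin coverage along a chromosome
#'
#' Per-bin mean depth from fragment intervals or a per-base depth vector. The
#' terminal partial bin is averaged over its true width.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, 0-based half-open,
#'   sorted by start within chromosome) or a numeric per-base depth vector
#'   (single unnamed chromosome `"chr"`).
#' @param bin_size Bin width in bp.
#' @param chrom_length Optional named vector of chromosome lengths (defaults
#'   to the maximum interval end / vector length).
#' @return Tibble `chrom`, `start`, `end`, `depth`.
#' @export
bin_coverage <- function(x, bin_size, chrom_length = NULL) {
  if (is.numeric(x) && is.null(dim(x))) {
    x <- tibble(chrom = "chr", pos = seq_along(x) - 1L, depth = as.numeric(x))
    per_base <- TRUE
  } else {
    per_base <- FALSE
    x <- as_tibble(x)
  }
  lookup_len <- function(ch, fallback) {
    len <- unname(chrom_length[ch])
    if (length(len) != 1 || is.na(len)) fallback else len
  }
  out <- lapply(split(x, x$chrom), function(d) {
    ch <- d$chrom[1]
    if (per_base) {
      len <- lookup_len(ch, nrow(d))
      cov <- S4Vectors::Rle(d$depth)
    } else {
      if (is.unsorted(d$start)) abort("intervals must be sorted by start")
      len <- lookup_len(ch, max(d$end))
      cov <- IRanges::coverage(IRanges::IRanges(d$start + 1L, d$end),
                               width = len)
    }
    starts <- seq.int(0L, len - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    v <- IRanges::Views(cov, start = starts + 1L, end = ends)
    tibble(chrom = ch, start = starts, end = ends,
           depth = IRanges::viewSums(v) / (ends - starts))
  })
  dplyr::bind_rows(out)
}

#' log2(ChIP/Input) enrichment track
#'
#' Joins two binned coverage tracks on their common grid and computes
#' `log2((chip + p) / (input + p))`. When library sizes are supplied, each
#' track is first rescaled to their common mean so the ratio is invariant to
#' sequencing depth; the pseudocount `p` keeps every bin finite.
#'
#' @param chip,input Binned tracks from [bin_coverage()] (identical grids).
#' @param pseudocount Pseudocount in depth units (default 0.5).
#' @param lib_sizes Optional numeric `c(chip, input)` library sizes.
#' @return Track tibble: `chrom`, `start`, `end`, `chip`, `input`,
#'   `log2_ratio`.
#' @export
log2_ratio <- function(chip, input, pseudocount = 0.5, lib_sizes = NULL) {
  if (nrow(chip) != nrow(input) ||
      !all(chip$chrom == input$chrom & chip$start == input$start &
             chip$end == input$end)) {
    abort("chip and input tracks are not on the same bin grid")
  }
  cd <- chip$depth
  id <- input$depth
  if (!is.null(lib_sizes)) {
    target <- mean(lib_sizes)
    cd <- cd * target / lib_sizes[1]
    id <- id * target / lib_sizes[2]
  }
  tibble(chrom = chip$chrom, start = chip$start, end = chip$end,
         chip = cd, input = id,
         log2_ratio = log2((cd + pseudocount) / (id + pseudocount)))
}

#' Call the centromere of each chromosome from an enrichment track
#'
#' Operationalizes "the region of highest CENH3 intensity": bins at or above
#' `threshold` are merged when separated by at most `merge_gap` bp, and the
#' merged region with the maximal summed log2 ratio is returned as the
#' chromosome's (monocentric) centromere. Secondary regions can be inspected
#' with `all_regions = TRUE`.
#'
#' @param track Tibble from [log2_ratio()].
#' @param threshold Minimum per-bin log2 ratio (default 1).
#' @param merge_gap Maximum gap in bp between merged bins (default 100 kb).
#' @param all_regions Return every merged region ranked by summed signal.
#' @return Tibble: `chrom`, `start`, `end`, `n_bins`, `sum_log2`,
#'   `mean_log2`. Zero rows if no bin passes.
#' @export
call_centromere <- function(track, threshold = 1, merge_gap = 1e5,
                            all_regions = FALSE) {
  out <- lapply(split(track, track$chrom), function(d) {
    d <- dplyr::arrange(d, .data$start)
    sel <- which(d$log2_ratio >= threshold)
    if (length(sel) == 0) return(NULL)
    grp <- cumsum(c(TRUE, d$start[sel[-1]] - d$end[sel[-length(sel)]] > merge_gap))
    regions <- tibble(
      chrom = d$chrom[1],
      start = as.numeric(tapply(d$start[sel], grp, min)),
      end = as.numeric(tapply(d$end[sel], grp, max)),
      n_bins = unname(as.integer(table(grp))),
      sum_log2 = as.numeric(tapply(d$log2_ratio[sel], grp, sum)),
      mean_log2 = as.numeric(tapply(d$log2_ratio[sel], grp, mean))
    )
    regions <- dplyr::arrange(regions, dplyr::desc(.data$sum_log2))
    if (all_regions) regions else regions[1, , drop = FALSE]
  })
  dplyr::bind_rows(out)
}

#' Centromeric enrichment level
#'
#' Ratio of the mean ChIP depth inside the centromere call to the genome-wide
#' mean ChIP depth (both width-weighted over bins). Invariant to scaling all
#' depths by a constant.
#'
#' @param call One-row centromere call (`chrom`, `start`, `end`).
#' @param chip_track Binned ChIP depth tibble from [bin_coverage()].
#' @return Dimensionless enrichment level.
#' @export
enrichment_level <- function(call, chip_track) {
  w <- chip_track$end - chip_track$start
  gw <- sum(chip_track$depth * w) / sum(w)
  if (gw == 0) abort("genome-wide mean depth is zero")
  d <- filter(chip_track, .data$chrom == call$chrom[1])
  ov <- pmax(0, pmin(d$end, call$end[1]) - pmax(d$start, call$start[1]))
  if (sum(ov) == 0) abort("call does not overlap the track")
  (sum(d$depth * ov) / sum(ov)) / gw
}

#' Classify repeat clusters as centromeric
#'
#' A cluster is centromeric when its normalized CENH3/Input read ratio is
#' strictly greater than `ratio_min` (2.6) and it occupies strictly more than
#' `fraction_min` (0.5%) of the genome.
#'
#' @param clusters Tibble with either a `ratio` column or `chip_count` and
#'   `input_count` (library-normalized internally), plus `genome_fraction`.
#' @param ratio_min,fraction_min Strict thresholds.
#' @return `clusters` with `ratio` and logical `is_centromeric`.
#' @export
classify_clusters <- function(clusters, ratio_min = 2.6, fraction_min = 0.005) {
  if (!"ratio" %in% names(clusters)) {
    clusters <- mutate(
      clusters,
      ratio = (.data$chip_count / sum(.data$chip_count)) /
        (.data$input_count / sum(.data$input_count))
    )
  }
  mutate(clusters,
         is_centromeric = .data$ratio > ratio_min &
           .data$genome_fraction > fraction_min)
}

#' Rank-based quantile groups
#'
#' Splits values into `n_groups` equal-count groups ordered by decreasing (or
#' increasing) value; group sizes differ by at most one and ties keep stable
#' input order. Used to band satellites by CENH3 occupancy or identity.
#'
#' @param values Numeric vector.
#' @param n_groups Number of groups (default 5).
#' @param decreasing Group 1 holds the largest values (default `TRUE`).
#' @return Integer group labels (1 = first group).
#' @export
quantile_groups <- function(values, n_groups = 5L, decreasing = TRUE) {
  n <- length(values)
  if (n_groups < 2) abort("n_groups must be >= 2")
  if (n < n_groups) abort("fewer values than groups")
  ord <- if (decreasing) order(-values) else order(values)  # stable
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- integer(n)
  labels[ord] <- rep.int(seq_len(n_groups), sizes)
  labels
}

# Exact mean of a binned step function over [a, b) via its cumulative
# integral; segments outside the track are clamped.
.segment_means <- function(bins, a, b) {
  w <- bins$end - bins$start
  cum <- c(0, cumsum(bins$depth_like * w))
  lo <- bins$start[1]; hi <- bins$end[nrow(bins)]
  integral_at <- function(x) {
    x <- pmin(pmax(x, lo), hi)
    i <- findInterval(x, bins$start)
    cum[i] + (x - bins$start[i]) * bins$depth_like[i]
  }
  a2 <- pmin(pmax(a, lo), hi); b2 <- pmin(pmax(b, lo), hi)
  out <- ifelse(b2 > a2, (integral_at(b) - integral_at(a)) / (b2 - a2), NA_real_)
  out
}

#' Metaprofile of enrichment over a set of features
#'
#' Each feature body is rescaled to `body_bins` equal segments; flanks keep
#' the native track bin resolution. Segment values are exact means of the
#' binned track (step function) over the segment, minus-strand features are
#' flipped, and the profile is the per-segment mean over features.
#'
#' @param track Enrichment track ([log2_ratio()] output; the `log2_ratio`
#'   column is profiled).
#' @param features Tibble `chrom`, `start`, `end` and optional `strand`.
#' @param flank Flank size in bp on each side (default 2000).
#' @param body_bins Number of body segments (default 100).
#' @return Tibble `position` (1..up+body+down), `section`
#'   (upstream/body/downstream), `mean_signal`; attribute `n_features`.
#' @export
metaprofile <- function(track, features, flank = 2000L, body_bins = 100L) {
  if (NROW(features) == 0) abort("at least one feature required")
  sig <- .col(track, "log2_ratio") %||% .col(track, "depth")
  track <- mutate(track, depth_like = sig)
  bin_w <- track$end[1] - track$start[1]
  flank_bins <- max(0L, as.integer(round(flank / bin_w)))
  strands <- .col(features, "strand") %||% rep("+", nrow(features))
  by_chrom <- split(track, track$chrom)

  prof <- matrix(NA_real_, nrow(features), 2L * flank_bins + body_bins)
  for (i in seq_len(nrow(features))) {
    d <- by_chrom[[features$chrom[i]]]
    if (is.null(d)) next
    s <- features$start[i]; e <- features$end[i]
    up <- if (flank_bins > 0) {
      edges <- s - flank + (0:flank_bins) * bin_w
      .segment_means(d, edges[-length(edges)], edges[-1])
    } else numeric(0)
    be <- s + (0:body_bins) * (e - s) / body_bins
    body <- .segment_means(d, be[-(body_bins + 1)], be[-1])
    down <- if (flank_bins > 0) {
      edges <- e + (0:flank_bins) * bin_w
      .segment_means(d, edges[-length(edges)], edges[-1])
    } else numeric(0)
    v <- c(up, body, down)
    if (strands[i] == "-") v <- rev(v)
    prof[i, ] <- v
  }
  out <- tibble(
    position = seq_len(ncol(prof)),
    section = rep(c("upstream", "body", "downstream"),
                  c(flank_bins, body_bins, flank_bins)),
    mean_signal = colMeans(prof, na.rm = TRUE)
  )
  attr(out, "n_features") <- nrow(features)
  out
}

#' Within-monomer phase profile of ChIP fragment midpoints
#'
#' Maps each fragment midpoint falling inside a monomer to its strand-aware
#' offset within that monomer and tabulates the density over offsets
#' `0..L-1`. The peak offset is the argmax of a small circular moving average
#' (window `2*smooth+1`), reported on the monomer coordinate.
#'
#' @param midpoints Numeric vector of fragment midpoints (0-based) on the
#'   monomers' chromosome.
#' @param monomers Monomer tibble (sorted, non-overlapping, one chromosome).
#' @param monomer_length Offset range L (default: median monomer length).
#' @param smooth Half-width of the circular smoothing window (default 2 bp).
#' @return `list(profile, peak_offset, n_fragments)` of class
#'   `pancent_phase`; `profile` is a tibble `offset`, `count`, `density`.
#' @export
phase_profile <- function(midpoints, monomers, monomer_length = NULL,
                          smooth = 2L) {
  monomers <- dplyr::arrange(as_tibble(monomers), .data$start)
  L <- as.integer(monomer_length %||% stats::median(monomers$end - monomers$start))
  idx <- findInterval(midpoints, monomers$start)
  ok <- idx >= 1 & midpoints < monomers$end[pmax(idx, 1L)]
  idx <- idx[ok]
  mid <- midpoints[ok]
  if (length(mid) == 0) abort("no fragment midpoints fall inside monomers")
  off <- ifelse(monomers$strand[idx] == "-",
                monomers$end[idx] - 1L - mid,
                mid - monomers$start[idx])
  off <- off[off >= 0 & off < L]
  counts <- tabulate(off + 1L, nbins = L)
  dens <- counts / sum(counts)
  if (smooth > 0) {
    k <- 2L * smooth + 1L
    ext <- c(dens[(L - smooth + 1L):L], dens, dens[1:smooth])
    sm <- stats::filter(ext, rep(1 / k, k), sides = 2)[(smooth + 1L):(smooth + L)]
  } else {
    sm <- dens
  }
  structure(
    list(profile = tibble(offset = 0:(L - 1L), count = counts, density = dens,
                          smoothed = as.numeric(sm)),
         peak_offset = which.max(sm) - 1L,
         n_fragments = sum(counts)),
    class = "pancent_phase"
  )
}

#' @export
print.pancent_phase <- function(x, ...) {
  cat(sprintf("<pancent_phase> %d fragments, peak offset %d bp\n",
              x$n_fragments, x$peak_offset))
  invisible(x)
}
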