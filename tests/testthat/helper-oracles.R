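# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals.

oracle_filter_fragments <- function(lengths, min_len = 146, max_len = 166) {
  lengths[lengths >= min_len & lengths <= max_len]
}

oracle_classify <- function(ratio, fraction, ratio_min = 2.6,
                            fraction_min = 0.005) {
  ratio > ratio_min & fraction > fraction_min
}

oracle_duplicated_within <- function(chrom, seqs) {
  n <- length(seqs)
  dup <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && chrom[i] == chrom[j] && seqs[i] == seqs[j]) dup[i] <- TRUE
    }
  }
  dup
}

oracle_shared <- function(a, b) {
  hit <- logical(length(a))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) if (a[i] == b[j]) hit[i] <- TRUE
  }
  mean(hit)
}

# per-base accumulation of mean depth in bins
oracle_bin_coverage <- function(starts, ends, bin_size, len) {
  depth <- numeric(len)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):ends[i]
    depth[idx] <- depth[idx] + 1
  }
  bs <- seq(0, len - 1, by = bin_size)
  be <- pmin(bs + bin_size, len)
  vapply(seq_along(bs), function(k) mean(depth[(bs[k] + 1):be[k]]), double(1))
}

# per-base metaprofile: value of the bin covering each base, averaged over
# per-feature scaled segments
oracle_metaprofile <- function(track, features, flank, body_bins) {
  bin_w <- track$end[1] - track$start[1]
  val_at <- function(pos) {  # pos is 0-based base index
    i <- findInterval(pos, track$start)
    track$log2_ratio[i]
  }
  flank_bins <- round(flank / bin_w)
  seg_mean <- function(a, b) {
    xs <- seq(floor(a), ceiling(b) - 1)
    xs <- xs[xs + 1 > a & xs < b]  # bases [xs, xs+1) overlapping [a, b)
    w <- pmin(xs + 1, b) - pmax(xs, a)
    sum(val_at(xs) * w) / sum(w)
  }
  prof <- matrix(NA_real_, nrow(features), 2 * flank_bins + body_bins)
  for (f in seq_len(nrow(features))) {
    s <- features$start[f]; e <- features$end[f]
    v <- c(
      vapply(seq_len(flank_bins), function(k)
        seg_mean(s - flank + (k - 1) * bin_w, s - flank + k * bin_w), double(1)),
      vapply(seq_len(body_bins), function(b)
        seg_mean(s + (b - 1) * (e - s) / body_bins,
                 s + b * (e - s) / body_bins), double(1)),
      vapply(seq_len(flank_bins), function(k)
        seg_mean(e + (k - 1) * bin_w, e + k * bin_w), double(1))
    )
    st <- if ("strand" %in% names(features)) features$strand[f] else "+"
    if (st == "-") v <- rev(v)
    prof[f, ] <- v
  }
  colMeans(prof)
}

# all-substring tandem scan for HORs on a label vector
oracle_find_hors <- function(labels, max_unit = 20, min_copies = 2) {
  n <- length(labels)
  is_prim <- function(u) {
    lu <- length(u)
    if (lu == 1) return(TRUE)
    for (d in seq_len(lu %/% 2)) {
      if (lu %% d == 0 && all(u == rep_len(u[seq_len(d)], lu))) return(FALSE)
    }
    TRUE
  }
  cand <- list()
  for (u in seq_len(min(max_unit, n %/% min_copies))) {
    i <- 1
    while (i + u <= n) {
      # maximal periodic stretch starting at i
      j <- i
      while (j + u <= n && labels[j + u] == labels[j]) j <- j + 1
      span <- j - i + u
      copies <- span %/% u
      if (copies >= min_copies && is_prim(labels[i:(i + u - 1)])) {
        cand[[length(cand) + 1]] <- data.frame(
          unit = paste(labels[i:(i + u - 1)], collapse = "-"),
          unit_length = u, copy_number = copies,
          start = i - 1, end = i - 1 + copies * u
        )
      }
      i <- if (j > i) j else i + 1
    }
  }
  if (!length(cand)) return(NULL)
  do.call(rbind, cand)
}
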