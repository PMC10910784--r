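# Simplified higher-order repeat (HOR) mining over a monomer-variant
# alphabet: monomers are labelled into variant classes by greedy single-pass
# clustering, then tandem repetitions of primitive label tuples are scanned
# and ranked by copy number.

#' Label monomers into variant classes
#'
#' Greedy single-pass clustering: each monomer joins the first existing
#' representative it matches with identity at or above the threshold,
#' otherwise it founds a new label. Labels (`A`, `B`, ...) are assigned in
#' first-occurrence order, so the result is deterministic given input order.
#' (A deliberate simplification of full agglomerative HOR-monomer clustering:
#' linear-time and adequate at satellite divergence levels.)
#'
#' @param monomers Monomer tibble (needs `sequence`) or character vector.
#' @param identity_threshold Minimum identity to a representative (default
#'   0.95).
#' @return `list(labels, representatives, identity_threshold)`: `labels` is a
#'   character vector per monomer; `representatives` a tibble
#'   (`label`, `sequence`).
#' @export
label_monomers <- function(monomers, identity_threshold = 0.95) {
  seqs <- if (is.data.frame(monomers)) monomers$sequence else monomers
  if (length(seqs) == 0) abort("no monomers to label")
  reps <- character(0)
  labels <- character(length(seqs))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    hit <- cache[[s]] %||% 0L
    if (hit == 0L) {
      for (j in seq_along(reps)) {
        if (identity_threshold <= 0 ||
            .pair_identity(s, reps[j]) >= identity_threshold) {
          hit <- j
          break
        }
      }
      if (hit == 0L) {
        reps <- c(reps, s)
        hit <- length(reps)
      }
      cache[[s]] <- hit
    }
    labels[i] <- .label_name(hit)
  }
  list(labels = labels,
       representatives = tibble(label = .label_name(seq_along(reps)),
                                sequence = reps),
       identity_threshold = identity_threshold)
}

# A, B, ..., Z, AA, AB, ... (base-26 label names)
.label_name <- function(i) {
  vapply(i, function(k) {
    out <- ""
    while (k > 0) {
      out <- paste0(LETTERS[(k - 1) %% 26 + 1], out)
      k <- (k - 1) %/% 26
    }
    out
  }, character(1))
}

.pair_identity <- function(a, b) {
  st <- .aln_stats(a, b, type = "global")
  with(st, match / (match + mismatch + ins + del))
}

#' Find ranked higher-order repeats in a label string
#'
#' Scans every primitive unit length `u <= max_unit` for maximal tandem runs
#' with at least `min_copies` copies (unit length 1 = monomic expansion).
#' Candidates are ranked by copy number, ties broken by longer unit and then
#' leftmost position; overlapping reports are resolved greedily by rank.
#'
#' @param labels Character vector of monomer variant labels of one array (or
#'   the `labels` element of [label_monomers()]).
#' @param max_unit Maximum unit length in monomers (default 20).
#' @param min_copies Minimum tandem copies (default 2).
#' @param top Number of top-ranked HORs returned (default 5; `Inf` for all).
#' @return Tibble `rank`, `unit` (labels joined by `-`), `unit_length`,
#'   `copy_number`, `start`, `end` (0-based monomer indices, half-open).
#' @export
find_hors <- function(labels, max_unit = 20L, min_copies = 2L, top = 5L) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  n <- length(labels)
  empty <- tibble(rank = integer(0), unit = character(0),
                  unit_length = integer(0), copy_number = integer(0),
                  start = integer(0), end = integer(0))
  if (n == 0) return(empty)
  cand <- list()
  for (u in seq_len(min(max_unit, n %/% min_copies))) {
    m <- labels[seq_len(n - u)] == labels[seq_len(n - u) + u]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- r$lengths[k]               # matched positions
      span <- run + u                   # bp of the periodic stretch, in monomers
      copies <- span %/% u
      if (copies < min_copies) next
      s0 <- starts[k] - 1L              # 0-based start of the periodic stretch
      unit <- labels[(s0 + 1L):(s0 + u)]
      if (!.is_primitive(unit)) next
      cand[[length(cand) + 1L]] <- tibble(
        unit = paste(unit, collapse = "-"), unit_length = u,
        copy_number = copies, start = s0, end = s0 + copies * u
      )
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- dplyr::bind_rows(cand)
  cand <- dplyr::arrange(cand, dplyr::desc(.data$copy_number),
                         dplyr::desc(.data$unit_length), .data$start)
  keep <- logical(nrow(cand))
  taken <- integer(0)
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):cand$end[i]
    if (!any(span %in% taken)) {
      keep[i] <- TRUE
      taken <- c(taken, span)
    }
    if (sum(keep) >= top) break
  }
  out <- cand[keep, , drop = FALSE]
  mutate(out, rank = row_number(), .before = 1)
}

# a unit is primitive if it is not a repetition of a shorter unit
.is_primitive <- function(unit) {
  u <- length(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u %/% 2)) {
    if (u %% d == 0L && all(unit == rep_len(unit[seq_len(d)], u))) return(FALSE)
  }
  TRUE
}
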