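# Read-based satellite harvesting: merge overlapping paired-end reads into
# fragments, keep monomer-sized fragments (146-166 bp), and assign them to a
# family consensus by local alignment with a BLAST-style E-value cut-off.

.reads_input <- function(r1, r2) {
  if (is.data.frame(r1) && all(c("r1", "r2") %in% names(r1))) {
    q <- .col(r1, "qual") %||% strrep("I", nchar(r1$r1))
    return(list(r1 = r1$r1, r2 = r1$r2, q1 = q, q2 = q,
                id = .col(r1, "id") %||% paste0("pair", seq_len(nrow(r1)))))
  }
  read_fq <- function(p) {
    # suppressed: readQualityScaledDNAStringSet warns about dropping the
    # mcols it creates itself from the FASTQ qualities
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(p))
    list(seq = as.character(x), qual = as.character(Biostrings::quality(x)),
         id = sub("\\s.*", "", names(x)))
  }
  if (is.character(r1) && length(r1) == 1 && file.exists(r1)) {
    a <- read_fq(r1); b <- read_fq(r2)
    return(list(r1 = a$seq, r2 = b$seq, q1 = a$qual, q2 = b$qual, id = a$id))
  }
  list(r1 = as.character(r1), r2 = as.character(r2),
       q1 = strrep("I", nchar(r1)), q2 = strrep("I", nchar(r2)),
       id = paste0("pair", seq_along(r1)))
}

#' Merge overlapping read pairs into fragments
#'
#' Mate 2 is reverse complemented and slid over the 3' end of mate 1; the
#' overlap with the lowest mismatch rate (ties to the longest overlap) wins.
#' Pairs whose best overlap is shorter than `min_overlap` or noisier than
#' `max_mismatch_rate` are dropped. Disagreeing overlap bases are resolved by
#' the higher base quality.
#'
#' @param r1,r2 Mates in consistent order: character vectors, FASTQ paths, or
#'   (passing only `r1`) a reads tibble with columns `r1`, `r2`, `qual` as
#'   produced by [simulate_reads()].
#' @param min_overlap Minimum overlap in bp (default 10).
#' @param max_mismatch_rate Maximum mismatch rate in the overlap (default 0.1).
#' @param source Optional label (`"ChIP"`, `"Input"`, `"WGS"`) carried along.
#' @return Fragment tibble: `id`, `sequence`, `length`, `overlap`,
#'   `mismatch_rate`, `source`. One row per merged pair.
#' @export
merge_pairs <- function(r1, r2 = NULL, min_overlap = 10L,
                        max_mismatch_rate = 0.1, source = NA_character_) {
  x <- .reads_input(r1, r2)
  if (length(x$r1) != length(x$r2)) abort("mate count mismatch between r1 and r2")
  r2rc <- dna_revcomp(x$r2)
  q2rc <- vapply(strsplit(x$q2, "", fixed = TRUE),
                 function(ch) paste(rev(ch), collapse = ""), character(1))
  m <- .merge_overlap_cpp(x$r1, r2rc, x$q1, q2rc,
                          as.integer(min_overlap), max_mismatch_rate)
  keep <- !is.na(m$length)
  tibble(id = x$id[keep], sequence = m$merged[keep], length = m$length[keep],
         overlap = m$overlap[keep], mismatch_rate = m$mismatch_rate[keep],
         source = source)
}

#' Keep monomer-sized fragments
#'
#' Retains fragments whose length is within `[min_len, max_len]`, bounds
#' inclusive — the 146-166 bp window that captures single-monomer
#' (CENH3-nucleosome-sized) fragments.
#'
#' @param fragments Fragment tibble with a `length` column (computed from
#'   `sequence` if absent).
#' @param min_len,max_len Inclusive bounds in bp.
#' @return The filtered tibble.
#' @export
filter_fragments <- function(fragments, min_len = 146L, max_len = 166L) {
  if (!"length" %in% names(fragments)) {
    fragments <- mutate(fragments, length = nchar(.data$sequence))
  }
  filter(fragments, .data$length >= min_len, .data$length <= max_len)
}

# Karlin-Altschul lambda for a match/mismatch scoring scheme under uniform
# base composition; K uses the blastn tabulated value for +1/-2.
.ka_lambda <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-10)$root
}
.KA_K <- 0.621

#' Assign fragments to a family consensus by local alignment
#'
#' Each fragment is aligned locally (both strands) against each consensus
#' concatenated to itself, so matches spanning the monomer phase junction are
#' scored in full. Scoring is +1/-2 with affine gaps (open 5, extend 2), and
#' the best score is converted to an E-value with Karlin-Altschul statistics
#' over a search space of fragment length x total consensus length x 2
#' strands. Fragments with best E-value at most `evalue_max` get the
#' best-scoring consensus; ties break by higher identity, then consensus
#' order.
#'
#' @param fragments Fragment tibble (needs `sequence`).
#' @param consensi One or more consensus records ([consensus_repeat()] rows
#'   bound together) or a named character vector.
#' @param evalue_max E-value cut-off (default 1e-5).
#' @return The fragment tibble with `assigned_consensus` (NA if unassigned)
#'   and `evalue` columns.
#' @export
assign_fragments <- function(fragments, consensi, evalue_max = 1e-5) {
  if (!is.data.frame(consensi)) {
    nm <- names(consensi) %||% paste0("cons", seq_along(consensi))
    consensi <- dplyr::bind_rows(purrr::map2(nm, unname(consensi), consensus_repeat))
  }
  if (nrow(consensi) < 1) abort("at least one consensus required")
  seqs <- fragments$sequence
  n <- length(seqs)
  if (n == 0) {
    return(mutate(fragments, assigned_consensus = character(0), evalue = double(0)))
  }
  rc <- dna_revcomp(seqs)
  sub_mat <- .nuc_mat(1, -2)
  score_vs <- function(qry, cons_seq) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(qry),
      subject = Biostrings::DNAString(paste0(cons_seq, cons_seq)),
      type = "local", substitutionMatrix = sub_mat,
      gapOpening = 5, gapExtension = 2
    )
    list(score = BiocGenerics::score(aln), pid = Biostrings::pid(aln))
  }
  best_score <- matrix(-Inf, n, nrow(consensi))
  best_pid <- matrix(0, n, nrow(consensi))
  for (ci in seq_len(nrow(consensi))) {
    fw <- score_vs(seqs, consensi$sequence[ci])
    rv <- score_vs(rc, consensi$sequence[ci])
    use_rv <- rv$score > fw$score
    best_score[, ci] <- ifelse(use_rv, rv$score, fw$score)
    best_pid[, ci] <- ifelse(use_rv, rv$pid, fw$pid)
  }
  # best consensus: score, then identity, then consensus order
  ord_key <- best_score * 1e6 + best_pid
  pick <- max.col(ord_key, ties.method = "first")
  s_best <- best_score[cbind(seq_len(n), pick)]
  lambda <- .ka_lambda(1, -2)
  space <- nchar(seqs) * sum(consensi$length) * 2
  evalue <- .KA_K * space * exp(-lambda * s_best)
  mutate(fragments,
         assigned_consensus = ifelse(evalue <= evalue_max,
                                     consensi$name[pick], NA_character_),
         evalue = evalue)
}
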