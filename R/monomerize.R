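# Consensus-anchored decomposition of assembled sequence into satellite
# monomers. Candidate array regions are seeded with exact consensus k-mers on
# both strands, then each region is segmented into monomer units by a
# wraparound edit-distance DP (compiled), which cuts every boundary at
# consensus position 0 (canonical phase). This is the assembly-side extraction
# route (the role LASTZ played in the original analyses).

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    g <- as.character(Biostrings::readDNAStringSet(genome))
    names(g) <- sub("\\s.*", "", names(g))
  } else {
    nm <- names(genome)
    g <- toupper(as.character(genome))
    names(g) <- nm
  }
  if (is.null(names(g))) names(g) <- paste0("seq", seq_along(g))
  g
}

.as_consensus <- function(consensus, canonicalize = TRUE) {
  if (is.data.frame(consensus)) return(consensus)
  consensus_repeat("cons", consensus, canonicalize = canonicalize)
}

# Exact k-mer seed starts (1-based) of a circular consensus in one sequence.
.seed_starts <- function(seq, cons, k) {
  d <- paste0(cons, cons)
  kmers <- unique(substring(d, seq_len(nchar(cons)), seq_len(nchar(cons)) + k - 1L))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(seq))
  sort(BiocGenerics::start(unlist(hits)))
}

# Cluster sorted seed starts into candidate regions (0-based half-open).
.seed_regions <- function(starts, k, L, chrom_len, gap = 2000L) {
  if (length(starts) == 0) return(tibble(start = integer(0), end = integer(0)))
  brk <- c(0L, which(diff(starts) > gap), length(starts))
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    s <- starts[(brk[i] + 1L):brk[i + 1L]]
    tibble(start = max(0L, min(s) - 1L - L), end = min(chrom_len, max(s) - 1L + k + L))
  })
  dplyr::bind_rows(out)
}

#' Decompose genomic sequence into satellite monomers
#'
#' Finds satellite arrays matching a family consensus and splits them into
#' individual monomer records with boundaries at the consensus canonical
#' phase. Contiguous same-strand monomers separated by at most `max_gap` bp
#' share one `array_id` (larger gaps — e.g. a CRM insertion — terminate the
#' array).
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param consensus A [consensus_repeat()] tibble or a DNA string (stored in
#'   canonical rotation).
#' @param min_identity Minimum identity to the consensus for a monomer to be
#'   reported (default 0.6).
#' @param both_strands Search the reverse strand too (default `TRUE`).
#' @param max_gap Maximum gap (bp) joining monomers into one array (default
#'   2000).
#' @param seed_k Seed k-mer length for locating candidate regions.
#' @return Tibble of monomer records: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `sequence` (as read on the annotated strand),
#'   `consensus_name`, `identity`, `array_id`; sorted and non-overlapping
#'   within each chromosome.
#' @export
decompose_array <- function(genome, consensus, min_identity = 0.6,
                            both_strands = TRUE, max_gap = 2000L,
                            seed_k = 12L) {
  genome <- .as_genome(genome)
  cons <- .as_consensus(consensus)
  if (cons$length < 50) abort("consensus shorter than 50 bp")
  if (min_identity <= 0 || min_identity > 1) abort("min_identity must be in (0, 1]")
  L <- cons$length

  one_strand <- function(chrom, seq, strand) {
    text <- if (strand == "-") dna_revcomp(seq) else seq
    n <- nchar(text)
    starts <- .seed_starts(text, cons$sequence, seed_k)
    regions <- .seed_regions(starts, seed_k, L, n, gap = max_gap)
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      r0 <- regions$start[i]; r1 <- regions$end[i]
      seg <- .wrap_decompose_cpp(substring(text, r0 + 1L, r1), cons$sequence)
      seg <- as_tibble(seg)
      seg$identity <- with(seg, match / pmax(1L, match + mismatch + ins + del))
      seg <- seg[seg$identity >= min_identity &
                   (seg$end - seg$start) >= 0.5 * L &
                   (seg$end - seg$start) <= 1.5 * L, , drop = FALSE]
      if (nrow(seg) == 0) return(NULL)
      if (strand == "+") {
        tibble(chrom = chrom, start = r0 + seg$start, end = r0 + seg$end,
               strand = strand,
               sequence = substring(text, r0 + seg$start + 1L, r0 + seg$end),
               identity = seg$identity)
      } else {
        # text coordinates are on the reverse strand of [0, n)
        tibble(chrom = chrom, start = n - (r0 + seg$end),
               end = n - (r0 + seg$start), strand = strand,
               sequence = substring(text, r0 + seg$start + 1L, r0 + seg$end),
               identity = seg$identity)
      }
    })
    dplyr::bind_rows(rows)
  }

  out <- list()
  for (chrom in names(genome)) {
    res <- one_strand(chrom, genome[[chrom]], "+")
    if (both_strands) res <- dplyr::bind_rows(res, one_strand(chrom, genome[[chrom]], "-"))
    if (NROW(res) == 0) next
    res <- dplyr::arrange(res, .data$start, .data$end)
    res <- .drop_overlaps(res)
    out[[chrom]] <- res
  }
  res <- dplyr::bind_rows(out)
  if (NROW(res) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), sequence = character(),
                  consensus_name = character(), identity = double(),
                  array_id = character()))
  }
  res$consensus_name <- cons$name
  res <- dplyr::group_by(res, .data$chrom)
  res <- mutate(res, array_id = paste0(
    .data$chrom, "_arr",
    cumsum(dplyr::coalesce(
      .data$start - lag(.data$end) > max_gap | .data$strand != lag(.data$strand),
      TRUE))
  ))
  res <- ungroup(res)
  select(res, "chrom", "start", "end", "strand", "sequence",
         "consensus_name", "identity", "array_id")
}

# Resolve rare overlapping records (opposite-strand edge effects) by keeping
# the higher-identity record.
.drop_overlaps <- function(res) {
  keep <- rep(TRUE, nrow(res))
  last_end <- -1L
  last_i <- 0L
  for (i in seq_len(nrow(res))) {
    if (res$start[i] < last_end) {
      if (res$identity[i] > res$identity[last_i]) {
        keep[last_i] <- FALSE
      } else {
        keep[i] <- FALSE
        next
      }
    }
    last_end <- res$end[i]
    last_i <- i
  }
  res[keep, , drop = FALSE]
}

#' Rebuild a consensus from monomer records by majority rule
#'
#' Center-star consensus: monomers are globally aligned to a reference copy
#' and a majority base is taken per reference column (gaps compete; ties break
#' by fixed base order A < C < G < T < gap). Two passes are used — the first
#' majority string selects the best-supported reference, protecting against a
#' reference copy that carries an indel. The result is returned in canonical
#' rotation.
#'
#' @param monomers Monomer tibble (needs a `sequence` column) or character
#'   vector of at least 2 sequences.
#' @param name Name for the rebuilt consensus.
#' @return A [consensus_repeat()] tibble.
#' @export
build_consensus <- function(monomers, name = "consensus") {
  seqs <- if (is.data.frame(monomers)) monomers$sequence else monomers
  if (length(seqs) < 2) abort("need at least 2 monomers")

  majority_vs <- function(ref) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(seqs),
      subject = Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = .nuc_mat(),
      gapOpening = 1, gapExtension = 1
    )
    mat <- Biostrings::consensusMatrix(Biostrings::aligned(aln))
    rows <- intersect(c("A", "C", "G", "T", "-"), rownames(mat))
    mat <- mat[rows, , drop = FALSE]
    best <- rows[apply(mat, 2, which.max)]
    paste(best[best != "-"], collapse = "")
  }

  lens <- nchar(seqs)
  modal_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  cand <- seqs[lens == modal_len]
  ref0 <- names(sort(table(cand), decreasing = TRUE))[1]  # most frequent copy
  m1 <- majority_vs(ref0)
  ident <- identity_to_consensus(seqs, m1)
  ref1 <- seqs[which.max(ident)]
  consensus_repeat(name, majority_vs(ref1))
}
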