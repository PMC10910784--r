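# safe column access: NULL when absent (no tibble warning)
.col <- function(d, nm) if (nm %in% names(d)) d[[nm]] else NULL

# Pairwise-alignment utilities shared by the diversity, assignment and CRM
# modules. All identity values use one denominator: matched columns divided by
# total alignment columns, so gaps count against identity.

.nuc_mat <- function(match = 1, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
}

# Align patterns against a subject and return per-alignment column counts.
# type/gap costs as in Biostrings::pairwiseAlignment (costs are positive).
.aln_stats <- function(patterns, subject, type = "global-local",
                       match = 1, mismatch = -1,
                       gap_opening = 1, gap_extension = 1) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = type, substitutionMatrix = .nuc_mat(match, mismatch),
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  ni <- Biostrings::nindel(aln)
  tibble(
    match = unname(Biostrings::nmatch(aln)),
    mismatch = unname(Biostrings::nmismatch(aln)),
    ins = unname(Biostrings::insertion(ni)[, "WidthSum"]),
    del = unname(Biostrings::deletion(ni)[, "WidthSum"]),
    score = unname(BiocGenerics::score(aln))
  )
}

#' Sequence identity of monomers to a consensus
#'
#' Identity of each monomer to the family consensus over the circularly best
#' phase: the monomer is aligned end-to-end against the doubled consensus
#' (free subject ends), so any rotation of the monomer scores equally.
#' Identity is matched columns / total alignment columns — gap columns count
#' against identity.
#'
#' @param monomers Character vector of monomer sequences, or a monomer tibble
#'   with a `sequence` column.
#' @param consensus A [consensus_repeat()] tibble or a single DNA sequence.
#' @return Numeric vector of identities in `[0, 1]`.
#' @examples
#' cons <- consensus_repeat("CentBd", strrep("ACGTT", 11))
#' identity_to_consensus(cons$sequence, cons)  # 1
#' @export
identity_to_consensus <- function(monomers, consensus) {
  if (is.data.frame(monomers)) monomers <- monomers$sequence
  cons <- if (is.data.frame(consensus)) consensus$sequence[1] else consensus
  st <- .aln_stats(monomers, paste0(cons, cons), type = "global-local")
  with(st, match / (match + mismatch + ins + del))
}

#' Count substitutions and indel runs between two sequences
#'
#' Optimal global alignment under unit costs (match 0, mismatch 1, each gap
#' column 1). Among co-optimal alignments the one with the fewest gap openings
#' is chosen, with a fixed deterministic tie-break on move order, so the
#' reported pair is reproducible. Returns the number of mismatch columns
#' (SNPs) and the number of maximal gap runs (indels) — the statistic behind
#' "19 SNPs and 1 INDEL" style consensus comparisons.
#'
#' @param a,b DNA sequences (single strings).
#' @return A one-row tibble with `n_snp`, `n_indel`, and `edit` (total cost).
#' @examples
#' count_snps_indels("ACGT", "ACGA")  # 1 SNP, 0 indels
#' count_snps_indels("ACGT", "ACG")   # 0 SNPs, 1 indel
#' @export
count_snps_indels <- function(a, b) {
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  if (n == 0L || m == 0L) abort("both sequences must be non-empty")
  W <- n + m + 1  # key = cost * W + gap_openings (lexicographic)
  INF <- Inf
  # layers: 1 diag (consume both), 2 up (gap in b), 3 left (gap in a)
  K <- array(INF, dim = c(n + 1L, m + 1L, 3L))
  P <- array(0L, dim = c(n + 1L, m + 1L, 3L))  # predecessor layer
  K[1, 1, 1] <- 0
  for (i in 1:n) { K[i + 1, 1, 2] <- i * W + 1; P[i + 1, 1, 2] <- if (i == 1L) 1L else 2L }
  for (j in 1:m) { K[1, j + 1, 3] <- j * W + 1; P[1, j + 1, 3] <- if (j == 1L) 1L else 3L }
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (A[i] == B[j]) 0 else W
      prev <- K[i, j, ]
      l <- which.min(prev)                      # diag: continue any layer
      K[i + 1, j + 1, 1] <- prev[l] + sub
      P[i + 1, j + 1, 1] <- l
      up <- K[i, j + 1, ] + c(W + 1, W, W + 1)  # opening unless already up
      l <- which.min(up)
      K[i + 1, j + 1, 2] <- up[l]
      P[i + 1, j + 1, 2] <- l
      le <- K[i + 1, j, ] + c(W + 1, W + 1, W)
      l <- which.min(le)
      K[i + 1, j + 1, 3] <- le[l]
      P[i + 1, j + 1, 3] <- l
    }
  }
  l <- which.min(K[n + 1, m + 1, ])
  key <- K[n + 1, m + 1, l]
  i <- n; j <- m
  n_snp <- 0L; n_indel <- 0L; last_gap <- 0L
  while (i > 0L || j > 0L) {
    pl <- P[i + 1, j + 1, l]
    if (l == 1L) {
      if (A[i] != B[j]) n_snp <- n_snp + 1L
      i <- i - 1L; j <- j - 1L; last_gap <- 0L
    } else if (l == 2L) {
      if (last_gap != 2L) n_indel <- n_indel + 1L
      last_gap <- 2L; i <- i - 1L
    } else {
      if (last_gap != 3L) n_indel <- n_indel + 1L
      last_gap <- 3L; j <- j - 1L
    }
    l <- pl
  }
  tibble(n_snp = n_snp, n_indel = n_indel, edit = key %/% W)
}
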