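#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical rotation of a circular sequence
#'
#' Tandem satellite monomers have an arbitrary phase: any rotation of a
#' consensus describes the same circular repeat. The canonical rotation is the
#' lexicographically smallest one; anchoring all consensuses (and therefore all
#' monomer boundaries) to it makes monomers comparable across arrays and
#' genomes.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector: the lexicographically minimal rotation of each
#'   input. Idempotent.
#' @examples
#' canonical_rotation("CGTA")  # "ACGT"
#' @export
canonical_rotation <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0L) abort("empty sequence")
    d <- paste0(s, s)
    min(substring(d, seq_len(n), seq_len(n) + n - 1L))
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a consensus repeat record
#'
#' A consensus repeat is the named canonical monomer of one satellite family
#' (the role CentBd and CentBs play in *Brachypodium*). The sequence is stored
#' in canonical rotation unless `canonicalize = FALSE` (useful when two family
#' consensuses must stay in a shared, pre-aligned register).
#'
#' @param name Family name.
#' @param sequence DNA sequence, at least 50 bp.
#' @param canonicalize Store the canonical rotation (default `TRUE`).
#' @return A one-row tibble with columns `name`, `sequence`, `length`.
#' @export
consensus_repeat <- function(name, sequence, canonicalize = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 50L) abort("consensus shorter than 50 bp")
  if (grepl("[^ACGT]", sequence)) abort("consensus contains non-ACGT symbols")
  if (canonicalize) sequence <- canonical_rotation(sequence)
  tibble(name = name, sequence = sequence, length = nchar(sequence))
}

#' Generate a random consensus monomer
#'
#' Stand-in for a de-novo satellite consensus: an i.i.d. random sequence with a
#' chosen GC content, returned in canonical rotation so that planted monomer
#' boundaries coincide with the canonical phase used by [decompose_array()].
#'
#' @param length Monomer length in bp (>= 50; centromeric satellites here are
#'   ~156-157 bp).
#' @param gc Expected GC fraction.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A single DNA sequence (character).
#' @export
make_consensus <- function(length, gc = 0.5, seed = 1L) {
  if (length < 50) abort("consensus length must be >= 50 bp")
  if (gc < 0 || gc > 1) abort("gc must be in [0, 1]")
  withr::with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
    canonical_rotation(s)
  })
}

#' k-mer frequency table of a set of sequences
#'
#' Counts the `L - k + 1` linear k-mers of each sequence over the full
#' `4^k` alphabet and row-normalizes to frequencies. k-mers containing
#' non-ACGT symbols are dropped before normalization. Sequences shorter than
#' `k` yield an all-zero row (flagged in the `"short"` attribute).
#'
#' @param seqs Character vector of DNA sequences (or a tibble with a
#'   `sequence` column).
#' @param k k-mer size (default 5, giving 1024 columns).
#' @return Numeric matrix, one row per sequence, `4^k` columns named by k-mer.
#'   Attribute `"short"` marks rows with no valid k-mer.
#' @export
kmer_table <- function(seqs, k = 5) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  if (k < 1) abort("k must be >= 1")
  dss <- Biostrings::DNAStringSet(seqs)
  cnt <- Biostrings::oligonucleotideFrequency(dss, width = k)
  tot <- rowSums(cnt)
  frq <- cnt / ifelse(tot == 0, 1, tot)
  attr(frq, "short") <- tot == 0
  frq
}
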