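# Plain-text interchange: FASTA/FASTQ via Biostrings, BED6/bedGraph/TSV via
# readr. All interval output is 0-based half-open (BED convention).

#' Read a FASTA file
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write simulated read pairs as gzipped FASTQ
#'
#' @param reads Output of [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_reads <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (smp in c("chip", "input")) {
    tb <- reads[[smp]]
    for (mate in 1:2) {
      p <- file.path(dir, sprintf("%s_R%d.fastq.gz", smp, mate))
      con <- gzfile(p, "wb")
      seqs <- tb[[paste0("r", mate)]]
      writeLines(paste0("@", tb$id, "/", mate, "\n", seqs, "\n+\n", tb$qual),
                 con)
      close(con)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write monomer records as BED6
#'
#' `name` is the variant/consensus label, `score` the substitution count (or
#' scaled identity when counts are absent).
#' @param monomers Monomer tibble.
#' @param path Output path.
#' @export
write_monomer_bed <- function(monomers, path) {
  score <- .col(monomers, "n_subs") %||%
    round(1000 * (.col(monomers, "identity") %||% 0))
  name <- .col(monomers, "label") %||% .col(monomers, "consensus_name") %||%
    "monomer"
  readr::write_tsv(
    tibble(chrom = monomers$chrom, start = monomers$start, end = monomers$end,
           name = name, score = score, strand = monomers$strand),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a bedGraph file as a binned track
#' @param path bedGraph path (chrom, start, end, value; no header).
#' @return Tibble `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "depth"),
                  col_types = "ciid", progress = FALSE)
}

#' Write a track as bedGraph
#' @param track Tibble with `chrom`, `start`, `end` and a value column
#'   (`log2_ratio` if present, else `depth`).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  value <- .col(track, "log2_ratio") %||% .col(track, "depth")
  readr::write_tsv(tibble(track$chrom, track$start, track$end, value),
                   path, col_names = FALSE)
  invisible(path)
}

#' Write simulation ground truth (BED6 + JSON sidecar)
#'
#' @param sim A `pancent_sim`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, "monomers.bed")
  write_monomer_bed(sim$truth$monomers, bed)
  js <- file.path(dir, "truth.json")
  cfg <- sim$truth$config
  jsonlite::write_json(
    list(
      seed = cfg$seed, sub_rate = cfg$sub_rate, indel_rate = cfg$indel_rate,
      clock_rate = cfg$clock_rate, phase_offset = sim$truth$phase_offset,
      centromere = as.list(sim$truth$centromere),
      crms = sim$truth$crms
    ),
    js, auto_unbox = TRUE, digits = NA
  )
  fa <- file.path(dir, "chromosome.fa")
  write_fasta(sim$sequence, fa)
  invisible(c(fa, bed, js))
}
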