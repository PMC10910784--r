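#' Synthetic CentBd/CentBs-style consensus pair
#'
#' Loads the bundled synthetic stand-in for a two-family satellite consensus
#' pair: 156 bp and 157 bp sequences in a shared alignment register, differing
#' by 19 substitutions and one single-base indel — the divergence pattern of
#' the CentBd/CentBs consensus pair. These are synthetic sequences (generated,
#' not derived from any genome) intended for worked examples and tests.
#'
#' @return A two-row consensus tibble (`name`, `sequence`, `length`), in the
#'   shared register (not individually re-rotated).
#' @export
synthetic_consensus_pair <- function() {
  fa <- read_fasta(system.file("extdata", "synthetic_centbd_centbs.fa",
                               package = "pancent", mustWork = TRUE))
  dplyr::bind_rows(
    consensus_repeat("CentBd", fa[["CentBd_synthetic"]], canonicalize = FALSE),
    consensus_repeat("CentBs", fa[["CentBs_synthetic"]], canonicalize = FALSE)
  )
}
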