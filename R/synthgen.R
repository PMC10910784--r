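# Synthetic centromere generator. Arrays are generated (not evolved): a
# consensus (or a HOR unit built from fixed variants of it) is tiled, per-copy
# substitutions/indels are applied, whole blocks may be strand-flipped, CRM
# retrotransposons carrying an aged LTR pair are inserted, and ChIP/Input read
# pairs are drawn with fold enrichment over the centromere plus a periodic
# positional bias within monomers. Everything is seeded and returns the ground
# truth needed for parameter-recovery tests.

#' Simulation configuration for a synthetic centromere
#'
#' @param seed Integer master seed; fixing it makes every downstream output
#'   (sequence, truth, FASTQ bytes) reproducible.
#' @param monomer_consensus Character vector of one or two monomer consensus
#'   sequences (~150-160 bp). Two consensuses produce two adjacent arrays
#'   (the two-subgenome CentBd/CentBs situation).
#' @param n_copies Monomer copies per array (ignored when `hor_spec` is given).
#' @param sub_rate Per-site substitution probability applied to each copy.
#' @param indel_rate Per-site probability of a single-base indel per copy.
#' @param hor_spec Optional HOR plan: `list(variants = <list of data frames
#'   with columns pos, base>, unit_copies = <int>)`. Each variant is a fixed
#'   substitution set on the consensus; the ordered variants form the unit,
#'   tiled `unit_copies` times.
#' @param strand_blocks Optional data frame with columns `n`, `strand`
#'   partitioning copies into blocks; `-` blocks are reverse-complemented as
#'   whole blocks (after mutation, so strand and divergence stay independent).
#' @param crm_spec Optional data frame with columns `at_copy` (insert after
#'   this copy), `element_length`, `ltr_length`, `age_mya`, `flank_factor`,
#'   `flank_window` (bp). Monomers within `flank_window` of the insertion are
#'   mutated at `sub_rate * flank_factor`.
#' @param chip_spec List: `fold` (>1 enrichment over the centromere),
#'   `phase_offset` (bp within the monomer of maximal fragment-midpoint
#'   density), `phase_kappa` (concentration of the periodic bias; 0 = none),
#'   `read_length`, `fragment_mean`, `fragment_sd`, `coverage`.
#' @param clock_rate Substitutions/site/year used to age CRM LTR pairs
#'   (divergence 2 * rate * age).
#' @param flank_length Random non-satellite sequence on each side (bp).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       monomer_consensus = NULL,
                       n_copies = 500L,
                       sub_rate = 0.02,
                       indel_rate = 0.002,
                       hor_spec = NULL,
                       strand_blocks = NULL,
                       crm_spec = NULL,
                       chip_spec = list(),
                       clock_rate = 1.3e-8,
                       flank_length = 5000L) {
  if (is.null(monomer_consensus)) {
    monomer_consensus <- make_consensus(156, gc = 0.45, seed = seed)
  }
  if (length(monomer_consensus) > 2) abort("one or two consensuses supported")
  for (r in c(sub_rate, indel_rate)) {
    if (r < 0 || r > 1) abort("rates must be in [0, 1]")
  }
  cs <- utils::modifyList(
    list(fold = 8, phase_offset = 80L, phase_kappa = 3, read_length = 101L,
         fragment_mean = 156, fragment_sd = 5, coverage = 20),
    chip_spec
  )
  if (cs$fold < 1) abort("chip fold enrichment must be >= 1")
  if (cs$phase_offset >= min(nchar(monomer_consensus))) {
    abort("phase_offset must be smaller than the monomer length")
  }
  if (!is.null(crm_spec)) crm_spec <- as_tibble(crm_spec)
  if (!is.null(strand_blocks)) strand_blocks <- as_tibble(strand_blocks)
  structure(
    list(seed = as.integer(seed), monomer_consensus = toupper(monomer_consensus),
         n_copies = as.integer(n_copies), sub_rate = sub_rate,
         indel_rate = indel_rate, hor_spec = hor_spec,
         strand_blocks = strand_blocks, crm_spec = crm_spec, chip_spec = cs,
         clock_rate = clock_rate, flank_length = as.integer(flank_length)),
    class = "sim_config"
  )
}

#' Mutate one monomer copy
#'
#' Applies i.i.d. per-site substitutions (never reproducing the original base)
#' and single-base indels (insertion or deletion with equal probability) using
#' the current RNG state. Wrap calls in [withr::with_seed()] (or a seeded
#' simulation) for reproducibility.
#'
#' @param seq DNA sequence.
#' @param sub_rate,indel_rate Per-site event probabilities.
#' @return `list(sequence, n_subs, n_indels)` with counts of applied events.
#' @export
mutate_copy <- function(seq, sub_rate, indel_rate = 0) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  n_subs <- 0L
  if (sub_rate > 0) {
    idx <- which(stats::runif(L) < sub_rate)
    n_subs <- length(idx)
    if (n_subs > 0) {
      shift <- sample.int(3L, n_subs, replace = TRUE)
      ch[idx] <- bases[(match(ch[idx], bases) - 1L + shift) %% 4L + 1L]
    }
  }
  n_indels <- 0L
  if (indel_rate > 0) {
    idx <- which(stats::runif(L) < indel_rate)
    n_indels <- length(idx)
    if (n_indels > 0) {
      is_ins <- stats::runif(n_indels) < 0.5
      ins_base <- sample(bases, n_indels, replace = TRUE)
      for (k in order(idx, decreasing = TRUE)) {  # right-to-left keeps indices valid
        i <- idx[k]
        ch <- if (is_ins[k]) append(ch, ins_base[k], after = i) else ch[-i]
      }
    }
  }
  list(sequence = paste(ch, collapse = ""), n_subs = n_subs, n_indels = n_indels)
}

.random_dna <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

.apply_variant <- function(cons, variant) {
  if (is.null(variant) || NROW(variant) == 0) return(cons)
  ch <- strsplit(cons, "", fixed = TRUE)[[1]]
  ch[variant$pos] <- variant$base
  paste(ch, collapse = "")
}

# Mutate each LTR of an initially identical pair so that their expected
# pairwise divergence is 2 * clock_rate * age.
.age_ltr_pair <- function(ltr, age_mya, clock_rate) {
  p <- clock_rate * age_mya * 1e6
  a <- mutate_copy(ltr, p, 0)
  b <- mutate_copy(ltr, p, 0)
  list(ltr5 = a$sequence, ltr3 = b$sequence)
}

#' Simulate a synthetic centromeric chromosome with ground truth
#'
#' Tiles the configured monomer (or HOR unit), mutates each copy, applies
#' strand blocks, inserts CRM elements with an aged LTR pair, hypermutates
#' monomers flanking each insertion, and pads with random flanks. All
#' coordinates are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return `list(sequence, truth)` of class `pancent_sim`. `truth` holds
#'   `monomers` (chrom, start, end, strand, label, consensus_name, n_subs,
#'   n_indels, sequence), `crms` (element and LTR intervals, ages), the
#'   `centromere` interval, `phase_offset`, and the config.
#' @export
simulate_centromere <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_centromere_impl(config))
}

.simulate_centromere_impl <- function(config) {
  chrom <- "sim_chr"
  pieces <- character(0)
  cursor <- 0L
  mono_rows <- list()
  crm_rows <- list()
  cen_start <- NA_integer_

  add_piece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }

  add_piece(.random_dna(config$flank_length))

  for (ci in seq_along(config$monomer_consensus)) {
    cons <- config$monomer_consensus[ci]
    cname <- if (length(config$monomer_consensus) == 1) "cons" else paste0("cons", ci)
    L <- nchar(cons)
    if (ci > 1) add_piece(.random_dna(3000L))  # spacer between family arrays

    # 1) plan copies and labels
    if (!is.null(config$hor_spec)) {
      variants <- vapply(config$hor_spec$variants, .apply_variant,
                         character(1), cons = cons)
      nv <- length(variants)
      tmpl <- rep(variants, config$hor_spec$unit_copies)
      labels <- rep(LETTERS[seq_len(nv)], config$hor_spec$unit_copies)
    } else {
      tmpl <- rep(cons, config$n_copies)
      labels <- rep("A", config$n_copies)
    }
    nc <- length(tmpl)

    # 2) per-copy mutation rates (flank hypermutation near CRM insertions)
    rate <- rep(config$sub_rate, nc)
    if (!is.null(config$crm_spec)) {
      if (any(config$crm_spec$at_copy > nc)) {
        abort("crm_spec at_copy beyond the array")
      }
      for (r in seq_len(nrow(config$crm_spec))) {
        wcopies <- ceiling(config$crm_spec$flank_window[r] / L)
        near <- abs(seq_len(nc) - config$crm_spec$at_copy[r] - 0.5) <= wcopies
        rate[near] <- config$sub_rate * config$crm_spec$flank_factor[r]
      }
    }

    # 3) mutate copies
    mut <- vector("list", nc)
    for (i in seq_len(nc)) mut[[i]] <- mutate_copy(tmpl[i], rate[i], config$indel_rate)
    seqs <- vapply(mut, `[[`, character(1), "sequence")
    nsub <- vapply(mut, `[[`, integer(1), "n_subs")
    nind <- vapply(mut, `[[`, integer(1), "n_indels")
    strand <- rep("+", nc)

    # 4) strand blocks: reverse-complement whole blocks after mutation
    if (!is.null(config$strand_blocks)) {
      if (sum(config$strand_blocks$n) != nc) {
        abort("strand_blocks copy counts must sum to the array copy number")
      }
      blk <- rep(seq_len(nrow(config$strand_blocks)), config$strand_blocks$n)
      ord <- integer(0)
      for (b in seq_len(nrow(config$strand_blocks))) {
        idx <- which(blk == b)
        if (config$strand_blocks$strand[b] == "-") {
          seqs[idx] <- dna_revcomp(seqs[idx])
          strand[idx] <- "-"
          ord <- c(ord, rev(idx))  # block revcomp reverses monomer order
        } else {
          ord <- c(ord, idx)
        }
      }
      seqs <- seqs[ord]; nsub <- nsub[ord]; nind <- nind[ord]
      strand <- strand[ord]; labels <- labels[ord]
    }

    # 5) lay out the array, inserting CRM elements between copies
    if (is.na(cen_start)) cen_start <- cursor
    ins_after <- if (is.null(config$crm_spec)) integer(0) else config$crm_spec$at_copy
    for (i in seq_len(nc)) {
      s0 <- cursor
      add_piece(seqs[i])
      mono_rows[[length(mono_rows) + 1L]] <- tibble(
        chrom = chrom, start = s0, end = cursor, strand = strand[i],
        label = labels[i], consensus_name = cname,
        n_subs = nsub[i], n_indels = nind[i], sequence = seqs[i]
      )
      hit <- which(ins_after == i)
      for (r in hit) {
        sp <- config$crm_spec[r, ]
        ltr0 <- .random_dna(sp$ltr_length)
        pair <- .age_ltr_pair(ltr0, sp$age_mya, config$clock_rate)
        internal <- .random_dna(max(0L, sp$element_length - 2L * sp$ltr_length))
        e0 <- cursor
        add_piece(paste0(pair$ltr5, internal, pair$ltr3))
        crm_rows[[length(crm_rows) + 1L]] <- tibble(
          chrom = chrom, start = e0, end = cursor,
          ltr5_start = e0, ltr5_end = e0 + sp$ltr_length,
          ltr3_start = cursor - sp$ltr_length, ltr3_end = cursor,
          age_mya = sp$age_mya, flank_factor = sp$flank_factor,
          flank_window = sp$flank_window
        )
      }
    }
  }
  cen_end <- cursor
  add_piece(.random_dna(config$flank_length))

  truth <- list(
    monomers = dplyr::bind_rows(mono_rows),
    crms = if (length(crm_rows)) dplyr::bind_rows(crm_rows) else
      tibble(chrom = character(), start = integer(), end = integer(),
             ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             age_mya = double(), flank_factor = double(),
             flank_window = double()),
    centromere = tibble(chrom = chrom, start = cen_start, end = cen_end),
    phase_offset = config$chip_spec$phase_offset,
    config = config
  )
  out <- list(sequence = setNames(paste(pieces, collapse = ""), chrom),
              truth = truth)
  class(out) <- "pancent_sim"
  out
}

#' Simulate ChIP and Input read pairs from a synthetic chromosome
#'
#' Input fragment midpoints are uniform. ChIP midpoints are drawn with weight
#' `fold` over the centromere interval, modulated within each monomer by a
#' periodic von-Mises-like weight `exp(kappa * cos(2*pi*(offset -
#' phase_offset)/L))` normalized to mean 1 per monomer, so the fold enrichment
#' is preserved while midpoints peak at `phase_offset`. The ChIP library is
#' scaled so its background (non-centromere) density matches the Input
#' density. Fragment lengths are Normal(mean, sd) truncated to
#' `[read_length, 2*read_length]`; mates are reverse complements in FR
#' orientation; base qualities are constant Q40.
#'
#' @param sim A `pancent_sim` from [simulate_centromere()].
#' @param seed Seed for read sampling (default: config seed + 1).
#' @return `list(chip, input, fragments)`: `chip`/`input` are tibbles with
#'   `id`, `r1`, `r2`, `qual`; `fragments` has `sample`, `start`, `end`,
#'   `mid` (0-based).
#' @export
simulate_reads <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "pancent_sim"))
  config <- sim$truth$config
  if (is.null(seed)) seed <- config$seed + 1L
  withr::with_seed(seed, .simulate_reads_impl(sim, config))
}

.simulate_reads_impl <- function(sim, config) {
  cs <- config$chip_spec
  chrom_seq <- unname(sim$sequence)
  L <- nchar(chrom_seq)
  cen <- sim$truth$centromere
  if (cen$end > L || cen$start < 0) abort("centromere interval outside chromosome")

  w <- rep(1, L)
  idx_cen <- (cen$start + 1L):cen$end
  w[idx_cen] <- cs$fold
  if (cs$phase_kappa > 0) {
    mono <- sim$truth$monomers
    for (i in seq_len(nrow(mono))) {
      len <- mono$end[i] - mono$start[i]
      off <- seq_len(len) - 1L
      if (mono$strand[i] == "-") off <- rev(off)
      pw <- exp(cs$phase_kappa * cos(2 * pi * (off - cs$phase_offset) / len))
      pw <- pw / mean(pw)
      w[(mono$start[i] + 1L):mono$end[i]] <- cs$fold * pw
    }
  }

  n_input <- round(cs$coverage * L / (2 * cs$read_length))
  n_chip <- round(n_input * sum(w) / L)  # equal background density

  draw <- function(n, prob) {
    mid0 <- sample.int(L, n, replace = TRUE, prob = prob) - 1L
    flen <- pmin(pmax(round(rnorm(n, cs$fragment_mean, cs$fragment_sd)),
                      cs$read_length), 2L * cs$read_length)
    start <- pmin(pmax(mid0 - flen %/% 2L, 0L), L - flen)
    tibble(start = start, end = start + flen, mid = start + flen %/% 2L)
  }
  frag_in <- draw(n_input, NULL)
  frag_ch <- draw(n_chip, w)

  reads_of <- function(fr, tag) {
    frag <- substring(chrom_seq, fr$start + 1L, fr$end)
    r1 <- substring(frag, 1L, cs$read_length)
    r2 <- dna_revcomp(substring(frag, nchar(frag) - cs$read_length + 1L, nchar(frag)))
    tibble(id = sprintf("%s_%06d", tag, seq_len(nrow(fr))),
           r1 = r1, r2 = r2, qual = strrep("I", cs$read_length))
  }
  list(
    chip = reads_of(frag_ch, "chip"),
    input = reads_of(frag_in, "input"),
    fragments = dplyr::bind_rows(
      mutate(frag_ch, sample = "ChIP", .before = 1),
      mutate(frag_in, sample = "Input", .before = 1)
    ) |>
      mutate(chrom = names(sim$sequence) %||% "sim_chr", .before = 2)
  )
}
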