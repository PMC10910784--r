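# Monomer extraction from assemblies and from read pairs.

test_that("canonical_rotation returns the minimal rotation, idempotently", {
  expect_identical(canonical_rotation("CGTA"), "ACGT")
  expect_identical(canonical_rotation("AAAA"), "AAAA")
  s <- make_copies(fix_cons, 5, 0.1, 0.01, seed = 3)
  expect_identical(canonical_rotation(canonical_rotation(s)),
                   canonical_rotation(s))
})

test_that("exact tandem arrays decompose into exact monomers", {
  genome <- c(chrA = paste0(random_dna(1000, seed = 1),
                            strrep(fix_cons, 10),
                            random_dna(1000, seed = 2)))
  mon <- decompose_array(genome, consensus_repeat("cons", fix_cons))
  expect_equal(nrow(mon), 10)
  expect_true(all(mon$identity == 1))
  expect_equal(mon$start, 1000 + (0:9) * 156)
  expect_true(all(mon$strand == "+"))
  expect_equal(length(unique(mon$array_id)), 1)
})

test_that("a planted 3-substitution copy gets identity 153/156", {
  mutated <- local({
    ch <- strsplit(fix_cons, "")[[1]]
    ch[c(30, 80, 130)] <- vapply(ch[c(30, 80, 130)], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], character(1))
    paste(ch, collapse = "")
  })
  genome <- c(chrA = paste0(random_dna(500, seed = 4),
                            strrep(fix_cons, 4), mutated, strrep(fix_cons, 4),
                            random_dna(500, seed = 5)))
  mon <- decompose_array(genome, consensus_repeat("cons", fix_cons))
  expect_equal(nrow(mon), 9)
  expect_equal(sort(unique(mon$identity)), c(153 / 156, 1))
  expect_equal(sum(mon$identity < 1), 1)
})

test_that("decomposition recovers mutated arrays against ground truth", {
  cfg <- sim_config(seed = 31, monomer_consensus = fix_cons, n_copies = 500,
                    sub_rate = 0.02, indel_rate = 0.002, flank_length = 2000)
  sim <- simulate_centromere(cfg)
  mon <- decompose_array(sim$sequence, consensus_repeat("cons", fix_cons))
  tm <- sim$truth$monomers
  expect_lte(abs(nrow(mon) - nrow(tm)) / nrow(tm), 0.01)
  mid_err <- abs((mon$start + mon$end) / 2 - (tm$start + tm$end) / 2)
  expect_lte(max(mid_err), 5)
  # intervals sorted and non-overlapping
  expect_true(all(diff(mon$start) > 0))
  expect_true(all(mon$start[-1] >= mon$end[-nrow(mon)]))
})

test_that("reverse-complementing the genome mirrors monomers", {
  sb <- data.frame(n = c(60, 40), strand = c("+", "-"))
  cfg <- sim_config(seed = 32, monomer_consensus = fix_cons, n_copies = 100,
                    sub_rate = 0.02, indel_rate = 0, strand_blocks = sb,
                    flank_length = 800)
  sim <- simulate_centromere(cfg)
  mon <- decompose_array(sim$sequence, consensus_repeat("cons", fix_cons))
  expect_identical(mon$strand, sim$truth$monomers$strand)
  n <- unname(nchar(sim$sequence))
  rc <- c(sim_chr = dna_revcomp(unname(sim$sequence)))
  mon_rc <- decompose_array(rc, consensus_repeat("cons", fix_cons))
  expect_equal(nrow(mon_rc), nrow(mon))
  expect_equal(rev(n - mon_rc$end), mon$start)
  expect_equal(rev(n - mon_rc$start), mon$end)
  expect_true(all(rev(mon_rc$strand) != mon$strand))
  expect_identical(rev(mon_rc$sequence), mon$sequence)
})

test_that("build_consensus recovers the template by majority rule", {
  expect_error(build_consensus(fix_cons), "at least 2")
  ident <- build_consensus(rep(fix_cons, 10))
  expect_identical(ident$sequence, fix_cons)

  # a 6/4 split column: majority base wins
  alt <- local({
    ch <- strsplit(fix_cons, "")[[1]]
    ch[50] <- setdiff(c("A", "C", "G", "T"), ch[50])[1]
    paste(ch, collapse = "")
  })
  bc <- build_consensus(c(rep(fix_cons, 6), rep(alt, 4)))
  expect_identical(bc$sequence, fix_cons)

  # round trip at 2% divergence with indels
  copies <- make_copies(fix_cons, 300, 0.02, 0.002, seed = 8)
  bc2 <- build_consensus(copies)
  expect_identical(bc2$sequence, fix_cons)
})

test_that("merge_pairs reconstructs fragments and drops non-overlapping pairs", {
  frag <- substring(strrep(fix_cons, 2), 10, 165)  # a 156-bp fragment
  r1 <- substring(frag, 1, 150)
  r2 <- dna_revcomp(substring(frag, 7, 156))
  merged <- merge_pairs(r1, r2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$length, 156)
  expect_identical(merged$sequence, frag)

  # zero overlap: nothing emitted
  none <- merge_pairs(substring(frag, 1, 60),
                      dna_revcomp(substring(frag, 100, 156)))
  expect_equal(nrow(none), 0)

  expect_error(merge_pairs(c(r1, r1), r2), "mate count")
})

test_that("simulated monomer-sized pairs merge to the true fragment length", {
  cfg <- sim_config(seed = 33, monomer_consensus = fix_cons, n_copies = 200,
                    sub_rate = 0.02, flank_length = 3000,
                    chip_spec = list(coverage = 3))
  sim <- simulate_centromere(cfg)
  rd <- simulate_reads(sim)
  merged <- merge_pairs(rd$input)
  truth_len <- with(dplyr::filter(rd$fragments, sample == "Input"), end - start)
  expect_gte(nrow(merged) / length(truth_len), 0.95)
  expect_gte(mean(merged$length == truth_len[match(
    as.integer(sub("input_", "", merged$id)), seq_along(truth_len))]), 0.95)
})

test_that("fragment length filter keeps the inclusive 146-166 window", {
  fr <- tibble::tibble(id = as.character(1:5),
                       sequence = strrep("A", c(145, 146, 156, 166, 167)))
  kept <- filter_fragments(fr)
  expect_equal(kept$length, c(146, 156, 166))
  expect_equal(nrow(filter_fragments(fr[0, ])), 0)
  all_in <- tibble::tibble(sequence = strrep("C", 150:160))
  expect_equal(nrow(filter_fragments(all_in)), 11)
  # property: equals the one-line predicate oracle
  lens <- withr::with_seed(5, sample(100:200, 300, replace = TRUE))
  fr2 <- tibble::tibble(sequence = strrep("A", lens))
  expect_equal(sort(filter_fragments(fr2)$length),
               sort(oracle_filter_fragments(lens)))
})

test_that("assign_fragments separates true families and rejects noise", {
  consensi <- c(CentBd = fix_cons, CentBs = fix_cons2)
  exact <- assign_fragments(tibble::tibble(sequence = fix_cons), consensi)
  expect_identical(exact$assigned_consensus, "CentBd")
  expect_lt(exact$evalue, 1e-20)

  # random 156-mers: >= 99% unassigned
  rnd <- withr::with_seed(9, vapply(1:300, function(i)
    paste(sample(c("A", "C", "G", "T"), 156, replace = TRUE), collapse = ""),
    character(1)))
  rnd_out <- assign_fragments(tibble::tibble(sequence = rnd), consensi)
  expect_gte(mean(is.na(rnd_out$assigned_consensus)), 0.99)

  # fragments at 2% divergence from each family: >= 98% correctly assigned
  fr <- tibble::tibble(
    sequence = c(make_copies(fix_cons, 250, 0.02, seed = 10),
                 make_copies(fix_cons2, 250, 0.02, seed = 11)),
    truth = rep(c("CentBd", "CentBs"), each = 250)
  )
  out <- assign_fragments(fr, consensi)
  expect_gte(mean(out$assigned_consensus == out$truth, na.rm = TRUE), 0.98)
  expect_lte(mean(is.na(out$assigned_consensus)), 0.02)

  # reverse-complemented fragments assign identically
  rc_out <- assign_fragments(
    tibble::tibble(sequence = dna_revcomp(fr$sequence[1:20])), consensi)
  expect_identical(rc_out$assigned_consensus, out$assigned_consensus[1:20])
})
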