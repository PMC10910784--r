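# Enrichment tracks, centromere calling, cluster classification, quantile
# groups, metaprofiles, phasing.

test_that("bin_coverage averages depth per bin, oracle-exact", {
  # uniform depth 10
  u <- bin_coverage(rep(10, 5000), 1000)
  expect_true(all(u$depth == 10))

  # one 100-bp read in an empty 1-kb bin
  one <- bin_coverage(tibble::tibble(chrom = "c", start = 200, end = 300),
                      1000, c(c = 1000))
  expect_equal(one$depth, 0.1)

  # oracle equality on a 10-kb toy with random intervals
  set.seed(6)
  st <- sort(sample(0:9800, 200, replace = TRUE))
  en <- st + sample(50:190, 200, replace = TRUE)
  got <- bin_coverage(tibble::tibble(chrom = "c", start = st, end = pmin(en, 10000)),
                      750, c(c = 10000))
  expect_equal(got$depth, oracle_bin_coverage(st, pmin(en, 10000), 750, 10000))

  expect_error(
    bin_coverage(tibble::tibble(chrom = "c", start = c(5, 1), end = c(9, 4)), 10),
    "sorted")
})

test_that("log2_ratio is zero at parity, ~3 at 8-fold, depth-invariant", {
  grid <- tibble::tibble(chrom = "c", start = (0:9) * 100, end = (1:10) * 100)
  chip <- dplyr::mutate(grid, depth = 40)
  inp <- dplyr::mutate(grid, depth = 40)
  expect_true(all(log2_ratio(chip, inp)$log2_ratio == 0))

  chip8 <- dplyr::mutate(grid, depth = 320)
  r8 <- log2_ratio(chip8, inp)$log2_ratio
  expect_equal(r8, rep(log2(320.5 / 40.5), 10))
  expect_equal(mean(r8), 3, tolerance = 0.01)

  # doubling both library sizes leaves ratios unchanged
  r1 <- log2_ratio(chip8, inp, lib_sizes = c(1e6, 2e6))$log2_ratio
  r2 <- log2_ratio(chip8, inp, lib_sizes = c(2e6, 4e6))$log2_ratio
  expect_equal(r1, r2)

  expect_error(log2_ratio(chip, inp[1:5, ]), "grid")
})

test_that("call_centromere selects the maximal merged region", {
  grid <- tibble::tibble(chrom = "c", start = (0:99) * 1000,
                         end = (1:100) * 1000, log2_ratio = 0)
  expect_equal(nrow(call_centromere(grid, threshold = 1)), 0)

  two <- grid
  two$log2_ratio[11:20] <- 2    # 10 bins
  two$log2_ratio[51:55] <- 3    # 5 bins, smaller sum
  call <- call_centromere(two, threshold = 1, merge_gap = 2000)
  expect_equal(nrow(call), 1)
  expect_equal(c(call$start, call$end), c(10000, 20000))
  allr <- call_centromere(two, threshold = 1, merge_gap = 2000,
                          all_regions = TRUE)
  expect_equal(nrow(allr), 2)
  expect_equal(allr$sum_log2, c(20, 15))

  # bins separated by a small gap merge into one region
  gap <- grid
  gap$log2_ratio[c(11:14, 17:20)] <- 2
  merged <- call_centromere(gap, threshold = 1, merge_gap = 3000)
  expect_equal(c(merged$start, merged$end), c(10000, 20000))
})

test_that("planted enriched intervals are recovered within one bin", {
  for (fold in c(4, 8, 16)) {
    cfg <- sim_config(seed = 40 + fold, monomer_consensus = fix_cons,
                      n_copies = 320, sub_rate = 0.02, flank_length = 25000,
                      chip_spec = list(fold = fold, coverage = 10))
    sim <- simulate_centromere(cfg)
    rd <- simulate_reads(sim)
    frag <- dplyr::arrange(rd$fragments, start)
    len <- unname(nchar(sim$sequence))
    bin <- 2500
    ch <- bin_coverage(dplyr::filter(frag, sample == "ChIP"), bin, c(sim_chr = len))
    inp <- bin_coverage(dplyr::filter(frag, sample == "Input"), bin, c(sim_chr = len))
    call <- call_centromere(log2_ratio(ch, inp), threshold = 1,
                            merge_gap = 10000)
    cen <- sim$truth$centromere
    expect_lte(abs(call$start - cen$start), bin)
    expect_lte(abs(call$end - cen$end), bin)
  }
})

test_that("enrichment_level matches mixture arithmetic and invariances", {
  grid <- tibble::tibble(chrom = "c", start = (0:99) * 1000,
                         end = (1:100) * 1000, depth = 5)
  call <- tibble::tibble(chrom = "c", start = 30000, end = 40000)
  expect_equal(enrichment_level(call, grid), 1)

  # 8-fold over 1% of the genome: 8 / (0.99 + 0.01 * 8)
  g2 <- tibble::tibble(chrom = "c", start = (0:999) * 1000,
                       end = (1:1000) * 1000, depth = 1)
  g2$depth[101:110] <- 8
  cl <- tibble::tibble(chrom = "c", start = 100000, end = 110000)
  expect_equal(enrichment_level(cl, g2), 8 / (0.99 + 0.01 * 8))
  g3 <- dplyr::mutate(g2, depth = depth * 17)
  expect_equal(enrichment_level(cl, g3), enrichment_level(cl, g2))

  expect_error(enrichment_level(call, dplyr::mutate(grid, depth = 0)), "zero")
})

test_that("cluster classification applies the strict (>2.6, >0.5%) rule", {
  cl <- tibble::tibble(ratio = c(2.7, 2.5, 2.6), genome_fraction = c(0.006, 0.05, 0.01))
  got <- classify_clusters(cl)
  expect_identical(got$is_centromeric, c(TRUE, FALSE, FALSE))

  # exhaustive grid vs the two-predicate oracle
  grid <- expand.grid(ratio = seq(0, 5, by = 0.1),
                      genome_fraction = seq(0, 0.02, by = 0.0005))
  got2 <- classify_clusters(tibble::as_tibble(grid))
  expect_identical(got2$is_centromeric,
                   oracle_classify(grid$ratio, grid$genome_fraction))

  # ratio computed from library-normalized counts
  counts <- tibble::tibble(chip_count = c(90, 10), input_count = c(50, 50),
                           genome_fraction = c(0.01, 0.01))
  got3 <- classify_clusters(counts)
  expect_equal(got3$ratio, c(0.9 / 0.5, 0.1 / 0.5))
})

test_that("quantile_groups splits by decreasing rank with stable ties", {
  g <- quantile_groups(1:10, 5)
  expect_equal(g, c(5, 5, 4, 4, 3, 3, 2, 2, 1, 1))
  same <- quantile_groups(rep(3, 7), 3)
  expect_equal(same, c(1, 1, 1, 2, 2, 3, 3))
  sizes <- table(quantile_groups(rnorm(23), 5))
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(quantile_groups(1:3, 5), "fewer values")
})

test_that("metaprofile equals the per-base brute-force average", {
  track <- tibble::tibble(chrom = "c", start = (0:99) * 100,
                          end = (1:100) * 100, log2_ratio = 0.5)
  feats <- tibble::tibble(chrom = "c", start = c(2000, 5000), end = c(2600, 6000))
  flat <- metaprofile(track, feats, flank = 500, body_bins = 10)
  expect_true(all(abs(flat$mean_signal - 0.5) < 1e-12))

  step <- track
  inside <- function(s, e) step$start >= s & step$end <= e
  step$log2_ratio <- ifelse(inside(2000, 2600) | inside(5000, 6000), 2, 0)
  prof <- metaprofile(step, feats, flank = 500, body_bins = 10)
  expect_true(all(prof$mean_signal[prof$section == "body"] == 2))
  expect_true(all(prof$mean_signal[prof$section != "body"] == 0))

  set.seed(8)
  bumpy <- dplyr::mutate(track, log2_ratio = rnorm(100))
  feats2 <- tibble::tibble(chrom = "c", start = c(1234, 4005, 7777),
                           end = c(1834, 5206, 8497),
                           strand = c("+", "-", "+"))
  got <- metaprofile(bumpy, feats2, flank = 600, body_bins = 7)
  expect_equal(got$mean_signal,
               oracle_metaprofile(bumpy, feats2, 600, 7))
})

test_that("phase_profile recovers the planted offset, strand-aware", {
  cfg <- sim_config(seed = 55, monomer_consensus = fix_cons, n_copies = 300,
                    sub_rate = 0.02, flank_length = 5000,
                    strand_blocks = data.frame(n = c(150, 150),
                                               strand = c("+", "-")),
                    chip_spec = list(fold = 8, phase_offset = 80, coverage = 12))
  sim <- simulate_centromere(cfg)
  rd <- simulate_reads(sim)
  mids <- dplyr::filter(rd$fragments, sample == "ChIP")$mid
  pp <- phase_profile(mids, sim$truth$monomers)
  expect_gte(pp$n_fragments, 10000)
  expect_lte(abs(pp$peak_offset - 80), 5)

  # reversing all monomer strands leaves the recovered offset unchanged
  flipped <- dplyr::mutate(sim$truth$monomers,
                           strand = ifelse(strand == "+", "-", "+"),
                           sequence = dna_revcomp(sequence))
  pp_f <- phase_profile(mids, flipped)
  # offsets mirror: peak at L-1-80 on the flipped annotation
  expect_lte(abs(pp_f$peak_offset - (156 - 1 - 80)), 5)

  # uniform (Input) fragments: flat profile, chi-square uniformity holds
  umids <- dplyr::filter(rd$fragments, sample == "Input")$mid
  up <- phase_profile(umids, sim$truth$monomers)
  gof <- suppressWarnings(chisq.test(up$profile$count))
  expect_gt(gof$p.value, 0.01)

  expect_error(phase_profile(c(1, 2), sim$truth$monomers[0, ]),
               "no fragment")
})
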