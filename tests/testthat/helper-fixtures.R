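# Shared fixtures: one small canonical consensus and convenience builders.
# Everything is generated in code under fixed seeds.

fix_cons <- make_consensus(156, gc = 0.45, seed = 7)

# a second family: 19 fixed substitutions + 1 single-base insertion on the
# first family's register (the CentBd/CentBs divergence pattern)
fix_cons2 <- local({
  ch <- strsplit(fix_cons, "", fixed = TRUE)[[1]]
  pos <- seq(6, 150, by = 8)
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- alt[1 + (p %% 3)]
  }
  ins <- setdiff(c("A", "C", "G", "T"), c(ch[81], ch[82]))[1]
  paste(c(ch[1:81], ins, ch[82:156]), collapse = "")
})

# mutated copies of a template under a fixed seed
make_copies <- function(template, n, sub_rate, indel_rate = 0, seed = 1) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    mutate_copy(template, sub_rate, indel_rate)$sequence
  }, character(1)))
}

random_dna <- function(n, seed = 1) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# variant definition: k fixed substitutions at distinct sites per variant,
# so any two variants differ at 2k sites
hor_variants <- function(n_var, k = 12) {
  c(list(data.frame(pos = integer(0), base = character(0))),
    lapply(seq_len(n_var - 1), function(v) {
      pos <- seq(3 + v, 154, by = 9)[seq_len(k)]
      ch <- strsplit(fix_cons, "")[[1]]
      data.frame(pos = pos, base = vapply(ch[pos], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1 + v %% 3], character(1)))
    }))
}

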