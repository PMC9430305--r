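test_that("the mutator is seeded, rate-faithful, and identity-preserving at rate 0", {
  rs <- get_ref_set()
  cons <- rs$refs$LTR5Hs$record
  el0 <- mutate_from_consensus(cons, 0, 0, seed = 1)
  expect_equal(el0$seq, cons$seq)
  expect_equal(attr(el0, "map"), seq_len(nchar(cons$seq)))
  # bit-reproducible
  e1 <- mutate_from_consensus(cons, 0.05, 0.001, seed = 9)
  e2 <- mutate_from_consensus(cons, 0.05, 0.001, seed = 9)
  expect_identical(e1$seq, e2$seq)
  # realized substitution count within the binomial 99% interval
  n <- nchar(cons$seq)
  ci <- binom_ci99(0.05, n)
  for (s in 1:5) {
    e <- mutate_from_consensus(cons, 0.05, 0, seed = 100 + s)
    mism <- sum(strsplit(e$seq, "")[[1]] != strsplit(cons$seq, "")[[1]])
    expect_gte(mism, ci[1]); expect_lte(mism, ci[2])
  }
  # the coordinate map tracks indels: mapped positions recover their bases
  ei <- mutate_from_consensus(cons, 0, 0.005, seed = 11)
  map <- attr(ei, "map")
  cc <- strsplit(cons$seq, "")[[1]]
  mc <- strsplit(ei$seq, "")[[1]]
  ok <- !is.na(map)
  expect_true(all(mc[map[ok]] == cc[ok]))
  expect_true(all(diff(map[ok]) > 0))  # monotone
})

test_that("motif planting restores or ablates sites with the requested probabilities", {
  rs <- get_ref_set()
  sites <- rs$sites$LTR5Hs
  p1 <- setNames(rep(1, nrow(sites)), sites$motif)
  el <- mutate_from_consensus(rs$refs$LTR5Hs$record, 0.0175, seed = 21,
                              id = "e")
  pl <- plant_motifs(el, sites, p1, seed = 22)
  expect_true(all(pl$presence))
  reg <- default_motif_registry(extended = TRUE)
  for (m in reg)
    expect_gte(length(scan_motif(pl$record$seq, m)), 1L)
  p0 <- setNames(rep(0, nrow(sites)), sites$motif)
  pl0 <- plant_motifs(el, sites, p0, seed = 23)
  expect_false(any(pl0$presence))
  # binomial recovery at the TP53-1 study frequency over n = 194 elements
  hitcount <- 0L
  for (i in 1:194) {
    e <- mutate_from_consensus(rs$refs$LTR5Hs$record, 0.0175,
                               seed = 3000L + i, id = "e")
    pp <- plant_motifs(e, sites, c(`TP53-1` = 0.9278), seed = 4000L + i)
    hitcount <- hitcount +
      (length(scan_motif(pp$record$seq, "GGGCTGG")) > 0L)
  }
  ci <- binom_ci99(0.9278, 194)
  expect_gte(hitcount, ci[1]); expect_lte(hitcount, ci[2])
})

test_that("genome simulation honours spacing, bounds, and byte determinism", {
  rs <- get_ref_set()
  sim <- get_genome_sim()
  expect_equal(nrow(sim$truth), 6L)
  tr <- sim$truth[order(sim$truth$start), ]
  expect_true(all(tr$start >= 0 & tr$end <= nchar(sim$genome[[1]]$seq)))
  expect_true(all(tr$start[-1] - tr$end[-6] >= 1000L))
  # planted sequences are really there
  for (i in seq_len(nrow(tr))) {
    sub <- substr(sim$genome[[1]]$seq, tr$start[i] + 1L, tr$end[i])
    ref <- rs$refs[[tr$subtype[i]]]$record$seq
    if (tr$strand[i] == "-") sub <- reverse_complement(sub)
    expect_equal(nchar(sub), nchar(ref))
  }
  sim2 <- simulate_genome(rs, seed = 42)
  expect_identical(sim2$genome[[1]]$seq, sim$genome[[1]]$seq)
  expect_error(simulate_genome(rs, background_len = 5000L), "infeasible")
})

test_that("luciferase plates recover effects exactly at sigma 0 and centrally at sigma 0.1", {
  eff <- data.frame(construct = c("empty", "LTR5Hs3-5B"),
                    stimulus = c("medium", "medium"),
                    fold = c(1, 3.28))
  p0 <- simulate_luciferase_plate(eff, sigma = 0, seed = 1)
  expect_equal(normalized_fold_change(p0, "LTR5Hs3-5B", "medium"), 3.28)
  # permuting wells changes nothing
  perm <- p0[sample(nrow(p0)), ]
  expect_equal(normalized_fold_change(perm, "LTR5Hs3-5B", "medium"), 3.28)
  # median recovery across 500 seeded noisy plates within 5%
  est <- vapply(1:500, function(s) {
    p <- simulate_luciferase_plate(eff, sigma = 0.1, n_reps = 3, seed = s)
    normalized_fold_change(p, "LTR5Hs3-5B", "medium")
  }, 0)
  expect_lt(abs(median(est) - 3.28) / 3.28, 0.05)
})

test_that("qPCR tables recover ddCT effects", {
  tab0 <- simulate_qpcr(c(control = 0, treated = -2), sigma_ct = 0, seed = 2)
  expect_equal(ddct_fold(tab0, "TP53", "ACTB", "treated", "control"), 4)
  tab1 <- simulate_qpcr(c(control = 0, treated = -2), sigma_ct = 0.1,
                        seed = 3)
  expect_identical(tab1, simulate_qpcr(c(control = 0, treated = -2),
                                       sigma_ct = 0.1, seed = 3))
  expect_lt(abs(log2(ddct_fold(tab1, "TP53", "ACTB", "treated", "control")) -
                  2), 0.5)
})

test_that("the curated-set generator reproduces the study's screening structure", {
  es <- get_element_set()
  tt <- es$truth
  expect_equal(as.vector(table(tt$subtype)[c("LTR5A", "LTR5B", "LTR5Hs")]),
               c(704L, 828L, 256L))
  expect_equal(as.vector(tapply(tt$kept, tt$subtype, sum)[
    c("LTR5A", "LTR5B", "LTR5Hs")]), c(43L, 62L, 194L))
  # truncated fragments are below the 60% screen; kept ones above
  for (st in names(es$elements)) {
    full <- get_ref_set()$refs[[st]]$full_length
    lens <- tt$length[tt$subtype == st]
    kept <- tt$kept[tt$subtype == st]
    expect_true(all(lens[!kept] < 0.6 * full))
    expect_true(all(lens[kept] >= 0.6 * full))
  }
})
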