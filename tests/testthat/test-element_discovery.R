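test_that("k-mer index content matches hand enumeration and a brute-force scan", {
  g <- list(seq_record("c1", strrep("A", 15)))
  idx <- build_kmer_index(g, k = 11, step = 5)
  # only offset 0 fits an 11-mer wholly within 15 nt at stride 5
  expect_length(idx$table, 1L)
  expect_equal(idx$table[["AAAAAAAAAAA"]]$offset, 0L)

  expect_length(build_kmer_index(list(), k = 11, step = 5)$table, 0L)
  expect_warning(build_kmer_index(list(seq_record("tiny", "ACGT"))),
                 "shorter than k")

  set.seed(21)
  contig <- seq_record("r1", random_dna(1000))
  idx2 <- build_kmer_index(list(contig), k = 11, step = 5)
  # brute-force oracle: every indexed offset holds its k-mer, and every
  # stride-5 offset is present under some k-mer
  offs <- sort(unname(unlist(lapply(idx2$table, `[[`, "offset"))))
  expect_equal(offs, seq.int(0L, 1000L - 11L, by = 5L))
  for (km in names(idx2$table))
    for (o in idx2$table[[km]]$offset)
      expect_equal(substr(contig$seq, o + 1, o + 11), km)
})

test_that("seed-and-chain finds planted copies on both strands and rejects noise", {
  rs <- get_ref_set()
  cons <- rs$refs$LTR5Hs
  L <- cons$full_length
  set.seed(31)
  bg <- random_dna(10000)
  planted <- paste0(substr(bg, 1, 2000), cons$record$seq,
                    substr(bg, 2001, 10000))
  idx <- build_kmer_index(list(seq_record("c", planted)))
  cands <- seed_and_chain(idx, cons)
  expect_length(cands, 1L)
  expect_lte(cands[[1]]$start, 2000L)
  expect_gte(cands[[1]]$end, 2000L + L)
  expect_equal(cands[[1]]$strand, "+")

  planted_rc <- paste0(substr(bg, 1, 2000),
                       reverse_complement(cons$record$seq),
                       substr(bg, 2001, 10000))
  idx2 <- build_kmer_index(list(seq_record("c", planted_rc)))
  cands2 <- seed_and_chain(idx2, cons)
  expect_length(cands2, 1L)
  expect_equal(cands2[[1]]$strand, "-")

  # negative control: shuffled consensus against plain background
  set.seed(32)
  shuffled <- paste(sample(strsplit(cons$record$seq, "")[[1]]), collapse = "")
  idx3 <- build_kmer_index(list(seq_record("c", bg)))
  expect_length(seed_and_chain(idx3, seq_record("shuf", shuffled),
                               min_seeds = 10), 0L)
})

test_that("extend-and-score recovers exact boundaries and discards junk", {
  rs <- get_ref_set()
  cons <- rs$refs$LTR5Hs
  set.seed(41)
  bg <- random_dna(8000)
  genome <- list(c1 = seq_record(
    "c1", paste0(substr(bg, 1, 3000), cons$record$seq,
                 substr(bg, 3001, 8000))))
  truth <- c(start = 3000L, end = 3000L + cons$full_length)
  cand <- genomic_interval("c1", 2950L, truth[["end"]] + 50L, "+")
  hit <- extend_and_score(cand, cons, genome)
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 1)
  expect_equal(hit$interval$start, truth[["start"]])
  expect_equal(hit$interval$end, truth[["end"]])

  # 5% substitutions: identity >= 90, boundaries within 5 nt
  mut <- mutate_from_consensus(cons$record, 0.05, seed = 5, id = "m")
  genome2 <- list(c1 = seq_record(
    "c1", paste0(substr(bg, 1, 3000), mut$seq, substr(bg, 3001, 8000))))
  cand2 <- genomic_interval("c1", 2950L, 3000L + nchar(mut$seq) + 50L, "+")
  hit2 <- extend_and_score(cand2, cons, genome2)
  expect_gte(hit2$identity, 90)
  expect_lte(abs(hit2$interval$start - 3000L), 5L)
  expect_lte(abs(hit2$interval$end - (3000L + nchar(mut$seq))), 5L)

  # unrelated sequence falls below the identity floor
  cand3 <- genomic_interval("c1", 5500L, 6500L, "+")
  expect_message(res <- extend_and_score(cand3, cons, genome2), "discarded")
  expect_null(res)
})

test_that("discovery on a planted genome is complete, correct, and deterministic", {
  rs <- get_ref_set()
  sim <- get_genome_sim()
  hits <- discover_elements(sim$genome, rs$refs)
  truth <- sim$truth[order(sim$truth$start), ]
  expect_length(hits, nrow(truth))
  ht <- hits_table(hits)
  expect_equal(ht$subtype, truth$subtype)
  expect_equal(ht$strand, truth$strand)
  expect_lte(max(abs(ht$start - truth$start), abs(ht$end - truth$end)), 5L)
  # intervals stay inside the contig
  expect_true(all(ht$start >= 0 &
                    ht$end <= nchar(sim$genome[[1]]$seq)))
  # determinism for fixed input
  hits2 <- discover_elements(sim$genome, rs$refs)
  expect_identical(hits_table(hits2), ht)
  expect_error(discover_elements(sim$genome, list()), "at least one")
})

test_that("overlapping per-reference hits collapse to the best single call", {
  rs <- get_ref_set()
  cons <- rs$refs$LTR5Hs
  set.seed(51)
  bg <- random_dna(6000)
  genome <- list(c1 = seq_record(
    "c1", paste0(substr(bg, 1, 2000), cons$record$seq,
                 substr(bg, 2001, 6000))))
  # all three references are similar enough to seed the same locus
  hits <- discover_elements(genome, rs$refs)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$subtype, "LTR5Hs")
})
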