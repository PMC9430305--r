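test_that("anchoring to the frame yields an identity map for the reference itself", {
  rs <- get_ref_set()
  fmap <- anchor_to_frame(rs$frame_ref, rs$frame_ref, rs$tss_index)
  expect_equal(fmap$map, seq_len(nchar(rs$frame_ref$seq)))
  expect_equal(fmap$identity, 100)
  expect_error(anchor_to_frame(random_dna(900), rs$frame_ref, rs$tss_index),
               "anchoring error")
})

test_that("a deletion upstream of -263 leaves the promoter section mapping intact", {
  rs <- get_ref_set()
  # delete 10 nt around frame position -500 (well upstream of the section)
  del_at <- rel_to_index(-500L, rs$tss_index)
  seq <- rs$frame_ref$seq
  el <- paste0(substr(seq, 1, del_at - 1), substr(seq, del_at + 10, nchar(seq)))
  fmap <- anchor_to_frame(el, rs$frame_ref, rs$tss_index)
  s3 <- ltr_sections()[3, ]
  ex <- extract_section(el, fmap, s3)
  expect_true(ex$included)
  expect_equal(ex$coverage, 1)
  # downstream of the deletion every mapping is shifted by exactly -10
  i1 <- rel_to_index(s3$start_rel, rs$tss_index)
  i2 <- rel_to_index(s3$end_rel, rs$tss_index)
  expect_equal(fmap$map[i1:i2], seq.int(i1 - 10L, i2 - 10L))
  expect_equal(ex$seq, substr(seq, i1, i2))
})

test_that("section extraction flags low-coverage elements instead of guessing", {
  rs <- get_ref_set()
  s3 <- ltr_sections()[3, ]
  i1 <- rel_to_index(s3$start_rel, rs$tss_index)
  # element missing most of the section (ends before -100)
  el <- substr(rs$frame_ref$seq, 1, i1 + 60L)
  fmap <- anchor_to_frame(el, rs$frame_ref, rs$tss_index)
  ex <- extract_section(el, fmap, s3)
  expect_false(ex$included)
  expect_lt(ex$coverage, 0.8)
  # identity map, section 1..177 -> last 177 nt of the frame
  fmap0 <- anchor_to_frame(rs$frame_ref, rs$frame_ref, rs$tss_index)
  s4 <- ltr_sections()[4, ]
  ex4 <- extract_section(rs$frame_ref, fmap0, s4)
  n <- nchar(rs$frame_ref$seq)
  expect_equal(ex4$seq, substr(rs$frame_ref$seq, n - 176L, n))
})

test_that("IUPAC motif scanning is exact, overlap-aware, and matches brute force", {
  expect_equal(scan_motif("GGTATAAACC", "TATAAA"), 2L)
  expect_equal(scan_motif("CCATGTT", "CCATNTT"), 0L)
  expect_equal(scan_motif("AAAAAA", "AAA"), 0:3)      # overlapping matches
  expect_equal(scan_motif("ACGT", "TTTT"), integer(0))
  # sequence N only matches motif N
  expect_equal(scan_motif("CCNTGTT", "CCATNTT"), integer(0))
  expect_equal(scan_motif("CCATNTT", "CCATNTT"), 0L)
  set.seed(23)
  motifs <- c("TATAAA", "GGGCWGS", "ATGCMAA", "CCATNTT", "RYN")
  for (i in 1:200) {
    s <- random_dna(sample(10:60, 1))
    m <- sample(motifs, 1)
    expect_identical(scan_motif(s, m), brute_scan(s, m))
  }
})

test_that("frequency tables count presence per element with half-up rounding", {
  seqs <- list(S = c("AATATAAA", "CCCTATAAAC", "GGTATAAA", "ACGTACGT"))
  tab <- motif_frequency_table(seqs, default_motif_registry()["TATA"])
  expect_equal(tab$n_present, 3L)
  expect_equal(tab$percent, 75.00)
  # zero hits
  tab0 <- motif_frequency_table(list(S = c("ACACAC", "GTGTGT")),
                                default_motif_registry()["TATA"])
  expect_equal(tab0$percent, 0)
  # empty subtype dropped with warning
  expect_warning(motif_frequency_table(list(S = character(0)),
                                       default_motif_registry()["TATA"]),
                 "row omitted")
  # order invariance
  rs <- get_ref_set()
  secs <- get_section_seqs()
  reg <- default_motif_registry()
  t1 <- motif_frequency_table(secs["LTR5Hs"], reg)
  t2 <- motif_frequency_table(lapply(secs["LTR5Hs"], rev), reg)
  expect_equal(t1[order(t1$motif), -1], t2[order(t2$motif), -1],
               ignore_attr = TRUE)
})

test_that("co-occurrence is a hand-countable intersection bounded by the margins", {
  a <- motif_def("A", "AAAA")
  b <- motif_def("B", "CCCC")
  seqs <- c("AAAAGG", "AAAACCCC", "CCCCGG", "GGGGGG")
  co <- cooccurrence_frequency(seqs, a, b)
  expect_equal(co$count, 1L)
  expect_equal(co$percent, 25.00)
  # degenerate case: A with A equals the single-motif frequency
  co_aa <- cooccurrence_frequency(seqs, a, a)
  expect_equal(co_aa$count, 2L)
  # co-occurrence <= min of single frequencies on real profiled sets
  secs <- get_section_seqs()
  reg <- default_motif_registry()
  tab <- motif_frequency_table(secs["LTR5Hs"], reg)
  co2 <- cooccurrence_frequency(secs$LTR5Hs, reg[["TP53-1"]], reg[["TP53-2"]])
  expect_lte(co2$percent,
             min(tab$percent[tab$motif %in% c("TP53-1", "TP53-2")]))
})

test_that("conservation matrix reproduces hand-computed information content", {
  cm <- conservation_matrix(rep("TATAAA", 5))
  expect_equal(cm$ic, rep(2, 6))
  cm2 <- conservation_matrix(c("AA", "AC", "CA", "CC"))
  expect_equal(cm2$ic, c(1, 1))
  # 4-sequence toy block, hand arithmetic: col1 {A,A,A,C} -> 2 - H(3/4,1/4)
  cm3 <- conservation_matrix(c("AT", "AT", "AT", "CT"))
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(cm3$ic, c(2 - h, 2))
  expect_equal(colSums(cm3$counts), c(4, 4))
  expect_true(all(cm3$ic >= 0 & cm3$ic <= 2))
})
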