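test_that("the canonical partition has the printed section lengths and no gaps", {
  rs <- get_ref_set()
  sec <- partition_sections(rs$frame_ref, rs$tss_index)
  expect_equal(sec$end_rel - sec$start_rel + 1L, c(240L, 289L, 264L, 177L))
  # adjacent and exhaustive over -792..177
  expect_equal(sec$start_rel[-1], sec$end_rel[-4] + 1L)
  expect_equal(range(c(sec$start_rel, sec$end_rel)), c(-792L, 177L))
  # overlapping custom sections are rejected
  bad <- rbind(section_spec("x", -100L, 0L), section_spec("y", -50L, 50L))
  expect_error(partition_sections(rs$frame_ref, rs$tss_index, bad),
               "overlapping")
  tiny <- seq_record("tiny", strrep("ACGT", 10))
  expect_error(partition_sections(tiny, 41L), "shorter")
})

test_that("homologous section replacement splices the donor and preserves flanks", {
  rs <- get_ref_set()
  backbone <- rs$refs$LTR5B$record
  donor <- rs$refs$LTR5Hs$record
  s3 <- ltr_sections()[3, ]
  # identity replacement: donor = backbone
  same <- homologous_replace(backbone, backbone, s3, rs$frame_ref,
                             rs$tss_index)
  expect_equal(same$final_seq, backbone$seq)
  expect_equal(same$length_delta, 0L)

  chim <- homologous_replace(backbone, donor, s3, rs$frame_ref, rs$tss_index)
  dmap <- anchor_to_frame(donor, rs$frame_ref, rs$tss_index)
  donor_sec <- extract_section(donor, dmap, s3)$seq
  # the donor section is present verbatim in the chimera
  expect_true(grepl(donor_sec, chim$final_seq, fixed = TRUE))
  # flanks are byte-identical to the backbone
  bmap <- anchor_to_frame(backbone, rs$frame_ref, rs$tss_index)
  bsec <- extract_section(backbone, bmap, s3)
  i1 <- rel_to_index(s3$start_rel, rs$tss_index)
  i2 <- rel_to_index(s3$end_rel, rs$tss_index)
  rng <- range(bmap$map[i1:i2], na.rm = TRUE)
  expect_equal(substr(chim$final_seq, 1, rng[1] - 1),
               substr(backbone$seq, 1, rng[1] - 1))
  expect_equal(substring(chim$final_seq, rng[1] + nchar(donor_sec)),
               substring(backbone$seq, rng[2] + 1))
  expect_equal(chim$length_delta, nchar(donor_sec) - nchar(bsec$seq))

  # replacing the section back with the backbone's own copy restores it
  restored <- homologous_replace(chim, backbone, s3, rs$frame_ref,
                                 rs$tss_index)
  expect_equal(restored$final_seq, backbone$seq)
})

test_that("site mutations edit exactly the designated occurrence", {
  reg <- default_mutation_registry()
  expect_equal(apply_site_mutation("AAGGGCTGGAA", reg[["TP53-1"]]),
               "AATGGCTGGAA")
  expect_equal(apply_site_mutation("CCTATAACC", reg[["TATA"]]),
               "CCTGTAACC")
  expect_error(apply_site_mutation("CCCCCC", reg[["TATA"]]), "not found")
  # ambiguous matches are refused unless an occurrence is designated
  expect_error(apply_site_mutation("TATAAxTATAA", reg[["TATA"]]),
               "occurs 2 times")
  m2 <- mutation_def("TATA", "TATAA", "TGTAA", occurrence = 2L)
  expect_equal(apply_site_mutation("TATAACTATAAC", m2), "TATAACTGTAAC")
  # unequal-length edit bookkeeping (POU2F1: 11 nt -> 30 nt)
  rs <- get_ref_set()
  con <- add_mutation(rs$frame_ref, reg[["POU2F1"]])
  expect_equal(con$length_delta, 19L)
  expect_equal(nchar(con$final_seq), nchar(rs$frame_ref$seq) + 19L)
})

test_that("edit replay reproduces the final sequence byte-for-byte", {
  rs <- get_ref_set()
  reg <- default_mutation_registry()
  s3 <- ltr_sections()[3, ]
  con <- homologous_replace(rs$refs$LTR5B$record, rs$refs$LTR5Hs$record, s3,
                            rs$frame_ref, rs$tss_index)
  con <- add_mutation(con, reg[["TP53-1"]])
  con <- add_mutation(con, reg[["POU2F1"]])
  expect_identical(replay_edits(con, rs$frame_ref, rs$tss_index),
                   con$final_seq)
  expect_equal(nchar(con$final_seq) - nchar(con$backbone_seq),
               con$length_delta)
})

test_that("mutant constructs lose exactly their targeted wild-type motifs", {
  rs <- get_ref_set()
  motifs <- default_motif_registry()
  mreg <- default_mutation_registry()
  s3 <- ltr_sections()[3, ]
  # the unedited LTR5Hs frame carries all wild-type motifs
  base <- new_construct(rs$frame_ref)
  v0 <- validate_construct(base, motifs)
  expect_true(all(v0$before))
  expect_true(attr(v0, "length_ok"))
  # the 5Hs3-5B chimera gains them on the LTR5B backbone
  chim <- homologous_replace(rs$refs$LTR5B$record, rs$refs$LTR5Hs$record, s3,
                             rs$frame_ref, rs$tss_index)
  vc <- validate_construct(chim, motifs)
  expect_true(all(vc$change == "gained"))
  # each single mutant loses its own motif and nothing else
  for (nm in names(mreg)) {
    mut <- add_mutation(chim, mreg[[nm]])
    vm <- validate_construct(mut, motifs)
    expect_false(vm$after[vm$motif == nm], label = nm)
    expect_true(all(vm$after[vm$motif != nm]), label = nm)
  }
  # the TP53-1 + TP53-2 double mutant loses both p53 sites
  dbl <- add_mutation(add_mutation(chim, mreg[["TP53-1"]]), mreg[["TP53-2"]])
  vd <- validate_construct(dbl, motifs)
  expect_false(any(vd$after[vd$motif %in% c("TP53-1", "TP53-2")]))
  expect_true(all(vd$after[!vd$motif %in% c("TP53-1", "TP53-2")]))
  # reverse-orientation insert is the reverse complement
  expect_equal(reverse_insert(dbl), reverse_complement(dbl$final_seq))
})
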