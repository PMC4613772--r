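test_that("alignment blocks validate shape and alphabet", {
  expect_error(alignment_block(c(a = "ACGU")), "2")
  expect_error(alignment_block(c(a = "ACGU", b = "ACG")), "equal length")
  expect_error(alignment_block(c(a = "ACXU", b = "ACGU")), "alphabet")
  b <- alignment_block(c(a = "AC-U", b = "ACGU"))
  expect_equal(b$width, 4L)
})

test_that("fallback folding matches exhaustive enumeration", {
  r <- fold_mfe("AAAA")
  expect_equal(r$energy, 0)
  expect_equal(r$structure, "....")

  r2 <- fold_mfe("GGGAAACCC")
  expect_equal(r2$energy, -3)
  expect_equal(r2$structure, "(((...)))")
  expect_identical(fold_mfe("GGGAAACCC"), fold_mfe("GGGAAACCC"))

  set.seed(40)
  for (i in 1:20) {
    s <- random_seq(sample(8:14, 1), c("A", "C", "G", "U"))
    got <- fold_mfe(s)
    want <- fold_oracle(s)
    expect_equal(-got$energy, want$pairs, info = s)
    expect_equal(got$structure, want$s, info = s)
  }
  # a couple of longer cases up to 18 nt
  for (s in c("GGGGAAAACCCCAAGGCC", "AUGCUAGCUAGCAUGCUA")) {
    got <- fold_mfe(s)
    want <- fold_oracle(s)
    expect_equal(-got$energy, want$pairs, info = s)
    expect_equal(got$structure, want$s, info = s)
  }
})

test_that("folded structures are balanced with loops >= 3", {
  set.seed(41)
  for (i in 1:10) {
    s <- random_seq(30, c("A", "C", "G", "U"))
    st <- fold_mfe(s)$structure
    op <- integer(0)
    for (pos in seq_len(nchar(st))) {
      ch <- substr(st, pos, pos)
      if (ch == "(") op <- c(op, pos)
      if (ch == ")") {
        expect_gte(pos - op[length(op)] - 1L, 3L)
        op <- op[-length(op)]
      }
    }
    expect_length(op, 0L)
  }
})

test_that("consensus folding agrees with single-row folding on identical rows", {
  s <- "GGGGAAACCCCAUGC"
  blk <- alignment_block(c(a = s, b = s, c = s))
  cons <- consensus_fold(blk)
  single <- fold_mfe(s)
  expect_equal(cons$structure, single$structure)
  expect_equal(cons$energy, single$energy)

  blk2 <- alignment_block(c(a = "AAAAAAAA", b = "AAAAAAAA"))
  cons2 <- consensus_fold(blk2)
  expect_equal(cons2$energy, 0)
  expect_false(grepl("[()]", cons2$structure))
})

test_that("planted hairpins drive the consensus fold", {
  blk <- plant_hairpin_alignment(6, 12, 6, stem_identity = 0.85,
                                 loop_substitution_rate = 0.5, seed = 44L)
  cons <- consensus_fold(blk)
  expect_gte(lengths(regmatches(cons$structure,
                                gregexpr("(", cons$structure, fixed = TRUE))),
             12L)
})

test_that("SCI is exactly 1 for identical rows and <= 1 for the fallback engine", {
  s <- "GGCGAAAGCGCCAAAU"
  blk <- alignment_block(c(a = s, b = s, c = s))
  expect_equal(as.numeric(structure_conservation_index(blk)), 1)

  flat <- alignment_block(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA"))
  sci <- structure_conservation_index(flat)
  expect_true(is.na(sci))
  expect_true(attr(sci, "unstructured"))

  # the pair-maximization engine can never exceed 1: the consensus structure
  # restricted to any row is itself a valid structure for that row
  set.seed(45)
  for (i in 1:15) {
    rows <- replicate(3, random_seq(20, c("A", "C", "G", "U")))
    sci <- structure_conservation_index(alignment_block(
      setNames(rows, c("a", "b", "c"))))
    if (!is.na(sci)) expect_lte(as.numeric(sci), 1 + 1e-12)
  }
})

test_that("the thermodynamic engine rewards compensatory mutations with SCI > 1", {
  blk <- alignment_block(c(a = "GGGGGAAAACCCCC", b = "CCCCGAAAACGGGG"))
  expect_equal(as.numeric(structure_conservation_index(blk, engine = "fallback")), 1)
  sci_v <- structure_conservation_index(blk, engine = "vienna")
  expect_gt(as.numeric(sci_v), 1)
})

test_that("RNAfold engine parses structures and energies", {
  r <- fold_mfe("GGGAAACCC", engine = "vienna")
  expect_equal(r$structure, "(((...)))")
  expect_lt(r$energy, 0)
})

test_that("column shuffling preserves the conservation pattern", {
  blk <- alignment_block(c(a = "ACGUACGUAC", b = "ACGAACGAAC",
                           c = "AC-UACGUAA"))
  sh <- shuffle_alignment_columns(blk, seed = 7L)
  m0 <- do.call(rbind, strsplit(unname(blk$rows), ""))
  m1 <- do.call(rbind, strsplit(unname(sh$rows), ""))
  # per-row residue multisets unchanged
  for (r in 1:3) expect_equal(sort(m1[r, ]), sort(m0[r, ]))
  # gap pattern per column-class unchanged: gapped column stays at position 3
  expect_equal(which(m1[3, ] == "-"), which(m0[3, ] == "-"))
  # column multiset unchanged as a whole
  cols0 <- sort(apply(m0, 2, paste, collapse = ""))
  cols1 <- sort(apply(m1, 2, paste, collapse = ""))
  expect_equal(cols0, cols1)
  expect_identical(sh, shuffle_alignment_columns(blk, seed = 7L))

  # fully conserved gapless columns may permute freely but keep content
  blk2 <- alignment_block(c(a = "ACGU", b = "ACGU"))
  sh2 <- shuffle_alignment_columns(blk2, seed = 1L)
  expect_equal(sort(strsplit(sh2$rows[[1]], "")[[1]]), c("A", "C", "G", "U"))
  expect_equal(sh2$rows[[1]], sh2$rows[[2]])
})

test_that("SCI of a block is invariant under row reordering", {
  blk <- plant_hairpin_alignment(4, 8, 5, stem_identity = 0.9,
                                 loop_substitution_rate = 0.4, seed = 50L)
  rows <- blk$rows
  sci1 <- as.numeric(structure_conservation_index(alignment_block(rows)))
  sci2 <- as.numeric(structure_conservation_index(alignment_block(rev(rows))))
  expect_equal(sci1, sci2)
})

test_that("hairpin blocks reach empirical significance; errors are raised cleanly", {
  blk <- plant_hairpin_alignment(6, 12, 6, stem_identity = 0.85,
                                 loop_substitution_rate = 0.5, seed = 52L)
  rep <- sci_empirical_pvalue(blk, n = 1000L, seed = 3L)
  expect_lt(rep$empirical_p, 0.05)
  expect_true(rep$reliable)
  expect_gte(rep$empirical_p, 1 / (rep$n_valid + 1))   # add-one rule
  expect_error(sci_empirical_pvalue(blk, n = 0L), "at least one")
})

test_that("aligned FASTA round-trips alignment blocks", {
  blk <- alignment_block(c(sp1 = "ACGU-ACG", sp2 = "ACGUAACG"))
  tf <- withr::local_tempfile(fileext = ".fa")
  write_alignment_fasta(blk, tf)
  expect_equal(read_alignment_fasta(tf), blk)
})
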