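test_that("sequence composition matches hand counts", {
  c1 <- sequence_composition("ACGT")
  expect_equal(c1$gc, 0.5)
  c2 <- sequence_composition("CGCGCG")
  expect_equal(c2$cpg_oe, 3 * 6 / (3 * 3))
  c3 <- sequence_composition("ATGATG")
  expect_equal(unname(c3$trinucleotides["ATG"]), 2L)
  c4 <- sequence_composition("AATTAA")
  expect_true(is.na(c4$cpg_oe))
  expect_false(c4$cpg_oe_defined)
  # N positions excluded from denominators
  c5 <- sequence_composition("GCNN")
  expect_equal(c5$gc, 1)
})

test_that("sliding GC profile has the right geometry", {
  p <- sliding_gc_profile(strrep("G", 100), 50, 10)
  expect_equal(nrow(p), 6L)
  expect_true(all(p$gc == 1))
  expect_equal(p$offset, seq(0L, 50L, by = 10L))
  set.seed(30)
  s <- random_seq(200)
  pr <- sliding_gc_profile(s, 50, 10)
  prc <- sliding_gc_profile(revcomp(s), 50, 10)
  expect_equal(pr$gc, rev(prc$gc))   # GC is strand-symmetric
  expect_warning(empty <- sliding_gc_profile("ACGT", 50, 10), "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("distance to the translation start anchors at the region 3' end", {
  expect_equal(distance_to_translation_start(1950L, 2000L, 2000L), 0L)
  expect_equal(distance_to_translation_start(0L, 50L, 2000L), 1950L)
  expect_equal(distance_to_translation_start(900L, 950L, 1000L), 50L)
  expect_error(distance_to_translation_start(900L, 1100L, 1000L), "outside")
})

test_that("positional conservation test matches hand-ranked Spearman", {
  r <- position_conservation_test(1:10, (1:10)^2)
  expect_equal(r$rho, 1)
  r2 <- position_conservation_test(c(1, 2, 3), c(2, 1, 3))
  expect_equal(r2$rho, 0.5)
  expect_error(position_conservation_test(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})

test_that("positional conservation p-values are null-calibrated", {
  set.seed(31)
  ps <- replicate(1000, {
    position_conservation_test(runif(50), runif(50))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank-sum test agrees with exhaustive enumeration", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)   # 2 / choose(6, 3)

  same <- rank_sum_test(c(5, 7, 7, 9), c(9, 7, 5, 7))
  expect_gte(same$p, 0.99)

  set.seed(32)
  for (i in 1:15) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties included
    y <- sample(1:6, m, replace = TRUE)
    got <- rank_sum_test(x, y)
    expect_equal(got$p, ranksum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("normal approximation stays within 0.005 of exact for 12 < n+m <= 16", {
  set.seed(33)
  for (i in 1:8) {
    n <- sample(6:8, 1); m <- sample(7:8, 1)
    if (n + m <= 12) m <- 13 - n
    x <- runif(n, 0, 10)
    y <- runif(m, 2, 12)
    approx_p <- rank_sum_test(x, y)$p
    exact_p <- ranksum_oracle(x, y)
    expect_lt(abs(approx_p - exact_p), 0.005)
  }
})

test_that("k-mer transcribed overlap counts exact both-strand matches", {
  set.seed(34)
  cne <- random_seq(20)
  expect_equal(kmer_transcribed_overlap(cne, paste0("AC", cne, "GT")), 100)
  expect_equal(kmer_transcribed_overlap(cne, revcomp(cne)), 100)
  expect_equal(kmer_transcribed_overlap(cne, character(0)), 0)

  first20 <- random_seq(21)
  tx <- substr(first20, 1, 20)
  got <- kmer_transcribed_overlap(first20, tx)
  expect_equal(got, 50)   # first of the two 20-mers matches

  expect_warning(nav <- kmer_transcribed_overlap("ACGT", "ACGT"), "shorter")
  expect_true(is.na(nav))
})

test_that("hypergeometric enrichment is exact", {
  expect_equal(hypergeometric_enrichment(10, 5, 2, 0), 1)
  expect_equal(hypergeometric_enrichment(10, 5, 2, 2), choose(5, 2) / choose(10, 2))
  expect_error(hypergeometric_enrichment(10, 5, 12, 2), "inconsistent")
  set.seed(35)
  for (i in 1:10) {
    N <- sample(5:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    if (n - k > N - K) next
    expect_equal(hypergeometric_enrichment(N, K, n, k),
                 hyper_oracle(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("matched control regions preserve length and distance exactly", {
  set.seed(36)
  regions <- setNames(lapply(c(300, 400, 500, 350), random_seq),
                      c("g1", "g2", "g3", "g4"))
  regions <- vapply(regions, identity, character(1))
  cnes <- data.frame(gene = c("g1", "g2"), start = c(100L, 200L),
                     end = c(190L, 290L))
  sets <- matched_control_regions(cnes, regions, n_sets = 10L, seed = 9L)
  expect_length(sets, 10L)
  for (set in sets) {
    for (i in seq_len(nrow(set))) {
      src <- set$source_cne[i]
      expect_false(set$gene[i] == cnes$gene[src])
      expect_equal(set$end[i] - set$start[i], cnes$end[src] - cnes$start[src])
      d_src <- nchar(regions[[cnes$gene[src]]]) - cnes$end[src]
      expect_equal(nchar(regions[[set$gene[i]]]) - set$end[i], d_src)
      expect_equal(nchar(set$sequence[i]), set$end[i] - set$start[i])
    }
  }
  expect_identical(sets, matched_control_regions(cnes, regions, 10L, seed = 9L))

  # geometry that fits nowhere is skipped with a warning
  cnes2 <- data.frame(gene = "g3", start = 0L, end = 500L)
  expect_warning(s2 <- matched_control_regions(cnes2, regions, 1L, seed = 1L),
                 "skipped")
  expect_null(s2[[1]])
})
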