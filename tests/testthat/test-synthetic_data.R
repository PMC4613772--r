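test_that("evolve_sequence is an identity at rate 0 and deterministic by seed", {
  anc <- random_seq(500)
  expect_equal(evolve_sequence(anc, 0, 0, seed = 1L), anc)
  a <- evolve_sequence(anc, 0.2, 0.02, 2, seed = 99L)
  b <- evolve_sequence(anc, 0.2, 0.02, 2, seed = 99L)
  expect_identical(a, b)
  expect_false(identical(a, evolve_sequence(anc, 0.2, 0.02, 2, seed = 100L)))
})

test_that("substitution-only divergence matches the nominal rate", {
  set.seed(3)
  anc <- random_seq(10000)
  ev <- evolve_sequence(anc, 0.1, 0, seed = 5L)
  d <- mean(strsplit(anc, "")[[1]] != strsplit(ev, "")[[1]])
  expect_gt(d, 0.08)
  expect_lt(d, 0.12)
})

test_that("cohort bookkeeping: truth intervals, regions, determinism", {
  cfg <- evolution_config(ancestor_length = 400L, n_genes = 10L, seed = 21L,
    species = data.frame(name = c("nvit", paste0("c", 1:3)),
                         substitution_rate = 0.3, indel_rate = 0.01,
                         indel_mean_len = 2))
  el <- planted_element(distance_from_tls = 60L, length = 90L,
                        element_substitution_rate = 0.02)
  coh <- generate_ortholog_cohort(cfg, list(el))
  expect_equal(nrow(coh$truth), 10L * 4L)
  # truth intervals lie within their region sequences, at the right distance
  for (i in seq_len(nrow(coh$truth))) {
    reg <- coh$regions[[coh$truth$species[i]]][[coh$truth$gene[i]]]
    expect_lte(coh$truth$end[i], nchar(reg))
    expect_equal(nchar(reg) - coh$truth$end[i], 60L)
  }
  coh2 <- generate_ortholog_cohort(cfg, list(el))
  expect_identical(coh$sequences, coh2$sequences)
})

test_that("planted elements stay out of each other's way and fit", {
  cfg <- evolution_config(ancestor_length = 300L, n_genes = 2L, seed = 1L)
  expect_error(generate_ortholog_cohort(cfg,
    list(planted_element(10L, 90L), planted_element(50L, 90L))),
    "overlapping")
  expect_error(generate_ortholog_cohort(cfg,
    list(planted_element(250L, 90L))), "fit")
})

test_that("an element absent from comparators yields no discovery support", {
  cfg <- evolution_config(ancestor_length = 400L, n_genes = 4L, seed = 5L,
    species = data.frame(name = c("nvit", "c1"),
                         substitution_rate = 0.35, indel_rate = 0.01,
                         indel_mean_len = 2))
  coh <- generate_ortholog_cohort(cfg,
    list(planted_element(60L, 90L, 0.02, present_in = "nvit")))
  expect_equal(unique(coh$truth$species), "nvit")
  res <- run_discovery(coh, run_config(span = 400L, seed = 2L))
  expect_equal(nrow(res$cnes), 0L)
})

test_that("identical planted elements give maximal window scores", {
  cfg <- evolution_config(ancestor_length = 400L, n_genes = 2L, seed = 9L,
    species = data.frame(name = c("nvit", "c1"),
                         substitution_rate = 0.35, indel_rate = 0,
                         indel_mean_len = 2))
  coh <- generate_ortholog_cohort(cfg,
    list(planted_element(60L, 90L, element_substitution_rate = 0)))
  g <- coh$genes[1]
  grid <- all_window_pairs(coh$regions$nvit[[g]], coh$regions$c1[[g]])
  expect_equal(max(grid), 50)
  # 90 bp identical element holds 41 consecutive perfect windows
  expect_gte(sum(grid == 50), 41L)
})

test_that("pseudo-ortholog pairing is a seeded uniform derangement", {
  expect_error(generate_pseudo_ortholog_pairs(c("only"), seed = 1L),
               "at least 2")
  p2 <- generate_pseudo_ortholog_pairs(c("a", "b"), seed = 1L)
  expect_equal(p2$comparator_gene, c("b", "a"))
  genes <- sprintf("g%02d", 1:9)
  p <- generate_pseudo_ortholog_pairs(genes, seed = 42L)
  expect_true(all(p$central_gene != p$comparator_gene))
  expect_setequal(p$comparator_gene, genes)
  expect_identical(p, generate_pseudo_ortholog_pairs(genes, seed = 42L))
})

test_that("hairpin blocks have self-complementary stems and respond to loop rate", {
  blk <- plant_hairpin_alignment(4, 12, 6, stem_identity = 1,
                                 loop_substitution_rate = 0, seed = 3L)
  expect_equal(length(unique(blk$rows)), 1L)
  blk2 <- plant_hairpin_alignment(5, 12, 6, stem_identity = 0.8,
                                  loop_substitution_rate = 0.5, seed = 3L)
  for (r in blk2$rows) {
    stem5 <- substr(r, 1, 12)
    stem3 <- substr(r, 19, 30)
    expect_equal(stem3, revcomp(stem5))
  }
  expect_equal(blk2$width, 2L * 12L + 6L)
})

test_that("transcriptome fractions control the k-mer overlap exactly", {
  coh <- make_test_cohort(seed = 31L, n_genes = 4L, ancestor = 400L)
  tr <- coh$truth[coh$truth$species == "nvit", ]
  elem_seq <- function(i) {
    substr(coh$regions$nvit[[tr$gene[i]]], tr$start[i] + 1L, tr$end[i])
  }
  tx_full <- generate_transcriptome(coh, 1.0)
  expect_equal(kmer_transcribed_overlap(elem_seq(1), tx_full$sequence), 100)

  tx_none <- generate_transcriptome(coh, 0.0)
  expect_false(any(grepl("_e1$", tx_none$id)))
  expect_equal(kmer_transcribed_overlap(elem_seq(1), tx_none$sequence), 0)

  tx_third <- generate_transcriptome(coh, 1 / 3)
  # ceiling(90/3) = 30 transcribed bases: 11 of the 71 20-mers fit inside
  expect_equal(kmer_transcribed_overlap(elem_seq(1), tx_third$sequence),
               100 * 11 / 71)
})

test_that("cohorts round-trip through the on-disk layout", {
  coh <- make_test_cohort(seed = 13L, n_genes = 3L, ancestor = 300L)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  for (s in coh$species$name) {
    fa <- read_fasta(file.path(dir, paste0(s, ".fa")))
    expect_equal(fa$sequence, coh$sequences[[s]]$sequence)
    expect_true(file.exists(file.path(dir, paste0(s, ".gff3"))))
  }
  expect_true(file.exists(file.path(dir, "manifest.cfg")))
  bed <- read_bed(file.path(dir, "nvit.elements.bed"))
  expect_equal(nrow(bed), 3L)
})
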