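test_that("repeat penalty turns masked windows into mismatches", {
  region <- list(sequence = random_seq(100),
                 repeat_mask = data.frame(start = integer(), end = integer()))
  expect_equal(apply_repeat_penalty(region), region$sequence)

  region$repeat_mask <- data.frame(start = 0L, end = 100L)
  masked <- apply_repeat_penalty(region)
  expect_equal(masked, strrep("N", 100))
  expect_equal(max(all_window_pairs(masked, masked)), 0)

  region$repeat_mask <- data.frame(start = 90L, end = 110L)
  expect_error(apply_repeat_penalty(region), "outside")

  # identical 50-mers with 10 masked positions: raw 40, intermediate 80
  s <- random_seq(50)
  reg <- list(sequence = s, repeat_mask = data.frame(start = 10L, end = 20L))
  m <- apply_repeat_penalty(reg)
  raw <- window_pair_score(m, m)
  expect_equal(raw, 40)
  expect_equal(intermediate_score(raw, 50), 80)
})

test_that("intermediate_score is percent-of-maximum and validated", {
  expect_equal(intermediate_score(50, 50), 100)
  expect_equal(intermediate_score(0, 50), 0)
  expect_equal(intermediate_score(43.5, 50), 87)
  expect_error(intermediate_score(51, 50), "outside")
  expect_error(intermediate_score(-1, 50), "outside")
})

test_that("sigmoid scaling clamps at the bounds and is symmetric in between", {
  expect_equal(sigmoid_scale(79, 80, 94), 0)
  expect_equal(sigmoid_scale(80, 80, 94), 0)
  expect_equal(sigmoid_scale(95, 80, 94), 1)
  expect_equal(sigmoid_scale(94, 80, 94), 1)
  expect_equal(sigmoid_scale(87, 80, 94), 0.5)
  s <- seq(80, 94, by = 0.25)
  p <- sigmoid_scale(s, 80, 94)
  expect_true(all(diff(p) > 0))
  # point symmetry about the midpoint
  expect_equal(sigmoid_scale(87 + 3, 80, 94), 1 - sigmoid_scale(87 - 3, 80, 94))
})

test_that("extract_significant_windows keeps only pairs above L", {
  g <- matrix(0, 5, 5)
  expect_equal(nrow(extract_significant_windows(g, 50, 80, 94)), 0L)
  g[2, 3] <- 50
  sig <- extract_significant_windows(g, 50, 80, 94)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$central_offset, 1L)
  expect_equal(sig$comparator_offset, 2L)
  expect_equal(sig$P, 1)
  g[4, 4] <- 40   # intermediate exactly 80: excluded by the strict rule
  expect_equal(nrow(extract_significant_windows(g, 50, 80, 94)), 1L)
})

test_that("bundling merges overlapping central windows transitively", {
  mk <- function(offs, comp, P = 0.9) {
    data.frame(central_offset = offs, comparator_offset = comp,
               raw_score = 50, intermediate_score = 100, P = P)
  }
  w <- 50L
  one <- bundle_windows(list(spA = mk(c(10L, 40L), c(100L, 130L))), w)
  expect_length(one, 1L)
  expect_equal(one[[1]]$central_start, 10L)
  expect_equal(one[[1]]$central_end, 90L)

  two <- bundle_windows(list(spA = mk(c(10L, 70L), c(0L, 0L))), w)
  expect_length(two, 2L)

  multi <- bundle_windows(list(spA = mk(10L, 5L, P = 0.6),
                               spB = mk(40L, 300L, P = 0.8)), w)
  expect_length(multi, 1L)
  expect_equal(multi[[1]]$central_start, 10L)
  expect_equal(multi[[1]]$central_end, 90L)
  expect_equal(nrow(multi[[1]]$supports), 2L)
  expect_equal(multi[[1]]$ccs, 1 - (1 - 0.6) * (1 - 0.8))
})

test_that("bundling is idempotent and order-independent", {
  set.seed(20)
  mkrand <- function() {
    n <- 8L
    data.frame(central_offset = sample(0:200, n),
               comparator_offset = sample(0:200, n),
               raw_score = 45, intermediate_score = 90,
               P = runif(n, 0.3, 1))
  }
  pa <- mkrand(); pb <- mkrand()
  r1 <- bundle_windows(list(spA = pa, spB = pb), 50L)
  r2 <- bundle_windows(list(spB = pb, spA = pa[sample(nrow(pa)), ]), 50L)
  key <- function(x) {
    o <- order(vapply(x, `[[`, numeric(1), "central_start"))
    lapply(x[o], function(c) c[c("central_start", "central_end", "ccs")])
  }
  expect_equal(key(r1), key(r2))
})

test_that("combined conservation score follows 1 - prod(1 - P)", {
  expect_equal(combined_conservation_score(0.5), 0.5)
  expect_equal(combined_conservation_score(c(0.5, 0.5)), 0.75)
  expect_equal(combined_conservation_score(c(1, 0.2, 0)), 1)
  expect_equal(combined_conservation_score(c(0, 0)), 0)
  expect_error(combined_conservation_score(numeric(0)), "empty")
  expect_error(combined_conservation_score(1.2), "\\[0, 1\\]")
  # monotone: adding a species never decreases the CCS; bounded by max P
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(1:5, 1))
    extra <- runif(1)
    expect_gte(combined_conservation_score(c(p, extra)),
               combined_conservation_score(p))
    expect_gte(combined_conservation_score(p), max(p))
    expect_lte(combined_conservation_score(p), min(1, sum(p)))
  }
})

test_that("CCS threshold calibration makes the control undetectable", {
  mkcand <- function(ccs) list(central_start = 0L, central_end = 50L,
                               supports = NULL, ccs = ccs)
  thr <- calibrate_ccs_threshold(list(mkcand(0.2), mkcand(0.4)))
  expect_equal(thr, 0.4)
  expect_true(0.41 > thr)
  expect_false(0.40 > thr)
  expect_equal(calibrate_ccs_threshold(list()), 0)
})

test_that("permute_sequence preserves the residue multiset deterministically", {
  expect_equal(permute_sequence("AAAA", seed = 1L), "AAAA")
  s <- random_seq(200)
  p <- permute_sequence(s, seed = 5L)
  expect_equal(sort(strsplit(p, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_identical(p, permute_sequence(s, seed = 5L))
})

test_that("coding filter discards hits more significant than the permuted floor", {
  hits <- function(id, e) data.frame(query_id = id, subject_id = "nr1",
                                     bit_score = 100, e_value = e)
  cf <- coding_filter(c("c1", "c2", "c3"),
                      rbind(hits("c1", 1e-7), hits("c2", 1e-3)),
                      hits("perm", 1e-5))
  expect_equal(cf$threshold, 1e-5)
  expect_equal(cf$removed, "c1")
  expect_setequal(cf$passed, c("c2", "c3"))

  empty <- data.frame(query_id = character(), subject_id = character(),
                      bit_score = numeric(), e_value = numeric())
  expect_message(cf2 <- coding_filter(c("c1", "c2"), hits("c1", 0.5), empty),
                 "\\+Inf")
  expect_equal(cf2$removed, "c1")
  expect_equal(cf2$passed, "c2")
})

test_that("pseudo-CNE calls respect the CCS cutoff monotonically", {
  set.seed(22)
  shared <- random_seq(70)   # unannotated shared similarity
  central <- list(g1 = paste0(random_seq(40), shared, random_seq(40)),
                  g2 = paste0(random_seq(60), shared, random_seq(30)))
  comp <- list(cmp1 = list(g1 = paste0(random_seq(20), shared, random_seq(50)),
                           g2 = paste0(shared, random_seq(80))))
  pp <- data.frame(central_gene = c("g1", "g2"),
                   comparator_gene = c("g2", "g1"))
  counts <- vapply(c(0, 0.5, 0.9999, 1), function(cut) {
    th <- threshold_config(pseudo_cne_ccs_cutoff = cut)
    length(call_pseudo_cnes(central, comp, pp, thresholds = th))
  }, numeric(1))
  expect_gte(counts[1], 2)          # cutoff 0: every candidate survives
  expect_equal(counts[4], 0)        # cutoff 1: nothing exceeds it
  expect_true(all(diff(counts) <= 0))
})
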