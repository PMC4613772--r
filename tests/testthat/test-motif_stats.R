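det_pwm <- function(id, bases) {
  m <- matrix(0, 4, length(bases), dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_along(bases)) m[bases[j], j] <- 1
  pwm(id, m)
}

rand_pwm <- function(id, L) {
  m <- matrix(stats::rgamma(4 * L, 1), 4, L)
  pwm(id, m)
}

test_that("PWM construction normalizes columns and validates", {
  p <- pwm("m1", matrix(c(2, 2, 2, 2, 8, 0, 0, 0), 4))
  expect_equal(unname(colSums(p$mat)), c(1, 1))
  expect_equal(unname(p$mat["A", 2]), 1)
  expect_error(pwm("bad", matrix(0, 4, 2)), "zero")
})

test_that("JASPAR-style PWM files parse", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    ">MA0001.1 test",
    "A [ 4 19  0 ]",
    "C [16  0  1 ]",
    "G [ 0  1 19 ]",
    "T [ 0  0  0 ]",
    ">MA0002.1 bare",
    "1 0", "0 1", "0 0", "0 0"), tf)
  ps <- read_jaspar_pwms(tf)
  expect_length(ps, 2L)
  expect_equal(ps[[1]]$id, "MA0001.1")
  expect_equal(unname(ps[[1]]$mat["A", 1]), 0.2)
  expect_equal(ncol(ps[[2]]$mat), 2L)

  shipped <- read_jaspar_pwms(system.file("extdata", "example_pwms.txt",
                                          package = "cnescan"))
  expect_length(shipped, 3L)
  # the palindromic example is its own reverse complement
  pal <- shipped[[which(vapply(shipped, `[[`, character(1), "id") ==
                          "EX0003.1")]]
  expect_equal(hellinger_distance(pal, pal), 0)
  expect_true(all(abs(colSums(pal$mat) - 1) < 1e-9))
})

test_that("Hellinger distance: identity, disjoint columns, symmetry, revcomp", {
  a <- det_pwm("a", c("A", "C", "G", "T", "A"))
  expect_equal(hellinger_distance(a, a), 0)

  one_a <- det_pwm("x", "A"); one_c <- det_pwm("y", "C")
  expect_equal(hellinger_distance(one_a, one_c), 1)

  set.seed(60)
  p1 <- rand_pwm("p1", 6); p2 <- rand_pwm("p2", 8)
  expect_equal(hellinger_distance(p1, p2), hellinger_distance(p2, p1))

  # a PWM is at distance 0 from its own reverse complement
  rc <- pwm("rc", p1$mat[c("T", "G", "C", "A"), rev(seq_len(6))])
  expect_equal(hellinger_distance(p1, rc), 0)
})

test_that("clustering cuts at the threshold and picks median-entropy reps", {
  sharp <- det_pwm("aaa", rep("A", 5))      # entropy 0
  sharp2 <- det_pwm("bbb", rep("A", 5))     # identical to sharp
  far <- det_pwm("ccc", rep("G", 5))
  cl <- cluster_pwms(list(far, sharp, sharp2), threshold = 0.5)
  expect_equal(max(cl$membership), 2L)
  expect_equal(cl$membership[["aaa"]], cl$membership[["bbb"]])

  cl0 <- cluster_pwms(list(sharp, far), threshold = 0)
  expect_equal(max(cl0$membership), 2L)
  expect_setequal(cl0$representatives, c("aaa", "ccc"))

  # lower-median representative for an even-sized cluster, by entropy
  flat <- pwm("flat", matrix(1, 4, 5))       # max entropy
  mid <- pwm("mid", cbind(matrix(1, 4, 4), c(0.7, 0.1, 0.1, 0.1)))
  cl2 <- cluster_pwms(list(sharp, flat, mid, sharp2), threshold = 100)
  expect_equal(max(cl2$membership), 1L)
  # entropies: aaa=0, bbb=0, mid<flat; lower median of 4 = 2nd smallest (bbb)
  expect_equal(cl2$representatives, "bbb")
})

test_that("entropy and information-weighted GC behave at the extremes", {
  flat <- pwm("flat", matrix(1, 4, 3))
  s <- pwm_summaries(flat)
  expect_equal(s$entropy_bits, 6)           # 2 bits per column
  expect_equal(s$gc_weight, 0.5)            # falls back to the unweighted mean

  allg <- det_pwm("g", rep("G", 4))
  expect_equal(pwm_summaries(allg)$gc_weight, 1)
  alla <- det_pwm("a", rep("A", 4))
  expect_equal(pwm_summaries(alla)$gc_weight, 0)
})

test_that("scanning counts strong matches on both strands", {
  p <- det_pwm("acg", c("A", "C", "G"))
  r <- scan_and_count(p, "ACG")
  expect_equal(r$n_positions, 2L)   # one offset per strand
  expect_equal(r$hits, 1L)

  # the reverse complement CGT matches on the minus strand
  r2 <- scan_and_count(p, "CGT")
  expect_equal(r2$hits, 1L)

  rN <- scan_and_count(p, strrep("N", 30))
  expect_equal(rN$hits, 0L)

  set.seed(61)
  seqs <- replicate(5, random_seq(60))
  pr <- rand_pwm("r", 6)
  hits <- vapply(c(0.5, 0.7, 0.9), function(f) {
    scan_and_count(pr, seqs, score_fraction = f)$hits
  }, integer(1))
  expect_true(all(diff(hits) <= 0))

  expect_equal(scan_and_count(p, "AC")$n_positions, 0L)
})

test_that("over-representation verdicts follow the all-controls rule", {
  set.seed(62)
  motif <- "GCGCATGCGC"
  p <- det_pwm("planted", strsplit(motif, "")[[1]])
  true_set <- replicate(8, paste0(random_seq(20), motif, random_seq(20)))
  controls <- lapply(1:25, function(i) replicate(8, random_seq(50)))
  call <- overrepresentation_call(p, true_set, controls)
  expect_equal(call$verdict, "over")
  expect_true(call$p_true < min(call$p_controls))

  # a true set identical to one control can never be strictly over
  call2 <- overrepresentation_call(p, controls[[1]], controls)
  expect_false(call2$verdict == "over")

  # nothing scannable: flagged neither
  tiny <- overrepresentation_call(p, "ACGT", list("ACGT"))
  expect_equal(tiny$verdict, "neither")
  expect_true(tiny$flagged)
})

test_that("N mirroring copies mask positions into controls", {
  out <- mirror_n_positions("ACNNGT", "TTTTTT")
  expect_equal(out, "TTNNTT")
  expect_equal(mirror_n_positions("ACGT", "TTTT"), "TTTT")
})
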