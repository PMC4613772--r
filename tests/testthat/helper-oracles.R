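## Independent brute-force oracles used across the suite. These deliberately
## re-derive results from first principles (quadratic DP, exhaustive
## enumeration) and never call the package's fast paths.

## Plain quadratic Needleman-Wunsch, linear gap cost; N matches nothing.
nw_oracle_slow <- function(a, b, match = 1, mismatch = 0, gap = -0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  D <- matrix(0, m + 1, n + 1)
  D[1, ] <- (0:n) * gap
  D[, 1] <- (0:m) * gap
  for (i in 1:m) {
    for (j in 1:n) {
      sub <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + sub, D[i, j + 1] + gap,
                             D[i + 1, j] + gap)
    }
  }
  D[m + 1, n + 1]
}

## Same DP with the left-gap recursion resolved by a running maximum, so a
## whole grid of window pairs can be checked in reasonable time. Verified
## against nw_oracle_slow in the tests before use.
nw_oracle <- function(a, b, match = 1, mismatch = 0, gap = -0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  prev <- (0:n) * gap
  for (i in 1:m) {
    sub <- ifelse(B == A[i] & A[i] != "N", match, mismatch)
    cand <- pmax(prev[1:n] + sub, prev[2:(n + 1)] + gap)
    adj <- c(i * gap, cand - gap * (1:n))
    prev <- cummax(adj)[-1] + gap * (1:n)
    prev <- c(i * gap, prev)
  }
  prev[n + 1]
}

random_seq <- function(n, alpha = c("A", "C", "G", "T")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

## Exhaustive enumeration of all nested secondary structures (min loop 3):
## returns max pairs and the lexicographically smallest max-pairing
## dot-bracket.
fold_oracle <- function(seq, minloop = 3) {
  chars <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  can_pair <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  n <- length(chars)
  memo <- new.env()
  solve <- function(i, j) {
    if (i > j) return(list(pairs = 0L, s = ""))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- solve(i + 1, j)
    best <- list(pairs = best$pairs, s = paste0(".", best$s))
    ks <- if (j >= i + minloop + 1) (i + minloop + 1):j else integer(0)
    for (k in ks) {
      if (!can_pair(chars[i], chars[k])) next
      inner <- solve(i + 1, k - 1)
      right <- solve(k + 1, j)
      p <- 1L + inner$pairs + right$pairs
      s <- paste0("(", inner$s, ")", right$s)
      if (p > best$pairs || (p == best$pairs && s < best$s)) {
        best <- list(pairs = p, s = s)
      }
    }
    memo[[key]] <- best
    best
  }
  solve(1, n)
}

## Exact upper-tail hypergeometric probability by enumerating every sample.
hyper_oracle <- function(N, K, n, k) {
  pop <- c(rep(1, K), rep(0, N - K))
  idx <- utils::combn(N, n)
  mean(colSums(matrix(pop[idx], nrow = n)) >= k)
}

## Exact two-sided rank-sum p by enumerating all assignments of the combined
## sample (handles ties through midranks).
ranksum_oracle <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  idx <- utils::combn(N, n)
  U_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

## Small standard cohort used by several pipeline tests (kept modest so the
## grids stay cheap).
make_test_cohort <- function(seed = 101L, n_genes = 6L, ancestor = 600L,
                             elem_rate = 0.02, elem_gc = NULL,
                             repeat_spec = NULL, n_comp = 3L) {
  cfg <- evolution_config(
    ancestor_length = ancestor, n_genes = n_genes, seed = seed,
    species = data.frame(name = c("nvit", paste0("cmp", seq_len(n_comp))),
                         substitution_rate = 0.35, indel_rate = 0.01,
                         indel_mean_len = 2))
  generate_ortholog_cohort(
    cfg,
    list(planted_element(distance_from_tls = 100L, length = 90L,
                         element_substitution_rate = elem_rate,
                         gc = elem_gc)),
    repeat_spec = repeat_spec)
}
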