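#' Sequence composition summary
#'
#' GC content, CpG observed/expected and trinucleotide counts. Positions with
#' `N` are excluded from all denominators; CpG O/E uses the standard
#' estimator `obs(CG) * len / (#C * #G)`.
#'
#' @param seq DNA sequence (string).
#' @return List with `gc`, `cpg_oe` (`NA` and flagged via the
#'   `cpg_oe_defined` field when `#C * #G == 0`), and `trinucleotides`
#'   (named counts over all 64 trinucleotides, every offset).
#' @export
sequence_composition <- function(seq) {
  check_dna(seq)
  d <- Biostrings::DNAString(seq)
  base <- Biostrings::oligonucleotideFrequency(d, 1)[c("A", "C", "G", "T")]
  len <- sum(base)
  gc <- if (len > 0) unname((base["C"] + base["G"]) / len) else NA_real_
  ncg <- unname(Biostrings::dinucleotideFrequency(d)["CG"])
  denom <- unname(base["C"] * base["G"])
  cpg_oe <- if (denom > 0) ncg * len / denom else NA_real_
  tri <- Biostrings::trinucleotideFrequency(d)
  list(gc = gc, cpg_oe = cpg_oe, cpg_oe_defined = denom > 0,
       trinucleotides = tri)
}

#' Sliding-window GC profile
#'
#' Windows start at offsets `0, step, 2*step, ...` while they fit entirely in
#' the sequence. `N` positions are excluded from each window's denominator.
#'
#' @param seq DNA sequence.
#' @param window Window size in bp.
#' @param step Step size in bp.
#' @return data.frame with columns `offset` (0-based) and `gc`.
#' @export
sliding_gc_profile <- function(seq, window = 50L, step = 10L) {
  len <- nchar(seq)
  if (len < window) {
    warning("sequence shorter than the window; empty profile")
    return(data.frame(offset = integer(), gc = numeric()))
  }
  offs <- seq.int(0L, len - window, by = step)
  gc <- vapply(offs, function(o) {
    win <- substr(seq, o + 1L, o + window)
    n <- nchar(gsub("N", "", win))
    if (n == 0) return(NA_real_)
    (nchar(gsub("[^GC]", "", win))) / n
  }, numeric(1))
  data.frame(offset = offs, gc = gc)
}

#' Distance from a CNE's 3' end to the translation start site
#'
#' Regions are laid out 5' to 3' ending at the translation start, so the
#' distance is `region_length - cne_end`; 0 means the element directly abuts
#' the translation start.
#'
#' @param cne_start,cne_end CNE interval in region coordinates (0-based
#'   half-open).
#' @param region_length Length of the (possibly truncated) upstream region.
#' @return Distance in bp.
#' @export
distance_to_translation_start <- function(cne_start, cne_end, region_length) {
  if (any(cne_start < 0) || any(cne_end > region_length) ||
      any(cne_start >= cne_end)) {
    stop("CNE interval outside its region")
  }
  region_length - cne_end
}

#' Positional conservation test
#'
#' Rank correlation between each element's distance to the translation start
#' in the central species and in the comparator species. Uses Spearman's rho
#' with the t approximation (exact for n <= 10 without ties).
#'
#' @param d_central,d_comparator Paired distance vectors.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `rho` (correlation estimate) and `p` (two-sided).
#' @export
position_conservation_test <- function(d_central, d_comparator,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(d_central) == length(d_comparator))
  if (length(d_central) < 3L) stop("need at least 3 pairs")
  if (sd(d_central) == 0 || sd(d_comparator) == 0) {
    stop("zero variance in a distance margin")
  }
  ct <- suppressWarnings(cor.test(d_central, d_comparator, method = method,
                                  exact = length(d_central) <= 10L))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of distributional shift. Uses midranks for ties. For
#' `length(x) + length(y) <= 12` the null distribution of U is enumerated
#' exactly over all assignments of the combined sample; otherwise a normal
#' approximation with tie correction, continuity correction and an
#' Edgeworth kurtosis term is used (accurate to well under 0.005 of the
#' exact p down to the enumeration boundary).
#'
#' @param x,y Numeric samples.
#' @return List with `U` (Mann-Whitney U for `x`) and `p` (two-sided).
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  comb <- c(x, y)
  r <- rank(comb)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (N <= 12L) {
    idx <- combn(N, n)
    dev <- abs(U - mu)
    cnt <- 0L
    for (j in seq_len(ncol(idx))) {
      Uj <- sum(r[idx[, j]]) - n * (n + 1) / 2
      if (abs(Uj - mu) >= dev - 1e-9) cnt <- cnt + 1L
    }
    p <- cnt / ncol(idx)
  } else {
    ties <- table(comb)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    ## excess kurtosis of U (tie-free form); Edgeworth term sharpens the tail
    g2 <- -(6 / 5) * (m^2 + n^2 + m * n + m + n) / (m * n * (N + 1))
    upper <- function(u) {
      x <- (u - 0.5 - mu) / sqrt(sigma2)
      p1 <- 1 - pnorm(x) + dnorm(x) * (g2 / 24) * (x^3 - 3 * x)
      min(max(p1, 0), 1)
    }
    p <- min(1, 2 * upper(max(U, 2 * mu - U)))
    ## no two-sided p can be smaller than twice one extreme assignment
    p <- max(p, 2 * exp(-lchoose(N, n)))
  }
  list(U = U, p = p)
}

#' Transcribed overlap of a CNE by exact k-mer matching
#'
#' Splits the CNE into all overlapping k-mers and reports the percentage
#' with an exact match (either strand) in any transcript. K-mers containing
#' `N` never match.
#'
#' @param cne_seq CNE sequence (string).
#' @param transcripts Character vector of transcript sequences, or a
#'   data.frame of sequence records.
#' @param k K-mer length.
#' @param max_mismatch Optional mismatch budget (0 or 1); exact matching by
#'   default.
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) if the CNE is
#'   shorter than `k`.
#' @export
kmer_transcribed_overlap <- function(cne_seq, transcripts, k = 20L,
                                     max_mismatch = 0L) {
  if (is.data.frame(transcripts)) transcripts <- transcripts$sequence
  if (nchar(cne_seq) < k) {
    warning("CNE shorter than k; overlap undefined")
    return(NA_real_)
  }
  kmers <- substring(cne_seq, seq_len(nchar(cne_seq) - k + 1L),
                     seq_len(nchar(cne_seq) - k + 1L) + k - 1L)
  if (!length(transcripts)) return(0)
  targets <- c(transcripts, revcomp(transcripts))
  hit <- if (max_mismatch == 0L) {
    tx_kmers <- unique(unlist(lapply(targets, function(t) {
      if (nchar(t) < k) return(character(0))
      substring(t, seq_len(nchar(t) - k + 1L),
                seq_len(nchar(t) - k + 1L) + k - 1L)
    })))
    kmers %in% tx_kmers
  } else {
    subject <- Biostrings::DNAStringSet(targets)
    vapply(kmers, function(km) {
      if (grepl("N", km)) return(FALSE)
      any(Biostrings::vcountPattern(km, subject,
                                    max.mismatch = max_mismatch) > 0)
    }, logical(1))
  }
  100 * sum(hit & !grepl("N", kmers)) / length(kmers)
}

#' Upper-tail hypergeometric enrichment test
#'
#' `P(X >= k)` where `X` is hypergeometric: `n` draws without replacement
#' from a population of `N` containing `K` successes.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Sample size.
#' @param k Observed successes in the sample.
#' @return The exact upper-tail probability.
#' @export
hypergeometric_enrichment <- function(N, K, n, k) {
  if (!(k >= 0 && k <= n && n <= N && k <= K && K <= N)) {
    stop("inconsistent hypergeometric arguments")
  }
  if (n - k > N - K) stop("inconsistent hypergeometric arguments")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Matched genomic control regions
#'
#' For each CNE and each of `n_sets` control sets, samples an interval with
#' the same length and the same distance to the translation start, upstream
#' of a uniformly chosen *different* gene whose region is long enough. CNEs
#' whose geometry fits no other gene are skipped with a warning.
#'
#' @param cnes data.frame with columns `gene`, `start`, `end` (region
#'   coordinates on the central species).
#' @param regions Named list or character vector of central-species region
#'   sequences (names are genes).
#' @param n_sets Number of control sets.
#' @param seed Integer seed.
#' @return List of `n_sets` data.frames with columns `gene`, `start`, `end`,
#'   `sequence`, `source_cne` (row index into `cnes`).
#' @export
matched_control_regions <- function(cnes, regions, n_sets = 10L, seed = 1L) {
  reg_len <- vapply(regions, nchar, integer(1))
  with_seed(seed, {
    lapply(seq_len(n_sets), function(set) {
      rows <- lapply(seq_len(nrow(cnes)), function(i) {
        g <- cnes$gene[i]
        l <- cnes$end[i] - cnes$start[i]
        d <- reg_len[[g]] - cnes$end[i]
        pool <- names(reg_len)[names(reg_len) != g & reg_len >= d + l]
        if (!length(pool)) {
          if (set == 1L) {
            warning("no gene long enough for CNE geometry (", g, ":",
                    cnes$start[i], "-", cnes$end[i], "); skipped")
          }
          return(NULL)
        }
        pick <- pool[sample.int(length(pool), 1L)]
        s0 <- reg_len[[pick]] - d - l
        data.frame(gene = pick, start = s0, end = s0 + l,
                   sequence = substr(regions[[pick]], s0 + 1L, s0 + l),
                   source_cne = i, stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (!length(rows)) return(NULL)
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    })
  })
}
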