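#' Position weight matrix
#'
#' @param id Matrix identifier.
#' @param mat 4 x L numeric matrix (rows A, C, G, T); columns are normalized
#'   to probabilities and must sum to 1 within 1e-9 after normalization of
#'   counts.
#' @return An object of class `pwm`.
#' @export
pwm <- function(id, mat) {
  stopifnot(is.matrix(mat), nrow(mat) == 4L, ncol(mat) >= 1L,
            all(mat >= 0))
  rownames(mat) <- c("A", "C", "G", "T")
  cs <- colSums(mat)
  if (any(cs == 0)) stop("PWM column with zero total")
  mat <- sweep(mat, 2, cs, "/")
  structure(list(id = as.character(id), mat = mat), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "(", ncol(x$mat), "positions )\n")
  print(round(x$mat, 3))
  invisible(x)
}

#' Read JASPAR-style PWM files
#'
#' Accepts the common JASPAR text layout: a `>id name` header followed by
#' four rows (`A`, `C`, `G`, `T`) of counts or probabilities, with or
#' without brackets. Counts are normalized per column.
#'
#' @param path File path.
#' @return List of [pwm()] objects.
#' @export
read_jaspar_pwms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop(sprintf("format error in %s: no '>' headers", path))
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) < 4L) {
      stop(sprintf("format error in %s: PWM '%s' needs 4 base rows", path, id))
    }
    rows <- lapply(body[1:4], function(l) {
      l <- sub("^\\s*[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop(sprintf("format error in %s: ragged PWM '%s'", path, id))
    }
    pwm(id, do.call(rbind, rows))
  })
}

pwm_revcomp <- function(mat) {
  mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
}

hellinger_column <- function(p, q) {
  sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
}

#' Hellinger distance between two PWMs
#'
#' Minimum over all ungapped relative offsets (with overlap at least
#' `min(L_a, L_b, 5)` columns) and over the reverse complement of `b` of
#' the mean per-column Hellinger distance
#' `h(p, q) = sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))` across the overlap.
#'
#' @param a,b [pwm()] objects.
#' @param aggregate `"mean"` (default) or `"sum"` of per-column distances
#'   over the overlap.
#' @return Non-negative distance; 0 for identical matrices.
#' @export
hellinger_distance <- function(a, b, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  ma <- a$mat
  best <- Inf
  for (mb in list(b$mat, pwm_revcomp(b$mat))) {
    La <- ncol(ma); Lb <- ncol(mb)
    minov <- min(La, Lb, 5L)
    for (o in seq(-(Lb - minov), La - minov)) {
      ia <- max(0L, o); ib <- max(0L, -o)
      ov <- min(La - ia, Lb - ib)
      if (ov < minov) next
      h <- vapply(seq_len(ov), function(j) {
        hellinger_column(ma[, ia + j], mb[, ib + j])
      }, numeric(1))
      d <- if (aggregate == "mean") mean(h) else sum(h)
      if (d < best) best <- d
    }
  }
  best
}

#' Entropy and information-weighted GC content of a PWM
#'
#' Total entropy is the sum over columns of `-sum(p * log2(p))`. The GC
#' weight averages each column's `p_G + p_C` with weight equal to its
#' information content `2 - H(column)`; for a matrix with no information at
#' all the unweighted mean is returned.
#'
#' @param x A [pwm()].
#' @return List with `entropy_bits` and `gc_weight`.
#' @export
pwm_summaries <- function(x) {
  mat <- x$mat
  colH <- apply(mat, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  gc <- colSums(mat[c("C", "G"), , drop = FALSE])
  info <- 2 - colH
  gcw <- if (sum(info) > 0) sum(gc * info) / sum(info) else mean(gc)
  list(entropy_bits = sum(colH), gc_weight = gcw)
}

#' Cluster PWMs by Hellinger distance
#'
#' Agglomerative clustering with complete linkage on the pairwise
#' [hellinger_distance()] matrix, cut at `threshold`. The representative of
#' each cluster is the member whose total entropy is the (lower) median,
#' ties broken by id.
#'
#' @param pwms List of [pwm()] objects.
#' @param threshold Height at which the dendrogram is cut.
#' @param aggregate Distance aggregation passed to [hellinger_distance()].
#' @return List with `membership` (named integer vector by PWM id),
#'   `representatives` (character vector of PWM ids, one per cluster) and
#'   `distances` (the distance matrix).
#' @export
cluster_pwms <- function(pwms, threshold = 1.5, aggregate = "mean") {
  ids <- vapply(pwms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate PWM ids")
  o <- order(ids)
  pwms <- pwms[o]; ids <- ids[o]
  n <- length(pwms)
  if (n == 1L) {
    return(list(membership = setNames(1L, ids), representatives = ids,
                distances = matrix(0, 1, 1, dimnames = list(ids, ids))))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- hellinger_distance(pwms[[i]], pwms[[j]],
                                               aggregate = aggregate)
    }
  }
  memb <- if (threshold <= 0) {
    setNames(seq_len(n), ids)
  } else {
    hc <- hclust(as.dist(D), method = "complete")
    cutree(hc, h = threshold)
  }
  ent <- vapply(pwms, function(p) pwm_summaries(p)$entropy_bits, numeric(1))
  reps <- vapply(sort(unique(memb)), function(cl) {
    members <- which(memb == cl)
    members <- members[order(ent[members], ids[members])]
    ids[members[ceiling(length(members) / 2)]]   # lower median for even sizes
  }, character(1))
  list(membership = setNames(as.integer(memb), ids),
       representatives = unname(reps), distances = D)
}

## log2 odds score matrix vs uniform background; zero probabilities give -Inf
pwm_score_matrix <- function(mat) log2(mat / 0.25)

scan_one_strand <- function(smat, seq) {
  L <- ncol(smat)
  n <- nchar(seq)
  if (n < L) return(numeric(0))
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))  # N -> NA
  vapply(0:(n - L), function(o) {
    idx <- code[o + seq_len(L)]
    if (anyNA(idx)) return(-Inf)
    sum(smat[cbind(idx, seq_len(L))])
  }, numeric(1))
}

#' Scan sequences with a PWM and count strong matches
#'
#' Both strands are scanned; a position is a hit when its log-odds score
#' against a uniform background reaches `score_fraction` of the maximum
#' attainable score. Positions containing `N` (log-odds `-Inf`) never hit.
#'
#' @param x A [pwm()].
#' @param sequences Character vector of DNA sequences.
#' @param score_fraction Fraction of the maximum score required for a hit.
#' @return List with `hits` and `n_positions` (positions scanned across both
#'   strands; sequences shorter than the PWM contribute 0 positions).
#' @export
scan_and_count <- function(x, sequences, score_fraction = 0.8) {
  smat <- pwm_score_matrix(x$mat)
  maxs <- sum(apply(smat, 2, max))
  thr <- score_fraction * maxs
  hits <- 0L; npos <- 0L
  for (s in sequences) {
    for (str in c(s, revcomp(s))) {
      sc <- scan_one_strand(smat, str)
      npos <- npos + length(sc)
      hits <- hits + sum(sc >= thr)
    }
  }
  list(hits = as.integer(hits), n_positions = as.integer(npos))
}

#' Over/under-representation call for one PWM
#'
#' Upper-tail binomial p-values for the hit count in the true set and in
#' each control set, with the per-position hit probability estimated from
#' the pooled control sets. The PWM is called over-represented if the true
#' p-value is strictly below every control p-value, under-represented if
#' strictly above all of them, and neither otherwise.
#'
#' @param x A [pwm()].
#' @param true_set Character vector of CNE sequences.
#' @param control_sets List of character vectors (geometry-matched control
#'   sets, typically 100).
#' @param score_fraction Hit threshold passed to [scan_and_count()].
#' @return List of class `overrep_call`: `pwm_id`, `p_true`, `p_controls`,
#'   `verdict` (`"over"`, `"under"`, `"neither"`), `flagged` (TRUE when no
#'   positions could be scanned).
#' @export
overrepresentation_call <- function(x, true_set, control_sets,
                                    score_fraction = 0.8) {
  true_counts <- scan_and_count(x, true_set, score_fraction)
  ctrl_counts <- lapply(control_sets, scan_and_count, x = x,
                        score_fraction = score_fraction)
  pooled_hits <- sum(vapply(ctrl_counts, `[[`, integer(1), "hits"))
  pooled_pos <- sum(vapply(ctrl_counts, `[[`, integer(1), "n_positions"))
  if (true_counts$n_positions == 0L || pooled_pos == 0L) {
    return(structure(list(pwm_id = x$id, p_true = NA_real_,
                          p_controls = rep(NA_real_, length(control_sets)),
                          verdict = "neither", flagged = TRUE),
                     class = "overrep_call"))
  }
  p0 <- pooled_hits / pooled_pos
  binp <- function(cnt) {
    pbinom(cnt$hits - 1L, cnt$n_positions, p0, lower.tail = FALSE)
  }
  p_true <- binp(true_counts)
  p_ctrl <- vapply(ctrl_counts, binp, numeric(1))
  verdict <- if (p_true < min(p_ctrl)) "over"
             else if (p_true > max(p_ctrl)) "under"
             else "neither"
  structure(list(pwm_id = x$id, p_true = p_true, p_controls = p_ctrl,
                 verdict = verdict, flagged = FALSE),
            class = "overrep_call")
}

#' Mirror N positions from a true sequence into a control sequence
#'
#' Control sequences matched to a CNE receive `N` at the same positions
#' where the CNE has `N`, so that unscannable positions are balanced
#' between the true and control sets.
#'
#' @param true_seq,control_seq Equal-length sequences.
#' @return The control sequence with mirrored `N`s.
#' @export
mirror_n_positions <- function(true_seq, control_seq) {
  stopifnot(nchar(true_seq) == nchar(control_seq))
  npos <- gregexpr("N", true_seq, fixed = TRUE)[[1]]
  if (npos[1] == -1L) return(control_seq)
  ch <- strsplit(control_seq, "")[[1]]
  ch[npos] <- "N"
  paste(ch, collapse = "")
}
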