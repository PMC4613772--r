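#' Window alignment scoring scheme
#'
#' The default values are the ones used throughout the pipeline: +1 for a
#' match, 0 for a mismatch, -0.5 for every gap symbol, and 50 bp windows.
#' `N` scores as a mismatch against everything, including another `N`.
#'
#' @param match Match score.
#' @param mismatch Mismatch score.
#' @param gap Score per gap symbol (applied to each gap character in either
#'   row of the alignment).
#' @param window_length Window length in bp.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = 0, gap = -0.5,
                           window_length = 50L) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap),
            window_length >= 1)
  structure(list(match = as.numeric(match), mismatch = as.numeric(mismatch),
                 gap = as.numeric(gap),
                 window_length = as.integer(window_length)),
            class = "scoring_scheme")
}

#' Optimal global alignment score of two windows
#'
#' End-to-end (global) alignment with linear gap cost. Intended for
#' equal-length windows but defined for any pair of non-empty sequences.
#'
#' @param a,b DNA sequences (single strings over A/C/G/T/N).
#' @param scheme A [scoring_scheme()].
#' @return The optimal global alignment score (numeric scalar).
#' @export
window_pair_score <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  cpp_window_score(a, b, scheme$match, scheme$mismatch, scheme$gap)
}

#' Score grid over all window pairs of two sequences
#'
#' Computes the optimal global alignment score for every pair of
#' `w`-length windows (step 1 bp in both sequences). Entry `[i, j]` is the
#' score of `substr(s1, i, i+w-1)` against `substr(s2, j, j+w-1)`.
#'
#' @param s1,s2 DNA sequences, each at least `w` long.
#' @param scheme A [scoring_scheme()].
#' @return A `window_score_grid`: numeric matrix of size
#'   `(nchar(s1)-w+1) x (nchar(s2)-w+1)` with the scheme attached as an
#'   attribute.
#' @export
all_window_pairs <- function(s1, s2, scheme = scoring_scheme()) {
  w <- scheme$window_length
  if (nchar(s1) < w || nchar(s2) < w) {
    stop("sequence shorter than window length")
  }
  g <- cpp_all_window_pairs(s1, s2, w, scheme$match, scheme$mismatch,
                            scheme$gap)
  structure(g, scheme = scheme, class = c("window_score_grid", class(g)))
}

#' Window pairs scoring at or above a floor
#'
#' Sparse equivalent of [all_window_pairs()]: returns only the cells with
#' `raw_score >= min_raw`, as 0-based offsets into the two sequences. Used by
#' the CNE caller so that full 2 kb x 2 kb grids never need to be retained.
#'
#' @inheritParams all_window_pairs
#' @param min_raw Raw score floor.
#' @return data.frame with columns `central_offset`, `comparator_offset`,
#'   `raw_score`.
#' @export
significant_window_pairs <- function(s1, s2, scheme = scoring_scheme(),
                                     min_raw) {
  w <- scheme$window_length
  if (nchar(s1) < w || nchar(s2) < w) {
    stop("sequence shorter than window length")
  }
  cpp_significant_window_pairs(s1, s2, w, scheme$match, scheme$mismatch,
                               scheme$gap, min_raw)
}

#' Number of window pairs scored between two sequences
#'
#' @param m,n Sequence lengths.
#' @param w Window length.
#' @return `(m - w + 1) * (n - w + 1)`.
#' @export
count_window_pairs <- function(m, n, w) {
  if (w > min(m, n)) stop("window length exceeds a sequence length")
  if (w < 1) stop("window length must be >= 1")
  (m - w + 1) * (n - w + 1)
}

#' Dump a score grid as TSV triplets
#'
#' Writes `i`, `j` (0-based offsets) and `score` for every cell at or above
#' `floor`.
#'
#' @param grid A `window_score_grid`.
#' @param path Output path.
#' @param floor Minimum score to include.
#' @return Invisibly, `path`.
#' @export
write_grid_tsv <- function(grid, path, floor = -Inf) {
  idx <- which(grid >= floor, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   score = grid[idx])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
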