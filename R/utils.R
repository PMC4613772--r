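#' @useDynLib cnescan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor.test pbinom phyper pnorm dnorm rgeom runif sd
#'   as.dist hclust cutree setNames median
#' @importFrom utils read.table write.table combn
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement; `N` maps to `N`.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

## Deterministic sub-seed derivation; keeps results < 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483629) + 1L
}

check_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what))
  }
  invisible(seq)
}

## Shared interval container: data.frame(seq_id, start, end[, name, strand]),
## 0-based half-open throughout the package.
interval_df <- function(seq_id = character(), start = integer(),
                        end = integer(), name = NULL, strand = NULL) {
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("seq_id", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start >= df$end)) {
    stop("invalid interval: start must be < end (0-based half-open)")
  }
  if (nrow(df) && any(df$start < 0)) stop("invalid interval: start must be >= 0")
  invisible(df)
}

## Merge overlapping intervals on one sequence (transitive closure of the
## "not disjoint" relation). Returns a start/end data.frame.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] < me) {          # strict overlap; abutting windows stay apart
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}
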