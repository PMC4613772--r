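#' Multi-species alignment block
#'
#' Equal-length gapped rows over the alphabet `{A,C,G,T,U,N,-}`. Input for
#' the structure conservation index and the column-shuffling control.
#'
#' @param rows Named character vector of gapped sequences (>= 2 rows).
#' @return An object of class `alignment_block`.
#' @export
alignment_block <- function(rows) {
  stopifnot(length(rows) >= 2L)
  rows <- toupper(rows)
  if (length(unique(nchar(rows))) != 1L) stop("rows must have equal length")
  if (any(grepl("[^ACGTUN-]", rows))) {
    stop("alignment alphabet is {A,C,G,T,U,N,-}")
  }
  if (is.null(names(rows))) names(rows) <- paste0("row", seq_along(rows))
  structure(list(rows = rows, width = nchar(rows[[1]])),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("Alignment block:", length(x$rows), "rows x", x$width, "columns\n")
  invisible(x)
}

block_matrix <- function(block) {
  do.call(rbind, strsplit(unname(block$rows), ""))
}

rna_codes <- function(chars) {
  m <- c(A = 0L, C = 1L, G = 2L, U = 3L, T = 3L, N = 4L, "-" = 5L)
  unname(m[chars])
}

degap <- function(s) gsub("-", "", s)

#' Fold a single sequence
#'
#' The built-in engine maximizes canonical base pairing (Watson-Crick plus
#' GU wobble) with a minimum hairpin loop of 3 nt; its energy is -1 per
#' pair, with ties between equal-energy structures broken toward fewer pairs
#' and then the lexicographically smallest dot-bracket string. The `vienna`
#' engine shells out to `RNAfold` for thermodynamic minimum free energies
#' (kcal/mol). Energies from different engines are not comparable.
#'
#' @param seq RNA or DNA sequence (`T` is read as `U`).
#' @param engine `"fallback"` (default) or `"vienna"`.
#' @param min_loop Minimum hairpin loop length (fallback engine).
#' @return List with `structure` (dot-bracket), `energy`, `engine`.
#' @export
fold_mfe <- function(seq, engine = c("fallback", "vienna"), min_loop = 3L) {
  engine <- match.arg(engine)
  if (!nzchar(seq)) stop("empty sequence")
  if (engine == "fallback") {
    codes <- rna_codes(strsplit(toupper(seq), "")[[1]])
    if (any(codes == 5L, na.rm = TRUE) || anyNA(codes)) {
      stop("fold_mfe input must be ungapped {A,C,G,T,U,N}")
    }
    r <- cpp_fold_structure(codes, as.integer(min_loop))
    list(structure = r$structure, energy = -1.0 * r$pairs,
         engine = "fallback")
  } else {
    rna <- chartr("Tt", "Uu", seq)
    out <- system2("RNAfold", args = "--noPS", input = rna, stdout = TRUE)
    line <- out[length(out)]
    m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    if (length(m) < 3L) stop("could not parse RNAfold output: ", line)
    list(structure = m[2], energy = as.numeric(m[3]), engine = "vienna")
  }
}

#' Consensus fold of an alignment block
#'
#' One structure applied to all rows. The built-in engine maximizes, over
#' column pairs, the sum of the fractions of rows that can pair at those
#' columns (same loop and tie rules as [fold_mfe()]); its energy is the
#' negative of that sum. The `vienna` engine shells out to `RNAalifold`.
#' All-gap columns are dropped; the retained column indices are returned.
#'
#' @param block An [alignment_block()].
#' @param engine `"fallback"` or `"vienna"`.
#' @param min_loop Minimum hairpin loop length (fallback engine).
#' @return List with `structure`, `energy`, `engine`, `columns_kept`
#'   (0-based indices of retained columns in the original block).
#' @export
consensus_fold <- function(block, engine = c("fallback", "vienna"),
                           min_loop = 3L) {
  engine <- match.arg(engine)
  mat <- block_matrix(block)
  keep <- which(colSums(mat != "-") > 0)
  mat <- mat[, keep, drop = FALSE]
  if (!ncol(mat)) stop("alignment has no non-gap columns")
  if (engine == "fallback") {
    codes <- matrix(rna_codes(mat), nrow = nrow(mat))
    r <- cpp_consensus_structure(codes, as.integer(min_loop))
    list(structure = r$structure, energy = -r$score / nrow(mat),
         engine = "fallback", columns_kept = keep - 1L)
  } else {
    tf <- tempfile(fileext = ".aln")
    on.exit(unlink(tf))
    rows <- chartr("Tt", "Uu", apply(mat, 1, paste, collapse = ""))
    nm <- sprintf("%-12s", substr(names(block$rows), 1, 12))
    writeLines(c("CLUSTAL W", "", paste0(nm, " ", rows)), tf)
    out <- system2("RNAalifold", args = c("--noPS", tf), stdout = TRUE)
    line <- out[length(out)]
    m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)", line))[[1]]
    if (length(m) < 3L) stop("could not parse RNAalifold output: ", line)
    list(structure = m[2], energy = as.numeric(m[3]), engine = "vienna",
         columns_kept = keep - 1L)
  }
}

#' Structure conservation index
#'
#' Consensus-fold energy divided by the mean energy of the rows folded
#' independently (gaps removed before independent folding). Values near 1
#' indicate a well-conserved structure; values above 1 can indicate
#' compensatory mutations. If the mean independent energy is 0 (no row
#' folds at all) the SCI is undefined and `NA` is returned with the
#' `unstructured` attribute set, rather than an error.
#'
#' @param block An [alignment_block()].
#' @param engine `"fallback"` or `"vienna"`.
#' @param min_loop Minimum hairpin loop length (fallback engine).
#' @return Numeric SCI (possibly `NA`), with attributes `e_consensus` and
#'   `mean_e_independent`.
#' @export
structure_conservation_index <- function(block,
                                         engine = c("fallback", "vienna"),
                                         min_loop = 3L) {
  engine <- match.arg(engine)
  e_cons <- consensus_fold(block, engine, min_loop)$energy
  e_ind <- vapply(block$rows, function(r) {
    s <- degap(r)
    if (!nzchar(s)) return(0)
    fold_mfe(s, engine, min_loop)$energy
  }, numeric(1))
  denom <- mean(e_ind)
  sci <- if (denom == 0) {
    structure(NA_real_, unstructured = TRUE)
  } else {
    e_cons / denom
  }
  attr(sci, "e_consensus") <- e_cons
  attr(sci, "mean_e_independent") <- denom
  sci
}

## Column conservation classes: identical gap pattern and identical number
## of distinct non-gap residues.
column_classes <- function(mat) {
  apply(mat, 2, function(col) {
    gaps <- paste(ifelse(col == "-", "1", "0"), collapse = "")
    lvl <- length(unique(col[col != "-"]))
    paste0(gaps, ":", lvl)
  })
}

#' Shuffle alignment columns preserving the conservation pattern
#'
#' Columns are permuted only within classes of identical gap pattern and
#' conservation level (number of distinct non-gap residues), so the overall
#' conservation pattern of the alignment is kept intact.
#'
#' @param block An [alignment_block()].
#' @param seed Integer seed.
#' @return A shuffled [alignment_block()].
#' @export
shuffle_alignment_columns <- function(block, seed = NULL) {
  mat <- block_matrix(block)
  if (ncol(mat) < 2L) stop("need at least 2 columns")
  cls <- column_classes(mat)
  with_seed(seed, {
    perm <- seq_len(ncol(mat))
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      if (length(idx) > 1L) perm[idx] <- idx[sample.int(length(idx))]
    }
    shuffled <- mat[, perm, drop = FALSE]
    alignment_block(setNames(apply(shuffled, 1, paste, collapse = ""),
                             names(block$rows)))
  })
}

#' Empirical p-value for structure conservation
#'
#' Compares the SCI of the true alignment with the SCIs of `n`
#' conservation-pattern-preserving column shuffles. Reports the Z score of
#' the true SCI against the shuffled distribution and the add-one empirical
#' p-value `(1 + #{shuffled SCI >= true}) / (n_valid + 1)` (never exactly
#' 0); shuffles with undefined SCI are dropped and counted.
#'
#' @param block An [alignment_block()].
#' @param engine `"fallback"` or `"vienna"`.
#' @param n Number of shuffles.
#' @param seed Integer seed.
#' @param min_loop Minimum hairpin loop length (fallback engine).
#' @return List of class `structure_report`: `sci`, `z`, `empirical_p`,
#'   `n_shuffles`, `n_valid`, `reliable` (FALSE when fewer than 10 shuffles
#'   had a defined SCI), `engine`.
#' @export
sci_empirical_pvalue <- function(block, engine = c("fallback", "vienna"),
                                 n = 1000L, seed = 1L, min_loop = 3L) {
  engine <- match.arg(engine)
  if (n < 1L) stop("need at least one shuffle")
  sci_true <- structure_conservation_index(block, engine, min_loop)
  if (is.na(sci_true)) stop("SCI undefined for this block (unstructured)")
  shuffled <- vapply(seq_len(n), function(i) {
    b <- shuffle_alignment_columns(block, seed = derive_seed(seed, i))
    as.numeric(structure_conservation_index(b, engine, min_loop))
  }, numeric(1))
  valid <- shuffled[!is.na(shuffled)]
  z <- if (length(valid) >= 2L && sd(valid) > 0) {
    (as.numeric(sci_true) - mean(valid)) / sd(valid)
  } else NA_real_
  p <- (1 + sum(valid >= as.numeric(sci_true))) / (length(valid) + 1)
  structure(list(sci = as.numeric(sci_true), z = z, empirical_p = p,
                 n_shuffles = n, n_valid = length(valid),
                 reliable = length(valid) >= 10L, engine = engine),
            class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf("SCI %.3f | z %.2f | empirical p %.4g (%d/%d valid shuffles, %s)\n",
              x$sci, x$z, x$empirical_p, x$n_valid, x$n_shuffles, x$engine))
  if (!x$reliable) cat("  [unreliable: < 10 valid shuffles]\n")
  invisible(x)
}

#' Read / write aligned FASTA for alignment blocks
#'
#' @param path File path.
#' @param block An [alignment_block()].
#' @return `read_alignment_fasta` returns an [alignment_block()].
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  alignment_block(setNames(toupper(as.character(set)),
                           sub("\\s.*$", "", names(set))))
}

#' @rdname read_alignment_fasta
#' @export
write_alignment_fasta <- function(block, path) {
  set <- Biostrings::BStringSet(block$rows)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
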