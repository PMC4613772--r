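#' Best hit per query
#'
#' For each query, selects the subject with the maximum bit score; ties are
#' broken by minimum e-value, then lexicographically smallest subject id.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`, `bit_score`,
#'   `e_value` (as from [read_hits_table()]).
#' @return Named character vector mapping query id to best subject id.
#' @export
best_hits <- function(hits) {
  if (!nrow(hits)) return(setNames(character(0), character(0)))
  o <- order(hits$query_id, -hits$bit_score, hits$e_value, hits$subject_id)
  h <- hits[o, ]
  first <- !duplicated(h$query_id)
  setNames(h$subject_id[first], h$query_id[first])
}

## Collapse transcript-level hits to gene level, keeping the max bit score
## (and its e-value) per (query gene, subject gene).
collapse_to_genes <- function(hits, tx2gene) {
  if (is.null(tx2gene) || !nrow(hits)) return(hits)
  map <- setNames(tx2gene$gene_id, tx2gene$transcript_id)
  q <- ifelse(hits$query_id %in% names(map), map[hits$query_id], hits$query_id)
  s <- ifelse(hits$subject_id %in% names(map), map[hits$subject_id],
              hits$subject_id)
  h <- data.frame(query_id = unname(q), subject_id = unname(s),
                  bit_score = hits$bit_score, e_value = hits$e_value,
                  stringsAsFactors = FALSE)
  o <- order(h$query_id, h$subject_id, -h$bit_score, h$e_value)
  h <- h[o, ]
  h[!duplicated(h[c("query_id", "subject_id")]), ]
}

#' Reciprocal best hit ortholog pairing
#'
#' A pair `(a, x)` is reported iff the best hit of `a` in the A-to-B table is
#' `x` and the best hit of `x` in the B-to-A table is `a`. If a
#' transcript-to-gene map is supplied, transcript-level hits are collapsed to
#' gene level (max bit score) before best-hit selection.
#'
#' @param hits_ab,hits_ba Directed hit tables (data.frames as from
#'   [read_hits_table()]).
#' @param tx2gene Optional data.frame with columns `transcript_id`,
#'   `gene_id`.
#' @return data.frame with columns `gene_a`, `gene_b` (a partial bijection:
#'   no gene appears twice), ordered by `gene_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, tx2gene = NULL) {
  ab <- best_hits(collapse_to_genes(hits_ab, tx2gene))
  ba <- best_hits(collapse_to_genes(hits_ba, tx2gene))
  keep <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  keep <- sort(keep)
  data.frame(gene_a = keep, gene_b = unname(ab[keep]),
             stringsAsFactors = FALSE)
}

#' Write / read an ortholog pair table (2-column TSV)
#'
#' @param pairs data.frame as returned by [reciprocal_best_hits()].
#' @param path File path.
#' @return `read_ortholog_pairs` returns the pair data.frame;
#'   `write_ortholog_pairs` returns `path` invisibly.
#' @export
write_ortholog_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_pairs
#' @export
read_ortholog_pairs <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character")
  data.frame(gene_a = tab[[1]], gene_b = tab[[2]], stringsAsFactors = FALSE)
}
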