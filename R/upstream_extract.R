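#' Extract the upstream non-coding region of one gene
#'
#' Takes the up-to-`span` bp immediately 5' of the gene's translation start
#' site, in gene orientation (minus-strand regions are reverse-complemented).
#' If the candidate region overlaps any other gene's span it is truncated at
#' the nearest overlapping gene boundary, keeping the translation-start
#' proximal part; if no non-coding sequence at all remains (the candidate is
#' contained in another gene, or the translation start sits at the contig
#' edge) a removal verdict is returned instead.
#'
#' @param gene One row of a gene table (as from [read_gff_genes()]).
#' @param genome Either a single sequence string or a data.frame of sequence
#'   records containing the gene's contig.
#' @param all_genes Gene table used for the truncation/removal rules
#'   (typically all genes of the species; may be just `gene` itself).
#' @param span Maximum region length (bp).
#' @param repeats Optional interval data.frame of repeat annotations in
#'   genomic coordinates; overlaps are lifted into region coordinates.
#' @param species Optional species label carried on the result.
#' @return An object of class `upstream_region` with fields `verdict`
#'   (`"ok"`, `"removed"` or `"empty"`), `gene_id`, `species`, `sequence`,
#'   `genomic_interval`, `span_used`, `truncated` and `repeat_mask` (region
#'   coordinates, 0-based half-open).
#' @export
extract_upstream <- function(gene, genome, all_genes = gene, span = 2000L,
                             repeats = NULL, species = NA_character_) {
  stopifnot(span > 0)
  if (is.data.frame(genome)) {
    contig <- genome$sequence[genome$id == gene$seq_id]
    if (length(contig) != 1L) stop("contig not found: ", gene$seq_id)
  } else contig <- genome
  clen <- nchar(contig)
  t <- gene$translation_start
  others <- all_genes[all_genes$gene_id != gene$gene_id &
                        all_genes$seq_id == gene$seq_id, , drop = FALSE]
  removal <- function(verdict) {
    structure(list(verdict = verdict, gene_id = gene$gene_id,
                   species = species), class = "upstream_region")
  }

  if (gene$strand == "+") {
    c0 <- max(0L, t - span)
    if (t <= 0L) return(removal("empty"))
    x <- c0
    for (i in seq_len(nrow(others))) {
      a <- others$start[i]; b <- others$end[i]
      if (b > c0 && a < t) x <- max(x, min(b, t))
    }
    if (x >= t) return(removal("removed"))
    gstart <- x; gend <- t
    seq <- substr(contig, gstart + 1L, gend)
  } else {
    c1 <- min(clen, t + 1L + span)
    if (t + 1L >= clen) return(removal("empty"))
    y <- c1
    for (i in seq_len(nrow(others))) {
      a <- others$start[i]; b <- others$end[i]
      if (b > t + 1L && a < c1) y <- min(y, max(a, t + 1L))
    }
    if (y <= t + 1L) return(removal("removed"))
    gstart <- t + 1L; gend <- y
    seq <- revcomp(substr(contig, gstart + 1L, gend))
  }

  span_used <- gend - gstart
  truncated <- span_used < min(span, if (gene$strand == "+") t else clen - t - 1L)
  mask <- NULL
  if (!is.null(repeats) && nrow(repeats)) {
    rr <- repeats[repeats$seq_id == gene$seq_id &
                    repeats$start < gend & repeats$end > gstart, , drop = FALSE]
    if (nrow(rr)) {
      rs <- pmax(rr$start, gstart); re <- pmin(rr$end, gend)
      mask <- if (gene$strand == "+") {
        data.frame(start = rs - gstart, end = re - gstart)
      } else {
        data.frame(start = gend - re, end = gend - rs)
      }
      mask <- mask[order(mask$start), , drop = FALSE]
      rownames(mask) <- NULL
    }
  }
  if (is.null(mask)) mask <- data.frame(start = integer(), end = integer())

  structure(list(verdict = "ok", gene_id = gene$gene_id, species = species,
                 sequence = seq,
                 genomic_interval = interval_df(gene$seq_id, gstart, gend,
                                                strand = gene$strand),
                 span_used = span_used, truncated = truncated,
                 repeat_mask = mask),
            class = "upstream_region")
}

#' @export
print.upstream_region <- function(x, ...) {
  if (x$verdict != "ok") {
    cat("Upstream region of", x$gene_id, "- verdict:", x$verdict, "\n")
  } else {
    cat("Upstream region of", x$gene_id, "(", x$span_used, "bp",
        if (x$truncated) ", truncated" else "", ")\n", sep = " ")
  }
  invisible(x)
}

#' Extract upstream regions for a whole gene table
#'
#' @param genes Gene table (as from [read_gff_genes()]).
#' @param genome Sequence records data.frame for the species.
#' @param span,repeats,species See [extract_upstream()].
#' @return List with `regions` (named list of `upstream_region` objects with
#'   verdict `"ok"`) and `counts` (extracted / truncated / removed / empty).
#' @export
extract_all_upstream <- function(genes, genome, span = 2000L, repeats = NULL,
                                 species = NA_character_) {
  out <- list(); counts <- c(extracted = 0L, truncated = 0L, removed = 0L,
                             empty = 0L)
  for (i in seq_len(nrow(genes))) {
    r <- extract_upstream(genes[i, ], genome, genes, span, repeats, species)
    if (r$verdict == "ok") {
      counts["extracted"] <- counts["extracted"] + 1L
      if (r$truncated) counts["truncated"] <- counts["truncated"] + 1L
      out[[r$gene_id]] <- r
    } else {
      counts[r$verdict] <- counts[r$verdict] + 1L
    }
  }
  list(regions = out, counts = counts)
}
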