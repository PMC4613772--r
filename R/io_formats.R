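#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any IUPAC ambiguity
#' code other than `N` is mapped to `N` with a warning. Record ids must be
#' unique and non-empty.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop(sprintf("format error in %s, line 1: empty FASTA file", path))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("format error in %s, line %d: expected '>' header",
                 path, nonblank[1]))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop(sprintf("format error in %s: empty record id", path))
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("format error in %s: duplicate record id '%s'",
                 path, ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    warning("ambiguity codes other than N mapped to N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s),
                   character(1), USE.NAMES = FALSE)
  }
  data.frame(id = ids, sequence = unname(seqs), description = desc,
             stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description`, or a named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          description = "", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts one row per gene with its span and translation start site. The
#' translation start is the 5'-most CDS base across all transcripts of the
#' gene (minimum CDS start on `+`, maximum CDS end on `-`). All coordinates
#' are converted from GFF3 1-based inclusive to 0-based half-open.
#'
#' @param path Path to a GFF3 file containing `gene` and `CDS` features
#'   (CDS `Parent` may point at the gene or at an intermediate transcript).
#' @return data.frame with columns `gene_id`, `seq_id`, `strand`, `start`,
#'   `end`, `translation_start`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop(sprintf("format error in %s: %s", path, conditionMessage(e)))
                 })
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  genes <- which(type == "gene")
  if (!length(genes)) stop(sprintf("format error in %s: no gene features", path))
  cds <- which(type == "CDS")

  ## Resolve each CDS to its gene: follow Parent links through intermediate
  ## transcript features (at most a few levels).
  id_to_parent <- setNames(parent, id)
  gene_ids <- id[genes]
  to_gene <- function(p) {
    seen <- 0L
    while (!is.na(p) && !(p %in% gene_ids) && seen < 5L) {
      p <- id_to_parent[[p]]
      if (is.null(p)) p <- NA_character_
      seen <- seen + 1L
    }
    if (!is.na(p) && p %in% gene_ids) p else NA_character_
  }
  cds_gene <- vapply(parent[cds], to_gene, character(1))

  out <- lapply(seq_along(genes), function(k) {
    gi <- genes[k]
    gid <- id[gi]
    strand <- as.character(GenomicRanges::strand(gr))[gi]
    if (!strand %in% c("+", "-")) strand <- "+"
    my_cds <- cds[!is.na(cds_gene) & cds_gene == gid]
    if (!length(my_cds)) {
      warning(sprintf("gene '%s' has no CDS; skipped", gid))
      return(NULL)
    }
    ## 1-based inclusive -> 0-based half-open
    g_start <- GenomicRanges::start(gr)[gi] - 1L
    g_end <- GenomicRanges::end(gr)[gi]
    tls <- if (strand == "+") {
      min(GenomicRanges::start(gr)[my_cds]) - 1L
    } else {
      max(GenomicRanges::end(gr)[my_cds]) - 1L
    }
    data.frame(gene_id = gid,
               seq_id = as.character(GenomicRanges::seqnames(gr))[gi],
               strand = strand, start = g_start, end = g_end,
               translation_start = as.integer(tls),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    stop(sprintf("format error in %s: no gene with a CDS", path))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write gene models as GFF3
#'
#' Emits one `gene` and one `CDS` feature per row; the inverse of
#' [read_gff_genes()] for single-CDS gene models.
#'
#' @param genes data.frame as returned by [read_gff_genes()], plus optional
#'   `cds_start`/`cds_end` columns (0-based half-open; default: CDS spans from
#'   the translation start to the gene boundary).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff_genes <- function(genes, path) {
  stopifnot(all(c("gene_id", "seq_id", "strand", "start", "end",
                  "translation_start") %in% names(genes)))
  cds_start <- if ("cds_start" %in% names(genes)) genes$cds_start else
    ifelse(genes$strand == "+", genes$translation_start, genes$start)
  cds_end <- if ("cds_end" %in% names(genes)) genes$cds_end else
    ifelse(genes$strand == "+", genes$end, genes$translation_start + 1L)
  att_gene <- paste0("ID=", genes$gene_id)
  att_cds <- paste0("ID=", genes$gene_id, ".cds;Parent=", genes$gene_id)
  line <- function(seqid, src, type, s0, e0, strand, att) {
    paste(seqid, src, type, s0 + 1L, e0, ".", strand, ".", att, sep = "\t")
  }
  rows <- character(0)
  for (i in seq_len(nrow(genes))) {
    rows <- c(rows,
              line(genes$seq_id[i], "cnescan", "gene", genes$start[i],
                   genes$end[i], genes$strand[i], att_gene[i]),
              line(genes$seq_id[i], "cnescan", "CDS", cds_start[i],
                   cds_end[i], genes$strand[i], att_cds[i]))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Only columns 1 (query), 2 (subject), 11 (e-value) and 12 (bit score) are
#' used; any further columns are ignored.
#'
#' @param path Path to a tab-separated hit table with at least 12 columns.
#' @return data.frame with columns `query_id`, `subject_id`, `bit_score`,
#'   `e_value`.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      bit_score = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "#", colClasses = "character")
  if (ncol(tab) < 12L) {
    stop(sprintf("format error in %s: expected >= 12 tab-separated columns, got %d",
                 path, ncol(tab)))
  }
  ev <- suppressWarnings(as.numeric(tab[[11]]))
  bs <- suppressWarnings(as.numeric(tab[[12]]))
  if (anyNA(ev)) {
    stop(sprintf("format error in %s, line %d: non-numeric e-value '%s'",
                 path, which(is.na(ev))[1], tab[[11]][which(is.na(ev))[1]]))
  }
  if (anyNA(bs)) {
    stop(sprintf("format error in %s, line %d: non-numeric bit score '%s'",
                 path, which(is.na(bs))[1], tab[[12]][which(is.na(bs))[1]]))
  }
  if (any(ev < 0)) stop(sprintf("format error in %s: negative e-value", path))
  data.frame(query_id = tab[[1]], subject_id = tab[[2]],
             bit_score = bs, e_value = ev, stringsAsFactors = FALSE)
}

#' Read and write BED intervals
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' `read_bed(write_bed(x))` round-trips losslessly. Zero- or negative-width
#' intervals are rejected.
#'
#' @param intervals data.frame with columns `seq_id`, `start`, `end` and
#'   optionally `name`, `strand`.
#' @param path File path.
#' @return `read_bed` returns an interval data.frame; `write_bed` returns
#'   `path` invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$seq_id,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = if ("strand" %in% names(intervals)) intervals$strand else "*")
  if ("name" %in% names(intervals)) gr$name <- intervals$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ## validate widths on the raw text: BED permits nothing of width <= 0 here
  raw <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "#", stringsAsFactors = FALSE)
  if (any(raw[[3]] <= raw[[2]])) {
    stop(sprintf("format error in %s: empty interval (start >= end)", path))
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- interval_df(seq_id = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
  if (!is.null(gr$name) && !all(is.na(gr$name))) out$name <- gr$name
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st %in% c("+", "-"))) out$strand <- st
  out
}
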