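#' Configuration for the synthetic ortholog cohort generator
#'
#' Describes a star phylogeny: every species' upstream region evolves
#' independently from a common ancestral sequence at its own substitution and
#' indel rates. The first species listed is the central species of the
#' downstream discovery step.
#'
#' @param ancestor_length Ancestral upstream region length in bp.
#' @param gc Background GC fraction of the ancestor.
#' @param species data.frame with columns `name`, `substitution_rate`
#'   (per-site), `indel_rate` (per-site), `indel_mean_len` (geometric mean
#'   indel length). Defaults to one central species and four comparators,
#'   all at substitution rate 0.35 and indel rate 0.01.
#' @param n_genes Number of orthologous gene loci to simulate.
#' @param seed Integer seed; all stage seeds are derived from it.
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(ancestor_length = 2000L, gc = 0.3,
                             species = NULL, n_genes = 10L, seed = 1L) {
  if (is.null(species)) {
    species <- data.frame(
      name = c("nvit", paste0("cmp", 1:4)),
      substitution_rate = 0.35,
      indel_rate = 0.01,
      indel_mean_len = 2,
      stringsAsFactors = FALSE)
  }
  stopifnot(ancestor_length > 0, gc >= 0, gc <= 1, n_genes >= 1,
            all(c("name", "substitution_rate", "indel_rate",
                  "indel_mean_len") %in% names(species)),
            all(species$substitution_rate >= 0 & species$substitution_rate <= 1),
            all(species$indel_rate >= 0 & species$indel_rate <= 1))
  structure(list(ancestor_length = as.integer(ancestor_length), gc = gc,
                 species = species, n_genes = as.integer(n_genes),
                 seed = as.integer(seed)),
            class = "evolution_config")
}

#' Planted conserved elements
#'
#' @param distance_from_tls Distance (bp) between the element's 3' end and
#'   the translation start site.
#' @param length Element length in bp (the characteristic length of detected
#'   elements is around 90 bp).
#' @param element_substitution_rate Per-site, per-branch substitution rate
#'   inside the element; much lower than the background rate for a conserved
#'   element.
#' @param present_in Character vector of carrier species (default: all).
#' @param gc Optional GC fraction of the element (default: inherits the
#'   ancestor backbone, i.e. the background composition).
#' @return An object of class `planted_element`.
#' @export
planted_element <- function(distance_from_tls = 200L, length = 90L,
                            element_substitution_rate = 0.02,
                            present_in = NULL, gc = NULL) {
  stopifnot(distance_from_tls >= 0, length >= 1,
            element_substitution_rate >= 0, element_substitution_rate <= 1)
  structure(list(distance_from_tls = as.integer(distance_from_tls),
                 length = as.integer(length),
                 element_substitution_rate = element_substitution_rate,
                 present_in = present_in, gc = gc),
            class = "planted_element")
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

substitute_sites <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  chars
}

#' Evolve a sequence along one branch
#'
#' Each site is independently substituted (to a uniformly chosen different
#' base) with probability `substitution_rate`. Indel events occur at each
#' site with probability `indel_rate`; each event is an insertion or deletion
#' with equal probability, with geometrically distributed length of mean
#' `indel_mean_len`.
#'
#' @param ancestor DNA sequence (string).
#' @param substitution_rate,indel_rate Per-site rates in \[0, 1\].
#' @param indel_mean_len Mean indel length (geometric).
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @return The evolved sequence (string).
#' @export
evolve_sequence <- function(ancestor, substitution_rate, indel_rate = 0,
                            indel_mean_len = 2, seed = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, indel_mean_len >= 1)
  with_seed(seed, {
    chars <- strsplit(ancestor, "")[[1]]
    chars <- substitute_sites(chars, substitution_rate)
    if (indel_rate > 0 && length(chars)) {
      ev <- which(runif(length(chars)) < indel_rate)
      ## process right-to-left so earlier coordinates stay valid
      for (i in rev(ev)) {
        len <- 1L + rgeom(1L, prob = min(1, 1 / indel_mean_len))
        if (runif(1) < 0.5) {   # deletion
          keep_to <- min(length(chars), i + len - 1L)
          chars <- chars[-(i:keep_to)]
        } else {                # insertion before site i
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          chars <- append(chars, ins, after = i - 1L)
        }
      }
    }
    paste(chars, collapse = "")
  })
}

#' Generate a synthetic orthologous upstream cohort with planted truth
#'
#' For each gene locus an ancestral upstream region is drawn, planted
#' elements are placed at fixed distances from the translation start site,
#' and each species' copy evolves independently (star phylogeny). Planted
#' element segments evolve at their own (lower) substitution rate with no
#' indels and are re-inserted at the configured distance from the translation
#' start in every carrier species, so element positions relative to the
#' translation start are conserved by construction. A short CDS is appended
#' 3' of each region, one contig per gene, so that upstream extraction from
#' the emitted genome and annotation reproduces each region byte-for-byte.
#'
#' @param config An [evolution_config()].
#' @param planted List of [planted_element()] objects (may be empty).
#' @param repeat_spec Optional list with `n_per_gene`, `length`, `divergence`
#'   and optionally `annotate` (default TRUE): copies of one shared repeat
#'   consensus planted at random positions (avoiding planted elements) in
#'   every species, recorded as truth. When `annotate` is FALSE the planted
#'   repeats are withheld from the repeat annotation given to the pipeline,
#'   emulating unannotated repetitive similarity between non-orthologous
#'   loci (the source of pseudo-CNEs).
#' @param minus_fraction Fraction of gene loci placed on the minus strand.
#' @param cds_length Length of the appended coding sequence.
#' @return An object of class `synthetic_cohort`: per-species genome
#'   sequences and gene tables, the true upstream regions, truth intervals
#'   for planted elements and repeats (region coordinates), and bookkeeping
#'   tables (`tx2gene`, per-comparator hit tables).
#' @export
generate_ortholog_cohort <- function(config, planted = list(),
                                     repeat_spec = NULL,
                                     minus_fraction = 0.25,
                                     cds_length = 120L) {
  stopifnot(inherits(config, "evolution_config"))
  if (inherits(planted, "planted_element")) planted <- list(planted)
  L <- config$ancestor_length
  ## element footprints on the ancestor (anchored at the 3' end = TLS)
  if (length(planted)) {
    foot <- t(vapply(planted, function(e) {
      s <- L - e$distance_from_tls - e$length
      c(s, L - e$distance_from_tls)
    }, numeric(2)))
    if (any(foot[, 1] < 0)) stop("planted element does not fit in the ancestor")
    o <- order(foot[, 1])
    if (any(foot[o, 1][-1] < foot[o, 2][-nrow(foot)])) {
      stop("overlapping planted elements")
    }
  }
  sp <- config$species
  central <- sp$name[1]
  genes <- sprintf("g%02d", seq_len(config$n_genes))

  with_seed(config$seed, {
    strand <- ifelse(runif(length(genes)) < minus_fraction, "-", "+")
    repeat_consensus <- if (!is.null(repeat_spec)) {
      random_dna(repeat_spec$length, config$gc)
    } else NULL

    sequences <- list(); gene_tabs <- list(); regions <- list()
    truth <- list(); truth_rep <- list()

    for (s in seq_len(nrow(sp))) {
      regions[[sp$name[s]]] <- character(0)
      sequences[[sp$name[s]]] <-
        data.frame(id = character(), sequence = character(),
                   description = character(), stringsAsFactors = FALSE)
      gene_tabs[[sp$name[s]]] <-
        data.frame(gene_id = character(), seq_id = character(),
                   strand = character(), start = integer(), end = integer(),
                   translation_start = integer(), stringsAsFactors = FALSE)
    }

    for (gi in seq_along(genes)) {
      g <- genes[gi]
      ancestor <- random_dna(L, config$gc)
      seg <- lapply(planted, function(e) {
        s0 <- L - e$distance_from_tls - e$length
        if (!is.null(e$gc)) random_dna(e$length, e$gc)
        else substr(ancestor, s0 + 1L, s0 + e$length)
      })
      ## splice fresh-GC segments back into the ancestor backbone
      for (k in seq_along(planted)) {
        e <- planted[[k]]
        s0 <- L - e$distance_from_tls - e$length
        substr(ancestor, s0 + 1L, s0 + e$length) <- seg[[k]]
      }
      body <- paste0("ATG", random_dna(cds_length - 6L, 0.5), "TAA")

      for (s in seq_len(nrow(sp))) {
        spn <- sp$name[s]
        sd1 <- derive_seed(config$seed, gi * 1000L + s)
        reg <- evolve_sequence(ancestor, sp$substitution_rate[s],
                               sp$indel_rate[s], sp$indel_mean_len[s],
                               seed = sd1)
        Ls <- nchar(reg)
        ## re-insert planted elements at the configured distance from the TLS
        for (k in seq_along(planted)) {
          e <- planted[[k]]
          carriers <- if (is.null(e$present_in)) sp$name else e$present_in
          if (!spn %in% carriers) next
          if (Ls < e$distance_from_tls + e$length) {
            stop("evolved region too short to carry a planted element; ",
                 "lower the indel rate or element distance")
          }
          ev <- evolve_sequence(seg[[k]], e$element_substitution_rate,
                                seed = derive_seed(config$seed,
                                                   gi * 100000L + s * 100L + k))
          s0 <- Ls - e$distance_from_tls - e$length
          substr(reg, s0 + 1L, s0 + e$length) <- ev
          truth[[length(truth) + 1L]] <-
            data.frame(species = spn, gene = g, element = k,
                       start = s0, end = s0 + e$length,
                       stringsAsFactors = FALSE)
        }
        ## planted repeats: shared consensus, lightly diverged copies
        if (!is.null(repeat_spec) && repeat_spec$n_per_gene > 0) {
          elem_foot <- merge_intervals(
            vapply(truth[vapply(truth, function(t)
              t$species == spn && t$gene == g, logical(1))],
              function(t) t$start, numeric(1)),
            vapply(truth[vapply(truth, function(t)
              t$species == spn && t$gene == g, logical(1))],
              function(t) t$end, numeric(1)))
          for (r in seq_len(repeat_spec$n_per_gene)) {
            rl <- repeat_spec$length
            for (try in 1:50) {
              pos <- sample.int(Ls - rl + 1L, 1L) - 1L
              clash <- nrow(elem_foot) &&
                any(pos < elem_foot$end & pos + rl > elem_foot$start)
              if (!clash) break
            }
            if (clash) next
            rep_seq <- evolve_sequence(repeat_consensus,
                                       repeat_spec$divergence,
                                       seed = derive_seed(config$seed,
                                                          gi * 7919L + s * 31L + r))
            substr(reg, pos + 1L, pos + rl) <- rep_seq
            truth_rep[[length(truth_rep) + 1L]] <-
              data.frame(species = spn, gene = g, start = pos,
                         end = pos + rl, stringsAsFactors = FALSE)
          }
        }

        gene_id <- paste0(spn, "_", g)
        contig_id <- paste0(gene_id, "_ctg")
        Lr <- nchar(reg)
        total <- Lr + nchar(body)
        if (strand[gi] == "+") {
          contig <- paste0(reg, body)
          gtab <- data.frame(gene_id = gene_id, seq_id = contig_id,
                             strand = "+", start = Lr, end = total,
                             translation_start = Lr,
                             stringsAsFactors = FALSE)
        } else {
          contig <- revcomp(paste0(reg, body))
          gtab <- data.frame(gene_id = gene_id, seq_id = contig_id,
                             strand = "-", start = 0L,
                             end = nchar(body),
                             translation_start = nchar(body) - 1L,
                             stringsAsFactors = FALSE)
        }
        sequences[[spn]] <- rbind(sequences[[spn]],
          data.frame(id = contig_id, sequence = contig,
                     description = paste0("synthetic locus ", g),
                     stringsAsFactors = FALSE))
        gene_tabs[[spn]] <- rbind(gene_tabs[[spn]], gtab)
        regions[[spn]][g] <- reg
      }
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(species = character(), gene = character(),
                 element = integer(), start = integer(), end = integer())
    truth_rep <- if (length(truth_rep)) do.call(rbind, truth_rep) else
      data.frame(species = character(), gene = character(),
                 start = integer(), end = integer())

    structure(list(config = config, planted = planted,
                   repeat_annotate = is.null(repeat_spec) ||
                     !isFALSE(repeat_spec$annotate),
                   species = sp, central_species = central, genes = genes,
                   strand = setNames(strand, genes),
                   sequences = sequences, gene_tables = gene_tabs,
                   regions = regions, truth = truth,
                   truth_repeats = truth_rep),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic ortholog cohort:", length(x$genes), "genes x",
      nrow(x$species), "species (central:", x$central_species, ")\n")
  cat("  ancestor", x$config$ancestor_length, "bp, GC", x$config$gc, "\n")
  cat("  planted elements per gene:", length(x$planted),
      " | truth intervals:", nrow(x$truth), "\n")
  invisible(x)
}

#' Random pseudo-ortholog pairing
#'
#' Draws a uniformly random derangement of the cohort's gene loci: every
#' central gene is paired with the comparator copy of a *different* gene, so
#' no pair shares any orthology. This is the false-discovery null used to
#' calibrate the CCS detection threshold.
#'
#' @param cohort A `synthetic_cohort` (or a character vector of gene ids).
#' @param seed Integer seed.
#' @return data.frame with columns `central_gene`, `comparator_gene`.
#' @export
generate_pseudo_ortholog_pairs <- function(cohort, seed = 1L) {
  genes <- if (inherits(cohort, "synthetic_cohort")) cohort$genes else cohort
  n <- length(genes)
  if (n < 2L) stop("need at least 2 genes to build a derangement")
  with_seed(seed, {
    repeat {
      p <- sample.int(n)
      if (!any(p == seq_len(n))) break
    }
    data.frame(central_gene = genes, comparator_gene = genes[p],
               stringsAsFactors = FALSE)
  })
}

#' Plant a gapless hairpin alignment
#'
#' Builds an alignment whose rows each consist of a 5' stem, a loop, and the
#' exact reverse complement of that row's stem, mimicking a structurally
#' conserved element whose apical loop sequence is free to vary: stems are
#' complementary within every row even where the stem sequence itself has
#' diverged between rows.
#'
#' @param n_rows Number of rows (species).
#' @param stem_len Stem length in bp (>= 2).
#' @param loop_len Loop length in bp (>= 3).
#' @param stem_identity Per-site probability that a row's stem site matches
#'   the ancestral stem.
#' @param loop_substitution_rate Per-site substitution rate in the loop.
#' @param seed Integer seed.
#' @return An [alignment_block()] (gapless, equal-length rows).
#' @export
plant_hairpin_alignment <- function(n_rows, stem_len, loop_len,
                                    stem_identity = 1, loop_substitution_rate = 0.5,
                                    seed = 1L) {
  stopifnot(n_rows >= 2, stem_len >= 2, loop_len >= 3)
  with_seed(seed, {
    stem <- random_dna(stem_len, 0.5)
    loop <- random_dna(loop_len, 0.5)
    rows <- vapply(seq_len(n_rows), function(r) {
      st <- paste(substitute_sites(strsplit(stem, "")[[1]], 1 - stem_identity),
                  collapse = "")
      lp <- paste(substitute_sites(strsplit(loop, "")[[1]],
                                   loop_substitution_rate), collapse = "")
      paste0(st, lp, revcomp(st))
    }, character(1))
    alignment_block(setNames(rows, paste0("row", seq_len(n_rows))))
  })
}

#' Synthetic transcript set covering planted elements
#'
#' Emits, per gene, one transcript per planted element containing exactly a
#' 5'-anchored fraction of the element (by length, rounded up), plus the
#' gene's coding sequence. Supports testing the k-mer transcribed-overlap
#' statistic with known overlap.
#'
#' @param cohort A `synthetic_cohort`.
#' @param fraction_of_element_transcribed Fraction in \[0, 1\].
#' @return data.frame of sequence records (`id`, `sequence`, `description`).
#' @export
generate_transcriptome <- function(cohort, fraction_of_element_transcribed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            fraction_of_element_transcribed >= 0,
            fraction_of_element_transcribed <= 1)
  central <- cohort$central_species
  recs <- list()
  tr <- cohort$truth[cohort$truth$species == central, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    reg <- cohort$regions[[central]][[tr$gene[i]]]
    elen <- tr$end[i] - tr$start[i]
    plen <- as.integer(ceiling(fraction_of_element_transcribed * elen))
    if (plen < 1L) next
    recs[[length(recs) + 1L]] <- data.frame(
      id = sprintf("tx_%s_e%d", tr$gene[i], tr$element[i]),
      sequence = substr(reg, tr$start[i] + 1L, tr$start[i] + plen),
      description = "element transcript", stringsAsFactors = FALSE)
  }
  for (g in cohort$genes) {
    gid <- paste0(central, "_", g)
    ctg <- cohort$sequences[[central]]
    contig <- ctg$sequence[ctg$id == paste0(gid, "_ctg")]
    reg_len <- nchar(cohort$regions[[central]][[g]])
    body <- if (cohort$strand[[g]] == "+") {
      substr(contig, reg_len + 1L, nchar(contig))
    } else {
      revcomp(substr(contig, 1L, nchar(contig) - reg_len))
    }
    recs[[length(recs) + 1L]] <- data.frame(
      id = paste0("tx_", g, "_cds"), sequence = body,
      description = "coding transcript", stringsAsFactors = FALSE)
  }
  if (!length(recs)) {
    return(data.frame(id = character(), sequence = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

#' Directed hit tables for a synthetic cohort
#'
#' Emulates the protein-similarity searches consumed by the orthology module:
#' for every comparator species, transcript-level hits in both directions in
#' which each gene's best hit is its true ortholog, plus weaker decoy hits,
#' together with the transcript-to-gene map.
#'
#' @param cohort A `synthetic_cohort`.
#' @return List with `hits` (per comparator: list of `ab`/`ba` hit tables)
#'   and `tx2gene` (data.frame `transcript_id`, `gene_id`).
#' @export
cohort_hit_tables <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  central <- cohort$central_species
  comps <- setdiff(cohort$species$name, central)
  tx <- function(gene_id) paste0(gene_id, ".t1")
  tx2gene <- do.call(rbind, lapply(cohort$species$name, function(s) {
    data.frame(transcript_id = tx(paste0(s, "_", cohort$genes)),
               gene_id = paste0(s, "_", cohort$genes),
               stringsAsFactors = FALSE)
  }))
  n <- length(cohort$genes)
  decoy <- c(cohort$genes[-1], cohort$genes[1])
  hits <- lapply(comps, function(s) {
    ab <- data.frame(
      query_id = tx(paste0(central, "_", cohort$genes)),
      subject_id = tx(paste0(s, "_", cohort$genes)),
      bit_score = 500, e_value = 1e-100, stringsAsFactors = FALSE)
    ab_decoy <- data.frame(
      query_id = tx(paste0(central, "_", cohort$genes)),
      subject_id = tx(paste0(s, "_", decoy)),
      bit_score = 60, e_value = 1e-6, stringsAsFactors = FALSE)
    ba <- data.frame(
      query_id = tx(paste0(s, "_", cohort$genes)),
      subject_id = tx(paste0(central, "_", cohort$genes)),
      bit_score = 500, e_value = 1e-100, stringsAsFactors = FALSE)
    list(ab = rbind(ab, ab_decoy), ba = ba)
  })
  names(hits) <- comps
  list(hits = hits, tx2gene = tx2gene)
}

#' Write a synthetic cohort to disk
#'
#' Emits, per species, a genome FASTA, a GFF3 gene annotation, a truth BED of
#' planted elements and a repeat BED (genomic coordinates), plus a plain
#' key-value manifest.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  region_to_genomic <- function(spn, gene, start, end) {
    reg_len <- nchar(cohort$regions[[spn]][[gene]])
    ctg <- cohort$sequences[[spn]]
    gid <- paste0(spn, "_", gene)
    total <- nchar(ctg$sequence[ctg$id == paste0(gid, "_ctg")])
    if (cohort$strand[[gene]] == "+") c(start, end)
    else c(total - end, total - start)
  }
  for (spn in cohort$species$name) {
    write_fasta(cohort$sequences[[spn]],
                file.path(dir, paste0(spn, ".fa")))
    write_gff_genes(cohort$gene_tables[[spn]],
                    file.path(dir, paste0(spn, ".gff3")))
    for (what in c("truth", "truth_repeats")) {
      tab <- cohort[[what]]
      tab <- tab[tab$species == spn, , drop = FALSE]
      if (what == "truth_repeats" && isFALSE(cohort$repeat_annotate)) {
        tab <- tab[0, , drop = FALSE]
      }
      fn <- file.path(dir, paste0(spn, if (what == "truth") ".elements.bed"
                                  else ".repeats.bed"))
      if (nrow(tab)) {
        gen <- t(mapply(region_to_genomic, spn, tab$gene, tab$start, tab$end))
        write_bed(interval_df(seq_id = paste0(spn, "_", tab$gene, "_ctg"),
                              start = gen[, 1], end = gen[, 2],
                              name = paste0(tab$gene, "_",
                                            seq_len(nrow(tab)))), fn)
      } else if (file.exists(fn)) file.remove(fn)
    }
  }
  ## hit tables + transcript map so the orthology stage can run from disk
  ht <- cohort_hit_tables(cohort)
  write_outfmt6 <- function(hits, path) {
    pad <- data.frame(pid = 100, len = 100, mm = 0, go = 0, qs = 1, qe = 100,
                      ss = 1, se = 100)
    tab <- cbind(hits$query_id, hits$subject_id, pad,
                 format(hits$e_value, scientific = TRUE), hits$bit_score)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  for (s in names(ht$hits)) {
    write_outfmt6(ht$hits[[s]]$ab, file.path(dir, paste0(s, ".ab.tsv")))
    write_outfmt6(ht$hits[[s]]$ba, file.path(dir, paste0(s, ".ba.tsv")))
  }
  write.table(ht$tx2gene, file.path(dir, "tx2gene.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  manifest <- c(
    paste0("central_species=", cohort$central_species),
    paste0("species=", paste(cohort$species$name, collapse = ",")),
    paste0("n_genes=", length(cohort$genes)),
    paste0("ancestor_length=", cohort$config$ancestor_length),
    paste0("seed=", cohort$config$seed))
  writeLines(manifest, file.path(dir, "manifest.cfg"))
  invisible(dir)
}
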