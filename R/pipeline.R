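#' Run configuration
#'
#' Bundles every tunable of the discovery and characterization stages with
#' the values used throughout the analysis: 50 bp windows scored +1/0/-0.5,
#' candidate bounds (80, 94), final bounds (87, 100), pseudo-CNE CCS cutoff
#' 0.528, up-to-2 kb regions, 20-mers for transcribed overlap, 1000 SCI
#' shuffles, 10 composition control sets and 100 motif control sets.
#'
#' @param scheme A [scoring_scheme()].
#' @param thresholds A [threshold_config()].
#' @param span Maximum upstream region length (bp).
#' @param k K-mer length for transcribed overlap.
#' @param sci_shuffles Shuffles per SCI empirical p-value.
#' @param n_composition_controls,n_motif_controls Numbers of matched control
#'   sets.
#' @param seed Integer seed for every stochastic stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scheme = scoring_scheme(),
                       thresholds = threshold_config(),
                       span = 2000L, k = 20L, sci_shuffles = 1000L,
                       n_composition_controls = 10L,
                       n_motif_controls = 100L, seed = 1L) {
  structure(list(scheme = scheme, thresholds = thresholds,
                 span = as.integer(span), k = as.integer(k),
                 sci_shuffles = as.integer(sci_shuffles),
                 n_composition_controls = as.integer(n_composition_controls),
                 n_motif_controls = as.integer(n_motif_controls),
                 seed = as.integer(seed)),
            class = "run_config")
}

## Normalize the two supported inputs (in-memory synthetic cohort, or a
## directory written by write_cohort) into one internal bundle.
load_run_input <- function(input) {
  if (inherits(input, "synthetic_cohort")) {
    ht <- cohort_hit_tables(input)
    rep_bed <- lapply(input$species$name, function(spn) {
      tab <- input$truth_repeats[input$truth_repeats$species == spn, ,
                                 drop = FALSE]
      if (!nrow(tab) || isFALSE(input$repeat_annotate)) return(interval_df())
      ## region -> genomic coordinates on the per-gene contig
      gen <- t(mapply(function(g, s, e) {
        total <- nchar(input$sequences[[spn]]$sequence[
          input$sequences[[spn]]$id == paste0(spn, "_", g, "_ctg")])
        if (input$strand[[g]] == "+") c(s, e) else c(total - e, total - s)
      }, tab$gene, tab$start, tab$end))
      interval_df(seq_id = paste0(spn, "_", tab$gene, "_ctg"),
                  start = gen[, 1], end = gen[, 2])
    })
    names(rep_bed) <- input$species$name
    list(species = input$species$name, central = input$central_species,
         genomes = input$sequences, gene_tables = input$gene_tables,
         repeats = rep_bed, hits = ht$hits, tx2gene = ht$tx2gene)
  } else if (is.character(input) && dir.exists(input)) {
    mf <- readLines(file.path(input, "manifest.cfg"))
    val <- function(key) sub(paste0("^", key, "="), "",
                             grep(paste0("^", key, "="), mf, value = TRUE))
    species <- strsplit(val("species"), ",")[[1]]
    central <- val("central_species")
    genomes <- lapply(species, function(s)
      read_fasta(file.path(input, paste0(s, ".fa"))))
    gene_tables <- lapply(species, function(s)
      read_gff_genes(file.path(input, paste0(s, ".gff3"))))
    repeats <- lapply(species, function(s) {
      fn <- file.path(input, paste0(s, ".repeats.bed"))
      if (file.exists(fn)) read_bed(fn) else interval_df()
    })
    names(genomes) <- names(gene_tables) <- names(repeats) <- species
    comps <- setdiff(species, central)
    hits <- lapply(comps, function(s) {
      list(ab = read_hits_table(file.path(input, paste0(s, ".ab.tsv"))),
           ba = read_hits_table(file.path(input, paste0(s, ".ba.tsv"))))
    })
    names(hits) <- comps
    tx2gene <- read.table(file.path(input, "tx2gene.tsv"), sep = "\t",
                          header = FALSE, colClasses = "character")
    names(tx2gene) <- c("transcript_id", "gene_id")
    list(species = species, central = central, genomes = genomes,
         gene_tables = gene_tables, repeats = repeats, hits = hits,
         tx2gene = tx2gene)
  } else {
    stop("input must be a synthetic_cohort or a cohort directory")
  }
}

region_to_genomic_interval <- function(region, start, end) {
  gi <- region$genomic_interval
  if (gi$strand == "+") {
    interval_df(gi$seq_id, gi$start + start, gi$start + end,
                strand = "+")
  } else {
    interval_df(gi$seq_id, gi$end - end, gi$end - start, strand = "-")
  }
}

#' Run CNE discovery
#'
#' Executes the full discovery protocol: reciprocal-best-hit orthology,
#' upstream region extraction with truncation/removal, repeat masking,
#' window-pair alignment of every central region against its orthologous
#' comparator regions, candidate bundling at the permissive bounds,
#' CCS-threshold calibration on pseudo-ortholog pairings (detection is
#' `CCS > max pseudo CCS`, so the control yields zero detections by
#' construction), optional permutation-calibrated coding filtering, and
#' re-scoring at the strict bounds with a second calibration against the
#' re-scored pseudo set. Pseudo-CNEs are harvested from the pseudo
#' candidates at the pseudo-CNE CCS cutoff.
#'
#' @param input A `synthetic_cohort` or a directory written by
#'   [write_cohort()].
#' @param config A [run_config()].
#' @param coding_hits Optional list with `true` and `permuted` hit tables
#'   for the coding filter, keyed by candidate id `"<gene>:<start>-<end>"`;
#'   `NULL` skips the filter.
#' @return An object of class `discovery_result`: `cnes` (data.frame with
#'   one row per CNE: id, gene, central interval, genomic interval, CCS at
#'   both phases), `cne_details` (per-CNE support tables), `pseudo_cnes`,
#'   `calibration_threshold`, `counts`, and the masked region sets used.
#' @export
run_discovery <- function(input, config = run_config(), coding_hits = NULL) {
  dat <- load_run_input(input)
  comps <- setdiff(dat$species, dat$central)
  th <- config$thresholds

  orthologs <- lapply(comps, function(s) {
    if (is.null(dat$hits[[s]])) {
      warning("no hit tables for species ", s, "; species skipped")
      return(NULL)
    }
    reciprocal_best_hits(dat$hits[[s]]$ab, dat$hits[[s]]$ba, dat$tx2gene)
  })
  names(orthologs) <- comps
  comps <- comps[!vapply(orthologs, is.null, logical(1))]

  extracted <- lapply(dat$species, function(s) {
    extract_all_upstream(dat$gene_tables[[s]], dat$genomes[[s]],
                         span = config$span, repeats = dat$repeats[[s]],
                         species = s)
  })
  names(extracted) <- dat$species
  masked <- lapply(dat$species, function(s) {
    vapply(extracted[[s]]$regions, apply_repeat_penalty, character(1))
  })
  names(masked) <- dat$species

  central_genes <- names(extracted[[dat$central]]$regions)
  ## comparator gene + region lookup per central gene, via the ortholog tables
  comp_gene_for <- function(gene) {
    out <- character(0)
    for (s in comps) {
      ot <- orthologs[[s]]
      hit <- ot$gene_b[ot$gene_a == gene]
      if (length(hit) == 1L && !is.null(masked[[s]][[hit]])) out[s] <- hit
    }
    out
  }
  comp_seq_for <- function(gene) {
    cg <- comp_gene_for(gene)
    setNames(lapply(names(cg), function(s) masked[[s]][[cg[[s]]]]),
             names(cg))
  }

  usable <- central_genes[vapply(central_genes,
                                 function(g) length(comp_seq_for(g)) > 0,
                                 logical(1))]

  ## phase 1: candidates at the permissive bounds
  candidates <- list()
  for (g in usable) {
    cg <- comp_gene_for(g)
    cands <- candidates_for_gene(masked[[dat$central]][[g]], comp_seq_for(g),
                                 config$scheme, th$L_candidate,
                                 th$U_candidate)
    for (cand in cands) {
      cand$gene_id <- g
      cand$supports$comp_gene <- unname(cg[cand$supports$species])
      cand$id <- sprintf("%s:%d-%d", g, cand$central_start, cand$central_end)
      candidates[[length(candidates) + 1L]] <- cand
    }
  }

  ## pseudo-ortholog calibration: derangement of the usable central genes
  pseudo_candidates <- list()
  if (length(usable) >= 2L) {
    pseudo_pairs <- generate_pseudo_ortholog_pairs(usable,
                                                   seed = derive_seed(config$seed, 17L))
    for (i in seq_len(nrow(pseudo_pairs))) {
      g <- pseudo_pairs$central_gene[i]
      pg <- pseudo_pairs$comparator_gene[i]
      comp <- comp_seq_for(pg)
      if (!length(comp)) next
      cands <- candidates_for_gene(masked[[dat$central]][[g]], comp,
                                   config$scheme, th$L_candidate,
                                   th$U_candidate)
      cg <- comp_gene_for(pg)
      for (cand in cands) {
        cand$gene_id <- g
        cand$supports$comp_gene <- unname(cg[cand$supports$species])
        cand$id <- sprintf("%s:%d-%d", g, cand$central_start,
                           cand$central_end)
        pseudo_candidates[[length(pseudo_candidates) + 1L]] <- cand
      }
    }
  } else {
    pseudo_pairs <- data.frame(central_gene = character(),
                               comparator_gene = character())
  }
  ccs_threshold <- calibrate_ccs_threshold(pseudo_candidates)

  detected <- Filter(function(c) c$ccs > ccs_threshold, candidates)

  ## coding filter on the detected candidates
  removed_ids <- character(0)
  coding_threshold <- NA_real_
  if (!is.null(coding_hits) && length(detected)) {
    ids <- vapply(detected, `[[`, character(1), "id")
    cf <- coding_filter(ids, coding_hits$true, coding_hits$permuted)
    removed_ids <- cf$removed
    coding_threshold <- cf$threshold
    detected <- detected[ids %in% cf$passed]
  }

  ## phase 2: re-score at the strict bounds, where the pseudo set shows no
  ## conservation (a perfect window is needed to saturate P at U = 100), and
  ## calibrate a final CCS threshold on the re-scored pseudo candidates
  finalize <- function(cand) {
    p_final <- sigmoid_scale(cand$supports$max_intermediate, th$L_final,
                             th$U_final)
    cand$supports$P_final <- p_final
    cand$ccs_final <- combined_conservation_score(p_final)
    cand
  }
  detected <- lapply(detected, finalize)
  pseudo_final <- vapply(lapply(pseudo_candidates, finalize), `[[`,
                         numeric(1), "ccs_final")
  final_threshold <- if (length(pseudo_final)) max(pseudo_final) else 0
  n_final_removed <- sum(vapply(detected, `[[`, numeric(1), "ccs_final") <=
                           final_threshold)
  detected <- Filter(function(c) c$ccs_final > final_threshold, detected)

  ## pseudo-CNE control set at the pseudo-CNE cutoff
  pseudo_cnes <- Filter(function(c) c$ccs > th$pseudo_cne_ccs_cutoff,
                        pseudo_candidates)
  pseudo_cnes <- lapply(pseudo_cnes, function(c) { c$pseudo <- TRUE; c })

  cne_df <- function(lst, ccs_final = TRUE) {
    if (!length(lst)) {
      return(data.frame(id = character(), gene = character(),
                        start = integer(), end = integer(),
                        length = integer(), n_species = integer(),
                        ccs = numeric(), ccs_final = numeric(),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(lst, function(c) {
      data.frame(id = c$id, gene = c$gene_id, start = c$central_start,
                 end = c$central_end, length = c$central_end - c$central_start,
                 n_species = nrow(c$supports), ccs = c$ccs,
                 ccs_final = if (ccs_final && !is.null(c$ccs_final))
                   c$ccs_final else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }

  counts <- list(
    regions = lapply(extracted, `[[`, "counts"),
    orthologous_genes = length(usable),
    candidates = length(candidates),
    pseudo_candidates = length(pseudo_candidates),
    calibration_threshold = ccs_threshold,
    final_threshold = final_threshold,
    detected = length(detected) + length(removed_ids) + n_final_removed,
    coding_removed = length(removed_ids),
    final_removed = n_final_removed,
    cnes = length(detected),
    pseudo_cnes = length(pseudo_cnes))

  structure(list(cnes = cne_df(detected),
                 cne_details = detected,
                 pseudo_cnes = cne_df(pseudo_cnes, ccs_final = FALSE),
                 pseudo_cne_details = pseudo_cnes,
                 calibration_threshold = ccs_threshold,
                 final_threshold = final_threshold,
                 pseudo_candidate_ccs = vapply(pseudo_candidates, `[[`,
                                               numeric(1), "ccs"),
                 pseudo_candidate_ccs_final = pseudo_final,
                 coding_threshold = coding_threshold,
                 pseudo_pairs = pseudo_pairs,
                 counts = counts,
                 central_species = dat$central,
                 comparators = comps,
                 regions = extracted,
                 masked = masked,
                 config = config),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("CNE discovery (", x$central_species, "vs",
      length(x$comparators), "comparators )\n")
  cat("  orthologous genes analysed:", x$counts$orthologous_genes, "\n")
  cat("  candidates:", x$counts$candidates,
      "| pseudo candidates:", x$counts$pseudo_candidates, "\n")
  cat("  calibrated CCS thresholds:",
      format(x$calibration_threshold, digits = 4), "(candidate),",
      format(x$final_threshold, digits = 4), "(final)\n")
  cat("  CNEs:", x$counts$cnes,
      "( coding filter removed", x$counts$coding_removed,
      ", final calibration removed", x$counts$final_removed, ")\n")
  cat("  pseudo-CNEs:", x$counts$pseudo_cnes, "\n")
  invisible(x)
}

## Region-anchored alignment of a CNE: each support sequence is globally
## aligned to the central sequence and projected onto central coordinates
## (comparator insertions relative to the central row are dropped).
cne_alignment_block <- function(central_seq, support_seqs) {
  width <- nchar(central_seq)
  rows <- vapply(support_seqs, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(s),
      subject = Biostrings::DNAString(central_seq), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -1, baseOnly = FALSE),
      gapOpening = 4, gapExtension = 1)
    al_p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    al_s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    paste(al_p[al_s != "-"], collapse = "")
  }, character(1))
  alignment_block(c(central = central_seq, rows))
}

#' Characterize a discovered CNE set
#'
#' Computes the per-CNE feature table (composition, length, distance to the
#' translation start, transcribed overlap), rank-sum comparisons of each
#' feature between CNEs and pseudo-CNEs, the positional-conservation test,
#' hypergeometric enrichment of transcribed overlap in a designated subset,
#' SCI structure reports, and PWM over-representation calls against matched
#' control sets.
#'
#' @param result A `discovery_result`.
#' @param transcripts Optional transcript sequences (character vector or
#'   sequence record data.frame) for the k-mer overlap statistic.
#' @param pwms Optional list of [pwm()] objects for motif statistics.
#' @param subset_ids CNE ids forming the designated subset for the
#'   hypergeometric enrichment (default: the 20 highest-CCS CNEs, or all if
#'   fewer).
#' @param overlap_success_pct Transcribed-overlap percentage at or above
#'   which a CNE counts as a success in the enrichment test.
#' @param sci Logical; compute SCI reports (can be disabled for speed).
#' @return An object of class `characterization_result` with elements
#'   `features`, `pseudo_features`, `comparisons`, `position_test`,
#'   `enrichment`, `sci_table`, `motif_calls`.
#' @export
run_characterization <- function(result, transcripts = NULL, pwms = NULL,
                                 subset_ids = NULL,
                                 overlap_success_pct = 33.3, sci = TRUE) {
  stopifnot(inherits(result, "discovery_result"))
  config <- result$config
  central <- result$central_species
  regions <- result$regions[[central]]$regions
  empty <- nrow(result$cnes) == 0L

  feature_row <- function(gene, start, end, id) {
    reg <- regions[[gene]]
    seq <- substr(reg$sequence, start + 1L, end)
    comp <- sequence_composition(seq)
    ov <- if (!is.null(transcripts) && nchar(seq) >= config$k) {
      kmer_transcribed_overlap(seq, transcripts, k = config$k)
    } else NA_real_
    data.frame(id = id, gene = gene, length = end - start,
               gc = comp$gc, cpg_oe = comp$cpg_oe,
               distance = distance_to_translation_start(start, end,
                                                        reg$span_used),
               transcribed_overlap_pct = ov,
               atg_count = unname(comp$trinucleotides["ATG"]),
               stringsAsFactors = FALSE)
  }
  feat_tab <- function(df) {
    if (!nrow(df)) {
      return(data.frame(id = character(), gene = character(),
                        length = integer(), gc = numeric(),
                        cpg_oe = numeric(), distance = integer(),
                        transcribed_overlap_pct = numeric(),
                        atg_count = integer(), stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      feature_row(df$gene[i], df$start[i], df$end[i], df$id[i])
    }))
  }
  features <- feat_tab(result$cnes)
  pseudo_features <- feat_tab(result$pseudo_cnes)

  comparisons <- NULL
  if (nrow(features) && nrow(pseudo_features)) {
    comparisons <- do.call(rbind, lapply(
      c("gc", "cpg_oe", "length", "distance"), function(f) {
        x <- features[[f]]; y <- pseudo_features[[f]]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (!length(x) || !length(y)) return(NULL)
        rs <- rank_sum_test(x, y)
        data.frame(feature = f, U = rs$U, p = rs$p,
                   median_cne = stats::median(x),
                   median_pseudo = stats::median(y),
                   stringsAsFactors = FALSE)
      }))
  }

  ## positional conservation: distance to the translation start in the
  ## central species vs in each supporting comparator species
  pos_pairs <- function(details) {
    rows <- lapply(details, function(c) {
      reg <- regions[[c$gene_id]]
      d_c <- distance_to_translation_start(c$central_start, c$central_end,
                                           reg$span_used)
      sup <- c$supports
      if (is.null(sup$comp_gene)) return(NULL)
      do.call(rbind, lapply(seq_len(nrow(sup)), function(j) {
        creg <- result$regions[[sup$species[j]]]$regions[[sup$comp_gene[j]]]
        if (is.null(creg)) return(NULL)
        data.frame(species = sup$species[j], d_central = d_c,
                   d_comparator = creg$span_used - sup$end[j],
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  run_pos_test <- function(details) {
    pp <- pos_pairs(details)
    if (is.null(pp) || nrow(pp) < 3L) return(NULL)
    res <- tryCatch(position_conservation_test(pp$d_central,
                                               pp$d_comparator),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    c(res, list(n = nrow(pp), pairs = pp))
  }
  position_test <- run_pos_test(result$cne_details)
  pseudo_position_test <- run_pos_test(result$pseudo_cne_details)

  enrichment <- NULL
  if (nrow(features) && any(!is.na(features$transcribed_overlap_pct))) {
    succ <- !is.na(features$transcribed_overlap_pct) &
      features$transcribed_overlap_pct >= overlap_success_pct
    if (is.null(subset_ids)) {
      o <- order(-result$cnes$ccs_final, result$cnes$id)
      subset_ids <- result$cnes$id[o[seq_len(min(20L, length(o)))]]
    }
    in_sub <- features$id %in% subset_ids
    enrichment <- list(N = nrow(features), K = sum(succ),
                       n = sum(in_sub), k = sum(succ & in_sub))
    enrichment$p <- hypergeometric_enrichment(enrichment$N, enrichment$K,
                                              enrichment$n, enrichment$k)
  }

  support_seq <- function(sup, j) {
    creg <- result$regions[[sup$species[j]]]$regions[[sup$comp_gene[j]]]
    if (is.null(creg)) return(NULL)
    substr(creg$sequence, sup$start[j] + 1L, sup$end[j])
  }

  sci_table <- NULL
  if (sci && length(result$cne_details)) {
    rows <- lapply(result$cne_details, function(c) {
      reg <- regions[[c$gene_id]]
      central_seq <- substr(reg$sequence, c$central_start + 1L, c$central_end)
      sup <- c$supports
      if (is.null(sup$comp_gene)) return(NULL)
      seqs <- list()
      for (j in seq_len(nrow(sup))) {
        s <- support_seq(sup, j)
        if (!is.null(s) && nzchar(s)) seqs[[sup$species[j]]] <- s
      }
      if (!length(seqs)) return(NULL)
      block <- cne_alignment_block(central_seq, unlist(seqs))
      rep <- tryCatch(
        sci_empirical_pvalue(block, n = config$sci_shuffles,
                             seed = derive_seed(config$seed, 23L)),
        error = function(e) NULL)
      if (is.null(rep)) return(NULL)
      data.frame(id = c$id, sci = rep$sci, z = rep$z, p = rep$empirical_p,
                 n_valid = rep$n_valid, engine = rep$engine,
                 stringsAsFactors = FALSE)
    })
    sci_table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }

  motif_calls <- NULL
  if (!is.null(pwms) && nrow(features)) {
    cl <- cluster_pwms(pwms, threshold = 1.5)
    reps <- pwms[match(cl$representatives,
                       vapply(pwms, `[[`, character(1), "id"))]
    true_seqs <- vapply(seq_len(nrow(result$cnes)), function(i) {
      reg <- regions[[result$cnes$gene[i]]]
      substr(reg$sequence, result$cnes$start[i] + 1L, result$cnes$end[i])
    }, character(1))
    region_seqs <- vapply(regions, `[[`, character(1), "sequence")
    ctrl <- matched_control_regions(
      data.frame(gene = result$cnes$gene, start = result$cnes$start,
                 end = result$cnes$end, stringsAsFactors = FALSE),
      region_seqs, n_sets = config$n_motif_controls,
      seed = derive_seed(config$seed, 29L))
    control_sets <- lapply(ctrl, function(set) {
      if (is.null(set) || !nrow(set)) return(character(0))
      vapply(seq_len(nrow(set)), function(i) {
        mirror_n_positions(true_seqs[set$source_cne[i]], set$sequence[i])
      }, character(1))
    })
    motif_calls <- do.call(rbind, lapply(reps, function(p) {
      call <- overrepresentation_call(p, true_seqs, control_sets)
      sm <- pwm_summaries(p)
      data.frame(pwm_id = p$id, entropy = sm$entropy_bits,
                 gc_weight = sm$gc_weight, p_true = call$p_true,
                 verdict = call$verdict, stringsAsFactors = FALSE)
    }))
  }

  structure(list(features = features, pseudo_features = pseudo_features,
                 comparisons = comparisons, position_test = position_test,
                 pseudo_position_test = pseudo_position_test,
                 enrichment = enrichment, sci_table = sci_table,
                 motif_calls = motif_calls, empty = empty),
            class = "characterization_result")
}

#' @export
print.characterization_result <- function(x, ...) {
  if (x$empty) {
    cat("Characterization of an empty CNE set\n")
    return(invisible(x))
  }
  cat("CNE characterization:", nrow(x$features), "CNEs vs",
      nrow(x$pseudo_features), "pseudo-CNEs\n")
  if (!is.null(x$comparisons)) {
    cat("  feature comparisons (rank-sum):\n")
    for (i in seq_len(nrow(x$comparisons))) {
      cat(sprintf("    %-9s median %.3g vs %.3g, p = %.3g\n",
                  x$comparisons$feature[i], x$comparisons$median_cne[i],
                  x$comparisons$median_pseudo[i], x$comparisons$p[i]))
    }
  }
  if (!is.null(x$position_test)) {
    cat(sprintf("  positional conservation: rho = %.3f, p = %.3g (n = %d)\n",
                x$position_test$rho, x$position_test$p, x$position_test$n))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("  transcribed-overlap enrichment: %d/%d in subset vs %d/%d, p = %.3g\n",
                x$enrichment$k, x$enrichment$n, x$enrichment$K,
                x$enrichment$N, x$enrichment$p))
  }
  if (!is.null(x$sci_table)) {
    cat(sprintf("  SCI: %d blocks, %d at p < 0.05, %d at p < 0.01\n",
                nrow(x$sci_table), sum(x$sci_table$p < 0.05),
                sum(x$sci_table$p < 0.01)))
  }
  if (!is.null(x$motif_calls)) {
    cat(sprintf("  motifs: %d representatives, %d over, %d under\n",
                nrow(x$motif_calls), sum(x$motif_calls$verdict == "over"),
                sum(x$motif_calls$verdict == "under")))
  }
  invisible(x)
}
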