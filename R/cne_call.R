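#' Threshold configuration for CNE calling
#'
#' Candidate discovery runs at permissive bounds (`L` 80, `U` 94); after
#' coding-sequence filtering, candidates are re-scored at the strict bounds
#' (`L` 87, `U` 100) where the pseudo-ortholog control shows no conservation.
#' Pseudo-CNE control sets are built at the candidate bounds with a CCS
#' cutoff of 0.528.
#'
#' @param L_candidate,U_candidate Candidate-phase lower/upper bounds on the
#'   intermediate (percent-of-maximum) score.
#' @param L_final,U_final Final-phase bounds.
#' @param pseudo_cne_ccs_cutoff CCS cutoff used to harvest pseudo-CNEs.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(L_candidate = 80, U_candidate = 94,
                             L_final = 87, U_final = 100,
                             pseudo_cne_ccs_cutoff = 0.528) {
  stopifnot(L_candidate < U_candidate, L_final < U_final,
            L_candidate >= 0, U_candidate <= 100,
            L_final >= 0, U_final <= 100)
  structure(list(L_candidate = L_candidate, U_candidate = U_candidate,
                 L_final = L_final, U_final = U_final,
                 pseudo_cne_ccs_cutoff = pseudo_cne_ccs_cutoff),
            class = "threshold_config")
}

#' Apply the repeat penalty to an upstream region
#'
#' Replaces repeat-masked positions by `N`; since `N` scores as a mismatch
#' against everything in the window aligner, annotated repeats are penalized
#' punitively in the intermediate scores.
#'
#' @param region An `upstream_region` (or a list with `sequence` and
#'   `repeat_mask`).
#' @return The masked sequence (string).
#' @export
apply_repeat_penalty <- function(region) {
  seq <- region$sequence
  mask <- region$repeat_mask
  if (is.null(mask) || !nrow(mask)) return(seq)
  if (any(mask$start < 0) || any(mask$end > nchar(seq))) {
    stop("repeat mask outside region")
  }
  for (i in seq_len(nrow(mask))) {
    substr(seq, mask$start[i] + 1L, mask$end[i]) <-
      strrep("N", mask$end[i] - mask$start[i])
  }
  seq
}

#' Intermediate score: percent of the maximum window score
#'
#' @param raw Raw window alignment score(s) in `[0, w]`.
#' @param w Window length.
#' @return `100 * raw / w`.
#' @export
intermediate_score <- function(raw, w) {
  if (any(raw < 0 | raw > w)) stop("raw score outside [0, w]")
  100 * raw / w
}

#' Sigmoid scaling of intermediate scores into conservation scores
#'
#' Scores at or below `L` map to 0, at or above `U` map to 1, and scores in
#' between follow a logistic curve with steepness `10 / (U - L)`, affinely
#' rescaled to hit exactly 0 at `L` and 1 at `U`; the curve is symmetric
#' about the midpoint, where it takes the value 0.5.
#'
#' @param s Intermediate score(s).
#' @param L,U Lower and upper bounds (`L < U`).
#' @return Conservation score(s) `P` in `[0, 1]`.
#' @export
sigmoid_scale <- function(s, L, U) {
  stopifnot(L < U)
  k <- 10 / (U - L)
  mid <- (L + U) / 2
  f <- function(x) 1 / (1 + exp(-k * (x - mid)))
  p <- (f(s) - f(L)) / (f(U) - f(L))
  p[s <= L] <- 0
  p[s >= U] <- 1
  pmin(1, pmax(0, p))
}

#' Window pairs above the lower bound, with conservation scores
#'
#' @param grid Either a `window_score_grid` from [all_window_pairs()] or a
#'   sparse data.frame from [significant_window_pairs()].
#' @param w Window length used to build the grid.
#' @param L,U Sigmoid bounds for this phase.
#' @return data.frame with columns `central_offset`, `comparator_offset`
#'   (0-based), `raw_score`, `intermediate_score`, `P`; only pairs with
#'   intermediate score strictly above `L`.
#' @export
extract_significant_windows <- function(grid, w, L, U) {
  if (is.matrix(grid)) {
    idx <- which(100 * grid / w > L, arr.ind = TRUE)
    df <- data.frame(central_offset = idx[, 1] - 1L,
                     comparator_offset = idx[, 2] - 1L,
                     raw_score = grid[idx])
  } else {
    df <- grid[100 * grid$raw_score / w > L, , drop = FALSE]
  }
  df$intermediate_score <- intermediate_score(df$raw_score, w)
  df <- df[df$intermediate_score > L, , drop = FALSE]
  df$P <- sigmoid_scale(df$intermediate_score, L, U)
  rownames(df) <- NULL
  df
}

#' Combined conservation score
#'
#' `CCS = 1 - prod(1 - P_i)` over the per-species maximum conservation
#' scores.
#'
#' @param p Numeric vector of per-species conservation scores in `[0, 1]`.
#' @return The CCS.
#' @export
combined_conservation_score <- function(p) {
  if (!length(p)) stop("empty conservation score list")
  if (any(p < 0 | p > 1)) stop("conservation scores must lie in [0, 1]")
  1 - prod(1 - p)
}

#' Bundle significant window pairs into candidate CNEs
#'
#' Central-species window intervals `[offset, offset + w)` from all species
#' that are not disjoint are merged (transitive closure) into candidate
#' intervals. For each candidate and species, the support interval is the
#' span of that species' windows mapping into the candidate, `P_i` is the
#' maximum conservation score among them, and the CCS combines the `P_i`
#' across species.
#'
#' @param pairs_by_species Named list (species -> data.frame as returned by
#'   [extract_significant_windows()]).
#' @param w Window length.
#' @return List of candidate CNEs; each is a list with `central_start`,
#'   `central_end`, `supports` (data.frame `species`, `start`, `end`,
#'   `max_intermediate`, `P`) and `ccs`.
#' @export
bundle_windows <- function(pairs_by_species, w) {
  pairs_by_species <- pairs_by_species[
    vapply(pairs_by_species, nrow, integer(1)) > 0]
  if (!length(pairs_by_species)) return(list())
  all_off <- unlist(lapply(pairs_by_species, `[[`, "central_offset"))
  merged <- merge_intervals(all_off, all_off + w)
  lapply(seq_len(nrow(merged)), function(m) {
    ms <- merged$start[m]; me <- merged$end[m]
    supports <- lapply(sort(names(pairs_by_species)), function(spn) {
      df <- pairs_by_species[[spn]]
      inside <- df$central_offset >= ms & df$central_offset + w <= me
      if (!any(inside)) return(NULL)
      df <- df[inside, , drop = FALSE]
      data.frame(species = spn,
                 start = min(df$comparator_offset),
                 end = max(df$comparator_offset) + w,
                 max_intermediate = max(df$intermediate_score),
                 P = max(df$P), stringsAsFactors = FALSE)
    })
    supports <- do.call(rbind, supports[!vapply(supports, is.null, logical(1))])
    list(central_start = ms, central_end = me, supports = supports,
         ccs = combined_conservation_score(supports$P))
  })
}

#' Calibrate the CCS detection threshold on pseudo-ortholog candidates
#'
#' The threshold is the maximum CCS observed among candidates built from
#' randomly paired (pseudo-orthologous) regions, or 0 if the pseudo set
#' produced no candidates. Detection uses the strict rule `CCS > threshold`,
#' so by construction no conservation is detected in the control.
#'
#' @param pseudo_candidates List of candidates from [bundle_windows()] run
#'   on pseudo-ortholog pairs with the same thresholds as the real pairs.
#' @return The calibrated CCS threshold (numeric scalar).
#' @export
calibrate_ccs_threshold <- function(pseudo_candidates) {
  if (!length(pseudo_candidates)) return(0)
  max(vapply(pseudo_candidates, `[[`, numeric(1), "ccs"))
}

#' Randomly permute the residues of a sequence
#'
#' Preserves the residue multiset; used to derive the coding-filter e-value
#' threshold from permuted (composition-matched) sequences.
#'
#' @param seq DNA sequence (string).
#' @param seed Integer seed.
#' @return The permuted sequence.
#' @export
permute_sequence <- function(seq, seed = NULL) {
  with_seed(seed, {
    paste(sample(strsplit(seq, "")[[1]]), collapse = "")
  })
}

#' Permutation-calibrated coding-sequence filter
#'
#' The e-value threshold is the minimum (most significant) e-value attained
#' by the permuted sequences against the protein database; any candidate
#' with a true hit more significant than that threshold is discarded as
#' putative unannotated coding sequence.
#'
#' @param candidate_ids Character vector of candidate identifiers.
#' @param true_hits Hit table for the real candidate sequences (`query_id`
#'   keyed by candidate id).
#' @param permuted_hits Hit table for the permuted candidate sequences.
#' @return List with `passed`, `removed` (character vectors of candidate
#'   ids) and `threshold` (the minimum permuted e-value, `Inf` if the
#'   permuted set had no hits at all; in that limit every candidate with any
#'   hit is removed, which is reported with a message).
#' @export
coding_filter <- function(candidate_ids, true_hits, permuted_hits) {
  threshold <- if (nrow(permuted_hits)) min(permuted_hits$e_value) else Inf
  if (!is.finite(threshold) && nrow(true_hits)) {
    message("coding filter: permuted set produced no hits; threshold is +Inf ",
            "and every candidate with any hit will be removed")
  }
  removed <- unique(true_hits$query_id[true_hits$e_value < threshold])
  removed <- intersect(candidate_ids, removed)
  list(passed = setdiff(candidate_ids, removed), removed = removed,
       threshold = threshold)
}

## Candidate discovery machinery shared by real and pseudo calls: one
## central region against the same gene's (or pseudo-paired gene's) region
## in each comparator species.
candidates_for_gene <- function(central_seq, comparator_seqs, scheme, L, U) {
  w <- scheme$window_length
  min_raw <- L * w / 100 + 0.25   # strictly above L on the percent scale
  pairs <- lapply(comparator_seqs, function(s) {
    if (nchar(s) < w || nchar(central_seq) < w) {
      return(data.frame(central_offset = integer(),
                        comparator_offset = integer(),
                        raw_score = numeric(),
                        intermediate_score = numeric(), P = numeric()))
    }
    sp <- significant_window_pairs(central_seq, s, scheme, min_raw)
    extract_significant_windows(sp, w, L, U)
  })
  bundle_windows(pairs, w)
}

#' Call pseudo-CNEs from pseudo-ortholog pairings
#'
#' Runs the same candidate machinery as the real discovery on randomly
#' paired regions at the permissive candidate bounds, applies the pseudo-CNE
#' CCS cutoff, and (optionally) the coding filter. The result is a control
#' set of high-scoring but non-orthologous alignments.
#'
#' @param central_regions Named list of masked central-species region
#'   sequences (by gene).
#' @param comparator_regions Named list (species -> named list of masked
#'   region sequences by gene).
#' @param pseudo_pairs data.frame with `central_gene`, `comparator_gene`.
#' @param scheme A [scoring_scheme()].
#' @param thresholds A [threshold_config()]; the candidate-phase `L`/`U` and
#'   `pseudo_cne_ccs_cutoff` are used.
#' @param true_hits,permuted_hits Optional hit tables for the coding filter
#'   (ids `"<gene>:<start>-<end>"`); omitted means no filtering.
#' @return List of pseudo-CNE records (flagged `pseudo = TRUE`), each with
#'   the fields of a [bundle_windows()] candidate plus `gene_id` and `id`.
#' @export
call_pseudo_cnes <- function(central_regions, comparator_regions,
                             pseudo_pairs, scheme = scoring_scheme(),
                             thresholds = threshold_config(),
                             true_hits = NULL, permuted_hits = NULL) {
  out <- list()
  for (i in seq_len(nrow(pseudo_pairs))) {
    g <- pseudo_pairs$central_gene[i]
    pg <- pseudo_pairs$comparator_gene[i]
    comp <- lapply(comparator_regions, function(sp) sp[[pg]])
    comp <- comp[!vapply(comp, is.null, logical(1))]
    if (is.null(central_regions[[g]]) || !length(comp)) next
    cands <- candidates_for_gene(central_regions[[g]], comp, scheme,
                                 thresholds$L_candidate,
                                 thresholds$U_candidate)
    for (cand in cands) {
      if (cand$ccs > thresholds$pseudo_cne_ccs_cutoff) {
        cand$gene_id <- g
        cand$id <- sprintf("%s:%d-%d", g, cand$central_start,
                           cand$central_end)
        cand$pseudo <- TRUE
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  if (!is.null(true_hits) && !is.null(permuted_hits) && length(out)) {
    ids <- vapply(out, `[[`, character(1), "id")
    cf <- coding_filter(ids, true_hits, permuted_hits)
    out <- out[ids %in% cf$passed]
  }
  out
}
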