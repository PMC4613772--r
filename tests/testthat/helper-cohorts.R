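## Shared cohorts, built once per test run (helpers persist across test
## files). 600 bp regions keep the window grids cheap while leaving room for
## 90 bp elements.
##  - repeat cohort: GC-elevated elements plus unannotated AT-background
##    repeats shared across loci, the synthetic source of pseudo-CNEs;
##  - clean cohort: repeat-free, elements planted at two distances so the
##    positional-conservation signal is strong.
cohort_cache <- new.env()

get_repeat_cohort <- function() {
  if (is.null(cohort_cache$coh_rep)) {
    cohort_cache$coh_rep <- make_test_cohort(
      seed = 72L, n_genes = 8L, ancestor = 600L, elem_rate = 0.02,
      elem_gc = 0.55,
      repeat_spec = list(n_per_gene = 2L, length = 60L, divergence = 0.10,
                         annotate = FALSE))
  }
  cohort_cache$coh_rep
}

get_repeat_result <- function() {
  if (is.null(cohort_cache$res_rep)) {
    cohort_cache$res_rep <- run_discovery(
      get_repeat_cohort(),
      run_config(span = 600L, sci_shuffles = 50L, seed = 5L))
  }
  cohort_cache$res_rep
}

get_clean_cohort <- function() {
  if (is.null(cohort_cache$coh_cl)) {
    cfg <- evolution_config(ancestor_length = 600L, n_genes = 6L, seed = 76L,
      species = data.frame(name = c("nvit", paste0("cmp", 1:3)),
                           substitution_rate = 0.35, indel_rate = 0.01,
                           indel_mean_len = 2))
    cohort_cache$coh_cl <- generate_ortholog_cohort(cfg, list(
      planted_element(60L, 90L, 0.02, gc = 0.55),
      planted_element(300L, 90L, 0.02, gc = 0.55)))
  }
  cohort_cache$coh_cl
}

get_clean_result <- function() {
  if (is.null(cohort_cache$res_cl)) {
    cohort_cache$res_cl <- run_discovery(
      get_clean_cohort(),
      run_config(span = 600L, sci_shuffles = 50L, seed = 5L))
  }
  cohort_cache$res_cl
}

## Fraction of planted central-species elements recovered by called CNEs
## with at least `min_frac` of the element length overlapped.
recovery_rate <- function(coh, res, min_frac = 0.5) {
  tr <- coh$truth[coh$truth$species == coh$central_species, ]
  mean(vapply(seq_len(nrow(tr)), function(i) {
    cc <- res$cnes[res$cnes$gene == paste0(coh$central_species, "_",
                                           tr$gene[i]), ]
    if (!nrow(cc)) return(FALSE)
    any(pmin(cc$end, tr$end[i]) - pmax(cc$start, tr$start[i]) >=
          min_frac * (tr$end[i] - tr$start[i]))
  }, logical(1)))
}
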