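## End-to-end helper shared by the type-I and recovery acceptance criteria:
## simulate a full three-type experiment, call genes per type, run all six
## ordered comparisons, and classify unique sets.
run_unique_set_experiment <- function(seed, cfg = sim_config()) {
  sim <- simulate_genome_annotation(cfg, seed)
  map <- gatc_fragment_map(sim$genome)
  expt <- simulate_damid_experiment(sim, cfg, seed, map = map)
  types <- cfg$cell_types
  st <- cfg$stages[1]
  ratios <- setNames(lapply(types, function(ty) {
    lapply(seq_len(cfg$replicates), function(r) log2_ratio(
      rpm_normalize(expt$profiles[[sprintf("%s_%s_dam_fusion_r%d", ty, st, r)]]),
      rpm_normalize(expt$profiles[[sprintf("%s_%s_dam_only_r%d", ty, st, r)]])))
  }), types)
  calls <- setNames(lapply(types, function(ty) call_polii_genes(
    average_profiles(ratios[[ty]]), sim$annotation,
    call_params(seed = derive_seed(seed, paste0("polii/", ty))))), types)
  self_enriched <- vapply(types, function(ty) {
    dg <- differential_genes(
      subtract_profiles(ratios[[ty]], ratios[[ty]]), sim$annotation,
      calls[[ty]], call_params(seed = derive_seed(seed, paste0("self/", ty))))
    sum(dg$enriched)
  }, 0L)
  pairwise <- list()
  for (a in types) for (b in types) {
    if (a == b) next
    pairwise[[paste0(a, "_vs_", b)]] <- differential_genes(
      subtract_profiles(ratios[[a]], ratios[[b]]), sim$annotation, calls[[a]],
      call_params(seed = derive_seed(seed, paste0("diff/", a, "/", b))))
  }
  us <- unique_sets(pairwise, calls, types)
  list(unique_sets = us, truth = expt$truth$stages[[st]],
       self_enriched = self_enriched, calls = calls, types = types)
}

## sensitivity/precision of recovered unique sets against planted truth
unique_set_recovery <- function(res) {
  tp <- called <- planted <- 0L
  for (ty in res$types) for (dir in c("enriched", "depleted")) {
    cg <- res$unique_sets[[ty]][[dir]]
    pg <- res$truth[[dir]][[ty]]
    tp <- tp + length(intersect(cg, pg))
    called <- called + length(cg)
    planted <- planted + length(pg)
  }
  c(tp = tp, called = called, planted = planted)
}

## peak-recovery helper: simulate a TF-binding experiment on a 5,000-fragment
## genome, call per-replicate significant peaks, form the consensus, and
## measure recall of the planted truth.
run_peak_experiment <- function(seed, n_peaks = 15, shuffles = 1000) {
  cfg <- sim_config(chrom_length = 1.25e6, n_genes = 60, n_peaks = n_peaks)
  sim <- simulate_genome_annotation(cfg, seed)
  map <- gatc_fragment_map(sim$genome)
  tf <- simulate_tf_binding(sim, cfg, seed, map = map)
  peaksets <- lapply(seq_len(cfg$tf_replicates), function(r) peak_fdr(
    log2_ratio(rpm_normalize(tf$fusion[[r]]), rpm_normalize(tf$dam[[r]])),
    shuffles = shuffles, seed = derive_seed(seed, paste0("peaks/r", r))))
  cons <- replicate_consensus(peaksets)
  truth <- tf$truth$peaks
  recall <- if (nrow(truth) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(truth)), function(i) {
      any(cons$chrom == truth$chrom[i] &
            cons$start < truth$end[i] & cons$end > truth$start[i])
    }, TRUE))
  }
  overlap_truth <- if (nrow(cons) == 0) logical(0) else
    vapply(seq_len(nrow(cons)), function(i) {
      any(truth$chrom == cons$chrom[i] &
            truth$start < cons$end[i] & truth$end > cons$start[i])
    }, TRUE)
  list(consensus = cons, truth = truth, recall = recall,
       n_false_consensus = sum(!overlap_truth))
}
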