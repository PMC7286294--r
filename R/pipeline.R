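#' Read a pipeline configuration file
#'
#' Plain-text Debian-control-style `key: value` format (one record). Every
#' numeric-looking value is coerced; comma-separated values become vectors.
#' See `system.file("extdata", "demo_config.dcf", package = "tadapipe")`
#' for the shipped demo configuration.
#'
#' @param path configuration file.
#' @return named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- read.dcf(path)
  cfg <- as.list(raw[1L, ])
  cfg <- lapply(cfg, function(v) {
    parts <- trimws(strsplit(v, ",")[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  pipeline_config(cfg)
}

#' Validate and complete a pipeline configuration
#'
#' @param cfg named list of overrides; see the demo config for fields.
#' @return named list of class `pipeline_config` with defaults filled in.
#' @export
pipeline_config <- function(cfg = list()) {
  defaults <- list(
    master_seed = 1,
    cell_types = c("cholinergic", "GABAergic", "glutamatergic"),
    stages = "larva",
    replicates = 3, reads_per_sample = 1e5,
    chrom_length = 3.5e6, n_chroms = 1, gatc_spacing = 250, n_genes = 200,
    beta = 1.0, dispersion = 0.2,
    n_unique_enriched = 20, n_unique_depleted = 10,
    pseudocount = 1, permutations = 100,
    fdr_threshold = 0.01, min_score = 0.2,
    run_peaks = 1, n_peaks = 15, peak_effect = 2.0, shuffles = 1000,
    peak_fdr_threshold = 1e-4, theta = 0, window = 5000,
    run_catada = 1, delta = 10, k = 3, up = 5000, down = 2000,
    run_scrna = 1,
    genome_fasta = "", annotation_gff = ""
  )
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad) > 0) stopf("unknown config field: %s", bad[1L])
  defaults[names(cfg)] <- cfg
  cfg <- defaults
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold >= 1 ||
      cfg$peak_fdr_threshold <= 0 || cfg$peak_fdr_threshold >= 1) {
    stopf("FDR thresholds must lie in (0, 1)")
  }
  for (p in c("genome_fasta", "annotation_gff")) {
    if (nzchar(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stopf("configured path does not exist: %s = %s", p, cfg[[p]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

cheap_hash <- function(obj) {
  bytes <- serialize(obj, NULL, version = 2L)
  sprintf("%d:%.0f", length(bytes),
          sum(as.double(bytes) * rep_len(c(1, 3, 7, 31), length(bytes))) %%
            2147483647)
}

tsv <- function(df, dir, name) {
  write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(name)
}

#' Run the full TaDa analysis pipeline
#'
#' Executes every stage in dependency order on simulated inputs (or a
#' supplied genome/annotation): fragment map, count profiles, RPM and log2
#' ratios, per-type Pol II gene calls, all pairwise differential
#' comparisons, unique-enrichment sets, stage transitions (when >= 2
#' stages), TF peak calling with replicate consensus and gene assignment,
#' CATaDa accessibility differences, scRNA-seq overlap, and correlation /
#' class-composition reports. All artefacts are TSV/BED/bedGraph files in
#' `out_dir`; the run is byte-reproducible from (config, master seed), and
#' `run_log.tsv` records each stage's input fingerprints and row counts.
#'
#' @param config a [pipeline_config()], a config-file path, or a list of
#'   overrides.
#' @param out_dir output directory.
#' @param seed optional master-seed override.
#' @return (invisibly) the output directory.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(seed)) config$master_seed <- seed
  seed <- as.integer(config$master_seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_rows <- list()
  note <- function(stage, input_hash, n) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, input_hash = input_hash, rows = n,
      stringsAsFactors = FALSE)
  }
  types <- config$cell_types
  stages <- config$stages

  scfg <- sim_config(
    n_chroms = as.integer(config$n_chroms),
    chrom_length = config$chrom_length, gatc_spacing = config$gatc_spacing,
    n_genes = as.integer(config$n_genes), cell_types = types, stages = stages,
    replicates = as.integer(config$replicates),
    reads_per_sample = config$reads_per_sample,
    dispersion = config$dispersion, beta = config$beta,
    n_unique_enriched = as.integer(config$n_unique_enriched),
    n_unique_depleted = as.integer(config$n_unique_depleted),
    n_peaks = as.integer(config$n_peaks), peak_effect = config$peak_effect)

  ## --- genome, annotation, fragment map -------------------------------
  if (nzchar(config$genome_fasta)) {
    genome <- Biostrings::readDNAStringSet(config$genome_fasta)
    annotation <- read_annotation(config$annotation_gff)
    sim <- list(genome = genome, annotation = annotation)
  } else {
    sim <- simulate_genome_annotation(scfg, seed)
  }
  map <- gatc_fragment_map(sim$genome)
  write_fragment_bed(map, file.path(out_dir, "fragments.bed"))
  note("fragment_map", cheap_hash(names(sim$genome)), n_fragments(map))

  ## --- DamID experiment ------------------------------------------------
  expt <- simulate_damid_experiment(sim, scfg, seed, map = map)
  class_map <- expt$truth$class_map
  params <- call_params(fdr_threshold = config$fdr_threshold,
                        min_score = config$min_score,
                        permutations = as.integer(config$permutations))

  ratio <- function(ty, st, r) {
    fus <- expt$profiles[[sprintf("%s_%s_dam_fusion_r%d", ty, st, r)]]
    dam <- expt$profiles[[sprintf("%s_%s_dam_only_r%d", ty, st, r)]]
    log2_ratio(rpm_normalize(fus), rpm_normalize(dam), config$pseudocount)
  }

  calls <- list(); ratios <- list()
  for (st in stages) {
    for (ty in types) {
      reps <- lapply(seq_len(scfg$replicates), function(r) ratio(ty, st, r))
      ratios[[paste0(ty, "_", st)]] <- reps
      p <- params
      p$seed <- derive_seed(seed, paste0("polii/", ty, "/", st))
      cl <- call_polii_genes(average_profiles(reps), sim$annotation, p)
      calls[[paste0(ty, "_", st)]] <- cl
      tsv(cl, out_dir, sprintf("gene_calls_%s_%s.tsv", ty, st))
      note(paste0("gene_calls/", ty, "_", st), cheap_hash(reps[[1L]]$values),
           sum(cl$bound))
    }
  }

  ## --- differential + unique sets + transitions ------------------------
  stage_sets <- list()
  for (st in stages) {
    pairwise <- list()
    for (a in types) for (b in types) {
      if (a == b) next
      p <- params
      p$seed <- derive_seed(seed, paste0("diff/", st, "/", a, "_vs_", b))
      diffs <- subtract_profiles(ratios[[paste0(a, "_", st)]],
                                 ratios[[paste0(b, "_", st)]])
      dg <- differential_genes(diffs, sim$annotation,
                               calls[[paste0(a, "_", st)]], p)
      key <- paste0(a, "_vs_", b)
      pairwise[[key]] <- dg
      tsv(dg, out_dir, sprintf("differential_%s_%s.tsv", st, key))
      note(paste0("differential/", st, "/", key), cheap_hash(diffs[[1L]]$values),
           sum(dg$enriched))
    }
    bound_tables <- setNames(lapply(types, function(ty)
      calls[[paste0(ty, "_", st)]]), types)
    us <- unique_sets(pairwise, bound_tables, types)
    stage_sets[[st]] <- us
    us_df <- do.call(rbind, lapply(types, function(ty) rbind(
      if (length(us[[ty]]$enriched) > 0)
        data.frame(cell_type = ty, direction = "enriched",
                   gene_id = us[[ty]]$enriched, stringsAsFactors = FALSE),
      if (length(us[[ty]]$depleted) > 0)
        data.frame(cell_type = ty, direction = "depleted",
                   gene_id = us[[ty]]$depleted, stringsAsFactors = FALSE))))
    if (is.null(us_df)) us_df <- data.frame(cell_type = character(0),
                                            direction = character(0),
                                            gene_id = character(0))
    tsv(us_df, out_dir, sprintf("unique_sets_%s.tsv", st))
    note(paste0("unique_sets/", st), cheap_hash(names(pairwise)), nrow(us_df))
  }
  if (length(stages) >= 2L) {
    tf_genes <- names(class_map)[class_map == "TF"]
    tt <- transition_table(stage_sets, genes = tf_genes)
    tsv(tt$transitions, out_dir, "transitions.tsv")
    tsv(tt$states, out_dir, "transition_states.tsv")
    note("transitions", cheap_hash(stage_sets), nrow(tt$states))
  }

  ## --- TF peak calling --------------------------------------------------
  if (config$run_peaks > 0) {
    tf <- simulate_tf_binding(sim, scfg, seed, map = map)
    peaksets <- lapply(seq_len(scfg$tf_replicates), function(r) {
      prof <- log2_ratio(rpm_normalize(tf$fusion[[r]]),
                         rpm_normalize(tf$dam[[r]]), config$pseudocount)
      pk <- peak_fdr(prof, theta = config$theta,
                     shuffles = as.integer(config$shuffles),
                     seed = derive_seed(seed, paste0("peaks/r", r)),
                     fdr_threshold = config$peak_fdr_threshold)
      tsv(pk, out_dir, sprintf("peaks_rep%d.tsv", r))
      pk
    })
    consensus <- replicate_consensus(peaksets)
    tsv(consensus, out_dir, "peaks_consensus.tsv")
    assigned <- assign_genes(consensus, sim$annotation, window = config$window)
    tsv(assigned, out_dir, "peak_gene_assignment.tsv")
    note("peaks", cheap_hash(lapply(peaksets, nrow)), nrow(consensus))
  }

  ## --- CATaDa -----------------------------------------------------------
  if (config$run_catada > 0) {
    st1 <- stages[1L]
    acc <- lapply(types, function(ty) {
      reps <- lapply(seq_len(scfg$replicates), function(r)
        expt$profiles[[sprintf("%s_%s_dam_only_r%d", ty, st1, r)]])
      accessibility_profile(reps)
    })
    names(acc) <- types
    write_profile_bedgraph(acc[[1L]],
                           file.path(out_dir, paste0("catada_", types[1L], ".bedgraph")))
    loci <- locus_accessibility(acc[[1L]], sim$annotation,
                                up = config$up, down = config$down)
    tsv(loci, out_dir, "catada_loci.tsv")
    dr <- robust_diff_regions(acc[[1L]], acc[[2L]], delta = config$delta,
                              k = as.integer(config$k))
    tsv(dr$regions, out_dir,
        sprintf("catada_diff_%s_vs_%s.tsv", types[1L], types[2L]))
    note("catada", cheap_hash(acc[[1L]]$values), nrow(dr$regions))
  }

  ## --- scRNA-seq overlap ------------------------------------------------
  if (config$run_scrna > 0) {
    st1 <- stages[length(stages)]
    chol_tfs <- filter_gene_class(
      stage_sets[[st1]][[types[1L]]]$enriched, class_map, "TF")
    planted <- if (length(chol_tfs) >= 2L) chol_tfs else NULL
    sc <- simulate_scrnaseq(scfg, seed,
                            gene_ids = sim$annotation$genes$gene_id,
                            planted_tfs = planted)
    om <- overlap_matrix(sc$triples, sc$truth$planted_tfs,
                         sc$cell_annotation, restrict_to_type = types[1L])
    tsv(as.data.frame(om$counts), out_dir, "scrna_overlap_counts.tsv")
    tsv(as.data.frame(om$jaccard), out_dir, "scrna_overlap_jaccard.tsv")
    note("scrna_overlap", cheap_hash(dim(sc$triples$mat)), nrow(om$counts))
  }

  ## --- reports ----------------------------------------------------------
  cm <- correlation_matrix(signal_matrix(calls))
  tsv(as.data.frame(cm), out_dir, "correlation_matrix.tsv")
  comp_sets <- lapply(stage_sets, function(us)
    unlist(lapply(us, function(s) s$enriched), use.names = FALSE))
  names(comp_sets) <- paste0("enriched_", names(stage_sets))
  tsv(class_composition(comp_sets, class_map), out_dir,
      "class_composition.tsv")

  ## resolved config + log
  resolved <- data.frame(key = names(config),
                         value = vapply(config, function(v)
                           paste(format(v, trim = TRUE), collapse = ","), ""),
                         stringsAsFactors = FALSE)
  tsv(resolved, out_dir, "resolved_config.tsv")
  tsv(do.call(rbind, log_rows), out_dir, "run_log.tsv")
  invisible(out_dir)
}
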