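#' Simulation configuration
#'
#' Defaults describe the desk-scale stand-in for a TaDa study: a 3.5 Mb
#' single-chromosome genome with GATC motifs at exponentially distributed
#' spacings (mean 250 bp, the fly-like motif density), 200 non-overlapping
#' genes of 8-16 kb (gene-body Pol II scoring needs tens of GATC fragments
#' per transcript; TaDa-profiled neuronal genes are large), three
#' neurotransmitter cell types with three replicates and 1e5 reads per
#' sample, negative-binomial count noise (dispersion 0.2), a single
#' expressed-gene log2 effect beta = 1, and per type 20 planted
#' uniquely-enriched plus 10 uniquely-depleted genes. 40% of genes form a
#' shared expressed baseline present in every type (neurons express about
#' half the genome).
#'
#' @param ... overrides for any default field.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    ## genome
    n_chroms = 1L, chrom_length = 3.5e6, gatc_spacing = 250,
    ## annotation
    n_genes = 200L, gene_length = c(8000, 16000), min_gap = 300,
    ## experiment design
    cell_types = c("cholinergic", "GABAergic", "glutamatergic"),
    stages = "larva", replicates = 3L, reads_per_sample = 1e5,
    dispersion = 0.2,
    ## effects
    baseline_sdlog = 0.5, beta = 1.0,
    shared_expressed_fraction = 0.4,
    n_unique_enriched = 20L, n_unique_depleted = 10L,
    ## TF-binding (peak) experiment
    n_peaks = 15L, peak_length = c(3L, 5L), peak_effect = 2.0,
    tf_replicates = 2L, tf_reads_per_sample = 2e5, fusion_name = "TF",
    ## scRNA-seq
    cells_per_type = c(cholinergic = 600L, GABAergic = 300L,
                       glutamatergic = 300L, unassigned = 300L),
    capture_mean = 0.5, scrna_dispersion = 0.5,
    n_planted_tfs = 8L, subpop_size = 40L, subpop_overlap = 0L,
    planted_mean_factor = 8
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stopf("unknown sim_config field: %s", bad[1L])
  cfg[names(over)] <- over
  if (cfg$gatc_spacing < 8) stopf("gatc_spacing must be >= 8 bp")
  if (cfg$beta < 0) stopf("beta must be >= 0")
  if (cfg$n_genes < 1 || cfg$replicates < 1) stopf("counts must be positive")
  structure(cfg, class = "sim_config")
}

## NB counts; dispersion -> 0 degenerates to Poisson
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a genome and gene annotation
#'
#' Background bases are drawn uniformly from \{A, C, G\} — an alphabet that
#' cannot form the GATC motif (T occurs only inside planted motifs), so
#' every GATC in the output is a planted cut site. Motif starts are placed
#' at exponential spacings (mean `gatc_spacing`, clipped to >= 8 bp).
#' Genes are non-overlapping with 1–3 transcripts each and Bernoulli(0.5)
#' strands. Byte-deterministic under (config, seed).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   ([annotation_set()]), `truth` (skeleton list with the planted motif
#'   positions).
#' @export
simulate_genome_annotation <- function(config = sim_config(), seed = 1L) {
  stopifnot(is(config, "sim_config"))
  set.seed(derive_seed(seed, "genome"))
  L <- as.integer(config$chrom_length)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))

  seqs <- character(config$n_chroms)
  motif_pos <- vector("list", config$n_chroms)
  for (ci in seq_len(config$n_chroms)) {
    chars <- sample(c("A", "C", "G"), L, replace = TRUE)
    n_draw <- ceiling(L / config$gatc_spacing * 2) + 10L
    gaps <- pmax(8, round(rexp(n_draw, 1 / config$gatc_spacing)))
    pos <- cumsum(gaps)           # 0-based motif starts
    pos <- pos[pos <= L - 4L]
    for (p in pos) chars[(p + 1L):(p + 4L)] <- c("G", "A", "T", "C")
    seqs[ci] <- paste(chars, collapse = "")
    motif_pos[[ci]] <- pos
  }
  genome <- Biostrings::DNAStringSet(setNames(seqs, chrom_names))

  ## distribute genes across chromosomes proportional to length
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1L)))
  genes <- list(); txs <- list(); gid <- 0L
  for (ci in seq_len(config$n_chroms)) {
    ng <- n_per[ci]
    if (ng == 0L) next
    lens <- round(runif(ng, config$gene_length[1L], config$gene_length[2L]))
    need <- sum(lens) + (ng + 1L) * config$min_gap
    if (need > L) {
      stopf("genes cannot fit on %s (%d bp needed, %d available); use a longer genome",
            chrom_names[ci], need, L)
    }
    slack <- L - need
    u <- runif(ng + 1L)
    extra <- floor(slack * u / sum(u))
    gaps <- config$min_gap + extra
    starts <- cumsum(gaps[seq_len(ng)]) + c(0, cumsum(lens[-ng]))
    for (k in seq_len(ng)) {
      gid <- gid + 1L
      g_id <- sprintf("gene%04d", gid)
      g_start <- starts[k]; g_end <- starts[k] + lens[k]
      genes[[gid]] <- data.frame(
        gene_id = g_id, chrom = chrom_names[ci],
        strand = if (rbinom(1L, 1L, 0.5) == 1L) "+" else "-",
        start = g_start, end = g_end, stringsAsFactors = FALSE)
      n_tx <- sample.int(3L, 1L)
      tx <- data.frame(transcript_id = sprintf("%s.t1", g_id), gene_id = g_id,
                       chrom = chrom_names[ci], start = g_start, end = g_end,
                       stringsAsFactors = FALSE)
      if (n_tx > 1L) {
        for (t in 2:n_tx) {
          off1 <- floor(runif(1L, 0, 0.1) * lens[k])
          off2 <- floor(runif(1L, 0, 0.1) * lens[k])
          tx <- rbind(tx, data.frame(
            transcript_id = sprintf("%s.t%d", g_id, t), gene_id = g_id,
            chrom = chrom_names[ci], start = g_start + off1,
            end = g_end - off2, stringsAsFactors = FALSE))
        }
      }
      txs[[gid]] <- tx
    }
  }
  annotation <- annotation_set(do.call(rbind, genes), do.call(rbind, txs))
  list(genome = genome, annotation = annotation,
       truth = list(motif_positions = setNames(motif_pos, chrom_names)))
}

## fraction of each fragment covered by a set of gene spans
fragment_coverage_fraction <- function(map, annotation, gene_ids) {
  x <- numeric(n_fragments(map))
  if (length(gene_ids) == 0L) return(x)
  g <- annotation$genes[annotation$genes$gene_id %in% gene_ids, ]
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end)))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(map$granges)
  hits <- GenomicRanges::findOverlaps(map$granges, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(map$granges)[qi], IRanges::ranges(gr)[si]))
  acc <- rowsum(as.numeric(ov), qi)
  idx <- as.integer(rownames(acc))
  x[idx] <- acc[, 1L] / IRanges::width(IRanges::ranges(map$granges))[idx]
  x
}

#' Simulate a multi-replicate TaDa Pol II experiment with planted truth
#'
#' Fragment weights are a shared log-normal accessibility baseline `a_f`
#' (Dam-only channel) or `a_f * 2^(beta * x_f)` (fusion channel), where
#' `x_f` is the fraction of fragment f covered by genes expressed in that
#' type/stage. Counts are negative binomial with the configured mean depth
#' and dispersion. Uniquely-enriched genes are expressed only in their
#' type; uniquely-depleted genes only in the two other types; a shared
#' baseline set is expressed everywhere.
#'
#' @param sim output of [simulate_genome_annotation()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param map optional precomputed [gatc_fragment_map()] of `sim$genome`.
#' @return list `map`, `profiles` (named list of count
#'   [fragment_profile()]s, `{type}_{stage}_{channel}_r{rep}`), `truth`
#'   (per-stage expressed/enriched/depleted sets, `class_map`).
#' @export
simulate_damid_experiment <- function(sim, config = sim_config(), seed = 1L,
                                      map = NULL) {
  stopifnot(is(config, "sim_config"))
  if (is.null(map)) map <- gatc_fragment_map(sim$genome)
  annotation <- sim$annotation
  gene_ids <- annotation$genes$gene_id
  types <- config$cell_types
  stopifnot(length(types) >= 2L)

  set.seed(derive_seed(seed, "expression_design"))
  shared <- sort(sample(gene_ids, round(config$shared_expressed_fraction *
                                          length(gene_ids))))
  pool0 <- setdiff(gene_ids, shared)
  n_ue <- config$n_unique_enriched; n_ud <- config$n_unique_depleted
  per_stage <- list()
  for (st in config$stages) {
    need <- length(types) * (n_ue + n_ud)
    if (need > length(pool0)) {
      stopf("not enough genes to plant %d unique genes per stage", need)
    }
    picked <- sample(pool0, need)
    enr <- list(); dep <- list(); k <- 0L
    for (ty in types) {
      enr[[ty]] <- sort(picked[(k + 1L):(k + n_ue)]); k <- k + n_ue
    }
    for (ty in types) {
      dep[[ty]] <- sort(picked[(k + 1L):(k + n_ud)]); k <- k + n_ud
    }
    expressed <- list()
    for (ty in types) {
      others <- setdiff(types, ty)
      expressed[[ty]] <- sort(unique(c(
        shared, enr[[ty]], unlist(dep[others], use.names = FALSE))))
    }
    per_stage[[st]] <- list(enriched = enr, depleted = dep,
                            expressed = expressed)
  }

  ## planted unique genes are transcription factors; sprinkle background classes
  set.seed(derive_seed(seed, "gene_classes"))
  planted <- unique(unlist(lapply(per_stage, function(s)
    c(unlist(s$enriched), unlist(s$depleted))), use.names = FALSE))
  class_map <- setNames(rep("other", length(gene_ids)), gene_ids)
  class_map[planted] <- "TF"
  rest <- setdiff(gene_ids, planted)
  extra_tf <- sample(rest, round(0.05 * length(rest)))
  class_map[extra_tf] <- "TF"
  extra_nc <- sample(setdiff(rest, extra_tf), round(0.05 * length(rest)))
  class_map[extra_nc] <- "lncRNA"

  set.seed(derive_seed(seed, "baseline"))
  a_f <- rlnorm(n_fragments(map), meanlog = 0, sdlog = config$baseline_sdlog)

  profiles <- list()
  for (st in config$stages) {
    for (ty in types) {
      x_f <- fragment_coverage_fraction(map, annotation,
                                        per_stage[[st]]$expressed[[ty]])
      w_fusion <- a_f * 2^(config$beta * x_f)
      for (rep_i in seq_len(config$replicates)) {
        for (ch in c("dam_only", "dam_fusion")) {
          sid <- sprintf("%s_%s_%s_r%d", ty, st, ch, rep_i)
          set.seed(derive_seed(seed, paste0("counts/", sid)))
          w <- if (ch == "dam_only") a_f else w_fusion
          mu <- config$reads_per_sample * w / sum(w)
          counts <- rcounts(length(mu), mu, config$dispersion)
          profiles[[sid]] <- fragment_profile(
            counts, map,
            sample_meta(sid, cell_type = ty, stage = st, replicate = rep_i,
                        channel = ch,
                        fusion_name = if (ch == "dam_fusion") "PolII" else ""),
            unit = "count")
        }
      }
    }
  }
  if (config$beta == 0 && (n_ue > 0 || n_ud > 0)) {
    warn <- "beta = 0: planted unique genes carry no recoverable signal"
  } else {
    warn <- NULL
  }
  list(map = map, profiles = profiles,
       truth = list(shared_expressed = shared, stages = per_stage,
                    class_map = class_map, warning = warn))
}

#' Simulate a TF-binding TaDa experiment with planted peaks
#'
#' Plants `n_peaks` binding peaks, each a run of 3–5 consecutive GATC
#' fragments with the fusion weight multiplied by `2^peak_effect`, placed
#' at the starts of randomly chosen target genes (hence within 5 kb of a
#' gene). Two replicate fusion/Dam channel pairs are generated by default.
#'
#' @inheritParams simulate_damid_experiment
#' @return list `map`, `fusion` / `dam` (lists of count profiles, one per
#'   replicate), `truth` (`peaks` data.frame with intervals, member
#'   fragments and target genes).
#' @export
simulate_tf_binding <- function(sim, config = sim_config(), seed = 1L,
                                map = NULL) {
  stopifnot(is(config, "sim_config"))
  if (is.null(map)) map <- gatc_fragment_map(sim$genome)
  if (config$peak_length[1L] < 2L) stopf("peak length must be >= 2 fragments")
  fr <- map$fragments
  genes <- sim$annotation$genes

  set.seed(derive_seed(seed, "tf_peaks"))
  order_genes <- sample(genes$gene_id)
  used <- logical(n_fragments(map))
  peaks <- list()
  for (g_id in order_genes) {
    if (length(peaks) >= config$n_peaks) break
    g <- genes[genes$gene_id == g_id, ]
    k <- sample(seq(config$peak_length[1L], config$peak_length[2L]), 1L)
    anchor <- fragments_overlapping(map, g$chrom, g$start, g$start + 1L)
    f0 <- anchor[1L]
    f1 <- f0 + k - 1L
    if (f1 > n_fragments(map) || fr$chrom[f1] != fr$chrom[f0]) next
    ## keep planted runs separated by >= 2 fragments so candidates never merge
    lo <- max(1L, f0 - 2L); hi <- min(n_fragments(map), f1 + 2L)
    if (any(used[lo:hi])) next
    used[f0:f1] <- TRUE
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = fr$chrom[f0], start = fr$start[f0], end = fr$end[f1],
      first_frag = f0, last_frag = f1, n_fragments = k,
      target_gene = g_id, stringsAsFactors = FALSE)
  }
  if (length(peaks) < config$n_peaks) {
    stopf("could only place %d of %d requested peaks; enlarge the genome",
          length(peaks), config$n_peaks)
  }
  truth_peaks <- if (length(peaks) > 0) do.call(rbind, peaks) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               first_frag = integer(0), last_frag = integer(0),
               n_fragments = integer(0), target_gene = character(0))

  set.seed(derive_seed(seed, "tf_baseline"))
  a_f <- rlnorm(n_fragments(map), 0, config$baseline_sdlog)
  in_peak <- logical(n_fragments(map))
  for (i in seq_len(nrow(truth_peaks))) {
    in_peak[truth_peaks$first_frag[i]:truth_peaks$last_frag[i]] <- TRUE
  }
  w_fusion <- a_f * ifelse(in_peak, 2^config$peak_effect, 1)

  make_reps <- function(w, channel) {
    lapply(seq_len(config$tf_replicates), function(r) {
      sid <- sprintf("%s_%s_r%d", config$fusion_name, channel, r)
      set.seed(derive_seed(seed, paste0("tf_counts/", sid)))
      mu <- config$tf_reads_per_sample * w / sum(w)
      fragment_profile(rcounts(length(mu), mu, config$dispersion), map,
                       sample_meta(sid, replicate = r, channel = channel,
                                   fusion_name = if (channel == "dam_fusion")
                                     config$fusion_name else ""),
                       unit = "count")
    })
  }
  list(map = map,
       fusion = make_reps(w_fusion, "dam_fusion"),
       dam = make_reps(a_f, "dam_only"),
       truth = list(peaks = truth_peaks))
}

#' Simulate a sparse single-cell expression matrix with planted
#' subpopulations
#'
#' Background counts are negative binomial at the capture mean. Each
#' planted TF is expressed only in its designated subpopulation of
#' cholinergic cells (mean = capture mean x `planted_mean_factor`, at least
#' 4x); subpopulations are pairwise disjoint by default
#' (`subpop_overlap = 0` shared cells between consecutive subpopulations).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param gene_ids optional gene universe (default `gene0001` ...).
#' @param planted_tfs optional ids of the planted TF genes (default: the
#'   first `n_planted_tfs` of a seeded sample of the universe).
#' @return list `triples` ([read_expression_triples()] object),
#'   `cell_annotation` (named vector), `truth` (`planted_tfs`,
#'   `memberships` list of cell-index vectors).
#' @export
simulate_scrnaseq <- function(config = sim_config(), seed = 1L,
                              gene_ids = NULL, planted_tfs = NULL) {
  stopifnot(is(config, "sim_config"))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  set.seed(derive_seed(seed, "scrna"))
  if (is.null(planted_tfs)) {
    planted_tfs <- sort(sample(gene_ids, config$n_planted_tfs))
  }
  stopifnot(all(planted_tfs %in% gene_ids))
  if (length(config$cells_per_type) < 2L) stopf("need >= 2 cell types")

  cell_types <- rep(names(config$cells_per_type), config$cells_per_type)
  n_cells <- length(cell_types)
  chol_cells <- which(cell_types == "cholinergic")
  need <- length(planted_tfs) * (config$subpop_size - config$subpop_overlap) +
    config$subpop_overlap
  if (config$subpop_size > length(chol_cells) || need > length(chol_cells)) {
    stopf("subpopulations (%d cells) exceed cholinergic population (%d)",
          need, length(chol_cells))
  }
  pool <- sample(chol_cells)
  memberships <- list()
  cursor <- 0L
  for (i in seq_along(planted_tfs)) {
    if (i == 1L || config$subpop_overlap == 0L) {
      mem <- pool[(cursor + 1L):(cursor + config$subpop_size)]
      cursor <- cursor + config$subpop_size
    } else {
      carry <- memberships[[i - 1L]][seq_len(config$subpop_overlap)]
      fresh <- pool[(cursor + 1L):(cursor + config$subpop_size -
                                     config$subpop_overlap)]
      cursor <- cursor + config$subpop_size - config$subpop_overlap
      mem <- c(carry, fresh)
    }
    memberships[[planted_tfs[i]]] <- sort(mem)
  }

  n_genes <- length(gene_ids)
  mu <- matrix(config$capture_mean, nrow = n_genes, ncol = n_cells)
  planted_mean <- config$capture_mean * max(config$planted_mean_factor, 4)
  for (g in planted_tfs) {
    gi <- match(g, gene_ids)
    mu[gi, ] <- 0
    mu[gi, memberships[[g]]] <- planted_mean
  }
  counts <- matrix(rcounts(length(mu), as.vector(mu), config$scrna_dispersion),
                   nrow = n_genes, ncol = n_cells)
  mat <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  triples <- read_expression_triples(
    mat, data.frame(gene_id = gene_ids, gene_index = seq_len(n_genes),
                    stringsAsFactors = FALSE))
  list(triples = triples,
       cell_annotation = setNames(cell_types, seq_len(n_cells)),
       truth = list(planted_tfs = planted_tfs, memberships = memberships))
}

#' Write simulated inputs to disk as plain-text files
#'
#' Emits FASTA, GFF3, per-sample fragment-count TSVs, a gene-class list,
#' the MatrixMarket expression matrix with gene index and cell annotation,
#' and truth tables.
#'
#' @param sim output of [simulate_genome_annotation()].
#' @param experiment output of [simulate_damid_experiment()] (optional).
#' @param scrna output of [simulate_scrnaseq()] (optional).
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, experiment = NULL, scrna = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_annotation_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  if (!is.null(experiment)) {
    for (sid in names(experiment$profiles)) {
      p <- experiment$profiles[[sid]]
      write.table(data.frame(seq_along(p$values), p$values),
                  file.path(dir, paste0(sid, ".counts.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    cm <- experiment$truth$class_map
    write.table(data.frame(names(cm), unname(cm)),
                file.path(dir, "gene_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  if (!is.null(scrna)) {
    Matrix::writeMM(scrna$triples$mat, file.path(dir, "expression.mtx"))
    write.table(scrna$triples$gene_index, file.path(dir, "gene_index.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    ca <- scrna$cell_annotation
    write.table(data.frame(names(ca), unname(ca)),
                file.path(dir, "cell_annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(dir)
}

#' Write an annotation set as GFF3
#' @param annotation an [annotation_set()].
#' @param path output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes; tx <- annotation$transcripts
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  tx_strand <- g$strand[match(tx$gene_id, g$gene_id)]
  tx_gr <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start + 1L, tx$end), strand = tx_strand,
    type = "mRNA", ID = tx$transcript_id)
  tx_gr$Parent <- as(tx$gene_id, "CharacterList")
  gene_gr$Parent <- IRanges::CharacterList(vector("list", length(gene_gr)))
  all_gr <- c(gene_gr, tx_gr)
  all_gr <- all_gr[order(as.character(GenomeInfoDb::seqnames(all_gr)),
                         BiocGenerics::start(all_gr),
                         match(all_gr$type, c("gene", "mRNA")))]
  rtracklayer::export(all_gr, path, format = "gff3")
  invisible(path)
}
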