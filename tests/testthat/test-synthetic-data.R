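## a small but non-degenerate configuration for generator tests
small_cfg <- function(...) {
  sim_config(chrom_length = 6e5, n_genes = 30, gene_length = c(8000, 14000),
             n_unique_enriched = 3, n_unique_depleted = 2,
             n_peaks = 4, reads_per_sample = 2e4,
             cells_per_type = c(cholinergic = 80, GABAergic = 40,
                                glutamatergic = 40, unassigned = 20),
             n_planted_tfs = 3, subpop_size = 10, ...)
}

test_that("genome generation is deterministic and well formed", {
  cfg <- small_cfg()
  s1 <- simulate_genome_annotation(cfg, 42)
  s2 <- simulate_genome_annotation(cfg, 42)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  s3 <- simulate_genome_annotation(cfg, 43)
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))

  ## requested number of genes, pairwise non-overlapping
  g <- s1$annotation$genes
  expect_equal(nrow(g), 30L)
  g <- g[order(g$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))

  ## every GATC in the sequence is a planted motif and vice versa
  map <- gatc_fragment_map(s1$genome)
  cuts <- map$fragments$start[-1]
  expect_equal(cuts, sort(s1$truth$motif_positions$chr1) + 2L)
})

test_that("realised GATC spacing tracks the configured mean", {
  cfg <- sim_config(chrom_length = 1e5, n_genes = 5,
                    gene_length = c(3000, 6000), gatc_spacing = 250)
  spacings <- vapply(1:5, function(s) {
    map <- gatc_fragment_map(simulate_genome_annotation(cfg, s)$genome)
    mean(map$fragments$end - map$fragments$start)
  }, 0)
  expect_lt(abs(mean(spacings) - 250) / 250, 0.15)
})

test_that("genes that cannot fit raise a helpful error", {
  cfg <- sim_config(chrom_length = 5e4, n_genes = 30,
                    gene_length = c(8000, 14000))
  expect_error(simulate_genome_annotation(cfg, 1), "longer genome")
})

test_that("DamID experiment simulation is deterministic and consistent", {
  cfg <- small_cfg()
  sim <- simulate_genome_annotation(cfg, 7)
  map <- gatc_fragment_map(sim$genome)
  e1 <- simulate_damid_experiment(sim, cfg, 7, map = map)
  e2 <- simulate_damid_experiment(sim, cfg, 7, map = map)
  expect_identical(e1$profiles[[1]]$values, e2$profiles[[1]]$values)

  ## expected sample grid: types x stages x reps x channels
  expect_length(e1$profiles, 3 * 1 * 3 * 2)

  ## truth consistency: planted genes exist in the annotation and the
  ## unique sets are disjoint across types within a stage
  st <- e1$truth$stages[[1]]
  all_unique <- c(unlist(st$enriched), unlist(st$depleted))
  expect_true(all(all_unique %in% sim$annotation$genes$gene_id))
  expect_equal(anyDuplicated(all_unique), 0L)

  ## uniquely-enriched genes expressed only in their own type;
  ## uniquely-depleted genes expressed in exactly the other two
  for (ty in cfg$cell_types) {
    others <- setdiff(cfg$cell_types, ty)
    for (g in st$enriched[[ty]]) {
      expect_true(g %in% st$expressed[[ty]])
      for (o in others) expect_false(g %in% st$expressed[[o]])
    }
    for (g in st$depleted[[ty]]) {
      expect_false(g %in% st$expressed[[ty]])
      for (o in others) expect_true(g %in% st$expressed[[o]])
    }
  }

  ## fusion channel carries more mass on expressed genes than dam-only
  expres <- st$expressed$cholinergic
  x <- tadapipe:::fragment_coverage_fraction(map, sim$annotation, expres)
  fus <- e1$profiles$cholinergic_larva_dam_fusion_r1$values
  dam <- e1$profiles$cholinergic_larva_dam_only_r1$values
  enr <- (sum(fus[x > 0.5]) / sum(fus)) / (sum(dam[x > 0.5]) / sum(dam))
  expect_gt(enr, 1.3)

  ## beta = 0 with planted genes records a warning in the truth
  e0 <- simulate_damid_experiment(sim, small_cfg(beta = 0), 7, map = map)
  expect_match(e0$truth$warning, "no recoverable signal")
})

test_that("TF-binding simulation plants recoverable peak truth", {
  cfg <- small_cfg()
  sim <- simulate_genome_annotation(cfg, 3)
  map <- gatc_fragment_map(sim$genome)
  tf <- simulate_tf_binding(sim, cfg, 3, map = map)
  truth <- tf$truth$peaks
  expect_equal(nrow(truth), 4L)
  expect_true(all(truth$n_fragments >= 2))
  expect_true(all(truth$n_fragments >= 3 & truth$n_fragments <= 5))
  expect_true(all(truth$end <= map$seqlengths[truth$chrom]))
  expect_true(all(truth$target_gene %in% sim$annotation$genes$gene_id))
  expect_length(tf$fusion, cfg$tf_replicates)

  ## determinism
  tf2 <- simulate_tf_binding(sim, cfg, 3, map = map)
  expect_identical(tf$fusion[[1]]$values, tf2$fusion[[1]]$values)

  ## planted fragments are enriched in the fusion channel
  in_peak <- unlist(mapply(seq, truth$first_frag, truth$last_frag))
  fus <- tf$fusion[[1]]$values; dam <- tf$dam[[1]]$values
  expect_gt(mean(fus[in_peak]) / mean(fus[-in_peak]),
            2 * mean(dam[in_peak]) / mean(dam[-in_peak]))
})

test_that("scRNA-seq simulation plants disjoint subpopulations", {
  cfg <- small_cfg()
  sc <- simulate_scrnaseq(cfg, 9)
  expect_equal(dim(sc$triples$mat), c(cfg$n_genes, 180L))
  mem <- sc$truth$memberships
  expect_length(mem, 3L)
  expect_true(all(lengths(mem) == 10L))
  expect_equal(length(Reduce(intersect, mem)), 0L)
  ## members are cholinergic cells
  expect_true(all(sc$cell_annotation[unlist(mem)] == "cholinergic"))
  ## planted TFs silent outside their subpopulation
  for (g in sc$truth$planted_tfs) {
    row <- sc$triples$mat[match(g, sc$triples$gene_index$gene_id), ]
    outside <- setdiff(seq_along(row), mem[[g]])
    expect_equal(sum(row[outside]), 0)
  }
  ## determinism incl. MTX bytes
  sc2 <- simulate_scrnaseq(cfg, 9)
  f1 <- tempfile(); f2 <- tempfile()
  Matrix::writeMM(sc$triples$mat, f1); Matrix::writeMM(sc2$triples$mat, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulate_scrnaseq(small_cfg(subpop_size = 200), 1),
               "exceed")
})

test_that("written simulation artefacts are plain text and consistent", {
  cfg <- small_cfg()
  sim <- simulate_genome_annotation(cfg, 5)
  expt <- simulate_damid_experiment(sim, cfg, 5)
  dir <- file.path(tempdir(), "simout")
  write_simulation(sim, expt, NULL, dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  ## GFF3 round trip reproduces the annotation
  ann <- read_annotation(file.path(dir, "annotation.gff3"))
  expect_equal(nrow(ann$genes), nrow(sim$annotation$genes))
  expect_setequal(ann$genes$gene_id, sim$annotation$genes$gene_id)
  expect_equal(ann$genes[order(ann$genes$gene_id), c("start", "end")],
               sim$annotation$genes[order(sim$annotation$genes$gene_id),
                                    c("start", "end")])
  ## counts TSV round trip
  map <- gatc_fragment_map(file.path(dir, "genome.fa"))
  sid <- names(expt$profiles)[1]
  p <- load_fragment_signal(file.path(dir, paste0(sid, ".counts.tsv")),
                            map, sample_meta(sid))
  expect_equal(p$values, expt$profiles[[1]]$values)
})
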