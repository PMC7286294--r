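test_that("candidate peaks implement the run definition", {
  map <- uniform_map(4, L = 100)
  p <- profile_on(c(0.5, 0.6, -0.1, 0.7), map)
  pk <- candidate_peaks(p, theta = 0, stat = "mean")
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$first_frag, 1L)
  expect_equal(pk$last_frag, 2L)
  expect_equal(pk$stat, 0.55)
  expect_equal(c(pk$start, pk$end), c(0L, 200L))

  ## single isolated positive fragment is not a peak
  pk2 <- candidate_peaks(profile_on(c(-1, 2, -1, -1), map))
  expect_equal(nrow(pk2), 0L)
})

test_that("candidate peaks match the exhaustive-run oracle", {
  set.seed(55)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    map <- uniform_map(n, L = 50)
    v <- rnorm(n)
    for (st in c("sum", "mean", "min")) {
      pk <- candidate_peaks(profile_on(v, map), theta = 0, stat = st)
      o <- oracle_peaks(v, map$fragments$chrom, 0, st)
      expect_equal(pk$first_frag, o$first)
      expect_equal(pk$last_frag, o$last)
      expect_equal(pk$stat, o$stat)
    }
  }
})

test_that("runs never cross chromosome boundaries", {
  mm <- multi_chrom_map(2, 5, 100)
  v <- rep(1, 10)   # everything positive
  pk <- candidate_peaks(profile_on(v, mm))
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$chrom, c("chr1", "chr2"))
  expect_equal(pk$n_fragments, c(5L, 5L))
  expect_equal(pk$first_frag, c(1L, 6L))
  o <- oracle_peaks(v, mm$fragments$chrom, 0, "sum")
  expect_equal(pk$first_frag, o$first)
})

test_that("peak FDR: degenerate and planted cases", {
  map <- uniform_map(5, L = 100)
  ## constant profile at theta 0 -> no candidates above threshold on zeros
  pk <- peak_fdr(profile_on(rep(0, 5), map), shuffles = 100, seed = 1)
  expect_equal(nrow(pk), 0L)

  expect_error(peak_fdr(profile_on(rep(1, 5), map), shuffles = 50), ">= 100")

  ## planted run dominates a quiet background (reduced scale of the
  ## acceptance setup; full version in test-acceptance.R)
  set.seed(77)
  map2 <- uniform_map(400, L = 50)
  v <- rnorm(400, 0, 0.3); v[101:104] <- 3.0
  pk <- peak_fdr(profile_on(v, map2), shuffles = 200, seed = 5)
  planted <- pk[pk$first_frag <= 101 & pk$last_frag >= 104, ]
  expect_equal(nrow(planted), 1L)
  expect_true(planted$significant)

  ## FDR monotone non-increasing in the statistic
  o <- order(pk$stat)
  expect_true(all(diff(pk$fdr[o]) <= 1e-12))
})

test_that("replicate consensus requires support in every replicate", {
  mk <- function(rows) {
    df <- as.data.frame(rows)
    names(df) <- c("start", "end")
    df$chrom <- "chr1"; df$significant <- TRUE
    df
  }
  ## overlapping in both replicates -> one consensus spanning the union
  cons <- replicate_consensus(list(mk(rbind(c(100, 300))),
                                   mk(rbind(c(250, 400)))))
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$start, cons$end), c(100, 400))

  ## peak in only one replicate -> dropped
  cons2 <- replicate_consensus(list(mk(rbind(c(100, 300))),
                                    mk(rbind(c(1000, 1100)))))
  expect_equal(nrow(cons2), 0L)

  ## abutting (zero-overlap) peaks do not merge
  cons3 <- replicate_consensus(list(mk(rbind(c(100, 200))),
                                    mk(rbind(c(200, 300)))))
  expect_equal(nrow(cons3), 0L)

  ## chained overlap: rep1 peak bridges two rep2 peaks -> single union
  cons4 <- replicate_consensus(list(mk(rbind(c(100, 500))),
                                    mk(rbind(c(80, 150), c(450, 600)))))
  expect_equal(nrow(cons4), 1L)
  expect_equal(c(cons4$start, cons4$end), c(80, 600))

  expect_error(replicate_consensus(list()), "zero replicates")
})

genes_df <- function(...) {
  rows <- list(...)
  data.frame(gene_id = sprintf("g%d", seq_along(rows)),
             chrom = "chr1", strand = "+",
             start = vapply(rows, `[[`, 0, 1),
             end = vapply(rows, `[[`, 0, 2), stringsAsFactors = FALSE)
}
ann_of <- function(genes) annotation_set(genes)

test_that("gene assignment follows the no-intervening-gene rule", {
  peaks <- data.frame(chrom = "chr1", start = 10000, end = 10400,
                      peak_id = "p1", stringsAsFactors = FALSE)
  ## A at gap 1600 assigned; B not (A intervenes)
  ann <- ann_of(genes_df(c(12000, 13000), c(14000, 15000)))
  out <- assign_genes(peaks, ann, window = 5000)
  expect_equal(out$gene_id, "g1")
  expect_equal(out$relation, "downstream")
  expect_equal(out$distance, 1600)

  ## exactly 5000 assigned, 5001 not
  ann <- ann_of(genes_df(c(15400, 16000)))
  expect_equal(nrow(assign_genes(peaks, ann, 5000)), 1L)
  ann <- ann_of(genes_df(c(15401, 16000)))
  expect_equal(nrow(assign_genes(peaks, ann, 5000)), 0L)

  ## overlapping gene plus a clear downstream gene -> both assigned
  ann <- ann_of(genes_df(c(9000, 10200), c(12000, 12500)))
  out <- assign_genes(peaks, ann, 5000)
  expect_setequal(out$gene_id, c("g1", "g2"))
  expect_equal(out$relation[out$gene_id == "g1"], "overlapping")
  expect_equal(out$distance[out$gene_id == "g2"], 1600)
})

test_that("gene assignment matches the betweenness oracle on random layouts", {
  set.seed(88)
  for (i in 1:60) {
    n_genes <- sample(2:8, 1)
    starts <- sort(sample(seq(0, 60000, 500), n_genes))
    lens <- sample(500:4000, n_genes, replace = TRUE)
    g <- data.frame(gene_id = sprintf("g%d", seq_len(n_genes)),
                    chrom = "chr1", strand = "+",
                    start = starts, end = starts + lens,
                    stringsAsFactors = FALSE)
    ## allow overlapping gene models occasionally; annotation_set permits them
    peak <- data.frame(chrom = "chr1",
                       start = sample(seq(0, 60000, 100), 1), peak_id = "p1",
                       stringsAsFactors = FALSE)
    peak$end <- peak$start + sample(c(200, 400, 800), 1)
    got <- assign_genes(peak, annotation_set(g), window = 5000)
    want <- oracle_assign(peak, g, window = 5000)
    expect_setequal(paste(got$gene_id, got$relation),
                    paste(want$gene_id, want$relation))
  }
})
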