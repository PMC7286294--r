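## Fixtures are built in code; no binary files.

## sequence with GATC motifs at the given 0-based start positions,
## background drawn from {A,C,G} so no accidental motifs can form
seq_with_motifs <- function(len, motif_starts, seed = 1) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G"), len, replace = TRUE)
  for (p in motif_starts) chars[(p + 1):(p + 4)] <- c("G", "A", "T", "C")
  paste(chars, collapse = "")
}

## map with n fragments of equal length L on one chromosome
## (cut sites at L, 2L, ...; motif starts at L-2, 2L-2, ...)
uniform_map <- function(n, L = 100, chrom = "chr1", seed = 1) {
  starts <- (seq_len(n - 1) * L) - 2
  gatc_fragment_map(setNames(seq_with_motifs(n * L, starts, seed), chrom))
}

## map spanning several chromosomes, k fragments of length L each
multi_chrom_map <- function(n_chrom = 2, k = 5, L = 100) {
  seqs <- vapply(seq_len(n_chrom), function(i)
    seq_with_motifs(k * L, (seq_len(k - 1) * L) - 2, seed = i), "")
  gatc_fragment_map(setNames(seqs, paste0("chr", seq_len(n_chrom))))
}

profile_on <- function(values, map, unit = "log2_ratio",
                       meta = sample_meta("test")) {
  fragment_profile(values, map, meta, unit = unit)
}

## minimal annotation on a uniform map: transcript spans given as
## 0-based half-open intervals; one gene per transcript unless gene_ids given
toy_annotation <- function(spans, chrom = "chr1", gene_ids = NULL,
                           strand = "+") {
  n <- nrow(spans)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(n))
  genes <- do.call(rbind, lapply(unique(gene_ids), function(g) {
    rows <- spans[gene_ids == g, , drop = FALSE]
    data.frame(gene_id = g, chrom = chrom, strand = strand,
               start = min(rows[, 1]), end = max(rows[, 2]),
               stringsAsFactors = FALSE)
  }))
  tx <- data.frame(transcript_id = sprintf("t%02d", seq_len(n)),
                   gene_id = gene_ids, chrom = chrom,
                   start = spans[, 1], end = spans[, 2],
                   stringsAsFactors = FALSE)
  annotation_set(genes, tx)
}

write_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
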