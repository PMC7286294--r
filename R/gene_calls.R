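#' Parameters for transcribed-gene calling
#'
#' The thresholds match the published analysis: genes are called bound by
#' Pol II at a 1% permutation FDR and a minimum mean log2 ratio of 0.2.
#'
#' @param fdr_threshold FDR cutoff; a gene is bound when its FDR is strictly
#'   below this (default 0.01).
#' @param min_score minimum gene score in log2 units, inclusive (default 0.2).
#' @param permutations number of genome-wide value permutations (default 100,
#'   minimum 10).
#' @param seed RNG seed for the permutation null.
#' @param weighted length-weight fragment values when scoring transcripts.
#'   Default FALSE (plain fragment mean): the permutation null shuffles
#'   values across fragments irrespective of fragment length, so an
#'   unweighted statistic keeps observed and null scores exchangeable;
#'   length weights concentrate on the few longest fragments and hand the
#'   shuffled null their weight with extreme low-coverage values, inflating
#'   its tail.
#' @return object of class `call_params`.
#' @export
call_params <- function(fdr_threshold = 0.01, min_score = 0.2,
                        permutations = 100L, seed = 1L, weighted = FALSE) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stopf("fdr_threshold must be in (0, 1)")
  }
  if (permutations < 10L) stopf("permutations must be >= 10")
  structure(list(fdr_threshold = fdr_threshold, min_score = min_score,
                 permutations = as.integer(permutations),
                 seed = as.integer(seed), weighted = isTRUE(weighted)),
            class = "call_params")
}

## sparse transcripts-x-fragments weight matrix; rows sum to 1.
## w[t, f] = (intersection length of transcript t with fragment f) / total,
## or 1/n_fragments(t) when weighted = FALSE.
transcript_weight_matrix <- function(annotation, map, weighted = TRUE) {
  txgr <- transcripts_granges(annotation)
  unknown <- setdiff(GenomeInfoDb::seqlevels(txgr), names(map$seqlengths))
  if (length(unknown) > 0) {
    stopf("transcript on chromosome absent from fragment map: %s", unknown[1L])
  }
  GenomeInfoDb::seqlevels(txgr) <- GenomeInfoDb::seqlevels(map$granges)
  hits <- GenomicRanges::findOverlaps(txgr, map$granges)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0L || !all(seq_along(txgr) %in% qi)) {
    stopf("transcript overlapping zero fragments (chromosome missing from map?)")
  }
  w <- if (weighted) {
    as.numeric(IRanges::width(IRanges::pintersect(
      IRanges::ranges(txgr)[qi], IRanges::ranges(map$granges)[si])))
  } else {
    rep(1, length(qi))
  }
  W <- Matrix::sparseMatrix(i = qi, j = si, x = w,
                            dims = c(length(txgr), n_fragments(map)))
  W / Matrix::rowSums(W)
}

#' Score transcripts on a log2-ratio profile
#'
#' The transcript score is the length-weighted mean of the fragment log2
#' ratios over all fragments intersecting the transcript span (weights =
#' intersection lengths), i.e. the average per-bp signal over the gene body.
#'
#' @param profile a [fragment_profile()] with unit `log2_ratio`.
#' @param annotation an [annotation_set()].
#' @param weighted length-weighting flag (see [call_params()]).
#' @return data.frame `transcript_id`, `gene_id`, `score`.
#' @export
transcript_scores <- function(profile, annotation, weighted = TRUE) {
  stopifnot(is(profile, "fragment_profile"), is(annotation, "annotation_set"))
  W <- transcript_weight_matrix(annotation, profile$map, weighted)
  data.frame(transcript_id = annotation$transcripts$transcript_id,
             gene_id = annotation$transcripts$gene_id,
             score = as.numeric(W %*% profile$values),
             stringsAsFactors = FALSE)
}

#' Score a single transcript span
#'
#' @param profile a [fragment_profile()] with unit `log2_ratio`.
#' @param chrom,start,end transcript span, 0-based half-open.
#' @param weighted length-weighting flag.
#' @return numeric score.
#' @export
transcript_score <- function(profile, chrom, start, end, weighted = TRUE) {
  idx <- fragments_overlapping(profile$map, chrom, start, end)
  if (length(idx) == 0L) stopf("transcript overlaps zero fragments")
  fr <- profile$map$fragments[idx, ]
  w <- if (weighted) pmin(fr$end, end) - pmax(fr$start, start) else rep(1, length(idx))
  sum(w * profile$values[idx]) / sum(w)
}

#' Per-transcript permutation FDR for Pol II occupancy
#'
#' For each of P seeded permutations the fragment values are shuffled
#' uniformly genome-wide and every transcript is re-scored. For an observed
#' score s the raw FDR is the mean (over permutations) number of null scores
#' >= s divided by the number of observed scores >= s, clipped to \[0, 1\].
#' FDRs are then made monotone non-increasing in score: each transcript
#' receives the minimum raw FDR over all thresholds at or below its score,
#' so a higher score never has a larger FDR than a lower one.
#'
#' @param profile a [fragment_profile()] with unit `log2_ratio`.
#' @param annotation an [annotation_set()] with >= 2 transcripts.
#' @param params a [call_params()].
#' @return data.frame `transcript_id`, `gene_id`, `score`, `fdr`.
#' @export
permutation_fdr <- function(profile, annotation, params = call_params()) {
  stopifnot(is(params, "call_params"))
  if (nrow(annotation$transcripts) == 0L) stopf("empty annotation")
  if (nrow(annotation$transcripts) < 2L) stopf("need >= 2 transcripts")
  W <- transcript_weight_matrix(annotation, profile$map, params$weighted)
  v <- profile$values
  obs <- as.numeric(W %*% v)
  P <- params$permutations
  n <- length(v)

  set.seed(params$seed)
  V <- matrix(0, nrow = n, ncol = P)
  for (p in seq_len(P)) V[, p] <- v[sample.int(n)]
  null_scores <- as.numeric(as.matrix(W %*% V))

  sorted_null <- sort(null_scores)
  sorted_obs <- sort(obs)
  null_ge <- count_ge(obs, sorted_null) / P
  obs_ge <- count_ge(obs, sorted_obs)
  raw <- pmin(pmax(null_ge / obs_ge, 0), 1)
  fdr <- regularize_fdr(obs, raw)

  data.frame(transcript_id = annotation$transcripts$transcript_id,
             gene_id = annotation$transcripts$gene_id,
             score = obs, fdr = fdr, stringsAsFactors = FALSE)
}

#' Reduce transcript calls to gene calls
#'
#' Each gene takes the values of its transcript with the most significant
#' FDR (ties broken by higher score, then lexicographic transcript id). A
#' gene is bound iff its FDR is strictly below the threshold and its score
#' is at least `min_score` (inclusive).
#'
#' @param transcript_table data.frame from [permutation_fdr()].
#' @param params a [call_params()].
#' @return data.frame `gene_id`, `transcript_id`, `score`, `fdr`, `bound`.
#' @export
call_genes <- function(transcript_table, params = call_params()) {
  req <- c("transcript_id", "gene_id", "score", "fdr")
  stopifnot(all(req %in% names(transcript_table)))
  tt <- transcript_table[order(transcript_table$gene_id,
                               transcript_table$fdr,
                               -transcript_table$score,
                               transcript_table$transcript_id), ]
  best <- tt[!duplicated(tt$gene_id), ]
  out <- data.frame(gene_id = best$gene_id,
                    transcript_id = best$transcript_id,
                    score = best$score, fdr = best$fdr,
                    stringsAsFactors = FALSE)
  out$bound <- out$fdr < params$fdr_threshold & out$score >= params$min_score
  rownames(out) <- NULL
  out
}

#' Identify Pol II occupied (transcribed) genes
#'
#' Convenience wrapper: transcript scoring, permutation FDR, and per-gene
#' reduction in one call.
#'
#' @inheritParams permutation_fdr
#' @return gene call table (see [call_genes()]).
#' @export
call_polii_genes <- function(profile, annotation, params = call_params()) {
  call_genes(permutation_fdr(profile, annotation, params), params)
}

#' Write a gene call table as TSV
#' @param calls gene call table.
#' @param path output file.
#' @export
write_gene_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
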