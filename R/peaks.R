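#' Candidate binding peaks as runs of consecutive GATC fragments
#'
#' A candidate peak is a maximal run of >= 2 consecutive fragments (within
#' one chromosome) whose log2 ratio exceeds the entry threshold `theta`.
#' The peak statistic defaults to the *sum* of member log2 ratios, which
#' rewards both amplitude and run length; `"mean"` and `"min"` are
#' available alternatives.
#'
#' @param profile a [fragment_profile()] with unit `log2_ratio`.
#' @param theta fragment entry threshold (strict >; default 0).
#' @param stat peak statistic: `"sum"` (default), `"mean"`, or `"min"`.
#' @param min_fragments minimum run length (default 2).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open span),
#'   `first_frag`, `last_frag`, `n_fragments`, `stat`.
#' @export
candidate_peaks <- function(profile, theta = 0, stat = c("sum", "mean", "min"),
                            min_fragments = 2L) {
  stat <- match.arg(stat)
  stopifnot(is(profile, "fragment_profile"))
  if (profile$unit != "log2_ratio") stopf("candidate_peaks expects log2_ratio")
  fr <- profile$map$fragments
  runs <- true_runs(profile$values > theta, fr$chrom)
  keep <- runs$last - runs$first + 1L >= min_fragments
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      first_frag = integer(0), last_frag = integer(0),
                      n_fragments = integer(0), stat = numeric(0)))
  }
  stat_val <- run_stats(profile$values, runs$first, runs$last, stat)
  data.frame(chrom = fr$chrom[runs$first],
             start = fr$start[runs$first],
             end = fr$end[runs$last],
             first_frag = runs$first, last_frag = runs$last,
             n_fragments = runs$last - runs$first + 1L,
             stat = stat_val, stringsAsFactors = FALSE)
}

run_stats <- function(values, first, last, stat) {
  if (stat == "min") {
    return(vapply(seq_along(first),
                  function(i) min(values[first[i]:last[i]]), 0))
  }
  cs <- c(0, cumsum(values))
  sums <- cs[last + 1L] - cs[first]
  if (stat == "sum") sums else sums / (last - first + 1L)
}

#' Assign permutation FDRs to candidate peaks
#'
#' For each of S seeded genome-wide uniform shuffles of the fragment values,
#' candidate peaks are re-called and their statistics pooled as the null.
#' For an observed statistic s, the raw FDR is the mean null count of peaks
#' with statistic >= s divided by the observed count with statistic >= s,
#' clipped to \[0, 1\] and made monotone non-increasing in the statistic
#' (each peak takes the minimum raw FDR over thresholds at or below its
#' statistic). Peaks with FDR below `fdr_threshold` (default 1e-4, the
#' published 0.01% cutoff) are flagged significant.
#'
#' @param profile a [fragment_profile()] with unit `log2_ratio`.
#' @param theta,stat,min_fragments as in [candidate_peaks()].
#' @param shuffles number of null shuffles S (default 1000, minimum 100).
#' @param seed RNG seed.
#' @param fdr_threshold significance cutoff (strict <).
#' @return the candidate peak table with `fdr` and `significant` columns.
#' @export
peak_fdr <- function(profile, theta = 0, stat = c("sum", "mean", "min"),
                     min_fragments = 2L, shuffles = 1000L, seed = 1L,
                     fdr_threshold = 1e-4) {
  stat <- match.arg(stat)
  if (shuffles < 100L) stopf("shuffles must be >= 100")
  peaks <- candidate_peaks(profile, theta, stat, min_fragments)
  if (nrow(peaks) == 0L) {
    peaks$fdr <- numeric(0); peaks$significant <- logical(0)
    return(peaks)
  }
  v <- profile$values
  n <- length(v)
  chrom <- profile$map$fragments$chrom
  set.seed(seed)
  null_stats <- vector("list", shuffles)
  for (s in seq_len(shuffles)) {
    vs <- v[sample.int(n)]
    runs <- true_runs(vs > theta, chrom)
    keep <- runs$last - runs$first + 1L >= min_fragments
    if (any(keep)) {
      null_stats[[s]] <- run_stats(vs, runs$first[keep], runs$last[keep], stat)
    }
  }
  sorted_null <- sort(unlist(null_stats, use.names = FALSE))
  sorted_obs <- sort(peaks$stat)
  raw <- pmin(count_ge(peaks$stat, sorted_null) / shuffles /
                count_ge(peaks$stat, sorted_obs), 1)
  peaks$fdr <- regularize_fdr(peaks$stat, raw)
  peaks$significant <- peaks$fdr < fdr_threshold
  peaks
}

#' Consensus peaks supported by every replicate
#'
#' Significant peaks from all replicates are merged by >= 1 bp overlap
#' (chained overlaps form one component); a component qualifies as a
#' consensus peak only if it contains at least one peak from every
#' replicate. The consensus interval is the union span of the component.
#'
#' @param peaksets list (one element per replicate) of significant peak
#'   tables (rows with `significant == TRUE` are used if the column exists).
#' @return data.frame `chrom`, `start`, `end`, `peak_id`, `n_replicates`,
#'   `support` (comma-separated per-replicate peak counts).
#' @export
replicate_consensus <- function(peaksets) {
  if (length(peaksets) == 0L) stopf("zero replicates")
  sig <- lapply(peaksets, function(p) {
    if ("significant" %in% names(p)) p[p$significant, , drop = FALSE] else p
  })
  n_rep <- length(sig)
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      peak_id = character(0), n_replicates = integer(0),
                      support = character(0))
  if (any(vapply(sig, nrow, 0L) == 0L)) return(empty)
  all_df <- do.call(rbind, lapply(seq_len(n_rep), function(i) {
    data.frame(chrom = sig[[i]]$chrom, start = sig[[i]]$start,
               end = sig[[i]]$end, rep = i, stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(all_df$chrom,
                               IRanges::IRanges(all_df$start + 1L, all_df$end))
  comp <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(comp, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  reps_per_comp <- lapply(split(all_df$rep[si], qi), unique)
  full <- as.integer(names(reps_per_comp))[
    vapply(reps_per_comp, length, 0L) == n_rep]
  if (length(full) == 0L) return(empty)
  comp <- comp[full]
  counts <- vapply(full, function(ci) {
    paste(tabulate(all_df$rep[si[qi == ci]], n_rep), collapse = ",")
  }, "")
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(comp)),
                    start = BiocGenerics::start(comp) - 1L,
                    end = BiocGenerics::end(comp),
                    n_replicates = n_rep, support = counts,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  out$peak_id <- sprintf("peak_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "peak_id", "n_replicates", "support")]
}

#' Assign genes to consensus peaks
#'
#' Genes overlapping a peak are assigned with distance 0. On each side of
#' the peak, the nearest non-overlapping gene whose proximal edge is within
#' `window` bp (default 5000, inclusive) is additionally assigned, provided
#' no other gene's span lies between the peak edge and that gene.
#' Distances are edge-to-edge; "upstream"/"downstream" refer to genomic
#' orientation relative to the peak (gene left / right of the peak),
#' irrespective of strand.
#'
#' @param peaks consensus peak table from [replicate_consensus()] (needs
#'   `chrom`, `start`, `end`, `peak_id`).
#' @param annotation an [annotation_set()].
#' @param window maximum edge-to-edge gap in bp (inclusive).
#' @return data.frame `peak_id`, `gene_id`, `relation`
#'   (`overlapping`/`upstream`/`downstream`), `distance`.
#' @export
assign_genes <- function(peaks, annotation, window = 5000) {
  genes <- annotation$genes
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    g <- genes[genes$chrom == p$chrom, , drop = FALSE]
    if (nrow(g) == 0L) next
    ov <- g$start < p$end & g$end > p$start
    if (any(ov)) {
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = p$peak_id, gene_id = g$gene_id[ov],
        relation = "overlapping", distance = 0, stringsAsFactors = FALSE)
    }
    for (side in c("upstream", "downstream")) {
      if (side == "upstream") {
        cand <- g[g$end <= p$start, , drop = FALSE]
        gap <- p$start - cand$end
      } else {
        cand <- g[g$start >= p$end, , drop = FALSE]
        gap <- cand$start - p$end
      }
      keep <- gap <= window
      cand <- cand[keep, , drop = FALSE]; gap <- gap[keep]
      if (nrow(cand) == 0L) next
      nearest <- which(gap == min(gap))
      for (j in nearest) {
        lo <- if (side == "upstream") cand$end[j] else p$end
        hi <- if (side == "upstream") p$start else cand$start[j]
        intervener <- g$gene_id != cand$gene_id[j] & g$start >= lo & g$end <= hi
        if (!any(intervener)) {
          rows[[length(rows) + 1L]] <- data.frame(
            peak_id = p$peak_id, gene_id = cand$gene_id[j],
            relation = side, distance = gap[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      relation = character(0), distance = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a peak table as BED6+
#' @param peaks peak table with `chrom`, `start`, `end`, `stat` and
#'   optionally `fdr`.
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  name <- if ("peak_id" %in% names(peaks)) peaks$peak_id else
    sprintf("peak_%04d", seq_len(nrow(peaks)))
  score <- if ("stat" %in% names(peaks)) formatC(peaks$stat, format = "g", digits = 6) else "."
  extra <- if ("fdr" %in% names(peaks)) formatC(peaks$fdr, format = "g", digits = 6) else NULL
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, name, score, ".")
  if (!is.null(extra)) df$fdr <- extra
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
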