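## Independent brute-force oracles. These deliberately avoid the package's
## code paths (no IRanges, no sparse matrices, no vectorised run finding).

## fragment boundaries by naive substring scan; cut at motif start + 2
oracle_fragments <- function(seq_string) {
  s <- toupper(seq_string)
  n <- nchar(s)
  cuts <- integer(0)
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      if (substr(s, i, i + 3) == "GATC") cuts <- c(cuts, (i - 1) + 2)
    }
  }
  bounds <- c(0, cuts, n)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

## linear-scan interval overlap
oracle_overlapping <- function(frag_df, chrom, start, end) {
  hits <- integer(0)
  for (i in seq_len(nrow(frag_df))) {
    f <- frag_df[i, ]
    if (f$chrom == chrom && f$start < end && f$end > start) hits <- c(hits, i)
  }
  hits
}

## naive transcript score over explicit fragment loop
oracle_tx_score <- function(values, frag_df, chrom, start, end, weighted) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(frag_df))) {
    f <- frag_df[i, ]
    if (f$chrom != chrom) next
    ov <- min(f$end, end) - max(f$start, start)
    if (ov <= 0) next
    w <- if (weighted) ov else 1
    num <- num + w * values[i]; den <- den + w
  }
  num / den
}

## explicit-enumeration permutation FDR: materialises every shuffle,
## counts tails with loops, regularises by direct min over weaker thresholds
oracle_perm_fdr <- function(values, frag_df, tx_df, P, seed, weighted) {
  score_all <- function(v) {
    vapply(seq_len(nrow(tx_df)), function(t)
      oracle_tx_score(v, frag_df, tx_df$chrom[t], tx_df$start[t],
                      tx_df$end[t], weighted), 0)
  }
  obs <- score_all(values)
  set.seed(seed)
  null_scores <- matrix(0, nrow = length(obs), ncol = P)
  for (p in seq_len(P)) {
    null_scores[, p] <- score_all(values[sample.int(length(values))])
  }
  raw <- vapply(obs, function(s) {
    per_perm <- vapply(seq_len(P), function(p) sum(null_scores[, p] >= s), 0)
    mean(per_perm) / sum(obs >= s)
  }, 0)
  raw <- pmin(pmax(raw, 0), 1)
  vapply(seq_along(obs), function(i) min(raw[obs <= obs[i]]), 0)
}

## exhaustive run enumeration for candidate peaks
oracle_peaks <- function(values, chroms, theta, stat = "sum", min_frag = 2) {
  n <- length(values)
  out <- list()
  i <- 1
  while (i <= n) {
    if (values[i] > theta) {
      j <- i
      while (j < n && values[j + 1] > theta && chroms[j + 1] == chroms[i]) j <- j + 1
      if (j - i + 1 >= min_frag) {
        vals <- values[i:j]
        st <- switch(stat, sum = sum(vals), mean = mean(vals), min = min(vals))
        out[[length(out) + 1]] <- data.frame(first = i, last = j, stat = st)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (length(out) == 0) {
    return(data.frame(first = integer(0), last = integer(0), stat = numeric(0)))
  }
  do.call(rbind, out)
}

## literal betweenness predicate for gene assignment
oracle_assign <- function(peak, genes, window = 5000) {
  res <- list()
  g <- genes[genes$chrom == peak$chrom, , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    if (g$start[i] < peak$end && g$end[i] > peak$start) {
      res[[length(res) + 1]] <- data.frame(gene_id = g$gene_id[i],
                                           relation = "overlapping",
                                           distance = 0)
    }
  }
  for (side in c("upstream", "downstream")) {
    if (side == "upstream") {
      cand_idx <- which(g$end <= peak$start)
      gaps <- peak$start - g$end[cand_idx]
    } else {
      cand_idx <- which(g$start >= peak$end)
      gaps <- g$start[cand_idx] - peak$end
    }
    keep <- which(gaps <= window)
    cand_idx <- cand_idx[keep]; gaps <- gaps[keep]
    if (length(cand_idx) == 0) next
    for (j in cand_idx[gaps == min(gaps)]) {
      lo <- if (side == "upstream") g$end[j] else peak$end
      hi <- if (side == "upstream") peak$start else g$start[j]
      blocked <- FALSE
      for (k in seq_len(nrow(g))) {
        if (k == j) next
        if (g$start[k] >= lo && g$end[k] <= hi) { blocked <- TRUE; break }
      }
      if (!blocked) {
        res[[length(res) + 1]] <- data.frame(gene_id = g$gene_id[j],
                                             relation = side,
                                             distance = min(gaps))
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(gene_id = character(0), relation = character(0),
                      distance = numeric(0)))
  }
  do.call(rbind, res)
}

## dense-reconstruction oracle for expressing-cell extraction
oracle_extract <- function(dense, gene_row, min_count = 3) {
  keep <- which(dense[gene_row, ] >= min_count)
  data.frame(cell_index = keep, count = dense[gene_row, keep])
}
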