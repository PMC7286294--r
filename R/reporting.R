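#' Cross-sample correlation matrix
#'
#' Pairwise correlation of sample columns over the rows (genes or loci)
#' complete in both columns. The diagonal is exactly 1 and the matrix
#' exactly symmetric. A column with zero variance yields `NA` (undefined)
#' against every other column rather than a number.
#'
#' @param mat numeric matrix, rows = genes/loci, columns = samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with the input column names.
#' @export
correlation_matrix <- function(mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stopf("need >= 2 columns")
  if (nrow(mat) < 3L) stopf("need >= 3 rows")
  if (is.null(colnames(mat)) || any(!nzchar(colnames(mat)))) {
    stopf("all columns must be labelled")
  }
  n <- ncol(mat)
  out <- matrix(NA_real_, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) { out[i, j] <- 1; next }
      ok <- stats::complete.cases(mat[, c(i, j)])
      x <- mat[ok, i]; y <- mat[ok, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        out[i, j] <- out[j, i] <- NA_real_
      } else {
        out[i, j] <- out[j, i] <- cor(x, y, method = method)
      }
    }
  }
  out
}

#' Gene-class composition of gene sets
#'
#' Counts and fractions per class (e.g. TF / lncRNA / other) for each gene
#' set. Fractions sum to 1 for non-empty sets and are `NA` for empty ones.
#'
#' @param sets named list of gene-id vectors.
#' @param class_map named character vector gene_id -> class; genes absent
#'   from the map count as `"other"`.
#' @return data.frame `set`, `class`, `n`, `fraction`.
#' @export
class_composition <- function(sets, class_map) {
  classes <- sort(unique(c(unname(class_map), "other")))
  rows <- lapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    cls <- unname(class_map[genes])
    cls[is.na(cls)] <- "other"
    n <- vapply(classes, function(cl) sum(cls == cl), 0L)
    data.frame(set = nm, class = classes, n = n,
               fraction = if (length(genes) == 0L) NA_real_ else
                 n / length(genes),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Matrix of gene scores across samples
#'
#' Builds the gene x sample score matrix used for correlation reporting
#' from a named list of gene call tables.
#'
#' @param call_tables named list of gene call tables (see
#'   [call_polii_genes()]).
#' @return numeric matrix, rows = genes present in every table.
#' @export
signal_matrix <- function(call_tables) {
  common <- Reduce(intersect, lapply(call_tables, function(t) t$gene_id))
  m <- vapply(call_tables, function(t) t$score[match(common, t$gene_id)],
              numeric(length(common)))
  rownames(m) <- common
  m
}
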