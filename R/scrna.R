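#' Read a sparse expression matrix with its gene index
#'
#' Reads a MatrixMarket coordinate file (genes x cells, 1-based indices)
#' plus a gene-index table mapping gene ids to row numbers.
#'
#' @param mtx path to the MatrixMarket file (or a `dgCMatrix`/`dgTMatrix`).
#' @param gene_index path to a TSV `gene_id<TAB>gene_index`, or a
#'   data.frame with those columns; row order is used when indices are
#'   omitted.
#' @return object of class `expression_triples`: `mat` (sparse
#'   genes x cells), `gene_index` data.frame.
#' @export
read_expression_triples <- function(mtx, gene_index) {
  mat <- if (is.character(mtx)) Matrix::readMM(mtx) else mtx
  mat <- methods::as(mat, "CsparseMatrix")
  if (any(mat@x < 0)) stopf("negative count in expression matrix")
  if (is.character(gene_index)) {
    gi <- read.delim(gene_index, header = FALSE, stringsAsFactors = FALSE)
    gene_index <- data.frame(gene_id = as.character(gi[[1L]]),
                             gene_index = if (ncol(gi) >= 2L)
                               as.integer(gi[[2L]]) else seq_len(nrow(gi)),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "gene_index") %in% names(gene_index)))
  if (anyDuplicated(gene_index$gene_id)) stopf("duplicated gene_id in index")
  if (any(gene_index$gene_index < 1L | gene_index$gene_index > nrow(mat))) {
    stopf("gene index out of matrix bounds")
  }
  structure(list(mat = mat, gene_index = gene_index),
            class = "expression_triples")
}

#' @export
print.expression_triples <- function(x, ...) {
  cat(sprintf("expression_triples: %d genes x %d cells, %d non-zero entries\n",
              nrow(x$mat), ncol(x$mat), length(x$mat@x)))
  invisible(x)
}

#' Read a cell-annotation table
#'
#' @param path TSV `cell_index<TAB>cell_type` (header optional).
#' @return named character vector indexed by cell index.
#' @export
read_cell_annotation <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(tab[[1L]]) && suppressWarnings(is.na(as.integer(tab[[1L]][1L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  setNames(as.character(tab[[2L]]), as.integer(tab[[1L]]))
}

cell_type_of <- function(cell_annotation, cell_index) {
  ty <- cell_annotation[as.character(cell_index)]
  ty[is.na(ty)] <- "unassigned"
  unname(ty)
}

#' Cells expressing a gene
#'
#' Extracts all cells with a transcript count of at least `min_count`
#' (default 3; cells with fewer counts for the gene are excluded) for one
#' gene, in ascending cell index.
#'
#' @param triples an [read_expression_triples()] object.
#' @param gene_id gene to extract.
#' @param min_count minimum count, inclusive (default 3).
#' @return data.frame `cell_index`, `count`.
#' @export
extract_gene_cells <- function(triples, gene_id, min_count = 3L) {
  stopifnot(is(triples, "expression_triples"))
  row <- triples$gene_index$gene_index[triples$gene_index$gene_id == gene_id]
  if (length(row) != 1L) stopf("unknown gene_id: %s", gene_id)
  counts <- triples$mat[row, ]
  keep <- which(counts >= min_count)
  data.frame(cell_index = as.integer(keep), count = as.numeric(counts[keep]),
             row.names = NULL)
}

#' Per-cell-type mean counts, ratio-normalised to a reference type
#'
#' For one gene: mean transcript count over each type's *expressing* cells
#' (count >= `min_count`), divided by the reference type's mean (so the
#' reference type is 1 by construction).
#'
#' @param triples an [read_expression_triples()] object.
#' @param gene_id gene of interest.
#' @param cell_annotation named vector from [read_cell_annotation()].
#' @param reference reference cell type (default `"cholinergic"`).
#' @param min_count expressing-cell threshold (default 3).
#' @return data.frame `cell_type`, `n_cells`, `mean_count`,
#'   `normalized_mean`.
#' @export
type_normalized_means <- function(triples, gene_id, cell_annotation,
                                  reference = "cholinergic", min_count = 3L) {
  cells <- extract_gene_cells(triples, gene_id, min_count)
  cells$cell_type <- cell_type_of(cell_annotation, cells$cell_index)
  if (!any(cells$cell_type == reference)) {
    stopf("gene %s: no expressing cells in reference type '%s'",
          gene_id, reference)
  }
  agg <- stats::aggregate(count ~ cell_type, data = cells, FUN = mean)
  n <- stats::aggregate(count ~ cell_type, data = cells, FUN = length)
  ref_mean <- agg$count[agg$cell_type == reference]
  data.frame(cell_type = agg$cell_type, n_cells = n$count,
             mean_count = agg$count,
             normalized_mean = agg$count / ref_mean,
             stringsAsFactors = FALSE)
}

#' Pairwise overlap of expressing-cell sets
#'
#' Restricted to cells of one type (default cholinergic), entry (i, j)
#' counts the cells expressing both gene i and gene j; the diagonal holds
#' the per-gene expressing-set sizes. A parallel Jaccard matrix
#' (intersection / union) is also returned.
#'
#' @param triples an [read_expression_triples()] object.
#' @param gene_ids two or more genes.
#' @param cell_annotation named vector from [read_cell_annotation()].
#' @param restrict_to_type cell type to restrict to; `NULL` for all cells.
#' @param min_count expressing-cell threshold (default 3).
#' @return object of class `overlap_matrix`: `counts` and `jaccard`
#'   symmetric matrices with gene ids as dimnames.
#' @export
overlap_matrix <- function(triples, gene_ids, cell_annotation,
                           restrict_to_type = "cholinergic", min_count = 3L) {
  if (length(gene_ids) < 2L) stopf("need >= 2 genes")
  sets <- lapply(gene_ids, function(g) {
    cells <- extract_gene_cells(triples, g, min_count)$cell_index
    if (!is.null(restrict_to_type)) {
      cells <- cells[cell_type_of(cell_annotation, cells) == restrict_to_type]
    }
    cells
  })
  names(sets) <- gene_ids
  m <- length(gene_ids)
  counts <- matrix(0L, m, m, dimnames = list(gene_ids, gene_ids))
  jac <- matrix(0, m, m, dimnames = list(gene_ids, gene_ids))
  for (i in seq_len(m)) {
    for (j in i:m) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      counts[i, j] <- counts[j, i] <- inter
      jac[i, j] <- jac[j, i] <- if (uni == 0L) 0 else inter / uni
    }
  }
  structure(list(counts = counts, jaccard = jac, sets = sets),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("overlap_matrix: %d genes; set sizes %s\n",
              nrow(x$counts), paste(diag(x$counts), collapse = ", ")))
  invisible(x)
}
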