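#' Replicate-wise subtraction of log2-ratio profiles
#'
#' Cell types are compared by subtracting their log2 ratio tracks replicate
#' by replicate (replicate i of the numerator minus replicate i of the
#' denominator), producing one comparison profile per replicate pair.
#'
#' @param a_reps,b_reps equal-length lists of [fragment_profile()]s with
#'   unit `log2_ratio` on the same map.
#' @return list of difference profiles (unit `log2_ratio`).
#' @export
subtract_profiles <- function(a_reps, b_reps) {
  if (length(a_reps) == 0L) stopf("empty replicate list")
  if (length(a_reps) != length(b_reps)) {
    stopf("replicate count mismatch: %d vs %d", length(a_reps), length(b_reps))
  }
  mapply(function(a, b) {
    stopifnot(is(a, "fragment_profile"), is(b, "fragment_profile"))
    if (a$unit != "log2_ratio" || b$unit != "log2_ratio") {
      stopf("subtract_profiles expects log2_ratio profiles")
    }
    if (!same_map(a$map, b$map)) stopf("profiles built on different maps")
    out <- a
    out$values <- a$values - b$values
    out$meta$sample_id <- paste0(a$meta$sample_id, "_minus_", b$meta$sample_id)
    out
  }, a_reps, b_reps, SIMPLIFY = FALSE)
}

#' Genes with significantly different Pol II occupancy between two datasets
#'
#' The replicate difference profiles are averaged fragment-wise into one
#' mean-difference profile, which is then analysed exactly like a primary
#' Pol II profile (transcript scores, permutation FDR, per-gene reduction).
#' Because DamID log2 ratios can be negative, a gene that passes the
#' significance thresholds is only reported as enriched if it is also bound
#' by Pol II in the numerator dataset.
#'
#' @param diff_reps list of difference profiles from [subtract_profiles()].
#' @param annotation an [annotation_set()].
#' @param numerator_calls gene call table computed from the numerator
#'   dataset (see [call_polii_genes()]).
#' @param params a [call_params()].
#' @return data.frame `gene_id`, `transcript_id`, `score`, `fdr`,
#'   `significant` (passes fdr/score thresholds), `enriched` (significant
#'   and numerator-bound).
#' @export
differential_genes <- function(diff_reps, annotation, numerator_calls,
                               params = call_params()) {
  if (length(diff_reps) == 0L) stopf("empty replicate list")
  mean_diff <- average_profiles(diff_reps)
  calls <- call_genes(permutation_fdr(mean_diff, annotation, params), params)
  names(calls)[names(calls) == "bound"] <- "significant"
  bound_in_num <- numerator_calls$gene_id[numerator_calls$bound]
  calls$enriched <- calls$significant & calls$gene_id %in% bound_in_num
  calls
}

#' Uniquely enriched and depleted genes per cell type
#'
#' A gene is uniquely enriched in type X at a stage when it is enriched in
#' both ordered comparisons X vs Y and X vs Z. It is uniquely depleted in X
#' when it is enriched in both Y vs X and Z vs X *and* bound by Pol II in
#' both Y and Z (a factor present in both other types but absent from X).
#'
#' @param pairwise named list of [differential_genes()] tables for all six
#'   ordered comparisons among the three types, named `"X_vs_Y"`.
#' @param bound_tables named list (by type) of gene call tables.
#' @param types character vector of the three cell-type labels.
#' @return object of class `unique_sets`: per type, `enriched` and
#'   `depleted` gene-id vectors.
#' @export
unique_sets <- function(pairwise, bound_tables, types) {
  stopifnot(length(types) == 3L)
  need <- as.vector(outer(types, types, function(a, b) paste0(a, "_vs_", b)))
  need <- need[rep(types, times = 3) != rep(types, each = 3)]
  missing <- setdiff(need, names(pairwise))
  if (length(missing) > 0) stopf("missing comparison: %s", missing[1L])

  enriched_in <- function(cmp) {
    tab <- pairwise[[cmp]]
    tab$gene_id[tab$enriched]
  }
  bound_in <- function(type) {
    tab <- bound_tables[[type]]
    tab$gene_id[tab$bound]
  }
  out <- lapply(types, function(x) {
    others <- setdiff(types, x)
    y <- others[1L]; z <- others[2L]
    enr <- intersect(enriched_in(paste0(x, "_vs_", y)),
                     enriched_in(paste0(x, "_vs_", z)))
    dep <- intersect(enriched_in(paste0(y, "_vs_", x)),
                     enriched_in(paste0(z, "_vs_", x)))
    dep <- intersect(dep, intersect(bound_in(y), bound_in(z)))
    list(enriched = sort(enr), depleted = sort(dep))
  })
  names(out) <- types
  structure(out, class = "unique_sets")
}

#' @export
print.unique_sets <- function(x, ...) {
  for (ty in names(x)) {
    cat(sprintf("%s: %d uniquely enriched, %d uniquely depleted\n",
                ty, length(x[[ty]]$enriched), length(x[[ty]]$depleted)))
  }
  invisible(x)
}

#' Read a gene-class list
#'
#' Plain-text two-column file `gene_id<TAB>class` (e.g. a FlyTF-style list of
#' transcription factors, or ncRNA class annotations).
#'
#' @param path input file.
#' @return named character vector gene_id -> class.
#' @export
read_gene_classes <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Filter genes by class
#'
#' Genes missing from the class map are class `"other"`. Input order is
#' preserved.
#'
#' @param genes character vector of gene ids.
#' @param class_map named character vector gene_id -> class.
#' @param class class to keep (e.g. `"TF"`, `"lncRNA"`, `"miRNA"`).
#' @return the matching subset of `genes`.
#' @export
filter_gene_class <- function(genes, class_map, class = "TF") {
  cls <- unname(class_map[genes])
  cls[is.na(cls)] <- "other"
  genes[cls == class]
}

#' Stage-transition table for uniquely enriched/depleted genes
#'
#' Tracks every gene that is uniquely enriched or depleted at any stage
#' through all stages, with state `"none"` where absent, and aggregates
#' state-to-state transition counts between consecutive stages.
#'
#' @param stage_sets named list (ordered stages) of [unique_sets()].
#' @param genes optional restriction to a gene subset (e.g. TFs only).
#' @return object of class `transition_table`: `states` (gene x stage
#'   data.frame) and `transitions` (long data.frame `stage_from`,
#'   `stage_to`, `state_from`, `state_to`, `n`).
#' @export
transition_table <- function(stage_sets, genes = NULL) {
  if (length(stage_sets) < 2L) stopf("need >= 2 stages for transitions")
  stages <- names(stage_sets)
  all_genes <- unique(unlist(lapply(stage_sets, function(us) {
    unlist(lapply(us, function(s) c(s$enriched, s$depleted)), use.names = FALSE)
  }), use.names = FALSE))
  if (!is.null(genes)) all_genes <- intersect(all_genes, genes)
  all_genes <- sort(all_genes)

  state_at <- function(us, g) {
    for (ty in names(us)) {
      if (g %in% us[[ty]]$enriched) return(paste0("enriched:", ty))
      if (g %in% us[[ty]]$depleted) return(paste0("depleted:", ty))
    }
    "none"
  }
  states <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  for (st in stages) {
    states[[st]] <- vapply(all_genes, state_at, "", us = stage_sets[[st]])
  }

  trans <- list()
  for (i in seq_len(length(stages) - 1L)) {
    from <- stages[i]; to <- stages[i + 1L]
    tab <- table(from_state = states[[from]], to_state = states[[to]])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    trans[[i]] <- data.frame(stage_from = from, stage_to = to,
                             state_from = df$from_state, state_to = df$to_state,
                             n = df$Freq, stringsAsFactors = FALSE)
  }
  transitions <- do.call(rbind, trans)
  rownames(transitions) <- NULL
  structure(list(states = states, transitions = transitions),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("transition_table: %d genes tracked over %d stages\n",
              nrow(x$states), ncol(x$states) - 1L))
  invisible(x)
}
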