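#' Sample metadata for one DamID channel
#'
#' @param sample_id unique sample label.
#' @param cell_type cell-type label (e.g. cholinergic, GABAergic, glutamatergic).
#' @param stage developmental stage label (e.g. embryo, larva, adult).
#' @param replicate positive integer replicate number.
#' @param channel `"dam_only"` (untethered Dam control) or `"dam_fusion"`.
#' @param fusion_name fused protein for the fusion channel (e.g. `"PolII"`,
#'   `"acj6"`); must be empty for `dam_only`.
#' @return object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, cell_type = "", stage = "", replicate = 1L,
                        channel = c("dam_fusion", "dam_only"), fusion_name = "") {
  channel <- match.arg(channel)
  replicate <- as.integer(replicate)
  stopifnot(length(sample_id) == 1L, replicate >= 1L)
  if (channel == "dam_only" && nzchar(fusion_name)) {
    stopf("dam_only channel must have an empty fusion_name")
  }
  structure(list(sample_id = sample_id, cell_type = cell_type, stage = stage,
                 replicate = replicate, channel = channel,
                 fusion_name = fusion_name),
            class = "sample_meta")
}

#' Per-fragment signal profile
#'
#' One sample's value per GATC fragment of a given map, in one of three
#' units: raw `count`, `rpm` (counts scaled to sum to 1e6), or `log2_ratio`
#' (Dam-fusion over Dam-only).
#'
#' @param values numeric vector, one value per fragment of `map`.
#' @param map the [gatc_fragment_map()] the values are resolved on.
#' @param meta a [sample_meta()].
#' @param unit `"count"`, `"rpm"`, or `"log2_ratio"`.
#' @return object of class `fragment_profile`.
#' @export
fragment_profile <- function(values, map, meta,
                             unit = c("count", "rpm", "log2_ratio")) {
  unit <- match.arg(unit)
  stopifnot(is(map, "gatc_map"), is(meta, "sample_meta"))
  if (length(values) != n_fragments(map)) {
    stopf("profile has %d values but map has %d fragments",
          length(values), n_fragments(map))
  }
  if (unit %in% c("count", "rpm") && any(values < 0)) {
    stopf("%s values must be non-negative", unit)
  }
  structure(list(values = as.numeric(values), map = map, meta = meta,
                 unit = unit),
            class = "fragment_profile")
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("fragment_profile [%s] %s: %d fragments, total %.4g\n",
              x$unit, x$meta$sample_id, length(x$values), sum(x$values)))
  invisible(x)
}

#' Load per-fragment counts from a bedGraph or fragment TSV
#'
#' bedGraph intervals (0-based half-open, non-overlapping) are re-binned onto
#' the fragment map by proportional allocation: each interval's value is
#' split across the fragments it overlaps in proportion to overlap length,
#' which conserves total mass exactly. A fragment TSV
#' (`fragment_index<TAB>value`) loads verbatim. Fragments absent from the
#' input get 0.
#'
#' @param path input file.
#' @param map a [gatc_fragment_map()].
#' @param meta a [sample_meta()].
#' @param format `"auto"` (by extension), `"bedgraph"`, or `"tsv"`.
#' @return a [fragment_profile()] with unit `count`.
#' @export
load_fragment_signal <- function(path, map, meta, format = c("auto", "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg|bedGraph)$", path)) "bedgraph" else "tsv"
  }
  if (format == "bedgraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    bg <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     value = gr$score, stringsAsFactors = FALSE)
    values <- bin_bedgraph(bg, map)
  } else {
    tab <- read.delim(path, header = FALSE, comment.char = "#")
    if (ncol(tab) < 2L) stopf("fragment TSV needs >= 2 columns (index, value)")
    ## tolerate a header row
    if (!is.numeric(tab[[1L]])) {
      tab <- tab[-1L, , drop = FALSE]
      tab[[1L]] <- as.numeric(tab[[1L]]); tab[[2L]] <- as.numeric(tab[[2L]])
    }
    idx <- as.integer(tab[[1L]]); val <- as.numeric(tab[[2L]])
    if (any(idx < 1L | idx > n_fragments(map))) stopf("fragment index out of range")
    if (anyDuplicated(idx)) stopf("duplicated fragment index in TSV")
    if (any(val < 0)) stopf("negative value in fragment TSV")
    values <- numeric(n_fragments(map))
    values[idx] <- val
  }
  fragment_profile(values, map, meta, unit = "count")
}

## proportional-allocation re-binning of bedGraph rows onto fragments
bin_bedgraph <- function(bg, map) {
  unknown <- setdiff(unique(bg$chrom), names(map$seqlengths))
  if (length(unknown) > 0) stopf("bedGraph interval on unknown chromosome: %s",
                                 unknown[1L])
  if (any(bg$value < 0)) stopf("negative bedGraph value")
  if (any(bg$end <= bg$start)) stopf("empty bedGraph interval")
  gr <- GenomicRanges::GRanges(bg$chrom, IRanges::IRanges(bg$start + 1L, bg$end))
  ## overlap check within the input
  self <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  if (any(S4Vectors::queryHits(self) != S4Vectors::subjectHits(self))) {
    stopf("overlapping bedGraph intervals")
  }
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(map$granges)
  hits <- GenomicRanges::findOverlaps(gr, map$granges)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr)[qi], IRanges::ranges(map$granges)[si]))
  alloc <- bg$value[qi] * ov / (bg$end[qi] - bg$start[qi])
  values <- numeric(n_fragments(map))
  acc <- rowsum(alloc, si)
  values[as.integer(rownames(acc))] <- acc[, 1L]
  values
}

#' Normalise a count profile to reads per million (RPM)
#'
#' @param profile a [fragment_profile()] with unit `count`.
#' @return the profile rescaled so values sum to 1e6.
#' @export
rpm_normalize <- function(profile) {
  stopifnot(is(profile, "fragment_profile"))
  if (profile$unit != "count") stopf("rpm_normalize expects unit 'count'")
  total <- sum(profile$values)
  if (total == 0) stopf("all-zero profile: no library size to normalise by")
  out <- profile
  out$values <- profile$values * 1e6 / total
  out$unit <- "rpm"
  out
}

#' Log2 ratio of Dam-fusion over Dam-only
#'
#' The central DamID quantity: `log2((fusion + psi) / (dam + psi))` per
#' fragment, with a symmetric additive pseudocount `psi` (RPM units,
#' default 1) that keeps zero-count fragments finite without breaking the
#' antisymmetry `log2_ratio(A, B) = -log2_ratio(B, A)`.
#'
#' @param fusion,dam [fragment_profile()]s with unit `rpm` on the same map.
#' @param pseudocount positive pseudocount in RPM.
#' @return a [fragment_profile()] with unit `log2_ratio`; metadata from
#'   `fusion`.
#' @export
log2_ratio <- function(fusion, dam, pseudocount = 1) {
  stopifnot(is(fusion, "fragment_profile"), is(dam, "fragment_profile"))
  if (fusion$unit != "rpm" || dam$unit != "rpm") {
    stopf("log2_ratio expects rpm profiles")
  }
  if (!same_map(fusion$map, dam$map)) stopf("profiles built on different maps")
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  out <- fusion
  ## difference of logs rather than log of quotient: makes the antisymmetry
  ## log2_ratio(A, B) == -log2_ratio(B, A) exact in floating point
  out$values <- log2(fusion$values + pseudocount) - log2(dam$values + pseudocount)
  out$unit <- "log2_ratio"
  out
}

#' Subtract the genome-wide median from a log2-ratio profile
#'
#' Optional between-channel centering; disabled by default in the pipeline.
#'
#' @param profile a [fragment_profile()] with unit `log2_ratio`.
#' @return the centred profile.
#' @export
median_center <- function(profile) {
  stopifnot(is(profile, "fragment_profile"))
  if (profile$unit != "log2_ratio") stopf("median_center expects log2_ratio")
  out <- profile
  out$values <- profile$values - median(profile$values)
  out
}

#' Average replicate profiles fragment-wise
#'
#' @param profiles list of [fragment_profile()]s with identical unit and map.
#' @return one profile of the same unit; metadata from the first replicate.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  u <- unique(vapply(profiles, function(p) p$unit, ""))
  if (length(u) != 1L) stopf("profiles have mixed units")
  for (p in profiles[-1L]) {
    if (!same_map(p$map, profiles[[1L]]$map)) stopf("profiles on different maps")
  }
  out <- profiles[[1L]]
  out$values <- rowMeans(vapply(profiles, function(p) p$values,
                                numeric(length(out$values))))
  out
}

#' Write a fragment profile as bedGraph
#'
#' @param profile a [fragment_profile()].
#' @param path output file.
#' @export
write_profile_bedgraph <- function(profile, path) {
  df <- profile$map$fragments
  out <- data.frame(df$chrom, df$start, df$end,
                    formatC(profile$values, format = "g", digits = 8))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
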