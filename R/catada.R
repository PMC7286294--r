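#' Chromatin accessibility profile from Dam-only samples (CATaDa)
#'
#' Open chromatin is preferentially methylated by untethered Dam, so the
#' Dam-only control doubles as an accessibility readout. Replicate count
#' profiles are RPM-normalised and averaged fragment-wise.
#'
#' @param dam_reps list of [fragment_profile()]s with unit `count`.
#' @return a [fragment_profile()] with unit `rpm` (sums to 1e6).
#' @export
accessibility_profile <- function(dam_reps) {
  if (length(dam_reps) == 0L) stopf("empty replicate list")
  average_profiles(lapply(dam_reps, rpm_normalize))
}

#' Mean accessibility over extended gene loci
#'
#' Each gene locus is extended 5 kb upstream and 2 kb downstream
#' (strand-oriented by default), clipped to the chromosome, and the
#' length-weighted mean RPM over overlapping fragments is reported.
#'
#' @param profile a [fragment_profile()] with unit `rpm`.
#' @param annotation an [annotation_set()].
#' @param up,down extension in bp upstream / downstream of the gene.
#' @param stranded orient the extension by gene strand (default TRUE);
#'   FALSE extends `up` leftward and `down` rightward for every gene.
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (extended,
#'   0-based half-open), `mean_rpm`.
#' @export
locus_accessibility <- function(profile, annotation, up = 5000, down = 2000,
                                stranded = TRUE) {
  stopifnot(is(profile, "fragment_profile"))
  if (profile$unit != "rpm") stopf("locus_accessibility expects rpm")
  g <- annotation$genes
  minus <- stranded & g$strand == "-"
  ext_start <- ifelse(minus, g$start - down, g$start - up)
  ext_end <- ifelse(minus, g$end + up, g$end + down)
  clen <- profile$map$seqlengths[g$chrom]
  ext_start <- pmax(ext_start, 0)
  ext_end <- pmin(ext_end, clen)

  mean_rpm <- vapply(seq_len(nrow(g)), function(i) {
    idx <- fragments_overlapping(profile$map, g$chrom[i], ext_start[i], ext_end[i])
    fr <- profile$map$fragments[idx, ]
    w <- pmin(fr$end, ext_end[i]) - pmax(fr$start, ext_start[i])
    sum(w * profile$values[idx]) / sum(w)
  }, 0)
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = ext_start, end = ext_end, mean_rpm = mean_rpm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Robust accessibility differences between two samples
#'
#' Reports maximal runs of at least `k` consecutive fragments whose RPM
#' difference exceeds `delta` with a consistent sign (strict `> delta`, per
#' the ">10 RPM" rule; a difference of exactly `delta` never qualifies),
#' together with a summary (total member fragments and region count).
#'
#' @param a,b [fragment_profile()]s with unit `rpm` on the same map.
#' @param delta minimum absolute per-fragment RPM difference (strict).
#' @param k minimum run length in fragments (default 3).
#' @return object of class `accessibility_diff`: `regions` data.frame
#'   (`chrom`, `start`, `end`, `first_frag`, `last_frag`, `n_fragments`,
#'   `direction`, `mean_diff`) and `summary` (`n_regions`,
#'   `n_fragments`).
#' @export
robust_diff_regions <- function(a, b, delta = 10, k = 3L) {
  stopifnot(is(a, "fragment_profile"), is(b, "fragment_profile"))
  if (a$unit != "rpm" || b$unit != "rpm") stopf("expects rpm profiles")
  if (!same_map(a$map, b$map)) stopf("profiles built on different maps")
  if (delta <= 0) stopf("delta must be > 0")
  if (k < 1L) stopf("k must be >= 1")
  d <- a$values - b$values
  fr <- a$map$fragments

  one_sign <- function(flag, direction) {
    runs <- true_runs(flag, fr$chrom)
    runs <- runs[runs$last - runs$first + 1L >= k, , drop = FALSE]
    if (nrow(runs) == 0L) return(NULL)
    data.frame(chrom = fr$chrom[runs$first],
               start = fr$start[runs$first], end = fr$end[runs$last],
               first_frag = runs$first, last_frag = runs$last,
               n_fragments = runs$last - runs$first + 1L,
               direction = direction,
               mean_diff = run_stats(d, runs$first, runs$last, "mean"),
               stringsAsFactors = FALSE)
  }
  regions <- rbind(one_sign(d > delta, "+"), one_sign(d < -delta, "-"))
  if (is.null(regions)) {
    regions <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), first_frag = integer(0),
                          last_frag = integer(0), n_fragments = integer(0),
                          direction = character(0), mean_diff = numeric(0))
  }
  regions <- regions[order(regions$chrom, regions$start), ]
  rownames(regions) <- NULL
  structure(list(regions = regions,
                 summary = data.frame(n_regions = nrow(regions),
                                      n_fragments = sum(regions$n_fragments))),
            class = "accessibility_diff")
}

#' @export
print.accessibility_diff <- function(x, ...) {
  cat(sprintf("accessibility_diff: %d region(s) covering %d GATC fragment(s)\n",
              x$summary$n_regions, x$summary$n_fragments))
  invisible(x)
}
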