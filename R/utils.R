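#' @importFrom methods is
#' @importFrom stats median rbinom rexp rlnorm rnbinom rpois runif cor setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Full-pipeline runs draw many independent random streams (per sample, per
#' permutation stage, per comparison). Each stream's seed is derived
#' deterministically from one master seed and a human-readable label, so a
#' single integer reproduces the whole run. The result is always a valid
#' 32-bit R seed.
#'
#' @param master integer master seed.
#' @param label character scalar naming the stream.
#' @return an integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

## maximal runs of TRUE in a logical vector, never crossing group boundaries
## (groups = chromosomes). Returns data.frame(first, last) of vector indices.
true_runs <- function(flag, group) {
  idx <- which(flag)
  if (length(idx) == 0L) {
    return(data.frame(first = integer(0), last = integer(0)))
  }
  new_run <- c(TRUE, diff(idx) != 1L | group[idx[-1L]] != group[idx[-length(idx)]])
  starts <- idx[new_run]
  ends <- idx[c(new_run[-1L], TRUE)]
  data.frame(first = starts, last = ends)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## count of sorted_vals >= each x (vectorised); sorted_vals ascending
count_ge <- function(x, sorted_vals) {
  length(sorted_vals) - findInterval(x, sorted_vals, left.open = TRUE)
}

## BH-style monotone regularisation: given scores and raw FDRs, return
## FDR(s) = min over thresholds s' <= s of raw(s'), so FDR is non-increasing
## in score (higher score can never have a larger FDR than a lower one).
regularize_fdr <- function(score, raw) {
  o <- order(score)
  reg <- raw
  reg[o] <- cummin_with_ties(score[o], raw[o])
  reg
}

cummin_with_ties <- function(sorted_score, raw_sorted) {
  cm <- cummin(raw_sorted)
  ## equal scores must share one FDR: the plain cummin reaches the tie-group
  ## minimum only at the last member, so spread the group min to all members
  grp <- cumsum(c(TRUE, sorted_score[-1L] != sorted_score[-length(sorted_score)]))
  stats::ave(cm, grp, FUN = min)
}
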