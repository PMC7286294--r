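#' Construct an annotation set
#'
#' Container for gene models: a gene table and a transcript table, both with
#' 0-based half-open coordinates. Genes lacking transcripts are given a
#' single transcript equal to the gene span, so non-coding entries flow
#' through transcript-level scoring unchanged.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end` (0-based half-open).
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`; may be missing rows for some genes.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(genes, transcripts = NULL) {
  req <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(genes))) {
    stopf("genes table needs columns: %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stopf("duplicated gene_id in annotation")
  if (!all(genes$strand %in% c("+", "-"))) stopf("gene strand must be + or -")
  if (any(genes$end <= genes$start)) stopf("gene with end <= start")
  if (is.null(transcripts)) {
    transcripts <- data.frame(transcript_id = character(0), gene_id = character(0),
                              chrom = character(0), start = integer(0),
                              end = integer(0), stringsAsFactors = FALSE)
  }
  if (nrow(transcripts) > 0) {
    missing_parent <- setdiff(transcripts$gene_id, genes$gene_id)
    if (length(missing_parent) > 0) {
      stopf("transcript references missing parent gene: %s", missing_parent[1L])
    }
    if (any(transcripts$end <= transcripts$start)) {
      stopf("transcript with end <= start")
    }
  }
  ## genes without any transcript get one spanning the gene
  orphan <- setdiff(genes$gene_id, transcripts$gene_id)
  if (length(orphan) > 0) {
    g <- genes[match(orphan, genes$gene_id), ]
    transcripts <- rbind(
      transcripts[, c("transcript_id", "gene_id", "chrom", "start", "end")],
      data.frame(transcript_id = paste0(orphan, ".t1"), gene_id = orphan,
                 chrom = g$chrom, start = g$start, end = g$end,
                 stringsAsFactors = FALSE))
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stopf("duplicated transcript_id in annotation")
  }
  ## gene span must cover its transcripts
  gs <- genes[match(transcripts$gene_id, genes$gene_id), ]
  if (any(transcripts$start < gs$start | transcripts$end > gs$end)) {
    stopf("transcript extends outside its gene span")
  }
  genes <- genes[order(genes$chrom, genes$start, genes$end), ]
  rownames(genes) <- rownames(transcripts) <- NULL
  structure(list(genes = genes, transcripts = transcripts),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d transcripts on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$transcripts), length(unique(x$genes$chrom))))
  invisible(x)
}

transcript_types <- c("mRNA", "transcript", "ncRNA", "lncRNA", "miRNA", "tRNA",
                      "rRNA", "snRNA", "snoRNA", "pre_miRNA", "pseudogene_transcript")

#' Read gene models from GFF3
#'
#' Parses gene and transcript-level features (mRNA, transcript, *RNA types)
#' from a GFF3 file. GFF3 coordinates are 1-based inclusive and are converted
#' to the internal 0-based half-open convention. Transcripts are attached to
#' their parent genes via the `Parent` attribute; a transcript naming an
#' unknown parent is an error, as is any feature with end < start or a
#' malformed (non 9-column) line.
#'
#' @param path GFF3 file.
#' @return an [annotation_set()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stopf("malformed GFF3 line %d: expected 9 tab-separated columns, found %d",
          bad, nfield[which(nfield != 9L)[1L]])
  }
  check_gff_coords(lines, body)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else
    rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = id[is_gene],
    chrom = as.character(GenomeInfoDb::seqnames(gr[is_gene])),
    strand = as.character(BiocGenerics::strand(gr[is_gene])),
    start = BiocGenerics::start(gr[is_gene]) - 1L,
    end = BiocGenerics::end(gr[is_gene]),
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  is_tx <- type %in% transcript_types
  parent <- rep(NA_character_, length(gr))
  if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    pl <- gr$Parent
    has_p <- lengths(pl) > 0
    parent[has_p] <- vapply(pl[has_p], function(p) as.character(p)[1L], "")
  }
  if (any(is_tx & is.na(parent))) {
    stopf("transcript feature without Parent attribute: %s",
          id[is_tx & is.na(parent)][1L])
  }
  transcripts <- data.frame(
    transcript_id = id[is_tx],
    gene_id = parent[is_tx],
    chrom = as.character(GenomeInfoDb::seqnames(gr[is_tx])),
    start = BiocGenerics::start(gr[is_tx]) - 1L,
    end = BiocGenerics::end(gr[is_tx]),
    stringsAsFactors = FALSE
  )
  annotation_set(genes, transcripts)
}

check_gff_coords <- function(lines, body) {
  idx <- which(body)
  if (length(idx) == 0L) return(invisible())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  bad <- which(is.na(s) | is.na(e) | e < s)
  if (length(bad) > 0) {
    stopf("GFF3 line %d: invalid coordinates (end < start or non-numeric)",
          idx[bad[1L]])
  }
  invisible()
}

## GRanges view of transcripts (1-based) for overlap machinery
transcripts_granges <- function(annotation) {
  tx <- annotation$transcripts
  GenomicRanges::GRanges(tx$chrom,
                         IRanges::IRanges(tx$start + 1L, tx$end),
                         transcript_id = tx$transcript_id,
                         gene_id = tx$gene_id)
}
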