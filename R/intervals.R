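#' @title Internal coordinate convention
#' @description All genomic coordinates inside clipmap are 0-based, half-open
#'   `[start, end)`, BED-style. GTF input (1-based, closed) is converted at the
#'   boundary by `read_gtf()` and never afterwards. Strand is `"+"` or `"-"`.
#' @name clipmap-coordinates
#' @keywords internal
NULL

# Validate a BED-like data.frame of stranded intervals. Returns it invisibly.
check_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, ": missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(x)) {
    if (any(x$start < 0)) stop(what, ": negative start")
    if (any(x$start >= x$end)) stop(what, ": start >= end (0-based half-open)")
    if (!all(x$strand %in% c("+", "-"))) stop(what, ": strand must be '+' or '-'")
  }
  invisible(x)
}

# Overlap length of [s1,e1) and [s2,e2); <= 0 means no overlap.
overlap_len <- function(s1, e1, s2, e2) {
  pmin(e1, e2) - pmax(s1, s2)
}

# Gap between two half-open intervals (0 when they touch or overlap).
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Construct a gene model
#'
#' A gene model is one transcript: strand, ordered exons, per-exon
#' constitutive/alternative labels, and an optional CDS span. Exons are stored
#' in genomic order; transcription order on the `-` strand is the reverse.
#'
#' @param gene_id,transcript_id,biotype identifiers; `biotype` is typically
#'   `"protein_coding"`.
#' @param chrom,strand chromosome name and `"+"`/`"-"`.
#' @param exon_starts,exon_ends integer vectors, 0-based half-open, sorted
#'   ascending, non-overlapping.
#' @param exon_labels per-exon `"constitutive"` or `"alternative"`; recycled
#'   from `"constitutive"` when omitted.
#' @param cds_start,cds_end genomic CDS span (0-based half-open) or `NA` for
#'   non-coding / unannotated transcripts.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand,
                       exon_starts, exon_ends,
                       biotype = "protein_coding",
                       exon_labels = NULL,
                       cds_start = NA_integer_, cds_end = NA_integer_) {
  n <- length(exon_starts)
  if (n == 0L) stop("gene model '", transcript_id, "' has zero exons")
  if (length(exon_ends) != n) stop("exon_starts/exon_ends length mismatch")
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends <- as.integer(exon_ends[o])
  if (any(exon_starts >= exon_ends)) stop("exon with start >= end")
  if (n > 1L && any(exon_starts[-1L] < exon_ends[-n])) {
    stop("overlapping exons in transcript '", transcript_id, "'")
  }
  if (is.null(exon_labels)) exon_labels <- rep("constitutive", n)
  exon_labels <- exon_labels[o]
  if (!all(exon_labels %in% c("constitutive", "alternative"))) {
    stop("exon_labels must be 'constitutive' or 'alternative'")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(
    gene_id = gene_id, transcript_id = transcript_id, biotype = biotype,
    chrom = chrom, strand = strand,
    start = exon_starts[1L], end = exon_ends[n],
    exon_starts = exon_starts, exon_ends = exon_ends,
    exon_labels = exon_labels,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s / %s (%s) %s:%d-%d [%s] %d exons (%d alternative)\n",
              x$gene_id, x$transcript_id, x$biotype, x$chrom, x$start, x$end,
              x$strand, length(x$exon_starts),
              sum(x$exon_labels == "alternative")))
  invisible(x)
}

# Exon index order in transcription order (5' -> 3').
transcription_order <- function(model) {
  n <- length(model$exon_starts)
  if (model$strand == "+") seq_len(n) else rev(seq_len(n))
}

# Span length of the transcript on the genome.
model_span <- function(model) model$end - model$start

# Internal boundary table of one transcript: for each junction, its genomic
# coordinate and kind in transcription orientation (exon_intron = 5'ss,
# intron_exon = 3'ss). A transcript with n exons has 2*(n-1) boundaries.
model_boundaries <- function(model) {
  n <- length(model$exon_starts)
  if (n < 2L) {
    return(data.frame(kind = character(), pos = integer(),
                      chrom = character(), strand = character(),
                      gene_id = character(), transcript_id = character(),
                      stringsAsFactors = FALSE))
  }
  # Genomic junctions: end of exon i (i<n) and start of exon i (i>1).
  right_pos <- model$exon_ends[-n]    # exon|intron in genomic order
  left_pos <- model$exon_starts[-1L]  # intron|exon in genomic order
  if (model$strand == "+") {
    kind <- c(rep("exon_intron", n - 1L), rep("intron_exon", n - 1L))
  } else {
    kind <- c(rep("intron_exon", n - 1L), rep("exon_intron", n - 1L))
  }
  data.frame(
    kind = kind,
    pos = c(right_pos, left_pos),
    chrom = model$chrom, strand = model$strand,
    gene_id = model$gene_id, transcript_id = model$transcript_id,
    stringsAsFactors = FALSE
  )
}

# Choose the host transcript for a stranded interval among gene models:
# overlapping models only; prefer protein_coding, then longest genomic span,
# then lexicographic transcript_id. NULL if no model overlaps.
choose_host_model <- function(chrom, start, end, strand, models) {
  best <- NULL
  for (m in models) {
    if (m$chrom != chrom || m$strand != strand) next
    if (overlap_len(start, end, m$start, m$end) <= 0L) next
    if (is.null(best)) { best <- m; next }
    b_pc <- best$biotype == "protein_coding"
    m_pc <- m$biotype == "protein_coding"
    if (m_pc != b_pc) { if (m_pc) best <- m; next }
    if (model_span(m) != model_span(best)) {
      if (model_span(m) > model_span(best)) best <- m
      next
    }
    if (m$transcript_id < best$transcript_id) best <- m
  }
  best
}
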