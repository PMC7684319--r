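#' High-confidence peak filter
#'
#' Keeps peaks with enrichment p-value at or below `p_threshold` and fold
#' enrichment at or above `fold_threshold` versus the size-matched input
#' (the reported peak set uses the inclusive fold rule; `fold_strict = TRUE`
#' switches to a strict `>` comparison). Input order is preserved.
#'
#' @param peaks peak data.frame (see [read_peaks()]).
#' @param p_threshold p-value cutoff (default 1e-3); compared via
#'   `neg_log10_p >= -log10(p_threshold)`.
#' @param fold_threshold fold-enrichment cutoff (default 5).
#' @param fold_strict use `fold > threshold` instead of `>=`.
#' @return filtered peak data.frame.
#' @export
filter_high_confidence <- function(peaks, p_threshold = 1e-3,
                                   fold_threshold = 5.0,
                                   fold_strict = FALSE) {
  if (p_threshold <= 0 || fold_threshold < 0) {
    stop("thresholds must be positive")
  }
  keep_p <- peaks$neg_log10_p >= -log10(p_threshold)
  keep_f <- if (fold_strict) peaks$fold_enrichment > fold_threshold
            else peaks$fold_enrichment >= fold_threshold
  peaks[keep_p & keep_f, , drop = FALSE]
}

#' Replicate-consensus peak merging
#'
#' Implements the 2-of-N consensus rule: peaks from all libraries are
#' grouped into connected components under same-chromosome, same-strand
#' overlap of at least `min_overlap_bp` bases; a component is kept when it
#' contains peaks from at least `min_support` distinct libraries; each kept
#' component is combined into one merged peak spanning the union of its
#' members. A final self-comparison pass unions any merged intervals that
#' still overlap (possible only when `gap_join > 0`, which also chains
#' peaks separated by up to that many bases).
#'
#' @param peak_lists list of per-library peak data.frames (>= 2 libraries),
#'   or a single data.frame carrying a `library_id` column.
#' @param min_support minimum number of distinct supporting libraries.
#' @param min_overlap_bp minimum overlap (bases) for two peaks to be
#'   considered common.
#' @param gap_join also chain peaks separated by up to this many bases
#'   (default 0 = require genuine overlap).
#' @return data.frame of merged peaks: `chrom,start,end,strand,support,
#'   n_peaks`, plus list columns `source_library` and `source_name`.
#' @export
merge_replicate_peaks <- function(peak_lists, min_support = 2L,
                                  min_overlap_bp = 1L, gap_join = 0L) {
  if (is.data.frame(peak_lists)) {
    peak_lists <- split(peak_lists, peak_lists$library_id)
  }
  if (length(peak_lists) < 2L) {
    stop("consensus merging needs >= 2 libraries")
  }
  all_pk <- do.call(rbind, lapply(peak_lists, function(p) {
    check_intervals(p, "peaks")
    p[, c("chrom", "start", "end", "name", "strand", "library_id")]
  }))
  rownames(all_pk) <- NULL
  if (!nrow(all_pk)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      support = integer(), n_peaks = integer()))
  }
  out <- list()
  for (key in sort(unique(paste0(all_pk$chrom, ":", all_pk$strand)))) {
    sel <- paste0(all_pk$chrom, ":", all_pk$strand) == key
    pk <- all_pk[sel, , drop = FALSE]
    pk <- pk[order(pk$start, pk$end), , drop = FALSE]
    # sweep: component extends while the next start is close enough to the
    # running max end for an overlap of >= min_overlap_bp (or gap <= gap_join)
    comp <- integer(nrow(pk))
    comp_id <- 1L
    comp[1L] <- comp_id
    max_end <- pk$end[1L]
    if (nrow(pk) > 1L) for (i in 2:nrow(pk)) {
      joined <- if (gap_join > 0L) pk$start[i] <= max_end + gap_join
                else (max_end - pk$start[i]) >= min_overlap_bp
      if (!joined) { comp_id <- comp_id + 1L; max_end <- pk$end[i] }
      else max_end <- max(max_end, pk$end[i])
      comp[i] <- comp_id
    }
    for (cid in unique(comp)) {
      rows <- pk[comp == cid, , drop = FALSE]
      support <- length(unique(rows$library_id))
      if (support < min_support) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = rows$chrom[1L], start = min(rows$start),
        end = max(rows$end), strand = rows$strand[1L],
        support = support, n_peaks = nrow(rows),
        source_library = I(list(rows$library_id)),
        source_name = I(list(rows$name)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      support = integer(), n_peaks = integer()))
  }
  merged <- do.call(rbind, out)
  merged <- merged[order(merged$chrom, merged$start, merged$end), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  # redundancy elimination: union any still-overlapping merged intervals
  if (nrow(merged) > 1L) {
    drop <- logical(nrow(merged))
    i <- 1L
    for (j in 2:nrow(merged)) {
      same <- merged$chrom[j] == merged$chrom[i] &&
        merged$strand[j] == merged$strand[i]
      if (same && merged$start[j] < merged$end[i]) {
        merged$end[i] <- max(merged$end[i], merged$end[j])
        merged$support[i] <- max(merged$support[i], merged$support[j])
        merged$n_peaks[i] <- merged$n_peaks[i] + merged$n_peaks[j]
        merged$source_library[[i]] <- c(merged$source_library[[i]],
                                        merged$source_library[[j]])
        merged$source_name[[i]] <- c(merged$source_name[[i]],
                                     merged$source_name[[j]])
        drop[j] <- TRUE
      } else {
        i <- j
      }
    }
    merged <- merged[!drop, , drop = FALSE]
    rownames(merged) <- NULL
  }
  merged
}

#' Genic annotation of merged peaks
#'
#' Assigns each peak one genic category against its host transcript (chosen
#' by the longest-protein-coding rule among overlapping models). Category
#' precedence: `exon_intron_junction` > `CDS_exon` > `5'UTR` > `3'UTR` >
#' `noncoding_exon` > `intron` > `intergenic`. Without CDS annotation on
#' the host, coding exonic categories collapse to `exon`.
#'
#' @param merged merged peak data.frame (or any BED-like peaks).
#' @param gene_models list of `gene_model`s.
#' @return data.frame with `chrom,start,end,strand,category,gene_id,
#'   transcript_id`.
#' @export
annotate_peaks <- function(merged, gene_models) {
  check_intervals(merged, "merged peaks")
  n <- nrow(merged)
  category <- character(n)
  gene_id <- rep(NA_character_, n)
  transcript_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    host <- choose_host_model(merged$chrom[i], merged$start[i],
                              merged$end[i], merged$strand[i], gene_models)
    if (is.null(host)) { category[i] <- "intergenic"; next }
    gene_id[i] <- host$gene_id
    transcript_id[i] <- host$transcript_id
    category[i] <- classify_region(merged$start[i], merged$end[i], host)
  }
  cbind(merged[, c("chrom", "start", "end", "strand")],
        data.frame(category = category, gene_id = gene_id,
                   transcript_id = transcript_id, stringsAsFactors = FALSE))
}

# Category of interval [s,e) on a host transcript; considers only the part
# of the peak inside the transcript span.
classify_region <- function(s, e, host) {
  s <- max(s, host$start)
  e <- min(e, host$end)
  ex_ov <- overlap_len(s, e, host$exon_starts, host$exon_ends)
  exonic <- sum(pmax(0L, ex_ov))
  total <- e - s
  intronic <- total - exonic
  if (exonic > 0L && intronic > 0L) return("exon_intron_junction")
  if (exonic == 0L) return("intron")
  if (host$biotype != "protein_coding") return("noncoding_exon")
  if (is.na(host$cds_start)) return("exon")
  cds_ov <- sum(pmax(0L, overlap_len(pmax(s, host$exon_starts),
                                     pmin(e, host$exon_ends),
                                     host$cds_start, host$cds_end)))
  if (cds_ov > 0L) return("CDS_exon")
  # fully exonic, fully outside CDS: pick UTR side in transcription order
  before_cds <- e <= host$cds_start
  if (host$strand == "+") {
    if (before_cds) "5'UTR" else "3'UTR"
  } else {
    if (before_cds) "3'UTR" else "5'UTR"
  }
}

#' Tabulate genic categories of annotated peaks
#'
#' @param annotated output of [annotate_peaks()].
#' @return data.frame of counts and percentages (1 decimal) per category.
#' @export
genic_category_table <- function(annotated) {
  tab <- table(annotated$category)
  data.frame(category = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 1),
             stringsAsFactors = FALSE)
}
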