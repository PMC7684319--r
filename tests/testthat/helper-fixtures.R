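# Hand-built fixtures and independent oracles shared across test files.

# Six-exon plus-strand gene used for the worked boundary-selection example:
# exons of 100 nt separated by 400 nt introns, starting at 1000.
six_exon_model <- function(strand = "+", chrom = "chr1") {
  starts <- 1000L + (0:5) * 500L
  gene_model(gene_id = "gACTB", transcript_id = "tACTB", chrom = chrom,
             strand = strand, exon_starts = starts, exon_ends = starts + 100L,
             cds_start = 1050L, cds_end = starts[6] + 50L)
}

# Build a coverage_track from a named list "chrom:+"/"chrom:-" -> vector.
track_from <- function(vectors, chrom_sizes) {
  structure(lapply(vectors, as.integer), chrom_sizes = chrom_sizes,
            class = "coverage_track")
}

# Random per-library peak lists on a couple of chromosomes/strands.
random_peak_lists <- function(n_libs = 4L, n_peaks = 50L, seed = 1L,
                              span = 5000L) {
  set.seed(seed)
  lapply(stats::setNames(seq_len(n_libs), paste0("lib", seq_len(n_libs))),
         function(l) {
    start <- sample.int(span, n_peaks, replace = TRUE)
    width <- sample(20:120, n_peaks, replace = TRUE)
    data.frame(chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
               start = start, end = start + width,
               name = sprintf("lib%d_p%03d", l, seq_len(n_peaks)),
               neg_log10_p = runif(n_peaks, 3, 8),
               strand = sample(c("+", "-"), n_peaks, replace = TRUE),
               fold_enrichment = runif(n_peaks, 5, 20),
               library_id = paste0("lib", l), stringsAsFactors = FALSE)
  })
}

# Independent union-find oracle for consensus merging: connected components
# of the pairwise >= min_overlap_bp same-chrom same-strand overlap graph.
uf_merge_oracle <- function(peak_lists, min_support = 2L,
                            min_overlap_bp = 1L) {
  pk <- do.call(rbind, peak_lists)
  n <- nrow(pk)
  if (!n) return(data.frame(chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            support = integer()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (pk$chrom[i] != pk$chrom[j] || pk$strand[i] != pk$strand[j]) next
    ov <- min(pk$end[i], pk$end[j]) - max(pk$start[i], pk$start[j])
    if (ov >= min_overlap_bp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(root), function(r) {
    rows <- pk[root == r, , drop = FALSE]
    support <- length(unique(rows$library_id))
    if (support < min_support) return(NULL)
    data.frame(chrom = rows$chrom[1], start = min(rows$start),
               end = max(rows$end), strand = rows$strand[1],
               support = support, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer(), strand = character(),
                                      support = integer()))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Independent host-transcript pick (protein_coding, then span, then id).
oracle_host <- function(chrom, s, e, strand, models) {
  cand <- Filter(function(m) m$chrom == chrom && m$strand == strand &&
                   min(e, m$end) - max(s, m$start) > 0L, models)
  if (!length(cand)) return(NULL)
  key <- vapply(cand, function(m) {
    sprintf("%d_%012d_%s", as.integer(m$biotype != "protein_coding"),
            1e9 - (m$end - m$start), m$transcript_id)
  }, character(1))
  cand[[order(key)[1L]]]
}

# Exhaustive per-peak boundary-selection oracle: walk outward base by base
# from each peak terminal to the first junction; junctions inside the peak
# are found by testing every junction for spanning coverage.
boundary_scan_oracle <- function(peak, model) {
  b <- model_boundaries(model)
  if (!nrow(b)) return(b[0, ])
  hit <- logical(nrow(b))
  for (k in seq_len(nrow(b))) {
    if (peak$start < b$pos[k] && b$pos[k] < peak$end) hit[k] <- TRUE
  }
  p <- peak$start
  while (p >= min(b$pos)) {
    at <- which(b$pos == p)
    if (length(at)) { hit[at] <- TRUE; break }
    p <- p - 1L
  }
  p <- peak$end
  while (p <= max(b$pos)) {
    at <- which(b$pos == p)
    if (length(at)) { hit[at] <- TRUE; break }
    p <- p + 1L
  }
  b[hit, , drop = FALSE]
}

# Per-base genic-category oracle with explicit precedence.
annotate_oracle <- function(chrom, s, e, strand, models) {
  host <- oracle_host(chrom, s, e, strand, models)
  if (is.null(host)) return("intergenic")
  states <- character(0)
  for (b in seq(max(s, host$start), min(e, host$end) - 1L)) {
    in_exon <- any(host$exon_starts <= b & b < host$exon_ends)
    if (!in_exon) { states <- c(states, "intron"); next }
    if (host$biotype != "protein_coding") {
      states <- c(states, "noncoding_exon"); next
    }
    if (is.na(host$cds_start)) { states <- c(states, "exon"); next }
    if (host$cds_start <= b && b < host$cds_end) {
      states <- c(states, "CDS_exon"); next
    }
    before <- b < host$cds_start
    five <- if (host$strand == "+") before else !before
    states <- c(states, if (five) "5'UTR" else "3'UTR")
  }
  exonic <- setdiff(states, "intron")
  if (length(exonic) && "intron" %in% states) return("exon_intron_junction")
  for (cat in c("CDS_exon", "5'UTR", "3'UTR", "noncoding_exon", "exon",
                "intron")) {
    if (cat %in% states) return(cat)
  }
  "intergenic"
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration.
fisher_enum_oracle <- function(k, a_only, b_only, neither) {
  m <- k + a_only          # size of set A
  n_tot <- k + a_only + b_only + neither
  K <- k + b_only          # items with property B
  support <- max(0L, m + K - n_tot):min(m, K)
  probs <- dhyper(support, K, n_tot - K, m)
  p_obs <- dhyper(k, K, n_tot - K, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small deterministic simulated world reused by several files.
small_world <- function(seed = 11L, ...) {
  cfg <- sim_config(seed = seed, n_genes = 24L, peaks_per_library = 200L, ...)
  ann <- simulate_annotation(cfg)
  list(cfg = cfg, ann = ann)
}
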