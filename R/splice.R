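#' Percent spliced-in from junction counts
#'
#' `PSI = (I/l_I) / (I/l_I + S/l_S)` for inclusion counts `I`, skipping
#' counts `S` and effective lengths `l_I`, `l_S`.
#'
#' @param inclusion_counts,skipping_counts non-negative counts (not both 0).
#' @param inclusion_eff_len,skipping_eff_len positive effective lengths.
#' @return PSI in \[0, 1\] (vectorised).
#' @export
compute_psi <- function(inclusion_counts, skipping_counts,
                        inclusion_eff_len = 1, skipping_eff_len = 1) {
  if (any(inclusion_counts < 0) || any(skipping_counts < 0)) {
    stop("counts must be non-negative")
  }
  if (any(inclusion_counts + skipping_counts == 0)) {
    stop("PSI undefined: inclusion and skipping counts both zero")
  }
  i_norm <- inclusion_counts / inclusion_eff_len
  s_norm <- skipping_counts / skipping_eff_len
  i_norm / (i_norm + s_norm)
}

#' PSI from RT-PCR band densitometry
#'
#' `PSI = inclusion / (inclusion + skip)` for gel band intensities.
#'
#' @param inclusion_intensity,skip_intensity non-negative intensities.
#' @return PSI in \[0, 1\] (vectorised).
#' @export
psi_from_band_intensities <- function(inclusion_intensity, skip_intensity) {
  if (any(inclusion_intensity < 0) || any(skip_intensity < 0)) {
    stop("intensities must be non-negative")
  }
  if (any(inclusion_intensity + skip_intensity == 0)) {
    stop("PSI undefined: both band intensities zero")
  }
  inclusion_intensity / (inclusion_intensity + skip_intensity)
}

#' Classify event responsiveness from delta-PSI and FDR
#'
#' An event is `enhanced` when `delta_psi > dpsi_threshold` and
#' `fdr < fdr_threshold`, `repressed` when `delta_psi < -dpsi_threshold`
#' and `fdr < fdr_threshold`, and `unresponsive` otherwise. With the
#' knockout-minus-wild-type sign convention, `enhanced` means inclusion
#' rises upon regulator loss. Thresholds are strict inequalities
#' (|delta PSI| > 0.1, FDR < 0.05 by default).
#'
#' @param events event data.frame with `delta_psi` and `fdr`.
#' @param dpsi_threshold |delta PSI| threshold (default 0.1).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return the events with a `responsiveness` column appended.
#' @export
classify_events <- function(events, dpsi_threshold = 0.1,
                            fdr_threshold = 0.05) {
  stopifnot(all(c("delta_psi", "fdr") %in% names(events)))
  sig <- events$fdr < fdr_threshold
  cls <- ifelse(sig & events$delta_psi > dpsi_threshold, "enhanced",
                ifelse(sig & events$delta_psi < -dpsi_threshold,
                       "repressed", "unresponsive"))
  events$responsiveness <- cls
  events
}

#' Count and percentage table by a grouping column
#'
#' Percentages are reported to one decimal, e.g. 223 SE of 454 events
#' prints as 49.1.
#'
#' @param x data.frame (classified events or any record table).
#' @param by grouping column (default `"event_type"`).
#' @return data.frame with `count` and `percent` per group.
#' @export
class_proportions <- function(x, by = "event_type") {
  stopifnot(by %in% names(x))
  tab <- table(x[[by]])
  data.frame(group = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 1),
             stringsAsFactors = FALSE)
}

#' Percentage summary of the overlap of two gene sets
#'
#' @param set_a,set_b character vectors of identifiers.
#' @return data.frame with the intersection size and the percentage of each
#'   set covered by it (1 decimal).
#' @export
set_overlap_summary <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  k <- length(intersect(set_a, set_b))
  data.frame(n_a = length(set_a), n_b = length(set_b), n_common = k,
             pct_of_a = round(100 * k / length(set_a), 1),
             pct_of_b = round(100 * k / length(set_b), 1))
}

#' Associate peaks with alternative and constitutive exons
#'
#' A peak is associated with an alternative exon when it overlaps the exon
#' body, and with a constitutive exon when it overlaps the exon or lies
#' within `flank_nt` bases up- or downstream of it. Gene-level sets (genes
#' carrying peaks, genes with splicing events, their intersection) are
#' derived for Venn-style summaries.
#'
#' @param merged_peaks BED-like peak data.frame.
#' @param gene_models list of `gene_model`s (source of exon labels).
#' @param events event table (source of the splicing-regulated gene set).
#' @param flank_nt flanking distance for constitutive-exon association
#'   (default 300).
#' @return list with `per_peak` (association flags per peak), `counts`
#'   (peaks on alternative exons, peaks near constitutive exons), and
#'   `genes` (peak genes, AS genes, intersection and percentage summary).
#' @export
intersect_peaks_events <- function(merged_peaks, gene_models, events,
                                   flank_nt = 300L) {
  check_intervals(merged_peaks, "peaks")
  n <- nrow(merged_peaks)
  on_alt <- logical(n)
  near_const <- logical(n)
  peak_gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- merged_peaks$start[i]
    e <- merged_peaks$end[i]
    for (m in gene_models) {
      if (m$chrom != merged_peaks$chrom[i] ||
          m$strand != merged_peaks$strand[i]) next
      if (overlap_len(s, e, m$start - flank_nt, m$end + flank_nt) <= 0L) next
      alt <- m$exon_labels == "alternative"
      if (any(overlap_len(s, e, m$exon_starts[alt], m$exon_ends[alt]) > 0L)) {
        on_alt[i] <- TRUE
      }
      con <- !alt
      if (any(overlap_len(s, e, m$exon_starts[con] - flank_nt,
                          m$exon_ends[con] + flank_nt) > 0L)) {
        near_const[i] <- TRUE
      }
      if (is.na(peak_gene[i]) &&
          overlap_len(s, e, m$start, m$end) > 0L) {
        peak_gene[i] <- m$gene_id
      }
    }
  }
  peak_genes <- unique(stats::na.omit(peak_gene))
  as_genes <- unique(events$gene_id)
  list(
    per_peak = data.frame(merged_peaks[, c("chrom", "start", "end", "strand")],
                          gene_id = peak_gene, on_alt_exon = on_alt,
                          near_const_exon = near_const,
                          stringsAsFactors = FALSE),
    counts = data.frame(n_peaks = n, peaks_on_alt_exons = sum(on_alt),
                        peaks_near_const_exons = sum(near_const)),
    genes = list(peak_genes = peak_genes, as_genes = as_genes,
                 common = intersect(peak_genes, as_genes),
                 summary = set_overlap_summary(peak_genes, as_genes))
  )
}

#' Significance of the overlap of two sets in a universe
#'
#' Builds the 2x2 membership table (in both, A only, B only, neither) and
#' applies a chi-squared test (df = 1, no continuity correction) or
#' Fisher's exact test (two-sided).
#'
#' @param set_a,set_b subsets of `universe`.
#' @param universe character vector of all items.
#' @param method `"chi2"` or `"fisher"`.
#' @return list with `table` (2x2 matrix), `statistic` (chi-squared
#'   statistic, NA for Fisher) and `p`.
#' @export
overlap_significance <- function(set_a, set_b, universe,
                                 method = c("chi2", "fisher")) {
  method <- match.arg(method)
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, dimnames = list(A = c("in", "out"),
                                          B = c("in", "out")))
  if (method == "chi2") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(table = tab, statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    list(table = tab, statistic = NA_real_, p = ht$p.value)
  }
}

#' Spearman correlation matrix of delta-PSI profiles across factors
#'
#' Pairwise Spearman correlation over events shared by each factor pair
#' (pairwise-complete); pairs sharing fewer than 3 events get `NA`.
#' Display order comes from average-linkage hierarchical clustering of
#' `1 - rho`.
#'
#' @param dpsi_tables named list; each element a named numeric vector
#'   `event_id -> delta_psi` for one splicing factor.
#' @return list with `rho` (matrix), `n_shared` (matrix) and `order`
#'   (dendrogram leaf order; NULL when clustering is impossible).
#' @export
dpsi_correlation_matrix <- function(dpsi_tables) {
  stopifnot(is.list(dpsi_tables), length(dpsi_tables) >= 2L,
            !is.null(names(dpsi_tables)))
  f <- names(dpsi_tables)
  k <- length(f)
  rho <- matrix(NA_real_, k, k, dimnames = list(f, f))
  nsh <- matrix(0L, k, k, dimnames = list(f, f))
  for (i in seq_len(k)) for (j in i:k) {
    shared <- intersect(names(dpsi_tables[[i]]), names(dpsi_tables[[j]]))
    nsh[i, j] <- nsh[j, i] <- length(shared)
    if (length(shared) >= 3L) {
      r <- stats::cor(dpsi_tables[[i]][shared], dpsi_tables[[j]][shared],
                      method = "spearman")
      rho[i, j] <- rho[j, i] <- r
    } else if (i == j) {
      rho[i, j] <- 1
    }
  }
  ord <- NULL
  if (!anyNA(rho)) {
    ord <- stats::hclust(stats::as.dist(1 - rho), method = "average")$order
  }
  list(rho = rho, n_shared = nsh, order = ord)
}

#' Exon-architecture features and class comparisons
#'
#' Computes, per event and in transcription order, the lengths of the
#' alternative exon, both flanking constitutive exons, and both flanking
#' introns, then compares every feature between every pair of classes with
#' a two-sided unpaired Wilcoxon (Mann-Whitney) test. Raw p-values are the
#' primary output; Benjamini-Hochberg-adjusted values across the whole
#' feature-by-pair grid are reported alongside.
#'
#' @param classified classified event table (with `responsiveness`).
#' @param class_col class column name.
#' @return list with `features` (per-event table) and `tests` (feature,
#'   pair, n per group, W, p, p_bh). Class pairs with fewer than 2 events
#'   on either side are reported with `NA` p-values.
#' @export
architecture_features <- function(classified, class_col = "responsiveness") {
  stopifnot(class_col %in% names(classified))
  ev <- classified
  plus <- ev$strand == "+"
  feats <- data.frame(
    event_id = ev$event_id,
    class = ev[[class_col]],
    alt_exon_len = ev$alt_end - ev$alt_start,
    upstream_exon_len = ev$up_end - ev$up_start,
    downstream_exon_len = ev$down_end - ev$down_start,
    upstream_intron_len = ifelse(plus, ev$alt_start - ev$up_end,
                                 ev$up_start - ev$alt_end),
    downstream_intron_len = ifelse(plus, ev$down_start - ev$alt_end,
                                   ev$alt_start - ev$down_end),
    stringsAsFactors = FALSE)
  if (any(feats[, 3:7] <= 0L)) stop("non-positive feature length; ",
                                    "event coordinates inconsistent")
  classes <- sort(unique(feats$class))
  pairs <- if (length(classes) >= 2L) utils::combn(classes, 2L) else NULL
  rows <- list()
  for (feat in names(feats)[3:7]) {
    if (is.null(pairs)) break
    for (pi in seq_len(ncol(pairs))) {
      a <- feats[feats$class == pairs[1, pi], feat]
      b <- feats[feats$class == pairs[2, pi], feat]
      if (length(a) < 2L || length(b) < 2L) {
        w <- NA_real_; p <- NA_real_
      } else {
        ht <- wilcoxon_unpaired(a, b)
        w <- ht$statistic; p <- ht$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, class_a = pairs[1, pi], class_b = pairs[2, pi],
        n_a = length(a), n_b = length(b), W = w, p = p,
        stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(tests)) tests$p_bh <- stats::p.adjust(tests$p, method = "BH")
  list(features = feats, tests = tests)
}

# Two-sided unpaired Wilcoxon (Mann-Whitney): exact enumeration for small
# tie-free groups, normal approximation with tie correction otherwise.
wilcoxon_unpaired <- function(a, b) {
  exact <- length(a) <= 10L && length(b) <= 10L &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Extract splice-site windows around alternative and flanking exons
#'
#' 5' splice-site windows are 9 bases (last 3 exonic + first 6 intronic);
#' 3' splice-site windows are 23 bases (last 20 intronic + first 3 exonic),
#' both in transcription orientation (minus-strand windows are
#' reverse-complemented). Sites extracted per event: the alternative exon's
#' donor (`alt_5ss`) and acceptor (`alt_3ss`), the upstream constitutive
#' exon's donor (`con1_5ss`) and the downstream constitutive exon's
#' acceptor (`con2_3ss`). Windows containing `N` are flagged.
#'
#' @param events event table.
#' @param genome named character vector of chromosome sequences.
#' @param sites which site kinds to extract.
#' @return data.frame: `event_id`, `site`, `kind` (`5ss`/`3ss`), `seq`,
#'   `has_n`.
#' @export
extract_splice_site_windows <- function(events, genome,
                                        sites = c("alt_5ss", "alt_3ss",
                                                  "con1_5ss", "con2_3ss")) {
  sites <- match.arg(sites, several.ok = TRUE)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    st <- events$strand[i]
    chrseq <- genome[[events$chrom[i]]]
    if (is.null(chrseq)) stop("chromosome ", events$chrom[i],
                              " missing from genome")
    for (site in sites) {
      exon <- switch(substr(site, 1, 4),
                     alt_ = c(events$alt_start[i], events$alt_end[i]),
                     con1 = c(events$up_start[i], events$up_end[i]),
                     con2 = c(events$down_start[i], events$down_end[i]))
      kind <- if (grepl("5ss$", site)) "5ss" else "3ss"
      w <- splice_site_window(chrseq, exon[1], exon[2], st, kind)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = events$event_id[i], site = site, kind = kind, seq = w,
        has_n = grepl("[^ACGT]", w), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# One window: exon [s,e) on `strand`; kind "5ss" = donor at the exon's
# transcription end, "3ss" = acceptor at its transcription start.
splice_site_window <- function(chrseq, s, e, strand, kind) {
  if (kind == "5ss") {
    if (strand == "+") substr(chrseq, e - 3L + 1L, e + 6L)
    else revcomp_chr(substr(chrseq, s - 6L + 1L, s + 3L))
  } else {
    if (strand == "+") substr(chrseq, s - 20L + 1L, s + 3L)
    else revcomp_chr(substr(chrseq, e - 3L + 1L, e + 20L))
  }
}

#' Train the built-in PWM log-odds splice-site scorer
#'
#' Builds position weight matrices from the constitutive splice sites of a
#' gene annotation (donor 9-mers and acceptor 23-mers, pseudocount 0.5 per
#' base) and scores windows as the summed log2 odds against a uniform
#' background. This scorer follows the standard 9/23-mer window
#' conventions; externally computed score tables (e.g. from a trained
#' maximum-entropy model) can be supplied instead wherever a scorer is
#' accepted.
#'
#' @param gene_models list of `gene_model`s.
#' @param genome named character vector of chromosome sequences.
#' @param pseudocount added per base and position (default 0.5).
#' @return object of class `pwm_scorer` with matrices `pwm_5ss` (4 x 9)
#'   and `pwm_3ss` (4 x 23) of log2 odds.
#' @export
train_pwm_scorer <- function(gene_models, genome, pseudocount = 0.5) {
  donors <- character()
  acceptors <- character()
  for (m in gene_models) {
    n_ex <- length(m$exon_starts)
    if (n_ex < 2L) next
    chrseq <- genome[[m$chrom]]
    const <- m$exon_labels == "constitutive"
    tr <- transcription_order(m)
    for (k in seq_len(n_ex - 1L)) {
      i <- tr[k]  # exon with a downstream intron in transcription order
      if (const[i]) {
        donors <- c(donors, splice_site_window(chrseq, m$exon_starts[i],
                                               m$exon_ends[i], m$strand,
                                               "5ss"))
      }
      j <- tr[k + 1L]  # exon with an upstream intron
      if (const[j]) {
        acceptors <- c(acceptors,
                       splice_site_window(chrseq, m$exon_starts[j],
                                          m$exon_ends[j], m$strand, "3ss"))
      }
    }
  }
  structure(list(pwm_5ss = build_pwm(donors, 9L, pseudocount),
                 pwm_3ss = build_pwm(acceptors, 23L, pseudocount),
                 n_donors = length(donors), n_acceptors = length(acceptors)),
            class = "pwm_scorer")
}

build_pwm <- function(seqs, width, pseudocount) {
  seqs <- seqs[nchar(seqs) == width & !grepl("[^ACGT]", seqs)]
  if (!length(seqs)) stop("no clean training sites for PWM of width ", width)
  counts <- matrix(pseudocount, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in seqs) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (p in seq_len(width)) counts[b[p], p] <- counts[b[p], p] + 1
  }
  freq <- sweep(counts, 2L, colSums(counts), "/")
  log2(freq / 0.25)
}

#' Score splice-site windows and compare classes
#'
#' Scores each window with the supplied scorer (a trained [train_pwm_scorer()]
#' object or a named numeric external score table `sequence -> score`) and,
#' when class labels are given, compares per-class score distributions with
#' two-sided unpaired Wilcoxon tests per site. Windows containing `N` are
#' excluded and counted.
#'
#' @param windows output of [extract_splice_site_windows()].
#' @param scorer `pwm_scorer` or named numeric vector.
#' @param classes optional character vector of class labels, one per row of
#'   `windows` (e.g. the event's responsiveness).
#' @return list with `scores` (windows plus a `score` column; `NA` for
#'   excluded windows), `n_excluded`, and `tests` (per site and class pair)
#'   when classes are supplied.
#' @export
score_splice_sites <- function(windows, scorer, classes = NULL) {
  score_one <- function(seq, kind) {
    if (grepl("[^ACGT]", seq)) return(NA_real_)
    if (is.numeric(scorer)) {
      s <- scorer[seq]
      return(if (is.na(s)) NA_real_ else unname(s))
    }
    stopifnot(inherits(scorer, "pwm_scorer"))
    pwm <- if (kind == "5ss") scorer$pwm_5ss else scorer$pwm_3ss
    b <- strsplit(seq, "", fixed = TRUE)[[1L]]
    if (length(b) != ncol(pwm)) stop("window length ", length(b),
                                     " does not match PWM width ", ncol(pwm))
    sum(pwm[cbind(match(b, rownames(pwm)), seq_along(b))])
  }
  sc <- vapply(seq_len(nrow(windows)),
               function(i) score_one(windows$seq[i], windows$kind[i]),
               numeric(1))
  out <- windows
  out$score <- sc
  res <- list(scores = out, n_excluded = sum(windows$has_n))
  if (!is.null(classes)) {
    stopifnot(length(classes) == nrow(windows))
    out$class <- classes
    rows <- list()
    for (site in unique(out$site)) {
      sub <- out[out$site == site & !is.na(out$score), , drop = FALSE]
      cls <- sort(unique(sub$class))
      if (length(cls) < 2L) next
      prs <- utils::combn(cls, 2L)
      for (pi in seq_len(ncol(prs))) {
        a <- sub$score[sub$class == prs[1, pi]]
        b <- sub$score[sub$class == prs[2, pi]]
        if (length(a) < 2L || length(b) < 2L) next
        ht <- wilcoxon_unpaired(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          site = site, class_a = prs[1, pi], class_b = prs[2, pi],
          n_a = length(a), n_b = length(b), W = ht$statistic, p = ht$p,
          stringsAsFactors = FALSE)
      }
    }
    res$tests <- if (length(rows)) do.call(rbind, rows) else NULL
    res$scores <- out
  }
  res
}
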