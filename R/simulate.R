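#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with validated
#' defaults. The defaults emulate the study conditions the pipeline was
#' designed for: four eCLIP replicate libraries whose binding concentrates
#' just upstream of 5' splice sites and just downstream of 3' splice sites,
#' five-fold IP-over-input enrichment under peaks, and splicing responses of
#' |delta PSI| = 0.3 against replicate noise of sd 0.02.
#'
#' @param seed integer; all generators derive their RNG streams from it
#'   (fixed per-generator offsets give independent, reproducible substreams).
#' @param n_genes number of simulated multi-exon genes.
#' @param exons_per_gene,exon_len,intron_len integer ranges `c(min, max)`
#'   (bases for the length ranges). Introns shorter than 30 nt are rejected:
#'   splice-site windows need room.
#' @param n_libraries number of eCLIP replicate libraries (default 4).
#' @param peaks_per_library number of true binding loci; each library
#'   observes each locus with probability `detect_prob`.
#' @param peak_width integer range of simulated cluster widths (nt).
#' @param jitter per-library positional jitter, +/- bases.
#' @param detect_prob probability a library observes a given true locus.
#' @param fail_frac fraction of observed peaks drawn to fail the
#'   high-confidence filter (low p or low fold).
#' @param positional_model named probabilities over regions `exon_body`,
#'   `within_50nt_upstream_of_5ss`, `within_25nt_downstream_of_3ss`,
#'   `deep_intron`; must sum to 1. A peak's midpoint is sampled uniformly
#'   inside the chosen region.
#' @param enrichment_fold IP/input depth ratio under true peaks.
#' @param background_rate mean input depth per base (Poisson).
#' @param class_fractions named probabilities over `enhanced`, `repressed`,
#'   `unresponsive`; must sum to 1.
#' @param effect_size_dpsi planted |delta PSI| for responsive events.
#' @param psi_noise_sd replicate PSI noise (sd).
#' @param n_replicates PSI replicates per condition.
#' @param ss_mismatch_rate per-base mismatch rate against the splice-site
#'   consensus when writing donor/acceptor sequence (GT/AG always kept).
#' @param go_n_terms,go_term_rate,go_planted_rr,go_list_size GO fixture:
#'   number of terms, base gene-term rate, planted relative risk, size of
#'   the designated gene list.
#' @param n_proteins,n_complexes,complex_size,planted_complex_size,
#'   planted_shift proteomics fixture: pool size, number of random
#'   complexes, their size range, planted complex size and score shift (sd
#'   units).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 40L,
                       exons_per_gene = c(5L, 8L),
                       exon_len = c(80L, 250L),
                       intron_len = c(300L, 1200L),
                       n_libraries = 4L,
                       peaks_per_library = 300L,
                       peak_width = c(30L, 80L),
                       jitter = 5L,
                       detect_prob = 0.85,
                       fail_frac = 0.3,
                       positional_model = c(exon_body = 0.20,
                                            within_50nt_upstream_of_5ss = 0.40,
                                            within_25nt_downstream_of_3ss = 0.25,
                                            deep_intron = 0.15),
                       enrichment_fold = 5,
                       background_rate = 5,
                       class_fractions = c(enhanced = 0.30,
                                           repressed = 0.25,
                                           unresponsive = 0.45),
                       effect_size_dpsi = 0.3,
                       psi_noise_sd = 0.02,
                       n_replicates = 2L,
                       ss_mismatch_rate = 0.05,
                       go_n_terms = 30L,
                       go_term_rate = 0.10,
                       go_planted_rr = 5,
                       go_list_size = NULL,
                       n_proteins = 200L,
                       n_complexes = 20L,
                       complex_size = c(4L, 10L),
                       planted_complex_size = 8L,
                       planted_shift = 2) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              n_libraries = as.integer(n_libraries),
              peaks_per_library = as.integer(peaks_per_library),
              peak_width = as.integer(peak_width),
              jitter = as.integer(jitter), detect_prob = detect_prob,
              fail_frac = fail_frac, positional_model = positional_model,
              enrichment_fold = enrichment_fold,
              background_rate = background_rate,
              class_fractions = class_fractions,
              effect_size_dpsi = effect_size_dpsi,
              psi_noise_sd = psi_noise_sd,
              n_replicates = as.integer(n_replicates),
              ss_mismatch_rate = ss_mismatch_rate,
              go_n_terms = as.integer(go_n_terms),
              go_term_rate = go_term_rate, go_planted_rr = go_planted_rr,
              go_list_size = if (is.null(go_list_size))
                max(5L, as.integer(n_genes) %/% 3L) else as.integer(go_list_size),
              n_proteins = as.integer(n_proteins),
              n_complexes = as.integer(n_complexes),
              complex_size = as.integer(complex_size),
              planted_complex_size = as.integer(planted_complex_size),
              planted_shift = planted_shift)
  ranges <- c("exons_per_gene", "exon_len", "intron_len", "peak_width",
              "complex_size")
  for (r in ranges) {
    v <- cfg[[r]]
    if (length(v) != 2L || v[1] > v[2] || v[1] < 1L) {
      stop("invalid range for ", r)
    }
  }
  if (cfg$intron_len[1] < 30L) {
    stop("intron_len minimum must be >= 30 (splice-site windows need room)")
  }
  pm_regions <- c("exon_body", "within_50nt_upstream_of_5ss",
                  "within_25nt_downstream_of_3ss", "deep_intron")
  if (!setequal(names(cfg$positional_model), pm_regions)) {
    stop("positional_model must name exactly: ",
         paste(pm_regions, collapse = ", "))
  }
  if (abs(sum(cfg$positional_model) - 1) > 1e-9) {
    stop("positional_model probabilities must sum to 1")
  }
  if (!setequal(names(cfg$class_fractions),
                c("enhanced", "repressed", "unresponsive")) ||
      abs(sum(cfg$class_fractions) - 1) > 1e-9) {
    stop("class_fractions must cover enhanced/repressed/unresponsive and sum to 1")
  }
  if (cfg$enrichment_fold <= 0 || cfg$background_rate < 0) {
    stop("enrichment_fold must be > 0 and background_rate >= 0")
  }
  structure(cfg, class = "sim_config")
}

# Reverse complement of a plain character DNA string.
revcomp_chr <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Splice-site consensus: donor 9-mer (last 3 exonic + first 6 intronic),
# acceptor 23-mer (last 20 intronic + first 3 exonic). GT/AG dinucleotides
# are invariant under mutation.
.ss_consensus <- list(
  donor = list(seq = "CAGGTAAGT", fixed = c(4L, 5L)),
  acceptor = list(seq = "TTTTTTTTTTTTTTTTTCAGGCT", fixed = c(19L, 20L))
)

mutate_consensus <- function(which, rate) {
  cons <- .ss_consensus[[which]]
  b <- strsplit(cons$seq, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(b)) < rate
  hit[cons$fixed] <- FALSE
  for (i in which(hit)) {
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  }
  paste(b, collapse = "")
}

# Write a transcribed-orientation window onto the genomic + strand.
# gstart is the genomic (0-based) start of the window span.
write_window <- function(chrseq, gstart, seq, strand) {
  if (strand == "-") seq <- revcomp_chr(seq)
  substr(chrseq, gstart + 1L, gstart + nchar(seq)) <- seq
  chrseq
}

#' Simulate a gene annotation and matching genome sequence
#'
#' Lays multi-exon genes on both strands of a small set of chromosomes
#' (500 nt intergenic gaps), labels one internal exon per gene (with at
#' least three exons) as alternative, assigns a CDS from the middle of the
#' first to the middle of the last exon, and writes a random genome in
#' which every intron carries canonical GT..AG dinucleotides and
#' consensus-derived donor/acceptor sequence on the transcribed strand.
#'
#' @param config a [sim_config()].
#' @return list with `models` (list of `gene_model`), `genome` (named
#'   character vector of chromosome sequences) and `chrom_sizes`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 0L)
  genes_per_chrom <- 25L
  n_chrom <- ceiling(config$n_genes / genes_per_chrom)
  models <- vector("list", config$n_genes)
  layout <- vector("list", n_chrom)
  gap <- 500L
  g <- 0L
  for (ci in seq_len(n_chrom)) {
    cursor <- gap
    rows <- list()
    while (g < config$n_genes && length(rows) < genes_per_chrom) {
      g <- g + 1L
      n_ex <- sample1(config$exons_per_gene[1]:config$exons_per_gene[2])
      ex_len <- sample_range(config$exon_len, n_ex)
      in_len <- if (n_ex > 1L) sample_range(config$intron_len, n_ex - 1L)
                else integer()
      starts <- integer(n_ex)
      ends <- integer(n_ex)
      pos <- cursor
      for (i in seq_len(n_ex)) {
        starts[i] <- pos
        ends[i] <- pos + ex_len[i]
        pos <- ends[i] + if (i < n_ex) in_len[i] else 0L
      }
      strand <- if (g %% 2L == 0L) "-" else "+"
      labels <- rep("constitutive", n_ex)
      if (n_ex >= 3L) {
        # transcription-internal exon marked alternative
        alt_i <- sample1(2:(n_ex - 1L))
        labels[alt_i] <- "alternative"
      }
      cds_start <- starts[1] + ex_len[1] %/% 2L
      cds_end <- ends[n_ex] - ex_len[n_ex] %/% 2L
      models[[g]] <- gene_model(
        gene_id = sprintf("gene%04d", g),
        transcript_id = sprintf("tx%04d", g),
        chrom = paste0("chr", ci), strand = strand,
        exon_starts = starts, exon_ends = ends, exon_labels = labels,
        biotype = "protein_coding",
        cds_start = cds_start, cds_end = cds_end)
      rows[[length(rows) + 1L]] <- g
      cursor <- pos + gap
    }
    layout[[ci]] <- cursor + gap
  }
  chrom_sizes <- stats::setNames(as.integer(unlist(layout)),
                                 paste0("chr", seq_len(n_chrom)))
  genome <- vapply(chrom_sizes, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  # stamp splice sites of every internal junction
  for (m in models) {
    n_ex <- length(m$exon_starts)
    if (n_ex < 2L) next
    for (i in seq_len(n_ex - 1L)) {
      donor <- mutate_consensus("donor", config$ss_mismatch_rate)
      acceptor <- mutate_consensus("acceptor", config$ss_mismatch_rate)
      if (m$strand == "+") {
        # donor at end of exon i, acceptor at start of exon i+1
        genome[[m$chrom]] <- write_window(genome[[m$chrom]],
                                          m$exon_ends[i] - 3L, donor, "+")
        genome[[m$chrom]] <- write_window(genome[[m$chrom]],
                                          m$exon_starts[i + 1L] - 20L,
                                          acceptor, "+")
      } else {
        # transcription runs right to left: donor at genomic start of the
        # transcription-earlier exon (i+1 in genomic order)
        genome[[m$chrom]] <- write_window(genome[[m$chrom]],
                                          m$exon_starts[i + 1L] - 6L,
                                          donor, "-")
        genome[[m$chrom]] <- write_window(genome[[m$chrom]],
                                          m$exon_ends[i] - 3L, acceptor, "-")
      }
    }
  }
  list(models = models, genome = genome, chrom_sizes = chrom_sizes)
}

# sample() guard: a length-1 vector is a value, not a range
sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

# n draws from an inclusive integer range, safe for degenerate ranges
sample_range <- function(rng, n) {
  if (rng[1] == rng[2]) rep(rng[1], n)
  else sample(rng[1]:rng[2], n, replace = TRUE)
}

# Sample a peak midpoint for a region of the positional model; returns a
# genomic midpoint coordinate or NA when the gene cannot host the region.
sample_region_midpoint <- function(model, region, width) {
  n_ex <- length(model$exon_starts)
  tr <- transcription_order(model)
  if (region == "exon_body") {
    ok <- which(model$exon_ends - model$exon_starts >= width)
    if (!length(ok)) return(NA_integer_)
    i <- sample1(ok)
    half <- width %/% 2L
    lo <- model$exon_starts[i] + half
    hi <- model$exon_ends[i] - (width - half)
    if (lo > hi) return(NA_integer_)
    return(sample1(lo:hi))
  }
  if (n_ex < 2L) return(NA_integer_)
  if (region == "within_50nt_upstream_of_5ss") {
    # 50 exonic nt abutting a donor site, transcription orientation
    i <- tr[sample1(seq_len(n_ex - 1L))]  # exon with a downstream intron
    w <- min(50L, model$exon_ends[i] - model$exon_starts[i])
    if (model$strand == "+") {
      e <- model$exon_ends[i]
      return(sample1((e - w):(e - 1L)))
    }
    s <- model$exon_starts[i]
    return(sample1(s:(s + w - 1L)))
  }
  if (region == "within_25nt_downstream_of_3ss") {
    # 25 exonic nt after an acceptor site, transcription orientation
    i <- tr[sample1(2:n_ex)]  # exon with an upstream intron
    w <- min(25L, model$exon_ends[i] - model$exon_starts[i])
    if (model$strand == "+") {
      s <- model$exon_starts[i]
      return(sample1(s:(s + w - 1L)))
    }
    e <- model$exon_ends[i]
    return(sample1((e - w):(e - 1L)))
  }
  if (region == "deep_intron") {
    margin <- 100L
    if (n_ex < 2L) return(NA_integer_)
    half <- max(width %/% 2L, width - width %/% 2L)
    cand <- which((model$exon_starts[-1L] - model$exon_ends[-n_ex]) >=
                    2L * margin + width)
    if (!length(cand)) return(NA_integer_)
    i <- sample1(cand)
    lo <- model$exon_ends[i] + margin + half
    hi <- model$exon_starts[i + 1L] - margin - half
    return(if (lo >= hi) lo else sample1(lo:hi))
  }
  stop("unknown region: ", region)
}

#' Simulate replicate eCLIP peak libraries
#'
#' Draws `peaks_per_library` true binding loci by sampling a gene, a region
#' from the positional model, and a cluster width; each replicate library
#' then observes each locus with probability `detect_prob`, shifted by a
#' per-library jitter of up to +/- `jitter` bases. Enrichment statistics are
#' drawn so that roughly `fail_frac` of observed peaks fail the
#' high-confidence filter (p <= 1e-3, fold >= 5).
#'
#' @param annotation result of [simulate_annotation()].
#' @param config a [sim_config()].
#' @return list of per-library peak data.frames (as from [read_peaks()]);
#'   attribute `"truth"` holds the true loci with their planted regions.
#' @export
simulate_peaks <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  models <- annotation$models
  regions <- names(config$positional_model)
  n_true <- config$peaks_per_library
  truth <- data.frame(chrom = character(n_true), start = integer(n_true),
                      end = integer(n_true), strand = character(n_true),
                      region = character(n_true), gene_id = character(n_true),
                      stringsAsFactors = FALSE)
  for (j in seq_len(n_true)) {
    placed <- FALSE
    for (try in seq_len(100L)) {
      m <- models[[sample1(seq_along(models))]]
      region <- sample(regions, 1L, prob = config$positional_model)
      width <- sample1(config$peak_width[1]:config$peak_width[2])
      mid <- sample_region_midpoint(m, region, width)
      if (is.na(mid)) next
      start <- mid - width %/% 2L
      if (start < 0L) next
      truth[j, ] <- list(m$chrom, start, start + width, m$strand, region,
                         m$gene_id)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place a peak after 100 tries; ",
                      "region model incompatible with gene architecture")
  }
  libs <- vector("list", config$n_libraries)
  names(libs) <- sprintf("lib%d", seq_len(config$n_libraries))
  for (l in seq_len(config$n_libraries)) {
    seen <- which(stats::runif(n_true) < config$detect_prob)
    if (!length(seen)) {
      libs[[l]] <- read_peaks_empty(names(libs)[l])
      next
    }
    shift <- if (config$jitter > 0L)
      sample(seq(-config$jitter, config$jitter), length(seen),
             replace = TRUE) else rep(0L, length(seen))
    fails <- stats::runif(length(seen)) < config$fail_frac
    p_fail_side <- stats::runif(length(seen)) < 0.5
    nlp <- ifelse(fails & p_fail_side, stats::runif(length(seen), 0, 2.8),
                  stats::runif(length(seen), 3.2, 8))
    fold <- ifelse(fails & !p_fail_side, stats::runif(length(seen), 0.5, 4.5),
                   stats::runif(length(seen), 5.5, 20))
    pk <- data.frame(
      chrom = truth$chrom[seen],
      start = pmax(0L, truth$start[seen] + shift),
      end = truth$end[seen] + shift,
      name = sprintf("%s_pk%05d", names(libs)[l], seen),
      neg_log10_p = nlp, strand = truth$strand[seen],
      fold_enrichment = fold, library_id = names(libs)[l],
      stringsAsFactors = FALSE)
    libs[[l]] <- pk[order(pk$chrom, pk$start), , drop = FALSE]
    rownames(libs[[l]]) <- NULL
  }
  attr(libs, "truth") <- truth
  libs
}

read_peaks_empty <- function(library_id) {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), neg_log10_p = numeric(), strand = character(),
             fold_enrichment = numeric(), library_id = character(),
             stringsAsFactors = FALSE)
}

#' Simulate IP and size-matched input coverage
#'
#' Input depth is Poisson(`background_rate`) at every base; IP depth is
#' Poisson(`background_rate * enrichment_fold`) under the supplied peaks
#' (on the matching strand) and Poisson(`background_rate`) elsewhere.
#'
#' @param annotation result of [simulate_annotation()].
#' @param peaks BED-like data.frame of true/merged peaks defining where IP
#'   is enriched.
#' @param config a [sim_config()].
#' @return list with elements `ip` and `input`, both `coverage_track`s.
#' @export
simulate_coverage <- function(annotation, peaks, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 202L)
  cs <- annotation$chrom_sizes
  keys <- c(paste0(names(cs), ":+"), paste0(names(cs), ":-"))
  mk <- function(rate_fun) {
    v <- lapply(keys, function(k) {
      ch <- sub(":[+-]$", "", k)
      rate_fun(k, cs[[ch]])
    })
    structure(stats::setNames(v, keys), chrom_sizes = cs,
              class = "coverage_track")
  }
  input <- mk(function(k, L) stats::rpois(L, config$background_rate))
  ip <- mk(function(k, L) {
    lambda <- rep(config$background_rate, L)
    ch <- sub(":[+-]$", "", k)
    st <- sub("^.*:", "", k)
    sel <- peaks$chrom == ch & peaks$strand == st
    for (i in which(sel)) {
      idx <- (peaks$start[i] + 1L):min(peaks$end[i], L)
      lambda[idx] <- config$background_rate * config$enrichment_fold
    }
    stats::rpois(L, lambda)
  })
  list(ip = ip, input = input)
}

#' Simulate an alternative-splicing event table
#'
#' One skipped-exon event per gene carrying an alternative exon. Each event
#' is assigned a planted class by `class_fractions`; condition-1 (WT)
#' replicate PSI values are drawn around a baseline, condition-2 (KO)
#' values around baseline `+ effect_size_dpsi` (enhanced), `-
#' effect_size_dpsi` (repressed) or baseline (unresponsive), all with
#' Gaussian noise `psi_noise_sd` and clipped to \[0,1\]. `delta_psi` is the
#' replicate-mean difference after clipping, so it equals
#' `mean(psi2) - mean(psi1)` by construction. FDR is drawn below 0.05 for
#' responsive events and uniform on (0.05, 1) otherwise.
#'
#' @param annotation result of [simulate_annotation()].
#' @param config a [sim_config()].
#' @return event data.frame (simple dialect, see [read_splice_events()])
#'   with a `planted_class` attribute column kept in `attr(,"truth")`.
#' @export
simulate_events <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303L)
  rows <- list()
  for (m in annotation$models) {
    alt_i <- which(m$exon_labels == "alternative")
    if (!length(alt_i)) next
    alt_i <- alt_i[1L]
    # flanking exons in transcription order
    if (m$strand == "+") { up_i <- alt_i - 1L; down_i <- alt_i + 1L }
    else { up_i <- alt_i + 1L; down_i <- alt_i - 1L }
    cls <- sample(names(config$class_fractions), 1L,
                  prob = config$class_fractions)
    base <- stats::runif(1L, 0.30, 0.60)
    shift <- switch(cls, enhanced = config$effect_size_dpsi,
                    repressed = -config$effect_size_dpsi, unresponsive = 0)
    psi1 <- pmin(1, pmax(0, base + stats::rnorm(config$n_replicates, 0,
                                                config$psi_noise_sd)))
    psi2 <- pmin(1, pmax(0, base + shift +
                           stats::rnorm(config$n_replicates, 0,
                                        config$psi_noise_sd)))
    fdr <- if (cls == "unresponsive") stats::runif(1L, 0.05, 1)
           else stats::runif(1L, 0, 0.049)
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = paste0("ev_", m$gene_id), gene_id = m$gene_id,
      event_type = "SE", chrom = m$chrom, strand = m$strand,
      alt_start = m$exon_starts[alt_i], alt_end = m$exon_ends[alt_i],
      up_start = m$exon_starts[up_i], up_end = m$exon_ends[up_i],
      down_start = m$exon_starts[down_i], down_end = m$exon_ends[down_i],
      psi1 = paste(sprintf("%.17g", psi1), collapse = ","),
      psi2 = paste(sprintf("%.17g", psi2), collapse = ","),
      delta_psi = mean(psi2) - mean(psi1), fdr = fdr,
      planted_class = cls, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  truth <- ev$planted_class
  ev$planted_class <- NULL
  attr(ev, "truth") <- truth
  ev
}

#' Plant peaks at splice sites of selected events
#'
#' Deterministically places one peak per event of the requested class,
#' centred on the chosen splice site of its alternative exon (transcription
#' orientation), with enrichment statistics that pass the high-confidence
#' filter. Used to emulate class-specific positional binding for
#' composite-map recovery.
#'
#' @param events event table with a `responsiveness` (or planted class)
#'   column named by `class_col`.
#' @param class which class of events receives peaks.
#' @param site `"alt_3ss"` (acceptor of the alternative exon) or
#'   `"alt_5ss"` (its donor).
#' @param halfwidth peak half-width in bases around the site.
#' @param class_col column holding the event class.
#' @param library_id label for the emitted peaks.
#' @return peak data.frame.
#' @export
simulate_event_peaks <- function(events, class = "enhanced",
                                 site = c("alt_3ss", "alt_5ss"),
                                 halfwidth = 25L, class_col = "responsiveness",
                                 library_id = "planted") {
  site <- match.arg(site)
  sel <- events[[class_col]] == class
  ev <- events[sel, , drop = FALSE]
  if (!nrow(ev)) return(read_peaks_empty(library_id))
  pos <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (site == "alt_3ss") {
      pos[i] <- if (ev$strand[i] == "+") ev$alt_start[i] else ev$alt_end[i]
    } else {
      pos[i] <- if (ev$strand[i] == "+") ev$alt_end[i] else ev$alt_start[i]
    }
  }
  data.frame(chrom = ev$chrom, start = pmax(0L, pos - halfwidth),
             end = pos + halfwidth,
             name = paste0(library_id, "_", ev$event_id),
             neg_log10_p = 6, strand = ev$strand, fold_enrichment = 10,
             library_id = library_id, stringsAsFactors = FALSE)
}

#' Simulate a gene-GO association fixture with one planted term
#'
#' Every gene receives each of `go_n_terms` background terms independently
#' with probability `go_term_rate`. One extra term (`GO:PLANTED`) is
#' assigned with probability `go_term_rate * go_planted_rr` (capped at 1)
#' inside a designated gene list and `go_term_rate` outside it.
#'
#' @param annotation result of [simulate_annotation()].
#' @param config a [sim_config()].
#' @return list with `associations` (data.frame), `gene_list`,
#'   `planted_term`, and `background` (all gene ids).
#' @export
simulate_go <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  genes <- vapply(annotation$models, `[[`, character(1), "gene_id")
  genes <- unique(genes)
  terms <- sprintf("GO:%07d", seq_len(config$go_n_terms))
  rows <- list()
  for (t in terms) {
    hit <- genes[stats::runif(length(genes)) < config$go_term_rate]
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(gene_id = hit, term_id = t,
                                              stringsAsFactors = FALSE)
    }
  }
  gene_list <- genes[seq_len(min(config$go_list_size, length(genes)))]
  p_in <- min(1, config$go_term_rate * config$go_planted_rr)
  planted <- "GO:PLANTED"
  take <- ifelse(genes %in% gene_list,
                 stats::runif(length(genes)) < p_in,
                 stats::runif(length(genes)) < config$go_term_rate)
  if (any(take)) {
    rows[[length(rows) + 1L]] <- data.frame(gene_id = genes[take],
                                            term_id = planted,
                                            stringsAsFactors = FALSE)
  }
  assoc <- do.call(rbind, rows)
  assoc$term_name <- assoc$term_id
  assoc <- assoc[order(assoc$gene_id, assoc$term_id), , drop = FALSE]
  rownames(assoc) <- NULL
  list(associations = assoc, gene_list = gene_list, planted_term = planted,
       background = genes)
}

#' Simulate protein scores and complex definitions with one planted complex
#'
#' Scores are standard normal; members of the planted complex are shifted
#' upward by `planted_shift` (sd units). Random complexes draw members
#' uniformly from the pool.
#'
#' @param config a [sim_config()].
#' @return list with `scores` (named numeric), `complexes` (data.frame
#'   `complex_id`, `member`) and `planted_complex`.
#' @export
simulate_complexes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 505L)
  prot <- sprintf("P%04d", seq_len(config$n_proteins))
  scores <- stats::setNames(stats::rnorm(config$n_proteins), prot)
  rows <- list()
  for (ci in seq_len(config$n_complexes)) {
    size <- sample1(config$complex_size[1]:config$complex_size[2])
    rows[[ci]] <- data.frame(complex_id = sprintf("C%03d", ci),
                             member = sample(prot, size),
                             stringsAsFactors = FALSE)
  }
  planted_members <- sample(prot, config$planted_complex_size)
  scores[planted_members] <- scores[planted_members] + config$planted_shift
  rows[[length(rows) + 1L]] <- data.frame(complex_id = "C_PLANTED",
                                          member = planted_members,
                                          stringsAsFactors = FALSE)
  complexes <- do.call(rbind, rows)
  rownames(complexes) <- NULL
  list(scores = scores, complexes = complexes, planted_complex = "C_PLANTED")
}

#' Rewrite splice-site windows of selected events with a weaker consensus
#'
#' Mutates the genome so that the chosen splice site of each selected
#' event's alternative exon is re-drawn from the consensus at an elevated
#' per-base mismatch rate (GT/AG preserved). Used to plant weaker splice
#' sites in responsive classes for strength-comparison recovery.
#'
#' @param genome named character vector of chromosome sequences.
#' @param events event table.
#' @param select logical vector (length `nrow(events)`) of events to weaken.
#' @param site `"alt_3ss"` or `"alt_5ss"`.
#' @param mismatch_rate per-base mismatch rate for the weakened sites.
#' @param seed RNG seed for the mutation draws.
#' @return modified genome.
#' @export
weaken_splice_sites <- function(genome, events, select,
                                site = c("alt_3ss", "alt_5ss"),
                                mismatch_rate = 0.3, seed = 0L) {
  site <- match.arg(site)
  set.seed(seed + 707L)
  for (i in which(select)) {
    st <- events$strand[i]
    ch <- events$chrom[i]
    if (site == "alt_3ss") {
      seq <- mutate_consensus("acceptor", mismatch_rate)
      gstart <- if (st == "+") events$alt_start[i] - 20L
                else events$alt_end[i] - 3L
    } else {
      seq <- mutate_consensus("donor", mismatch_rate)
      gstart <- if (st == "+") events$alt_end[i] - 3L
                else events$alt_start[i] - 6L
    }
    genome[[ch]] <- write_window(genome[[ch]], gstart, seq, st)
  }
  genome
}
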