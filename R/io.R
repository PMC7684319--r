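#' Read gene models from a GTF file
#'
#' Parses `gene`/`transcript`/`exon`/`CDS` features of a Gencode-style GTF and
#' returns one [gene_model()] per transcript. GTF coordinates (1-based,
#' closed) are converted to the package's 0-based half-open convention at this
#' boundary. Exons are sorted in genomic order regardless of file order; a CDS
#' span is recorded when CDS features are present.
#'
#' @param path GTF file path.
#' @param exon_labels optional sidecar data.frame (or TSV path) with columns
#'   `transcript_id`, `start`, `end` (0-based half-open, matching exons) and
#'   `label`; exons not listed default to `"constitutive"`.
#' @return list of `gene_model` objects.
#' @export
read_gtf <- function(path, exon_labels = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  tx <- list()
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    if (!length(m)) return(NA_character_)
    sub(paste0(key, ' "([^"]*)"'), "\\1", m)
  }
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) stop("malformed GTF line ", i, " in ", path,
                              " (expected 9 tab-separated fields)")
    type <- f[3L]
    if (!type %in% c("exon", "CDS", "transcript")) next
    start1 <- suppressWarnings(as.integer(f[4L]))
    end1 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start1) || is.na(end1) || start1 > end1) {
      stop("malformed GTF line ", i, ": bad coordinates")
    }
    if (!f[7L] %in% c("+", "-")) stop("malformed GTF line ", i, ": bad strand")
    tid <- get_attr(f[9L], "transcript_id")
    if (is.na(tid)) stop("malformed GTF line ", i, ": no transcript_id")
    if (is.null(tx[[tid]])) {
      bt <- get_attr(f[9L], "transcript_biotype")
      if (is.na(bt)) bt <- get_attr(f[9L], "transcript_type")
      if (is.na(bt)) bt <- get_attr(f[9L], "gene_biotype")
      if (is.na(bt)) bt <- "protein_coding"
      tx[[tid]] <- list(gene_id = get_attr(f[9L], "gene_id"),
                        chrom = f[1L], strand = f[7L], biotype = bt,
                        es = integer(), ee = integer(),
                        cs = integer(), ce = integer())
    }
    if (type == "exon") {
      tx[[tid]]$es <- c(tx[[tid]]$es, start1 - 1L)  # to 0-based half-open
      tx[[tid]]$ee <- c(tx[[tid]]$ee, end1)
    } else if (type == "CDS") {
      tx[[tid]]$cs <- c(tx[[tid]]$cs, start1 - 1L)
      tx[[tid]]$ce <- c(tx[[tid]]$ce, end1)
    }
  }
  if (!is.null(exon_labels)) {
    if (is.character(exon_labels)) {
      exon_labels <- utils::read.delim(exon_labels, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("transcript_id", "start", "end", "label") %in%
                    names(exon_labels)))
  }
  models <- vector("list", length(tx))
  for (k in seq_along(tx)) {
    tid <- names(tx)[k]
    t <- tx[[tid]]
    if (!length(t$es)) stop("transcript '", tid, "' has zero exons")
    labels <- NULL
    if (!is.null(exon_labels)) {
      o <- order(t$es)
      labels <- rep("constitutive", length(t$es))
      side <- exon_labels[exon_labels$transcript_id == tid, , drop = FALSE]
      if (nrow(side)) {
        hit <- match(paste(t$es[o], t$ee[o]), paste(side$start, side$end))
        labels[!is.na(hit)] <- side$label[hit[!is.na(hit)]]
      }
    }
    models[[k]] <- gene_model(
      gene_id = t$gene_id, transcript_id = tid, chrom = t$chrom,
      strand = t$strand, exon_starts = t$es, exon_ends = t$ee,
      biotype = t$biotype, exon_labels = labels,
      cds_start = if (length(t$cs)) min(t$cs) else NA_integer_,
      cds_end = if (length(t$ce)) max(t$ce) else NA_integer_
    )
  }
  models
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gtf()]: emits transcript/exon (and CDS, when present)
#' features with 1-based closed coordinates and Gencode-style attributes.
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  out <- character()
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                     m$gene_id, m$transcript_id, m$biotype)
    out <- c(out, paste(m$chrom, "clipmap", "transcript", m$start + 1L, m$end,
                        ".", m$strand, ".", attrs, sep = "\t"))
    for (i in seq_along(m$exon_starts)) {
      out <- c(out, paste(m$chrom, "clipmap", "exon", m$exon_starts[i] + 1L,
                          m$exon_ends[i], ".", m$strand, ".", attrs, sep = "\t"))
      if (!is.na(m$cds_start)) {
        cs <- max(m$exon_starts[i], m$cds_start)
        ce <- min(m$exon_ends[i], m$cds_end)
        if (cs < ce) {
          out <- c(out, paste(m$chrom, "clipmap", "CDS", cs + 1L, ce,
                              ".", m$strand, "0", attrs, sep = "\t"))
        }
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

# Sidecar exon-label table for a list of models (used with write_gtf so that
# alternative-exon labels survive a round trip through GTF).
exon_label_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(transcript_id = m$transcript_id, start = m$exon_starts,
               end = m$exon_ends, label = m$exon_labels,
               stringsAsFactors = FALSE)
  }))
}

#' Read an eCLIP peak table (BED6+2)
#'
#' Columns: chrom, start, end, name, score (= -log10 p of the IP-vs-input
#' enrichment), strand, fold_enrichment, and optionally raw_p. BED
#' coordinates are already 0-based half-open and are taken as-is.
#'
#' @param path peak file path (tab-separated, no header).
#' @param library_id label attached to every peak (replicate library).
#' @return data.frame with columns `chrom,start,end,name,neg_log10_p,strand,
#'   fold_enrichment,library_id`.
#' @export
read_peaks <- function(path, library_id) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), neg_log10_p = numeric(),
                      strand = character(), fold_enrichment = numeric(),
                      library_id = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (!nrow(raw)) return(empty)
  if (ncol(raw) < 7L) stop("peak file ", path, " has ", ncol(raw),
                           " columns; BED6+2 needs at least 7")
  pk <- raw[, 1:7]
  names(pk) <- c("chrom", "start", "end", "name", "neg_log10_p", "strand",
                 "fold_enrichment")
  pk$library_id <- library_id
  if (any(pk$neg_log10_p < 0)) stop("negative -log10(p) in ", path)
  if (any(pk$fold_enrichment < 0)) stop("negative fold enrichment in ", path)
  check_intervals(pk, what = paste0("peaks (", path, ")"))
  pk
}

#' @rdname read_peaks
#' @param peaks peak data.frame as returned by [read_peaks()].
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(
    peaks[, c("chrom", "start", "end", "name", "neg_log10_p", "strand",
              "fold_enrichment")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Stranded per-base coverage tracks
#'
#' `read_coverage` loads a pair of bedGraph files (one per strand) into dense
#' per-base integer vectors keyed by `chrom:strand`. Overlapping bedGraph
#' records are summed; uncovered bases are 0. With `unstranded = TRUE` a
#' single file is mirrored onto both strands.
#'
#' @param plus_path bedGraph for the `+` strand (or the single unstranded file).
#' @param minus_path bedGraph for the `-` strand; required unless
#'   `unstranded = TRUE`.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param unstranded mirror `plus_path` onto both strands.
#' @return object of class `coverage_track`: list of integer vectors named
#'   `"chrom:+"` / `"chrom:-"` with attribute `chrom_sizes`.
#' @export
read_coverage <- function(plus_path, minus_path = NULL, chrom_sizes,
                          unstranded = FALSE) {
  if (is.null(minus_path) && !unstranded) {
    stop("minus-strand bedGraph missing (pass minus_path or unstranded = TRUE)")
  }
  load_one <- function(p) {
    vecs <- lapply(chrom_sizes, function(L) integer(L))
    if (file.size(p) == 0L) return(vecs)
    bg <- utils::read.table(p, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "depth"))
    for (i in seq_len(nrow(bg))) {
      ch <- bg$chrom[i]
      if (!ch %in% names(vecs)) stop("unknown chromosome '", ch, "' in ", p)
      if (bg$end[i] > chrom_sizes[[ch]]) {
        stop("record beyond chromosome length in ", p, ": ", ch, ":",
             bg$start[i], "-", bg$end[i])
      }
      idx <- (bg$start[i] + 1L):bg$end[i]
      vecs[[ch]][idx] <- vecs[[ch]][idx] + bg$depth[i]
    }
    vecs
  }
  plus <- load_one(plus_path)
  minus <- if (unstranded) plus else load_one(minus_path)
  track <- c(stats::setNames(plus, paste0(names(plus), ":+")),
             stats::setNames(minus, paste0(names(minus), ":-")))
  structure(track, chrom_sizes = chrom_sizes, class = "coverage_track")
}

#' @rdname read_coverage
#' @param track a `coverage_track`.
#' @param plus_path,minus_path output bedGraph paths.
#' @export
write_coverage <- function(track, plus_path, minus_path) {
  emit <- function(strand, path) {
    keys <- grep(paste0(":", strand, "$"), names(track), value = TRUE,
                 fixed = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    for (k in sort(keys)) {
      ch <- sub(":[+-]$", "", k)
      r <- rle(track[[k]])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      nz <- r$values != 0L
      if (any(nz)) {
        writeLines(paste(ch, starts[nz], ends[nz], r$values[nz], sep = "\t"),
                   con)
      }
    }
  }
  emit("\\+", plus_path)
  emit("-", minus_path)
  invisible(c(plus_path, minus_path))
}

# Total depth of a track (used by conservation checks).
coverage_total <- function(track) sum(vapply(track, sum, numeric(1)))

#' Read alternative-splicing event tables
#'
#' Unifies rMATS per-type output and a documented simple TSV into one event
#' table. `delta_psi` is always recomputed as `mean(PSI condition 2) -
#' mean(PSI condition 1)` (e.g. knockout minus wild type) and cross-checked
#' against the file's own value within 1e-6 when one is present (for the
#' rMATS dialect the file's `IncLevelDifference` is `mean1 - mean2`, so the
#' check is against its negation).
#'
#' Simple dialect columns: `event_id, gene_id, event_type, chrom, strand,
#' alt_start, alt_end, up_start, up_end, down_start, down_end, psi1, psi2,
#' delta_psi, fdr` with comma-separated replicate PSI lists; up/down are the
#' flanking constitutive exons in transcription order. The `majiq` dialect is
#' accepted as an alias of `simple` (LSVs reduced to binary events upstream).
#'
#' @param path event table path (tab-separated with header).
#' @param dialect one of `"simple"`, `"rmats"`, `"majiq"`.
#' @param event_type for `rmats` files, the event type of the file
#'   (`SE`, `MXE`, `A5SS`, `A3SS`, `RI`); rMATS writes one file per type.
#' @return data.frame of events (one row each) with the simple-dialect
#'   columns; MXE second exons are kept in `mxe2_start`/`mxe2_end`.
#' @export
read_splice_events <- function(path, dialect = c("simple", "rmats", "majiq"),
                               event_type = "SE") {
  dialect <- match.arg(dialect)
  if (dialect == "majiq") dialect <- "simple"
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "simple") {
    ev <- tab
    need <- c("event_id", "gene_id", "event_type", "chrom", "strand",
              "alt_start", "alt_end", "up_start", "up_end", "down_start",
              "down_end", "psi1", "psi2", "fdr")
    miss <- setdiff(need, names(ev))
    if (length(miss)) stop("simple events TSV missing columns: ",
                           paste(miss, collapse = ", "))
    file_dpsi <- if ("delta_psi" %in% names(ev)) ev$delta_psi else NULL
  } else {
    stopifnot(event_type %in% c("SE", "MXE", "A5SS", "A3SS", "RI"))
    coords <- switch(event_type,
      SE = list(alt = c("exonStart_0base", "exonEnd"),
                up = c("upstreamES", "upstreamEE"),
                down = c("downstreamES", "downstreamEE")),
      MXE = list(alt = c("1stExonStart_0base", "1stExonEnd"),
                 up = c("upstreamES", "upstreamEE"),
                 down = c("downstreamES", "downstreamEE"),
                 mxe2 = c("2ndExonStart_0base", "2ndExonEnd")),
      A5SS = list(alt = c("longExonStart_0base", "longExonEnd"),
                  up = c("shortES", "shortEE"),
                  down = c("flankingES", "flankingEE")),
      A3SS = list(alt = c("longExonStart_0base", "longExonEnd"),
                  up = c("flankingES", "flankingEE"),
                  down = c("shortES", "shortEE")),
      RI = list(alt = c("riExonStart_0base", "riExonEnd"),
                up = c("upstreamES", "upstreamEE"),
                down = c("downstreamES", "downstreamEE")))
    ev <- data.frame(
      event_id = paste0(event_type, "_", tab$ID),
      gene_id = tab$GeneID, event_type = event_type,
      chrom = tab$chr, strand = tab$strand,
      alt_start = tab[[coords$alt[1]]], alt_end = tab[[coords$alt[2]]],
      up_start = tab[[coords$up[1]]], up_end = tab[[coords$up[2]]],
      down_start = tab[[coords$down[1]]], down_end = tab[[coords$down[2]]],
      psi1 = tab$IncLevel1, psi2 = tab$IncLevel2, fdr = tab$FDR,
      stringsAsFactors = FALSE)
    if (event_type == "RI") {
      # retained-intron interval, not the spanning exon
      ev$alt_start <- ev$up_end
      ev$alt_end <- ev$down_start
    }
    if (event_type == "MXE") {
      ev$mxe2_start <- tab[[coords$mxe2[1]]]
      ev$mxe2_end <- tab[[coords$mxe2[2]]]
    }
    file_dpsi <- if ("IncLevelDifference" %in% names(tab))
      -tab$IncLevelDifference else NULL
  }
  p1 <- parse_psi(ev$psi1)
  p2 <- parse_psi(ev$psi2)
  bad <- vapply(c(p1, p2), function(v) any(v < 0 | v > 1), logical(1))
  if (any(bad)) stop("PSI value outside [0,1] in ", path)
  ev$delta_psi <- vapply(seq_len(nrow(ev)),
                         function(i) mean(p2[[i]]) - mean(p1[[i]]), numeric(1))
  if (!is.null(file_dpsi)) {
    off <- abs(ev$delta_psi - file_dpsi)
    if (any(off > 1e-6 + 1e-9, na.rm = TRUE)) {
      stop("delta_psi in file disagrees with recomputed mean difference ",
           "(max |diff| = ", format(max(off, na.rm = TRUE)), ") in ", path)
    }
  }
  if (any(ev$fdr < 0 | ev$fdr > 1)) stop("FDR outside [0,1] in ", path)
  if (any(overlap_len(ev$alt_start, ev$alt_end, ev$up_start, ev$up_end) > 0) ||
      any(overlap_len(ev$alt_start, ev$alt_end, ev$down_start, ev$down_end) > 0)) {
    stop("flanking exon overlaps alternative segment in ", path)
  }
  ev
}

# Comma-separated replicate PSI strings -> list of numeric vectors.
parse_psi <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) as.numeric(v))
}

#' @rdname read_splice_events
#' @param events event data.frame (simple-dialect columns).
#' @export
write_splice_events <- function(events, path) {
  cols <- c("event_id", "gene_id", "event_type", "chrom", "strand",
            "alt_start", "alt_end", "up_start", "up_end", "down_start",
            "down_end", "psi1", "psi2", "delta_psi", "fdr")
  extra <- intersect(c("mxe2_start", "mxe2_end"), names(events))
  utils::write.table(events[, c(cols, extra)], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GO annotation file (GAF 2.x)
#'
#' Keeps the DB object symbol (column 3) as `gene_id` and the GO ID
#' (column 5) as `term_id`; duplicate (gene, term) pairs are collapsed.
#' GAF carries no term names, so `term_name` falls back to the term ID
#' unless a names map is supplied.
#'
#' @param path GAF path (`!` comment lines ignored).
#' @param term_names optional named character vector `term_id -> name`.
#' @return data.frame with `gene_id`, `term_id`, `term_name`.
#' @export
read_gaf <- function(path, term_names = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(gene_id = character(), term_id = character(),
                      term_name = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 15L)) {
    stop("GAF line with ", min(nf), " columns (need >= 15): line ",
         which(nf < 15L)[1L])
  }
  assoc <- data.frame(
    gene_id = vapply(parts, `[[`, character(1), 3L),
    term_id = vapply(parts, `[[`, character(1), 5L),
    stringsAsFactors = FALSE)
  assoc <- unique(assoc)
  assoc$term_name <- if (is.null(term_names)) assoc$term_id else {
    nm <- term_names[assoc$term_id]
    ifelse(is.na(nm), assoc$term_id, nm)
  }
  assoc[order(assoc$gene_id, assoc$term_id), , drop = FALSE]
}

#' @rdname read_gaf
#' @param associations data.frame with `gene_id`, `term_id`.
#' @export
write_gaf <- function(associations, path) {
  a <- unique(associations[, c("gene_id", "term_id")])
  a <- a[order(a$gene_id, a$term_id), , drop = FALSE]
  lines <- vapply(seq_len(nrow(a)), function(i) {
    f <- rep("", 17L)
    f[1] <- "CLIPMAP"; f[2] <- a$gene_id[i]; f[3] <- a$gene_id[i]
    f[5] <- a$term_id[i]; f[7] <- "IDA"; f[9] <- "P"; f[12] <- "gene"
    f[13] <- "taxon:10090"; f[14] <- "20200101"; f[15] <- "CLIPMAP"
    paste(f, collapse = "\t")
  }, character(1))
  writeLines(c("!gaf-version: 2.1", lines), path)
  invisible(path)
}

#' Deterministic TSV writer
#'
#' Writes a data.frame as a sorted, header-bearing TSV (rows ordered by all
#' columns left to right) so repeated runs are byte-identical.
#'
#' @param records data.frame.
#' @param path output path.
#' @param sort sort rows before writing (default TRUE).
#' @export
write_table <- function(records, path, sort = TRUE) {
  if (sort && nrow(records) > 1L) {
    keys <- lapply(records, function(col) if (is.list(col)) NULL else col)
    keys <- Filter(Negate(is.null), keys)
    if (length(keys)) records <- records[do.call(order, unname(keys)), ,
                                         drop = FALSE]
  }
  flat <- records
  for (j in seq_along(flat)) {
    if (is.list(flat[[j]])) {
      flat[[j]] <- vapply(flat[[j]], function(v) paste(unlist(v),
                                                       collapse = ","),
                          character(1))
    }
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write genome FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as a named character
#' vector (one entry per chromosome) to match the package's plain containers.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_genome_fasta
#' @param genome named character vector of chromosome sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}
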