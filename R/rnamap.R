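#' Select splice-site boundaries informed by peaks
#'
#' For each peak (on its host transcript, chosen by the
#' longest-protein-coding rule) the selected boundaries are the union of:
#' (1) every exon-intron or intron-exon boundary covered by at least one
#' peak base, and (2) for each peak terminal, the nearest boundary in that
#' direction not covered by the peak. A peak reaching from inside exon 3 to
#' inside intron 4 of a six-exon gene therefore contributes the five
#' boundaries intron2|exon3 through intron4|exon5. Duplicates are removed;
#' peaks overlapping no transcript are skipped and counted in the
#' `"n_skipped"` attribute.
#'
#' @param merged_peaks BED-like peak data.frame.
#' @param gene_models list of `gene_model`s.
#' @return data.frame of boundaries: `kind` (`exon_intron` = 5'ss,
#'   `intron_exon` = 3'ss), `pos` (0-based junction coordinate), `chrom`,
#'   `strand`, `gene_id`, `transcript_id`.
#' @export
select_boundaries <- function(merged_peaks, gene_models) {
  check_intervals(merged_peaks, "peaks")
  acc <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(merged_peaks))) {
    s <- merged_peaks$start[i]
    e <- merged_peaks$end[i]
    host <- choose_host_model(merged_peaks$chrom[i], s, e,
                              merged_peaks$strand[i], gene_models)
    if (is.null(host)) { n_skipped <- n_skipped + 1L; next }
    b <- model_boundaries(host)
    if (!nrow(b)) next
    covered <- b$pos > s & b$pos < e
    take <- covered
    left <- which(b$pos <= s)
    if (length(left)) take[left[which.max(b$pos[left])]] <- TRUE
    right <- which(b$pos >= e)
    if (length(right)) take[right[which.min(b$pos[right])]] <- TRUE
    if (any(take)) acc[[length(acc) + 1L]] <- b[take, , drop = FALSE]
  }
  if (!length(acc)) {
    out <- model_boundaries(gene_model("g", "t", "chr0", "+", 0L, 1L))[0, ]
  } else {
    out <- unique(do.call(rbind, acc))
    out <- out[order(out$chrom, out$pos, out$kind), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (n_skipped) {
    message("select_boundaries: ", n_skipped,
            " peak(s) overlapped no transcript and were skipped")
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Input-normalised metagene density around splice sites
#'
#' Sums per-base IP and input depth over a window around each boundary in
#' transcription orientation (minus-strand windows are reversed before
#' aggregation) and reports the per-offset relative density
#' `(IP + eps) / (input + eps)`. Windows reach `exon_window` bases into the
#' exon and `intron_window` bases into the intron; positions truncated at
#' chromosome ends contribute only their defined offsets.
#'
#' Offset conventions: for 5' splice sites, offset 0 is the first intronic
#' base and negative offsets are exonic; for 3' splice sites, offset 0 is
#' the first exonic base and negative offsets are intronic.
#'
#' @param boundaries output of [select_boundaries()].
#' @param ip_track,input_track `coverage_track`s for IP and size-matched
#'   input.
#' @param exon_window,intron_window window sizes in bases (defaults 100 and
#'   300).
#' @param epsilon pseudocount applied to both numerator and denominator.
#' @return list with elements `five_prime` and `three_prime`, each a
#'   `boundary_profile`: offsets, summed `ip`/`input` counts, per-offset
#'   `relative_density`, and the number of contributing boundaries.
#' @export
boundary_density <- function(boundaries, ip_track, input_track,
                             exon_window = 100L, intron_window = 300L,
                             epsilon = 1.0) {
  if (!nrow(boundaries)) stop("no boundaries supplied")
  profile_for <- function(kind) {
    b <- boundaries[boundaries$kind == kind, , drop = FALSE]
    offs <- if (kind == "exon_intron") seq(-exon_window, intron_window - 1L)
            else seq(-intron_window, exon_window - 1L)
    ip_sum <- numeric(length(offs))
    in_sum <- numeric(length(offs))
    for (i in seq_len(nrow(b))) {
      key <- paste0(b$chrom[i], ":", b$strand[i])
      ipv <- ip_track[[key]]
      inv <- input_track[[key]]
      if (is.null(ipv) || is.null(inv)) {
        stop("coverage track missing for ", key)
      }
      idx <- if (b$strand[i] == "+") b$pos[i] + offs else b$pos[i] - 1L - offs
      ok <- idx >= 0L & idx < length(ipv)
      ip_sum[ok] <- ip_sum[ok] + ipv[idx[ok] + 1L]
      in_sum[ok] <- in_sum[ok] + inv[idx[ok] + 1L]
    }
    structure(list(kind = kind, offsets = offs, ip = ip_sum, input = in_sum,
                   relative_density = (ip_sum + epsilon) / (in_sum + epsilon),
                   n_boundaries = nrow(b), epsilon = epsilon),
              class = "boundary_profile")
  }
  list(five_prime = profile_for("exon_intron"),
       three_prime = profile_for("intron_exon"))
}

#' @export
print.boundary_profile <- function(x, ...) {
  side <- if (x$kind == "exon_intron") "5' splice site" else "3' splice site"
  cat(sprintf("<boundary_profile> %s, %d boundaries, offsets %d..%d\n",
              side, x$n_boundaries, min(x$offsets), max(x$offsets)))
  cat(sprintf("  max relative density %.3f at offset %d\n",
              max(x$relative_density),
              x$offsets[which.max(x$relative_density)]))
  invisible(x)
}

#' @export
plot.boundary_profile <- function(x, ...) {
  side <- if (x$kind == "exon_intron") "5'ss" else "3'ss"
  plot(x$offsets, x$relative_density, type = "l",
       xlab = paste("offset from", side, "(nt, transcription orientation)"),
       ylab = "relative density (IP / input)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  invisible(x)
}

#' @rdname boundary_density
#' @param profile a `boundary_profile`.
#' @export
profile_table <- function(profile) {
  data.frame(kind = profile$kind, offset = profile$offsets,
             ip = profile$ip, input = profile$input,
             relative_density = profile$relative_density)
}

#' Class-stratified composite occupancy maps
#'
#' For every event, the window from the 5' splice site of its upstream
#' constitutive exon to the 3' splice site of its downstream constitutive
#' exon (transcription orientation, boundary to boundary) is divided into
#' `n_bins` equal-width bins; a bin is occupied for the event when at least
#' one peak base falls in it. Occupancy of a bin is the fraction of the
#' class's usable events occupying it. `bin_mode = "fixed100bp"` instead
#' uses 100-bp bins anchored at the upstream boundary, with per-bin
#' denominators counting only events whose window reaches the bin.
#'
#' @param merged_peaks BED-like peak data.frame.
#' @param events event table carrying the class column.
#' @param n_bins number of fractional bins (default 100).
#' @param bin_mode `"fractional"` or `"fixed100bp"`.
#' @param weight `"binary"` (default: occupied or not) or `"coverage"`
#'   (fraction of bin bases covered).
#' @param class_col events column holding class labels.
#' @return list of `composite_map` objects, one per class present.
#' @export
composite_map <- function(merged_peaks, events, n_bins = 100L,
                          bin_mode = c("fractional", "fixed100bp"),
                          weight = c("binary", "coverage"),
                          class_col = "responsiveness") {
  bin_mode <- match.arg(bin_mode)
  weight <- match.arg(weight)
  check_intervals(merged_peaks, "peaks")
  stopifnot(class_col %in% names(events))
  classes <- unique(events[[class_col]])
  lapply(stats::setNames(classes, classes), function(cls) {
    ev <- events[events[[class_col]] == cls, , drop = FALSE]
    n_skip <- 0L
    per_event <- list()
    max_bins <- if (bin_mode == "fractional") n_bins else 0L
    for (i in seq_len(nrow(ev))) {
      if (ev$strand[i] == "+") {
        ws <- ev$up_end[i]; we <- ev$down_start[i]
      } else {
        ws <- ev$down_end[i]; we <- ev$up_start[i]
      }
      width <- we - ws
      if (width <= 0L || (bin_mode == "fractional" && width < n_bins)) {
        n_skip <- n_skip + 1L
        next
      }
      nb <- if (bin_mode == "fractional") n_bins else ceiling(width / 100L)
      max_bins <- max(max_bins, nb)
      cover <- numeric(nb)
      sel <- merged_peaks$chrom == ev$chrom[i] &
        merged_peaks$strand == ev$strand[i] &
        merged_peaks$start < we & merged_peaks$end > ws
      for (p in which(sel)) {
        os <- max(merged_peaks$start[p], ws)
        oe <- min(merged_peaks$end[p], we)
        # transcription coordinates within the window
        if (ev$strand[i] == "+") { t0 <- os - ws; t1 <- oe - ws }
        else { t0 <- we - oe; t1 <- we - os }
        if (bin_mode == "fractional") {
          k0 <- (t0 * n_bins) %/% width
          k1 <- ((t1 - 1L) * n_bins) %/% width
          for (k in k0:k1) {
            b_lo <- (k * width) %/% n_bins
            b_hi <- ((k + 1L) * width) %/% n_bins
            ov <- min(t1, b_hi) - max(t0, b_lo)
            if (ov > 0L) cover[k + 1L] <- cover[k + 1L] + ov
          }
        } else {
          k0 <- t0 %/% 100L
          k1 <- (t1 - 1L) %/% 100L
          for (k in k0:k1) {
            ov <- min(t1, (k + 1L) * 100L) - max(t0, k * 100L)
            if (ov > 0L) cover[k + 1L] <- cover[k + 1L] + ov
          }
        }
      }
      widths <- if (bin_mode == "fractional") {
        diff((seq_len(n_bins + 1L) - 1L) * width %/% n_bins)
      } else {
        w <- rep(100L, nb); w[nb] <- width - (nb - 1L) * 100L; w
      }
      per_event[[length(per_event) + 1L]] <-
        if (weight == "binary") as.numeric(cover > 0)
        else pmin(1, cover / widths)
    }
    n_used <- length(per_event)
    occ <- numeric(max_bins)
    den <- numeric(max_bins)
    for (v in per_event) {
      occ[seq_along(v)] <- occ[seq_along(v)] + v
      den[seq_along(v)] <- den[seq_along(v)] + 1
    }
    occupancy <- ifelse(den > 0, occ / den, NA_real_)
    if (bin_mode == "fractional") occupancy <- occupancy[seq_len(n_bins)]
    structure(list(event_class = cls, n_bins = length(occupancy),
                   occupancy = occupancy, n_events = n_used,
                   n_skipped = n_skip, bin_mode = bin_mode, weight = weight),
              class = "composite_map")
  })
}

#' @export
print.composite_map <- function(x, ...) {
  cat(sprintf("<composite_map> class=%s, %d events (%d skipped), %d %s bins\n",
              x$event_class, x$n_events, x$n_skipped, x$n_bins, x$bin_mode))
  if (any(is.finite(x$occupancy))) {
    cat(sprintf("  max occupancy %.3f at bin %d\n", max(x$occupancy, na.rm = TRUE),
                which.max(x$occupancy)))
  }
  invisible(x)
}

#' @export
plot.composite_map <- function(x, ...) {
  plot(seq_len(x$n_bins), x$occupancy, type = "h",
       xlab = "bin (upstream 5'ss -> downstream 3'ss)",
       ylab = "occupancy (fraction of events)",
       main = paste("class:", x$event_class), ...)
  invisible(x)
}

#' Replicate reproducibility of coverage tracks
#'
#' Collects all positions where read depth exceeds `min_depth` in both
#' tracks and reports the Pearson correlation of the log2 depths.
#'
#' @param track_a,track_b `coverage_track`s over the same chromosomes.
#' @param min_depth depth must be strictly greater in both tracks
#'   (default 3).
#' @return list with `r` (Pearson correlation of log2 depths) and
#'   `n_positions`.
#' @export
replicate_correlation <- function(track_a, track_b, min_depth = 3L) {
  keys <- intersect(names(track_a), names(track_b))
  if (!length(keys)) stop("tracks share no chromosome:strand keys")
  a <- numeric()
  b <- numeric()
  for (k in keys) {
    va <- track_a[[k]]
    vb <- track_b[[k]]
    L <- min(length(va), length(vb))
    sel <- va[seq_len(L)] > min_depth & vb[seq_len(L)] > min_depth
    a <- c(a, va[seq_len(L)][sel])
    b <- c(b, vb[seq_len(L)][sel])
  }
  if (length(a) < 3L) {
    stop("fewer than 3 positions pass the depth filter; correlation undefined")
  }
  list(r = stats::cor(log2(a), log2(b)), n_positions = length(a))
}
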