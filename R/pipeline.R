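#' Default pipeline parameters
#'
#' Every analysis threshold with its default: high-confidence filter
#' p <= 1e-3 and fold >= 5, 2-of-4 replicate support, 100 nt exon / 300 nt
#' intron metagene windows, 100 composite bins, 300 nt constitutive-exon
#' flank, |delta PSI| > 0.1 with FDR < 0.05, 1000 permutations with the
#' 5.012e-2 ranked-curve cutoff.
#'
#' @return named list of defaults; override entries via the `params`
#'   element of the [run_pipeline()] config.
#' @export
pipeline_defaults <- function() {
  list(p_threshold = 1e-3, fold_threshold = 5, fold_strict = FALSE,
       min_support = 2L, min_overlap_bp = 1L,
       exon_window = 100L, intron_window = 300L, epsilon = 1.0,
       n_bins = 100L, bin_mode = "fractional",
       flank_nt = 300L, dpsi_threshold = 0.1, fdr_threshold = 0.05,
       min_term_size = 5L, n_perm = 1000L, cutoff_p = 5.012e-2,
       min_depth = 3L)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate-or-load, high-confidence filtering, consensus
#' merging, genic annotation, boundary selection, metagene density,
#' event classification, composite maps, peak-event intersection and GO /
#' complex enrichment, writing each stage's table to `out_dir` and an
#' append-only manifest listing every output with the seed and parameters.
#' Identical config and seed give byte-identical outputs.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   * `sim`: arguments for [sim_config()] (simulate mode), or
#'   * `inputs`: paths (`gtf`, `exon_labels`, `peaks` = named vector of
#'     per-library BED6+2 files, `coverage` = list with `ip_plus`,
#'     `ip_minus`, `input_plus`, `input_minus`, `chrom_sizes` 2-column TSV,
#'     `events`, `gaf`); stages whose inputs are absent are skipped with a
#'     notice;
#'   * `params`: overrides of [pipeline_defaults()];
#'   * `out_dir`: output directory.
#' @param out_dir overrides `config$out_dir`.
#' @return (invisibly) the manifest data.frame.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir missing")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  manifest <- list()
  note <- function(stage, msg) message("[", stage, "] ", msg)
  emit <- function(stage, name, tab, sort = TRUE) {
    path <- file.path(out_dir, name)
    write_table(tab, path, sort = sort)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = name, stage = stage, n_rows = nrow(tab),
      stringsAsFactors = FALSE)
    note(stage, paste0("wrote ", name, " (", nrow(tab), " rows)"))
  }

  models <- NULL; genome <- NULL; chrom_sizes <- NULL
  peak_libs <- NULL; ip <- NULL; input <- NULL; events <- NULL
  go_data <- NULL; cx_data <- NULL; seed <- NA_integer_

  if (!is.null(config$sim)) {
    cfg <- do.call(sim_config, config$sim)
    seed <- cfg$seed
    note("simulate", paste0("generating synthetic inputs (seed ", seed, ")"))
    ann <- simulate_annotation(cfg)
    models <- ann$models; genome <- ann$genome; chrom_sizes <- ann$chrom_sizes
    peak_libs <- simulate_peaks(ann, cfg)
    truth <- attr(peak_libs, "truth")
    ip_in <- simulate_coverage(ann, truth, cfg)
    ip <- ip_in$ip; input <- ip_in$input
    events <- simulate_events(ann, cfg)
    go_data <- simulate_go(ann, cfg)
    cx_data <- simulate_complexes(cfg)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (!is.null(inp$gtf)) {
      models <- read_gtf(inp$gtf, exon_labels = inp$exon_labels)
      note("load", paste0("loaded ", length(models), " transcripts"))
    }
    if (!is.null(inp$peaks)) {
      peak_libs <- lapply(names(inp$peaks), function(lib) {
        read_peaks(inp$peaks[[lib]], lib)
      })
      names(peak_libs) <- names(inp$peaks)
    }
    if (!is.null(inp$coverage)) {
      cs <- utils::read.table(inp$coverage$chrom_sizes, sep = "\t",
                              col.names = c("chrom", "size"),
                              stringsAsFactors = FALSE)
      chrom_sizes <- stats::setNames(cs$size, cs$chrom)
      ip <- read_coverage(inp$coverage$ip_plus, inp$coverage$ip_minus,
                          chrom_sizes)
      input <- read_coverage(inp$coverage$input_plus,
                             inp$coverage$input_minus, chrom_sizes)
    }
    if (!is.null(inp$events)) {
      events <- read_splice_events(inp$events,
                                   dialect = inp$events_dialect %||% "simple")
    }
    if (!is.null(inp$gaf)) {
      go_data <- list(associations = read_gaf(inp$gaf))
    }
  } else {
    stop("config error: provide either 'sim' or 'inputs'")
  }

  # --- peaks ---------------------------------------------------------------
  merged <- NULL
  if (!is.null(peak_libs)) {
    filtered <- lapply(peak_libs, filter_high_confidence,
                       p_threshold = params$p_threshold,
                       fold_threshold = params$fold_threshold,
                       fold_strict = params$fold_strict)
    n_in <- sum(vapply(peak_libs, nrow, integer(1)))
    n_keep <- sum(vapply(filtered, nrow, integer(1)))
    note("filter", paste0(n_keep, "/", n_in, " peaks pass p<=",
                          params$p_threshold, ", fold>=",
                          params$fold_threshold))
    merged <- merge_replicate_peaks(filtered,
                                    min_support = params$min_support,
                                    min_overlap_bp = params$min_overlap_bp)
    emit("merge", "merged_peaks.tsv",
         merged[, c("chrom", "start", "end", "strand", "support", "n_peaks")])
    if (!is.null(models)) {
      annotated <- annotate_peaks(merged, models)
      emit("annotate", "peak_annotation.tsv", annotated)
      emit("annotate", "genic_categories.tsv", genic_category_table(annotated))
    } else {
      note("annotate", "skipped: no gene annotation supplied")
    }
  } else {
    note("peaks", "skipped: no peak libraries supplied")
  }

  # --- RNA map -------------------------------------------------------------
  if (!is.null(merged) && !is.null(models) && !is.null(ip)) {
    boundaries <- select_boundaries(merged, models)
    emit("rnamap", "boundaries.tsv", boundaries)
    prof <- boundary_density(boundaries, ip, input,
                             exon_window = params$exon_window,
                             intron_window = params$intron_window,
                             epsilon = params$epsilon)
    emit("rnamap", "density_5ss.tsv", profile_table(prof$five_prime),
         sort = FALSE)
    emit("rnamap", "density_3ss.tsv", profile_table(prof$three_prime),
         sort = FALSE)
  } else {
    note("rnamap", "skipped: needs merged peaks, annotation and coverage")
  }

  # --- splicing ------------------------------------------------------------
  classified <- NULL
  if (!is.null(events)) {
    classified <- classify_events(events,
                                  dpsi_threshold = params$dpsi_threshold,
                                  fdr_threshold = params$fdr_threshold)
    emit("classify", "classified_events.tsv", classified)
    emit("classify", "class_proportions.tsv",
         class_proportions(classified, by = "responsiveness"))
    emit("classify", "type_proportions.tsv",
         class_proportions(classified, by = "event_type"))
    if (!is.null(merged)) {
      maps <- composite_map(merged, classified, n_bins = params$n_bins,
                            bin_mode = params$bin_mode)
      comp <- do.call(rbind, lapply(maps, function(m) {
        data.frame(event_class = m$event_class, bin = seq_len(m$n_bins),
                   occupancy = m$occupancy, n_events = m$n_events,
                   stringsAsFactors = FALSE)
      }))
      emit("composite", "composite_maps.tsv", comp, sort = FALSE)
    }
    if (!is.null(merged) && !is.null(models)) {
      ixn <- intersect_peaks_events(merged, models, events,
                                    flank_nt = params$flank_nt)
      emit("intersect", "peak_event_association.tsv", ixn$per_peak)
      emit("intersect", "peak_event_counts.tsv",
           cbind(ixn$counts, ixn$genes$summary))
    }
  } else {
    note("splice", "skipped: no event table supplied")
  }

  # --- enrichment ----------------------------------------------------------
  if (!is.null(go_data) && !is.null(classified)) {
    bg <- go_data$background %||% unique(go_data$associations$gene_id)
    responsive <- unique(classified$gene_id[
      classified$responsiveness != "unresponsive"])
    responsive <- intersect(responsive, bg)
    if (length(responsive) >= 2L) {
      go_res <- go_enrichment(responsive, bg, go_data$associations,
                              min_term_size = params$min_term_size)
      emit("go", "go_enrichment.tsv", go_res, sort = FALSE)
    } else {
      note("go", "skipped: fewer than 2 responsive genes in background")
    }
  } else {
    note("go", "skipped: needs associations and classified events")
  }
  if (!is.null(cx_data)) {
    cx_res <- complex_enrichment(cx_data$scores, cx_data$complexes,
                                 n_perm = params$n_perm,
                                 seed = (if (is.na(seed)) 1L else seed) + 11L,
                                 cutoff_p = params$cutoff_p)
    emit("complex", "complex_enrichment.tsv", cx_res, sort = FALSE)
  }

  mani <- do.call(rbind, manifest)
  mani$seed <- seed
  write_table(mani, file.path(out_dir, "manifest.tsv"), sort = FALSE)
  param_lines <- paste0(names(params), "\t",
                        vapply(params, function(v) paste(v, collapse = ","),
                               character(1)))
  writeLines(c("parameter\tvalue", param_lines),
             file.path(out_dir, "parameters.tsv"))
  invisible(mani)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
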