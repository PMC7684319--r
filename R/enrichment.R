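#' Chi-squared GO enrichment with Bonferroni correction
#'
#' For every term annotated to at least `min_term_size` background genes,
#' builds the 2x2 table of list membership against term membership over the
#' background universe and applies a chi-squared test (df = 1, no
#' continuity correction). Terms with a degenerate margin (annotated to
#' all or none of the background) are skipped and counted. Bonferroni
#' multiplies raw p by the number of tested terms, capped at 1.
#'
#' @param gene_list character vector, a subset of `background`.
#' @param background character vector of all candidate genes.
#' @param associations data.frame with `gene_id`, `term_id` (and optional
#'   `term_name`), as from [read_gaf()].
#' @param min_term_size minimum background genes per tested term.
#' @return data.frame sorted by raw p: term, counts, chi-squared statistic,
#'   `p_raw`, `p_bonferroni`; attribute `"n_skipped_degenerate"`.
#' @export
go_enrichment <- function(gene_list, background, associations,
                          min_term_size = 5L) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  if (!length(gene_list) || !length(background)) {
    stop("empty gene list or background")
  }
  if (!all(gene_list %in% background)) {
    stop("gene_list must be a subset of background")
  }
  assoc <- associations[associations$gene_id %in% background, , drop = FALSE]
  terms <- split(assoc$gene_id, assoc$term_id)
  terms <- terms[lengths(lapply(terms, unique)) >= min_term_size]
  n_list <- length(gene_list)
  n_bg <- length(background)
  rows <- list()
  n_skipped <- 0L
  for (t in names(terms)) {
    with_term <- unique(terms[[t]])
    k_bg <- length(with_term)
    k_list <- sum(gene_list %in% with_term)
    if (k_bg == 0L || k_bg == n_bg) { n_skipped <- n_skipped + 1L; next }
    tab <- matrix(c(k_list, n_list - k_list,
                    k_bg - k_list, n_bg - n_list - (k_bg - k_list)),
                  nrow = 2)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    nm <- if ("term_name" %in% names(assoc)) {
      assoc$term_name[match(t, assoc$term_id)]
    } else t
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = t, term_name = nm, k_list = k_list, n_list = n_list,
      k_bg = k_bg, n_bg = n_bg, chi2_stat = unname(ht$statistic),
      p_raw = ht$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      k_list = integer(), n_list = integer(),
                      k_bg = integer(), n_bg = integer(),
                      chi2_stat = numeric(), p_raw = numeric(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_skipped_degenerate") <- n_skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_degenerate") <- n_skipped
  out
}

#' Permutation-based protein-complex enrichment
#'
#' Scores each complex of at least `min_members` members as the unweighted
#' mean of its members' scores (members absent from the data contribute
#' the background minimum and are counted), then compares the observed
#' score against `n_perm` random same-size member sets drawn from all
#' scored proteins. The empirical p-value uses add-one smoothing:
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`. Complexes are ranked
#' by score and flagged at the p-value cutoff.
#'
#' @param protein_scores named numeric vector `protein -> score` (e.g.
#'   log spectral-count enrichment).
#' @param complexes data.frame with `complex_id`, `member`.
#' @param n_perm number of permutations (default 1000; fewer than 100
#'   raises a warning).
#' @param min_members smallest complex scored (default 3).
#' @param seed RNG seed for the permutations.
#' @param cutoff_p pass/fail p-value cutoff for the ranked curve
#'   (default 5.012e-2).
#' @return data.frame (one row per scored complex) sorted by score:
#'   `complex_id`, `n_members`, `n_members_in_data`, `score`, `p_perm`,
#'   `rank`, `pass`.
#' @export
complex_enrichment <- function(protein_scores, complexes, n_perm = 1000L,
                               min_members = 3L, seed = 1L,
                               cutoff_p = 5.012e-2) {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse empirical p-value")
  if (!nrow(complexes)) {
    return(data.frame(complex_id = character(), n_members = integer(),
                      n_members_in_data = integer(), score = numeric(),
                      p_perm = numeric(), rank = integer(),
                      pass = logical(), stringsAsFactors = FALSE))
  }
  set.seed(seed)
  pool <- protein_scores
  bg_min <- min(pool)
  by_complex <- split(complexes$member, complexes$complex_id)
  by_complex <- by_complex[lengths(by_complex) >= min_members]
  if (!length(by_complex)) {
    return(data.frame(complex_id = character(), n_members = integer(),
                      n_members_in_data = integer(), score = numeric(),
                      p_perm = numeric(), rank = integer(),
                      pass = logical(), stringsAsFactors = FALSE))
  }
  ids <- names(by_complex)
  res <- data.frame(complex_id = ids,
                    n_members = lengths(by_complex),
                    n_members_in_data = NA_integer_, score = NA_real_,
                    p_perm = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(by_complex)) {
    members <- by_complex[[i]]
    present <- members[members %in% names(pool)]
    vals <- c(pool[present], rep(bg_min, length(members) - length(present)))
    obs <- mean(vals)
    size <- length(members)
    null <- vapply(seq_len(n_perm), function(j) {
      mean(pool[sample.int(length(pool), size)])
    }, numeric(1))
    res$n_members_in_data[i] <- length(present)
    res$score[i] <- obs
    res$p_perm[i] <- (1 + sum(null >= obs)) / (1 + n_perm)
  }
  res <- res[order(-res$score, res$complex_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$pass <- res$p_perm < cutoff_p
  rownames(res) <- NULL
  res
}

#' Fraction of hits participating in enriched complexes
#'
#' @param hits character vector of hit proteins.
#' @param complex_results output of [complex_enrichment()].
#' @param complexes the complex definition table (`complex_id`, `member`).
#' @param cutoff_p complexes with `p_perm` below this count as enriched.
#' @return list with `k` (hits in at least one enriched complex), `n`
#'   (number of hits) and `percentage` (1 decimal).
#' @export
hit_fraction_in_networks <- function(hits, complex_results, complexes,
                                     cutoff_p = 5.012e-2) {
  hits <- unique(hits)
  passing <- complex_results$complex_id[complex_results$p_perm < cutoff_p]
  members <- unique(complexes$member[complexes$complex_id %in% passing])
  k <- sum(hits %in% members)
  list(k = k, n = length(hits),
       percentage = round(100 * k / length(hits), 1))
}
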