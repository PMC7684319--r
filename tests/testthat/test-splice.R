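test_that("PSI formulas follow their definitions", {
  expect_equal(compute_psi(10, 10), 0.5)
  expect_equal(compute_psi(0, 5), 0.0)
  expect_equal(compute_psi(30, 10, inclusion_eff_len = 3,
                           skipping_eff_len = 1), 0.5)
  # scale invariance
  set.seed(1)
  i <- sample(1:100, 20); s <- sample(1:100, 20)
  expect_equal(compute_psi(i, s), compute_psi(7 * i, 7 * s))
  expect_error(compute_psi(0, 0), "both zero")
  expect_error(compute_psi(-1, 5), "non-negative")

  expect_equal(psi_from_band_intensities(50, 50), 0.5)
  expect_equal(psi_from_band_intensities(10, 0), 1.0)
  expect_equal(psi_from_band_intensities(80, 20), 0.8)
})

test_that("classification applies strict delta-PSI and FDR thresholds", {
  ev <- data.frame(event_id = letters[1:6],
                   delta_psi = c(0.2, 0.2, -0.2, 0.1, 0.11, -0.5),
                   fdr = c(0.01, 0.2, 0.01, 0.01, 0.05, 0.049))
  cl <- classify_events(ev)
  expect_equal(cl$responsiveness,
               c("enhanced",      # passes both
                 "unresponsive",  # FDR fails
                 "repressed",
                 "unresponsive",  # |dPSI| not strictly > 0.1
                 "unresponsive",  # FDR not strictly < 0.05
                 "repressed"))
  # partition property: one class per event, counts add up
  expect_equal(sum(table(cl$responsiveness)), nrow(ev))
})

test_that("planted classes are recovered at the stated effect and noise", {
  cfg <- sim_config(seed = 77L, n_genes = 60L, effect_size_dpsi = 0.3,
                    psi_noise_sd = 0.02)
  ann <- simulate_annotation(cfg)
  ev <- simulate_events(ann, cfg)
  cl <- classify_events(ev)
  expect_gte(mean(cl$responsiveness == attr(ev, "truth")), 0.95)
})

test_that("proportion tables reproduce printed percentages", {
  ev <- data.frame(event_type = rep(c("SE", "MXE", "A5SS", "A3SS", "RI"),
                                    c(223, 86, 33, 30, 82)))
  tab <- class_proportions(ev)
  expect_equal(tab$percent[tab$group == "SE"], 49.1)
  expect_equal(tab$percent[tab$group == "RI"], 18.1)
  expect_equal(sum(tab$count), 454L)
  one <- class_proportions(data.frame(event_type = rep("SE", 7)))
  expect_equal(one$percent, 100.0)
})

test_that("set overlap summaries report one-decimal percentages", {
  a <- sprintf("g%04d", 1:2047)
  b <- c(sprintf("g%04d", 1:319), sprintf("x%04d", 1:1104))
  s <- set_overlap_summary(a, b)
  expect_equal(s$n_common, 319L)
  expect_equal(s$pct_of_a, 15.6)
  expect_equal(s$pct_of_b, 22.4)
})

test_that("peak-event association honours the 300 nt flank rule", {
  starts <- c(1000L, 3000L, 5000L)
  m <- gene_model("g1", "t1", "chr1", "+", starts, starts + 200L,
                  exon_labels = c("constitutive", "alternative",
                                  "constitutive"))
  ev <- data.frame(event_id = "e", gene_id = "g1", event_type = "SE",
                   chrom = "chr1", strand = "+", alt_start = 3000L,
                   alt_end = 3200L, up_start = 1000L, up_end = 1200L,
                   down_start = 5000L, down_end = 5200L, delta_psi = 0.2,
                   fdr = 0.01, stringsAsFactors = FALSE)
  pk <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                  name = "p", neg_log10_p = 5, strand = "+",
                                  fold_enrichment = 8, library_id = "m",
                                  stringsAsFactors = FALSE)
  # 200 nt into the intron upstream of the constitutive exon at 1000
  near <- intersect_peaks_events(pk(760, 800), list(m), ev)
  expect_true(near$per_peak$near_const_exon)
  expect_false(near$per_peak$on_alt_exon)
  # 500 nt away: not associated
  far <- intersect_peaks_events(pk(400, 500), list(m), ev)
  expect_false(far$per_peak$near_const_exon)
  # on the alternative exon body
  alt <- intersect_peaks_events(pk(3100, 3150), list(m), ev)
  expect_true(alt$per_peak$on_alt_exon)
  expect_equal(alt$genes$summary$n_common, 1L)
})

test_that("association flags equal a brute-force distance oracle", {
  w <- small_world(seed = 61L)
  libs <- simulate_peaks(w$ann, w$cfg)
  merged <- merge_replicate_peaks(lapply(libs, filter_high_confidence))
  ev <- simulate_events(w$ann, w$cfg)
  res <- intersect_peaks_events(merged, w$ann$models, ev, flank_nt = 300L)
  gap <- function(s1, e1, s2, e2) max(0L, max(s1, s2) - min(e1, e2))
  for (i in seq_len(nrow(merged))) {
    alt_hit <- FALSE; con_hit <- FALSE
    for (m in w$ann$models) {
      if (m$chrom != merged$chrom[i] || m$strand != merged$strand[i]) next
      for (j in seq_along(m$exon_starts)) {
        g <- gap(merged$start[i], merged$end[i], m$exon_starts[j],
                 m$exon_ends[j])
        if (m$exon_labels[j] == "alternative" && g == 0L &&
            overlap_len(merged$start[i], merged$end[i], m$exon_starts[j],
                        m$exon_ends[j]) > 0L) alt_hit <- TRUE
        if (m$exon_labels[j] == "constitutive" && g < 300L) con_hit <- TRUE
      }
    }
    expect_equal(res$per_peak$on_alt_exon[i], alt_hit)
    expect_equal(res$per_peak$near_const_exon[i], con_hit)
  }
})

test_that("overlap significance matches closed forms and the hypergeometric", {
  u <- sprintf("u%03d", 1:40)
  a <- u[1:20]; b <- u[c(1:10, 21:30)]
  bal <- overlap_significance(a, b, u, "chi2")
  expect_equal(unname(bal$table), matrix(c(10, 10, 10, 10), 2))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)

  u2 <- sprintf("v%03d", 1:100)
  perfect <- overlap_significance(u2[1:50], u2[1:50], u2, "chi2")
  expect_lt(perfect$p, 1e-10)
  expect_lt(overlap_significance(u2[1:50], u2[1:50], u2, "fisher")$p, 1e-10)

  expect_error(overlap_significance(c(a, "zzz"), b, u), "subsets")

  # Fisher equals exhaustive hypergeometric enumeration, margins <= 30
  set.seed(5)
  for (rep in 1:25) {
    k <- sample(0:10, 1); a_only <- sample(0:10, 1)
    b_only <- sample(0:10, 1); neither <- sample(0:10, 1)
    if (k + a_only + b_only + neither < 2) next
    n_tot <- k + a_only + b_only + neither
    ids <- sprintf("i%03d", seq_len(n_tot))
    sa <- ids[seq_len(k + a_only)]
    sb <- c(ids[seq_len(k)],
            ids[k + a_only + seq_len(b_only)])
    got <- overlap_significance(sa, sb, ids, "fisher")$p
    expect_equal(got, fisher_enum_oracle(k, a_only, b_only, neither),
                 tolerance = 1e-9)
  }
})

test_that("delta-PSI correlation matrix matches rank-based hand computation", {
  set.seed(3)
  e <- sprintf("e%02d", 1:10)
  f1 <- stats::setNames(rnorm(10), e)
  f2 <- stats::setNames(rank(f1) + rnorm(10, 0, 0.1), e)
  f3 <- -f1
  res <- dpsi_correlation_matrix(list(A = f1, B = f2, C = f3))
  expect_equal(diag(res$rho), c(A = 1, B = 1, C = 1))
  expect_equal(res$rho["A", "C"], -1)
  expect_equal(res$rho["A", "B"],
               cor(rank(f1), rank(f2), method = "pearson"))
  expect_equal(res$n_shared["A", "B"], 10L)
  expect_length(res$order, 3L)
  # fewer than 3 shared events -> NA
  res2 <- dpsi_correlation_matrix(list(A = f1[1:2], B = f2[1:2]))
  expect_true(is.na(res2$rho["A", "B"]))
})

test_that("architecture features are transcription-ordered and tested", {
  # minus-strand event: upstream exon genomically right of the alt exon
  ev <- data.frame(event_id = "m1", gene_id = "g", event_type = "SE",
                   chrom = "chr1", strand = "-",
                   alt_start = 2000L, alt_end = 2080L,
                   up_start = 2500L, up_end = 2650L,
                   down_start = 1000L, down_end = 1200L,
                   delta_psi = 0.3, fdr = 0.01,
                   responsiveness = "enhanced", stringsAsFactors = FALSE)
  f <- architecture_features(ev)$features
  expect_equal(f$alt_exon_len, 80L)
  expect_equal(f$upstream_exon_len, 150L)
  expect_equal(f$downstream_exon_len, 200L)
  expect_equal(f$upstream_intron_len, 2500L - 2080L)
  expect_equal(f$downstream_intron_len, 2000L - 1200L)

  # planted shorter enhanced exons are detected by Wilcoxon
  set.seed(8)
  n <- 200L
  mk <- function(len, cls, off) {
    alt_start <- 10000L * seq_len(n) + off
    data.frame(event_id = sprintf("%s%03d", cls, seq_len(n)), gene_id = "g",
               event_type = "SE", chrom = "chr1", strand = "+",
               alt_start = alt_start, alt_end = alt_start + len,
               up_start = alt_start - 2000L, up_end = alt_start - 1800L,
               down_start = alt_start + len + 1500L,
               down_end = alt_start + len + 1700L,
               delta_psi = 0, fdr = 1, responsiveness = cls,
               stringsAsFactors = FALSE)
  }
  enh <- mk(as.integer(round(rnorm(n, 80, 10))), "enhanced", 0L)
  unr <- mk(as.integer(round(rnorm(n, 150, 15))), "unresponsive", 5L)
  res <- architecture_features(rbind(enh, unr))
  row <- res$tests[res$tests$feature == "alt_exon_len", ]
  expect_lt(row$p, 0.01)

  # single event per class: no test, flagged NA
  solo <- architecture_features(rbind(enh[1, ], unr[1, ]))
  expect_true(all(is.na(solo$tests$p)))
})

test_that("splice-site windows slice 9-mers and 23-mers correctly", {
  #                 0....5....10...15...20...25...30...35...40
  seqs <- c(chrW = "AACCAGGTAAGTGGTTTTTTTTTTTTTTTTTTTCAGGCTAAA")
  # plus-strand exon ending at 5 with CAG|GTAAGT
  ev <- data.frame(event_id = "w", gene_id = "g", event_type = "SE",
                   chrom = "chrW", strand = "+",
                   alt_start = 36L, alt_end = 39L,
                   up_start = 3L, up_end = 6L,
                   down_start = 41L, down_end = 42L,
                   delta_psi = 0, fdr = 1, stringsAsFactors = FALSE)
  w5 <- extract_splice_site_windows(ev, seqs, sites = "con1_5ss")
  expect_equal(w5$seq, "CAGGTAAGT")
  w3 <- extract_splice_site_windows(ev, seqs, sites = "alt_3ss")
  expect_equal(w3$seq, "TTTTTTTTTTTTTTTTTCAGGCT")
  expect_false(any(w3$has_n))

  # minus-strand window equals reverse complement of the mirrored sequence
  rc <- clipmap:::revcomp_chr(seqs)
  names(rc) <- "chrW"
  L <- nchar(seqs)
  ev_m <- ev
  ev_m$strand <- "-"
  ev_m$up_start <- L - 6L; ev_m$up_end <- L - 3L
  ev_m$alt_start <- L - 39L; ev_m$alt_end <- L - 36L
  w5m <- extract_splice_site_windows(ev_m, rc, sites = "con1_5ss")
  expect_equal(w5m$seq, "CAGGTAAGT")
  w3m <- extract_splice_site_windows(ev_m, rc, sites = "alt_3ss")
  expect_equal(w3m$seq, "TTTTTTTTTTTTTTTTTCAGGCT")
})

test_that("windows from simulated events equal hand-sliced substrings", {
  w <- small_world(seed = 71L)
  ev <- simulate_events(w$ann, w$cfg)
  win <- extract_splice_site_windows(ev, w$ann$genome)
  for (i in sample(nrow(win), 20)) {
    row <- win[i, ]
    e <- ev[ev$event_id == row$event_id, ]
    chrseq <- w$ann$genome[[e$chrom]]
    exon <- switch(substr(row$site, 1, 4),
                   alt_ = c(e$alt_start, e$alt_end),
                   con1 = c(e$up_start, e$up_end),
                   con2 = c(e$down_start, e$down_end))
    manual <- if (row$kind == "5ss") {
      if (e$strand == "+") substr(chrseq, exon[2] - 2, exon[2] + 6)
      else clipmap:::revcomp_chr(substr(chrseq, exon[1] - 5, exon[1] + 3))
    } else {
      if (e$strand == "+") substr(chrseq, exon[1] - 19, exon[1] + 3)
      else clipmap:::revcomp_chr(substr(chrseq, exon[2] - 2, exon[2] + 20))
    }
    expect_equal(row$seq, manual)
  }
})

test_that("the PWM scorer separates consensus from background sequence", {
  w <- small_world(seed = 81L)
  scorer <- train_pwm_scorer(w$ann$models, w$ann$genome)
  expect_equal(dim(scorer$pwm_5ss), c(4L, 9L))
  expect_equal(dim(scorer$pwm_3ss), c(4L, 23L))
  win <- function(seq, kind) data.frame(event_id = "x", site = "s",
                                        kind = kind, seq = seq,
                                        has_n = grepl("[^ACGT]", seq),
                                        stringsAsFactors = FALSE)
  cons <- score_splice_sites(win("CAGGTAAGT", "5ss"), scorer)$scores$score
  scram <- score_splice_sites(win("TGACATGCA", "5ss"), scorer)$scores$score
  expect_gt(cons, scram)

  # AUC-style check: true donors outscore random 9-mers in >= 90% of pairs
  set.seed(82)
  true_sites <- vapply(1:50, function(i) {
    clipmap:::mutate_consensus("donor", 0.05)
  }, character(1))
  bg <- vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
  }, character(1))
  st <- vapply(true_sites, function(s)
    score_splice_sites(win(s, "5ss"), scorer)$scores$score, numeric(1))
  sb <- vapply(bg, function(s)
    score_splice_sites(win(s, "5ss"), scorer)$scores$score, numeric(1))
  expect_gte(mean(outer(st, sb, ">")), 0.90)

  # windows containing N are excluded and counted
  res <- score_splice_sites(win("NAGGTAAGT", "5ss"), scorer)
  expect_true(is.na(res$scores$score))
  expect_equal(res$n_excluded, 1L)

  # external score tables round-trip their values
  ext <- c(CAGGTAAGT = 9.9)
  expect_equal(score_splice_sites(win("CAGGTAAGT", "5ss"), ext)$scores$score,
               9.9)
})

test_that("planted weak 3' splice sites are detected at printed group sizes", {
  cfg <- sim_config(seed = 91L, n_genes = 230L,
                    class_fractions = c(enhanced = 0.32, repressed = 0.28,
                                        unresponsive = 0.40))
  ann <- simulate_annotation(cfg)
  ev <- simulate_events(ann, cfg)
  cl <- classify_events(ev)
  # sample the group sizes reported for the 3'ss comparison: 79/61/53
  pick <- function(cls, n) which(cl$responsiveness == cls)[seq_len(n)]
  idx <- c(pick("unresponsive", 79), pick("enhanced", 61),
           pick("repressed", 53))
  stopifnot(!anyNA(idx))
  sub <- cl[idx, ]
  genome <- weaken_splice_sites(ann$genome, sub,
                                sub$responsiveness != "unresponsive",
                                site = "alt_3ss", mismatch_rate = 0.35,
                                seed = 91L)
  scorer <- train_pwm_scorer(ann$models, genome)
  w3 <- extract_splice_site_windows(sub, genome, sites = "alt_3ss")
  r3 <- score_splice_sites(w3, scorer, classes = sub$responsiveness)
  p3 <- r3$tests
  expect_lt(p3$p[p3$class_a == "enhanced" & p3$class_b == "unresponsive"],
            0.05)
  expect_lt(p3$p[p3$class_a == "repressed" & p3$class_b == "unresponsive"],
            0.05)
  # donor sites untouched: no signal at the 5'ss
  w5 <- extract_splice_site_windows(sub, genome, sites = "alt_5ss")
  r5 <- score_splice_sites(w5, scorer, classes = sub$responsiveness)
  p5 <- r5$tests
  expect_gt(min(p5$p), 0.01)
})
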