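peak_df <- function(start, end, chrom = "chr1", strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, name = "pk",
             neg_log10_p = 5, strand = strand, fold_enrichment = 8,
             library_id = "m", stringsAsFactors = FALSE)
}

test_that("a peak from exon 3 into intron 4 selects exactly five boundaries", {
  m <- six_exon_model()  # exons at 1000,1500,...,3500 (width 100)
  # covers part of exon3 [2000,2100), intron3, exon4 [2500,2600), part of intron4
  pk <- peak_df(2050, 2700)
  b <- select_boundaries(pk, list(m))
  expect_equal(nrow(b), 5L)
  expect_setequal(b$pos, c(2000L,  # intron2|exon3 (nearest left, uncovered)
                           2100L,  # exon3|intron3
                           2500L,  # intron3|exon4
                           2600L,  # exon4|intron4
                           3000L)) # intron4|exon5 (nearest right, uncovered)
  expect_equal(sum(b$kind == "exon_intron"), 2L)
  expect_equal(sum(b$kind == "intron_exon"), 3L)
})

test_that("a peak inside one intron selects its two flanking boundaries", {
  m <- six_exon_model()
  b <- select_boundaries(peak_df(1200, 1300), list(m))
  expect_equal(sort(b$pos), c(1100L, 1500L))
  expect_setequal(b$kind, c("exon_intron", "intron_exon"))
})

test_that("peaks with no host transcript are skipped and counted", {
  m <- six_exon_model()
  expect_message(b <- select_boundaries(peak_df(100000, 100100), list(m)),
                 "skipped")
  expect_equal(nrow(b), 0L)
  expect_equal(attr(b, "n_skipped"), 1L)
})

test_that("boundary selection equals the exhaustive scan oracle", {
  w <- small_world(seed = 41L)
  set.seed(42)
  n <- 200L
  chrom <- sample(names(w$ann$chrom_sizes), n, replace = TRUE)
  start <- vapply(chrom, function(ch) {
    sample.int(w$ann$chrom_sizes[[ch]] - 400L, 1L)
  }, integer(1))
  pk <- peak_df(start, start + sample(20:300, n, replace = TRUE),
                chrom = chrom,
                strand = sample(c("+", "-"), n, replace = TRUE))
  got <- suppressMessages(select_boundaries(pk, w$ann$models))
  expected <- list()
  for (i in seq_len(n)) {
    host <- oracle_host(pk$chrom[i], pk$start[i], pk$end[i], pk$strand[i],
                        w$ann$models)
    if (is.null(host)) next
    expected[[length(expected) + 1L]] <-
      boundary_scan_oracle(list(start = pk$start[i], end = pk$end[i]), host)
  }
  expected <- unique(do.call(rbind, expected))
  expected <- expected[order(expected$chrom, expected$pos, expected$kind), ]
  expect_equal(got, expected, ignore_attr = TRUE)
})

test_that("per-offset density ratios match a hand computation", {
  # one plus-strand boundary at position 4 (exon left, intron right)
  m <- gene_model("g", "t", "chrT", "+", c(0L, 8L), c(4L, 12L))
  b <- clipmap:::model_boundaries(m)[1, ]  # exon_intron at pos 4
  ip <- track_from(list("chrT:+" = c(1, 2, 3, 4, 5, 6, 7, 8, 0, 0, 0, 0),
                        "chrT:-" = rep(0, 12)), c(chrT = 12L))
  input <- track_from(list("chrT:+" = c(2, 2, 2, 2, 1, 1, 1, 1, 0, 0, 0, 0),
                           "chrT:-" = rep(0, 12)), c(chrT = 12L))
  prof <- boundary_density(b, ip, input, exon_window = 4L, intron_window = 4L,
                           epsilon = 1)
  expect_equal(prof$five_prime$offsets, -4:3)
  # exonic offsets -4..-1 map to bases 0..3; intronic 0..3 to bases 4..7
  expect_equal(prof$five_prime$ip, c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(prof$five_prime$input, c(2, 2, 2, 2, 1, 1, 1, 1))
  expect_equal(prof$five_prime$relative_density,
               (c(1, 2, 3, 4, 5, 6, 7, 8) + 1) / (c(2, 2, 2, 2, 1, 1, 1, 1) + 1))
  expect_equal(prof$five_prime$n_boundaries, 1L)
})

test_that("minus-strand windows mirror the plus-strand computation", {
  # same depths written mirror-reversed on the minus strand
  mp <- gene_model("g", "t", "chrT", "+", c(0L, 8L), c(4L, 12L))
  mm <- gene_model("g", "t", "chrT", "-", c(0L, 8L), c(4L, 12L))
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  ipp <- track_from(list("chrT:+" = vals, "chrT:-" = rep(0, 12)),
                    c(chrT = 12L))
  ipm <- track_from(list("chrT:+" = rep(0, 12), "chrT:-" = rev(vals)),
                    c(chrT = 12L))
  flat <- track_from(list("chrT:+" = rep(2, 12), "chrT:-" = rep(2, 12)),
                     c(chrT = 12L))
  bp <- clipmap:::model_boundaries(mp)
  bm <- clipmap:::model_boundaries(mm)
  pp <- boundary_density(bp, ipp, flat, exon_window = 3L, intron_window = 3L)
  pm <- boundary_density(bm, ipm, flat, exon_window = 3L, intron_window = 3L)
  # the minus-strand gene mirrors the plus-strand one, so profiles agree
  expect_equal(pm$five_prime$ip, pp$five_prime$ip)
  expect_equal(pm$three_prime$ip, pp$three_prime$ip)
})

test_that("equal IP and input tracks give density near 1", {
  w <- small_world(seed = 51L)
  libs <- simulate_peaks(w$ann, w$cfg)
  merged <- merge_replicate_peaks(lapply(libs, filter_high_confidence))
  b <- suppressMessages(select_boundaries(merged, w$ann$models))
  cov <- simulate_coverage(w$ann, attr(libs, "truth"), w$cfg)
  prof <- boundary_density(b, cov$input, cov$input)
  expect_true(all(prof$five_prime$relative_density == 1))
  expect_error(boundary_density(b[0, ], cov$input, cov$input),
               "no boundaries")
})

test_that("profile counts conserve total depth over selected windows", {
  w <- small_world(seed = 52L)
  libs <- simulate_peaks(w$ann, w$cfg)
  merged <- merge_replicate_peaks(lapply(libs, filter_high_confidence))
  b <- suppressMessages(select_boundaries(merged, w$ann$models))
  cov <- simulate_coverage(w$ann, attr(libs, "truth"), w$cfg)
  prof <- boundary_density(b, cov$ip, cov$input, exon_window = 10L,
                           intron_window = 20L)
  # brute force: sum depth over each boundary window independently
  brute <- 0
  for (i in seq_len(nrow(b))) {
    v <- cov$ip[[paste0(b$chrom[i], ":", b$strand[i])]]
    offs <- if (b$kind[i] == "exon_intron") -10:19 else -20:9
    idx <- if (b$strand[i] == "+") b$pos[i] + offs else b$pos[i] - 1L - offs
    idx <- idx[idx >= 0 & idx < length(v)]
    brute <- brute + sum(v[idx + 1L])
  }
  expect_equal(sum(prof$five_prime$ip) + sum(prof$three_prime$ip), brute)
})

test_that("composite maps handle degenerate peak configurations", {
  ev <- data.frame(event_id = "e1", gene_id = "g", event_type = "SE",
                   chrom = "chr1", strand = "+",
                   alt_start = 1500L, alt_end = 1600L,
                   up_start = 800L, up_end = 1000L,
                   down_start = 2000L, down_end = 2200L,
                   delta_psi = 0.3, fdr = 0.01,
                   responsiveness = "enhanced", stringsAsFactors = FALSE)
  empty <- peak_df(1, 2)[0, ]
  maps <- composite_map(empty, ev)
  expect_equal(maps$enhanced$occupancy, rep(0, 100))
  full <- peak_df(900, 2100)
  maps2 <- composite_map(full, ev)
  expect_equal(maps2$enhanced$occupancy, rep(1, 100))
  expect_equal(maps2$enhanced$n_events, 1L)
  # occupancy monotonicity: adding a peak never lowers occupancy
  some <- peak_df(1450, 1480)
  m1 <- composite_map(some, ev)$enhanced$occupancy
  m2 <- composite_map(rbind(some, peak_df(1700, 1750)), ev)$enhanced$occupancy
  expect_true(all(m2 >= m1))
  # short window is skipped under fractional binning
  ev_short <- ev
  ev_short$up_end <- 1540L; ev_short$down_start <- 1610L
  m3 <- composite_map(full, ev_short)
  expect_equal(m3$enhanced$n_events, 0L)
  expect_equal(m3$enhanced$n_skipped, 1L)
})

test_that("fixed 100-bp bins anchor at the upstream boundary", {
  ev <- data.frame(event_id = "e1", gene_id = "g", event_type = "SE",
                   chrom = "chr1", strand = "+",
                   alt_start = 1200L, alt_end = 1300L,
                   up_start = 800L, up_end = 1000L,
                   down_start = 1450L, down_end = 1600L,
                   delta_psi = 0, fdr = 1,
                   responsiveness = "unresponsive", stringsAsFactors = FALSE)
  # window [1000,1450): bins [1000,1100),[1100,1200),... peak in bin 3 only
  maps <- composite_map(peak_df(1210, 1240), ev, bin_mode = "fixed100bp")
  occ <- maps$unresponsive$occupancy
  expect_equal(length(occ), 5L)  # ceiling(450/100)
  expect_equal(occ, c(0, 0, 1, 0, 0))
})

test_that("replicate correlation follows its contract", {
  v <- c(0, 5, 10, 20, 2, 50, 7, 3, 4, 100)
  t1 <- track_from(list("chr1:+" = v), c(chr1 = 10L))
  expect_equal(replicate_correlation(t1, t1)$r, 1.0)
  # hand-computed Pearson on the 5 shared deep positions
  w2 <- c(0, 6, 12, 15, 2, 40, 9, 3, 5, 90)
  t2 <- track_from(list("chr1:+" = w2), c(chr1 = 10L))
  sel <- v > 3 & w2 > 3
  expect_equal(replicate_correlation(t1, t2)$r,
               cor(log2(v[sel]), log2(w2[sel])))
  expect_equal(replicate_correlation(t1, t2)$n_positions, sum(sel))
  t3 <- track_from(list("chr1:+" = c(4, 5, 0, 0, 0, 0, 0, 0, 0, 0)),
                   c(chr1 = 10L))
  expect_error(replicate_correlation(t1, t3), "fewer than 3")

  # independent Poisson tracks decorrelate
  set.seed(9)
  big1 <- track_from(list("chr1:+" = rpois(20000, 8)), c(chr1 = 20000L))
  big2 <- track_from(list("chr1:+" = rpois(20000, 8)), c(chr1 = 20000L))
  expect_lt(abs(replicate_correlation(big1, big2)$r), 0.1)
})
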