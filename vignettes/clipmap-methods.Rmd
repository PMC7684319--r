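---
title: "Position-resolved integration of eCLIP binding with alternative splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-resolved integration of eCLIP binding with alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipmap)
```

# The analysis

RNA-binding proteins that regulate splicing tend to act in a
position-dependent way: the same factor enhances or represses exon inclusion
depending on where it sits relative to the splice sites. clipmap implements
the downstream arm of an eCLIP / RNA-seq integration study of this question:
starting from per-replicate binding peaks, per-base IP and size-matched
input coverage, a transcript annotation and a table of alternative-splicing
(AS) events with percent-spliced-in (PSI) quantifications, it produces

1. a replicate-consensus peak set,
2. genic annotation of those peaks,
3. input-normalised metagene binding maps anchored on 5' and 3' splice
   sites,
4. a classification of AS events into enhanced / repressed / unresponsive by
   delta-PSI and FDR,
5. class-stratified composite occupancy maps between flanking constitutive
   exons,
6. splice-site strength and exon-architecture comparisons across classes,
   and
7. chi-squared GO enrichment and permutation-based protein-complex
   enrichment.

Every stage is driven through plain data frames (BED-like, 0-based
half-open coordinates throughout; GTF input is converted once at the
boundary) so each step is inspectable and independently testable.

# Consensus peak merging

Peak callers are run upstream, per replicate library. clipmap first applies
the high-confidence filter (enrichment p <= 1e-3 **and** fold >= 5 over the
size-matched input; `filter_high_confidence()`). The fold rule is inclusive
(>= 5) by default because the reported peak set uses that form; a strict
`>` flag is available since the two conventions coexist in practice.

`merge_replicate_peaks()` then builds connected components of
same-chromosome, same-strand peaks under >= 1 bp overlap across all
libraries, keeps components supported by at least `min_support = 2` distinct
libraries, and combines each kept component into the union span of its
members. "Common to" is operationalised as any positive overlap because no
minimal overlap is canonical; `min_overlap_bp` exposes the choice. Combining
to the union span (rather than keeping overlapping peaks separately) is what
makes the final self-comparison/redundancy-elimination pass meaningful: with
`gap_join = 0` the sweep already yields disjoint intervals, and the pass
only has work to do when gap-joining is enabled. The merge is validated
against an independent union-find oracle over the pairwise overlap graph,
plus idempotence and support-monotonicity properties.

# Splice-site metagene maps

`select_boundaries()` picks, per peak, the exon-intron (5'ss) and
intron-exon (3'ss) boundaries of its host transcript that are either (1)
covered by the peak or (2) the nearest non-covered boundary beyond each peak
terminal. When a peak overlaps several genes the host is the longest
protein-coding transcript (ties broken by length then identifier) — the
same rule used for genic annotation. A peak reaching from inside exon 3 to
inside intron 4 of a six-exon transcript therefore contributes five
boundaries (intron2|exon3 through intron4|exon5).

`boundary_density()` sums per-base IP and input depth over windows of 100 nt
into the exon and 300 nt into the intron around each selected boundary, in
transcription orientation (minus-strand windows are reversed before
aggregation, so "upstream of the 5'ss" always means the exonic side). The
relative density at each offset is

$$\mathrm{RD}(o) = \frac{\sum_b \mathrm{IP}_b(o) + \varepsilon}
                        {\sum_b \mathrm{Input}_b(o) + \varepsilon},$$

summing counts across boundaries *before* dividing (the alternative,
averaging per-boundary ratios, is noisier at low depth and does not match
the "total number of reads" reading of the procedure). The pseudocount
`epsilon = 1` guards zero-input positions and is exposed as a parameter;
with deep coverage its effect vanishes. Windows truncated at chromosome
ends contribute only their defined offsets.

# Event classification and composite maps

Events are classified by `classify_events()` with strict thresholds:
enhanced when `delta_psi > 0.1` and `fdr < 0.05`, repressed when
`delta_psi < -0.1` and `fdr < 0.05`, unresponsive otherwise. The sign
convention is condition2 minus condition1 (knockout minus wild type), so
"enhanced" means inclusion rises when the regulator is lost; both the
convention and the strictness of the inequalities are documented switches
because the two natural readings differ only at the threshold boundary.

`composite_map()` takes, per event, the window from the 5'ss of the
upstream constitutive exon to the 3'ss of the downstream constitutive exon
(boundary to boundary; the flanking exon bodies are excluded so the window
is purely the regulated region) and divides it into 100 equal-width bins. A
bin is occupied for an event when at least one peak base falls in it;
occupancy of a bin is the fraction of the class's events occupying it. The
equal-width ("fractional") default makes windows of different lengths
comparable on a common axis, which composite averaging requires; a
fixed-100-bp mode anchored at the upstream boundary is provided for
length-preserving views, with per-bin denominators counting only events
whose window reaches the bin. Events whose window is shorter than the bin
count are skipped and counted. Binary occupancy is the default; a
coverage-weighted variant (fraction of bin bases covered) sits behind the
`weight` flag.

Replicate reproducibility of coverage (`replicate_correlation()`) uses
positions with depth strictly greater than 3 *in both tracks* — the
procedure's "depth > 3" does not say which track, and requiring both makes
the statistic symmetric — and reports the Pearson correlation of log2
depths.

# Splice-site strength and exon architecture

Splice-site windows follow the 9/23-mer convention: a 5'ss window is the
last 3 exonic plus first 6 intronic bases; a 3'ss window the last 20
intronic plus first 3 exonic bases, reverse-complemented on the minus
strand. Four sites are extracted per skipped-exon event: the alternative
exon's donor and acceptor and the flanking constitutive exons' outer sites.

The built-in scorer (`train_pwm_scorer()`) is a position-weight-matrix
log-odds model trained on the annotation's constitutive sites with a
pseudocount of 0.5 per base and a uniform background. It is a transparent
stand-in obeying the same window conventions as trained maximum-entropy
scorers; externally computed score tables are accepted wherever a scorer is
(`score_splice_sites()` with a named vector), so published scorers can be
dropped in without code changes. Windows containing `N` are excluded and
counted.

Class comparisons (site scores and the five exon/intron length features,
all in transcription order) use two-sided unpaired Wilcoxon (Mann-Whitney)
tests: exact enumeration for tie-free groups of at most 10, normal
approximation with tie correction otherwise. Raw p-values are the primary
output; Benjamini-Hochberg adjusted values across the feature-by-pair grid
are reported alongside. Unresponsive events serve as the control group for
the length comparisons — the natural in-experiment background when no
expressed-gene universe is supplied.

# Enrichment statistics

GO enrichment (`go_enrichment()`) is a chi-squared test (df = 1, no
continuity correction) on the 2x2 list-membership by term-membership table
over the background, per term with at least 5 annotated background genes,
followed by Bonferroni correction over the tested terms. Terms annotated to
all or none of the background have a degenerate margin and are skipped with
a count. GO graph propagation is out of scope: term assignments are taken
as given.

Complex enrichment (`complex_enrichment()`) scores each complex as the
unweighted mean of its members' scores (a weighted variant would need
information the input does not carry; missing members contribute the
background minimum and are counted), and compares it against `n_perm =
1000` random same-size member sets. The empirical p-value uses add-one
smoothing, `p = (1 + k)/(1 + n_perm)`, so it is never exactly zero; the
ranked-curve output flags complexes at the conventional cutoff
`p < 5.012e-2`, which is treated as a plain threshold parameter.

# The synthetic-data generator

`sim_config()` plus the `simulate_*()` functions emulate the full input
stack so the pipeline can be exercised end to end without downloads:

* **Annotation/genome** — multi-exon genes on both strands (5-8 exons of
  80-250 nt, introns 300-1200 nt by default; 500 nt intergenic gaps), one
  internal exon per gene labelled alternative, a CDS spanning mid-first to
  mid-last exon, and a random genome in which every intron carries GT..AG
  and consensus-derived donor (9-mer) / acceptor (23-mer) sequence with a
  5% per-base mismatch rate.
* **Peaks** — true binding loci placed by a positional model over four
  regions (exon body; the 50 exonic nt upstream of 5' splice sites; the 25
  exonic nt downstream of 3' splice sites; deep intron, >= 100 nt from any
  boundary), mirroring the splice-site-proximal preference the analysis is
  designed to detect. The default mixture (0.40 / 0.25 near the two sites,
  0.20 exonic, 0.15 deep intron) concentrates binding at splice sites while
  leaving enough background for the null regions to be informative. A
  peak's midpoint is uniform within its region; each of 4 libraries
  observes each locus with probability 0.85, jittered +/- 5 nt, and about
  30% of observed peaks are drawn to fail the high-confidence filter so
  the filter is always exercised.
* **Coverage** — input depth Poisson(5) per base; IP depth Poisson(5 x 5)
  under true peaks. Poisson is the simplest count model with known
  moments, which is what the recovery tests need.
* **Events** — one skipped-exon event per alternative exon; planted classes
  (30/25/45% enhanced/repressed/unresponsive by default), |delta PSI| = 0.3
  against replicate noise of sd 0.02, FDR below 0.05 for responsive events
  and uniform above otherwise. delta-PSI equals the replicate-mean
  difference by construction (computed after clipping PSI to [0,1]).
* **GO / complexes** — one term planted at relative risk 5 in a designated
  gene list; one complex of 8 among 200 proteins with member scores shifted
  by 2 sd.

Each generator seeds its own RNG stream from `seed` plus a fixed offset, so
outputs are byte-identical across runs and the substreams are independent.
The generator writes the exact formats the readers consume (GTF, BED6+2,
bedGraph, events TSV, GAF, FASTA), so file-driven runs are equivalent to
in-memory ones.

What the generator does *not* emulate — read-level noise, PCR duplication,
mappability, realistic sequence composition beyond splice-site consensus,
transcript-abundance-dependent occupancy, overlapping genes, multi-isoform
loci — bounds what the recovery tests show: they demonstrate that the
implementation recovers planted structure under the stated noise model, not
that the statistics are robust to every artefact of real libraries.

# Validation problem sizes

The shipped test-suite exercises the pipeline at sizes chosen to make the
planted effects identifiable while keeping the suite quick to run: 100
random 4-library instances against the union-find merge oracle; >= 1000
donor boundaries (250 genes) for metagene recovery at enrichment fold 5,
with an enrichment-fold-1 null; 300+ events per class for composite-map
recovery, using a fixed gene geometry (5 x 120 nt exons, 500 nt introns) so
the planted acceptor position maps to a known bin range; 500 genes for
classification recovery; 100 simulation seeds each for the GO type-I and
permutation-recovery checks. The composite-map recovery plants peaks at
the alternative exon's 3'ss of enhanced events only, reproducing the
qualitative class-specific occupancy pattern the analysis is meant to
reveal.

# Known limitations

* Genic annotation assigns a single transcript per peak (longest
  protein-coding); peaks on antisense or overlapping genes inherit that
  transcript's categories.
* Occupancy is not normalised for transcript abundance; composite maps
  inherit expression-dependent binding detectability.
* The rMATS reader covers the standard junction-count column layout; other
  quantifiers are consumed through the documented simple TSV (the `majiq`
  dialect name is accepted for tables produced by reducing local splicing
  variations to binary events upstream).
* The PWM scorer is intentionally simple; for publication-grade splice-site
  strength, supply an external score table from a trained model.
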