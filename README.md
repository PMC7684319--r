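# clipmap

Splice-site-anchored RNA binding maps and alternative-splicing integration
for eCLIP peak data.

## The problem

RNA-binding proteins that regulate splicing often do so in a
position-dependent manner: binding just upstream of a 5' splice site or
just downstream of a 3' splice site can have opposite consequences for
exon inclusion. Connecting *where* a protein binds (from eCLIP peaks and
coverage) with *what happens to splicing* (from RNA-seq percent-spliced-in
tables) is the recurring downstream analysis this package implements, for
analysts who already have peak calls, coverage tracks, an annotation, and
rMATS-style event tables in hand.

The core quantities:

* **Consensus peaks** — high-confidence peaks (p ≤ 10⁻³, ≥ 5-fold over the
  size-matched input) merged across replicate libraries by a 2-of-N support
  rule: connected components of overlapping same-strand peaks are kept when
  ≥ 2 distinct libraries contribute, and combined into their union span.
* **RNA maps** — per-base relative density around splice sites,
  RD(o) = (ΣIP(o) + ε) / (ΣInput(o) + ε), over windows of 100 nt into the
  exon and 300 nt into the intron, in transcription orientation.
* **ΔPSI classification** — events with FDR < 0.05 and ΔPSI > 0.1 (KO −
  WT) are *enhanced*, ΔPSI < −0.1 *repressed*, the rest *unresponsive*;
  composite occupancy maps stratify binding between the flanking
  constitutive exons by class (100 equal-width bins, binary per-event
  occupancy).
* **Comparisons & enrichment** — splice-site strength (9-mer donor /
  23-mer acceptor windows, PWM log-odds or external score tables) and
  exon-architecture features compared across classes by two-sided Wilcoxon
  tests; chi-squared + Bonferroni GO enrichment; permutation-based
  protein-complex enrichment with add-one-smoothed empirical p-values.

A deterministic synthetic-data generator (`sim_config()` +
`simulate_*()`) emulates the complete input stack — annotation with GT..AG
introns, four jittered peak libraries with a planted positional preference,
Poisson IP/input coverage, event tables with planted effect sizes, GO and
complex fixtures — so the whole pipeline is testable end to end without any
downloads.

## Worked example

```r
library(clipmap)

cfg  <- sim_config(seed = 7)                 # 40 genes, 4 libraries, fold 5
ann  <- simulate_annotation(cfg)
libs <- simulate_peaks(ann, cfg)

merged <- merge_replicate_peaks(lapply(libs, filter_high_confidence))
nrow(merged)
#> [1] 199

b   <- select_boundaries(merged, ann$models)
cov <- simulate_coverage(ann, attr(libs, "truth"), cfg)
prof <- boundary_density(b, cov$ip, cov$input)
prof$five_prime
#> <boundary_profile> 5' splice site, 161 boundaries, offsets -100..299
#>   max relative density 3.399 at offset -26
prof$three_prime
#> <boundary_profile> 3' splice site, 156 boundaries, offsets -300..99
#>   max relative density 3.204 at offset 19

ev <- simulate_events(ann, cfg)
cl <- classify_events(ev)
class_proportions(cl, by = "responsiveness")
#>          group count percent
#> 1     enhanced    13    32.5
#> 2    repressed     8    20.0
#> 3 unresponsive    19    47.5
```

The 199 merged peaks are the 2-of-4 consensus of the filtered libraries.
The metagene maxima sit at offset −26 from the 5' splice site (inside the
exon) and +19 from the 3' splice site (just inside the exon) — exactly
where the generator planted binding preference — and the relative density
of ~3.4 reflects the five-fold IP enrichment diluted by peaks outside the
windows. The classification table recovers the generator's planted class
mixture; at the default effect size (|ΔPSI| = 0.3, noise sd 0.02) label
recovery is 100%.

The whole analysis can also be driven from one config:

```r
run_pipeline(list(sim = list(seed = 7), out_dir = "run1"))
# or: Rscript inst/cli/clipmap.R run --config run.yaml
```

which writes each stage's TSV (merged peaks, genic categories, metagene
densities, classified events, composite maps, intersections, enrichment
tables) plus a manifest; identical config and seed give byte-identical
outputs.

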