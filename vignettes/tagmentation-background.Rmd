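---
title: "Modelling untargeted tagmentation background in targeted CUT&Tag"
author: "tagbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling untargeted tagmentation background in targeted CUT&Tag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagbench)
library(GenomicRanges)
```

## The problem

CUT&Tag directs a Protein A/G–Tn5 fusion to an antibody-bound epitope and
tagments nearby DNA. Tn5, however, also tagments nucleosome-depleted,
accessible chromatin on its own — this is the very signal ATAC-seq is
built on. For most chromatin targets the two signals live in different
places and an untargeted (no-antibody or IgG) control library cleanly
measures background. G-quadruplex (G4) DNA structures are different:
they form in single-stranded, nucleosome-free DNA, so true G4 signal and
untargeted accessibility background pile up at the *same* loci. Three
consequences follow:

1. untargeted control libraries are spatially correlated with both
   ATAC-seq and G4-targeted libraries;
2. using the matched untargeted control during sparse-enrichment peak
   calling removes real G4 peaks along with background (higher
   precision, lower recall);
3. differential read-count testing of targeted versus untargeted
   libraries loses most significant sites once library complexity is
   normalized between the groups.

tagbench packages the machinery needed to study these effects —
simulator, complexity normalization, peak callers, interval
benchmarking, differential testing — in a form where every rule is
explicit and testable at desk scale.

## The generative model

`simulate_genome()` and `simulate_library()` implement a deliberately
small hierarchy:

* **Genome.** Three 10 Mb chromosomes by default; 1% of each chromosome
  is blacklisted in 10 kb blocks, mimicking the role of assembly
  blacklists (simulated reads never start there and shuffled intervals
  avoid them). The scale is chosen so peaks stay sparse while every
  analysis runs in seconds.
* **Sites.** `n_accessible` (default 500) non-overlapping 1 kb
  accessible sites are placed uniformly outside the blacklist. Each
  receives a log-normal(0, 1) relative accessibility weight, normalized
  to sum to one — a heavy-tailed strength distribution like real open
  chromatin. A fraction `g4_fraction` (default 0.25) of sites carries a
  true G4: a 200 bp interval centred in the site. Each G4 site also
  receives its own log-normal *capture weight*, independent of its
  accessibility weight: folding fraction and probe accessibility vary
  between loci, so targeted enrichment strength forms a continuum
  rather than an all-or-nothing flag. This continuum is what makes
  borderline significance — and therefore normalization behaviour —
  observable at all.
* **Molecules.** Each unique molecule is a fragment whose midpoint
  comes from a three-way mixture: with probability `p_target` it is
  capture at a G4 site (site chosen by capture weight, midpoint
  Gaussian-jittered around the site centre, sd 50 bp); otherwise with
  probability `p_accessible_bg` (default 0.7) it is untargeted
  tagmentation at an accessible site (site chosen by accessibility
  weight, midpoint uniform within the site — uniform rather than
  centred so that the expected fraction of midpoints inside accessible
  sites is exactly `p_accessible_bg` plus the uniform-hit correction,
  which the test suite checks analytically); otherwise it falls
  uniformly on the non-blacklisted genome. Fragment lengths are Normal
  (200 ± 50 bp) truncated at 30 bp. Site weights receive per-library
  log-normal jitter (`site_noise_sd`, default 0.3 ≈ 30% CV) so
  replicates are overdispersed the way real replicates are; without it
  the negative-binomial dispersion machinery would be exercised against
  data with no dispersion.
* **Reads.** Every molecule is sequenced a Poisson(λ) number of times
  (`mean_depth_per_molecule`, default 2) and molecules with zero draws
  are unobserved. Molecule coordinates are kept exactly distinct (the
  generator redraws collisions), so the zero-truncated Poisson is not
  an approximation but the exact sampling law of the simulated data —
  deliberately, so the complexity estimator can be tested by parameter
  recovery. An optional log-normal per-molecule amplification bias
  (`amplification_sd`, off by default) breaks this exactness on demand;
  with it enabled the estimator is expected to be biased, which is
  documented rather than asserted.

`p_target` deserves a caveat: the real targeted:background mixture in
G4 CUT&Tag libraries is not known, so its default (0.6) is a scenario
knob, not an estimate. Conclusions that depend on its exact value
should be swept over it.

## Library complexity

For a library of $N$ unique molecules sequenced to $R$ total reads with
per-molecule depth Poisson($\lambda$), only $u = N(1 - e^{-\lambda})$
molecules are observed, and the mean copy number of observed molecules
is the zero-truncated Poisson mean
$$\frac{R}{u} = \frac{\lambda}{1 - e^{-\lambda}}.$$
`estimate_complexity()` solves this monotone equation for
$\hat\lambda$ by root finding (relative tolerance ~1e-10) and reports
$\hat N = R/\hat\lambda$, never below $u$. A library with no duplicate
reads leaves $\lambda$ unidentifiable; the estimator then returns the
observed count with an explicit warning status instead of a number it
cannot defend.

`downsample_library()` implements ratio-based thinning: every read is
retained independently with probability $p =$ target / estimated
unique, after which `deduplicate_library()` collapses identical
(chrom, start, end) fragments. Two properties are worth stating
plainly. First, thinning then deduplicating leaves
$N(1 - e^{-p\lambda})$ expected unique reads in the file — the test
suite checks this closed form to 2%. Second, thinning to a common
estimated-unique target equalizes the *observed* unique counts of two
libraries only in the low-duplication regime ($\lambda \lesssim 0.3$,
where observed ≈ $\lambda \times$ target on both sides); at high
duplication the surviving unique counts differ by construction. The
equalization test therefore runs at ATAC-like $\lambda = 0.15$, and
users normalizing heavily duplicated libraries should compare
post-thinning estimates, not observed counts.

`filter_min_unique()` applies the minimum-unique-reads exclusion rule
(boundary inclusive: a library with exactly the minimum is kept).

## Coverage and counting

`fragments_to_coverage()` bins fragments at 50 bp by default. Span mode
(every overlapped bin) feeds peak calling; midpoint mode (one bin per
fragment, left-biased for even lengths) is the centred-read
visualization analog and makes CPM exactly conservative: a
midpoint-mode CPM track sums to one million. Real-data pipelines
normalize CPM by an effective genome size; synthetic tracks use the
actual fragment totals, a documented divergence. Counting conventions:
coverage weights records by copy count (reads); `frip()` and
`count_matrix()` count molecules, one per fragment, with ≥1 bp overlap,
and a fragment spanning two regions counts in both.
`background_size_factors()` is median-of-ratios normalization computed
on 15 kb background bins (dropping bins with a zero anywhere) rather
than on peaks, so depth is measured where targeting does not reach.

## Peak calling

`find_signal_blocks()` segments a track into maximal runs of positive
bins; each block's AUC (value × bin width summed) is the calling
currency, as in sparse-enrichment callers for CUT&RUN/CUT&Tag data.

*Threshold mode* (`call_peaks_threshold()`) retains the top fraction
`f` of blocks by AUC. The rule is top-$k$ with $k = \lceil fn \rceil$
and ties at the cutoff retained, which makes "top 5%" exact for
distinct AUCs: 1000 blocks at `f = 0.05` yield exactly 50 peaks. (A
naive inverse-ECDF quantile cutoff with `>=` retains 51 — one of the
small places where a fully specified rule has to choose.)

*Control mode* (`call_peaks_control()`) is a simplified re-statement of
control-based sparse-enrichment calling: scale the control's block AUCs
so total AUC matches the target's, take every observed AUC as a
candidate threshold, and keep the threshold maximizing (fraction of
target blocks above) − (fraction of control blocks above). `stringent`
keeps target blocks above the maximizing threshold (largest such
threshold under ties — the conservative choice); `relaxed` uses the
smallest candidate reaching 90% of the maximum difference, so relaxed
calls always contain stringent calls. A control identical to the
target yields no peaks. This is not the reference implementation of
any published caller: the published control-mode normalization scales
by the ratio of AUC-distribution modes and defines relaxed via a
different curve. The package's claims concern the threshold-mode vs
control-mode *contrast*, which survives this simplification, and every
rule here is testable by exhaustive search.

## Interval benchmarking

`multi_consensus()` partitions the genome at all interval breakpoints,
keeps atoms covered by at least `min_count` input sets, and merges
book-ended pieces; `consensus_min_count(n)` encodes the default
at-least-half rule, `ceiling(n/2)`. Precision is the fraction of query
peaks overlapping any reference peak by ≥1 bp; recall the fraction of
reference peaks overlapped; each interval counts once (peak-level, not
base-pair-level, matching the definitional reading of "overlapped by at
least 1 peak"). Empty query or reference yields a flagged `NA` rather
than a silent 0, because "no peaks were called" and "no peaks
overlapped" are different findings. `jaccard_index()` is intersection
over union in base pairs. `shuffle_intervals()` re-places intervals
width-preserving, uniformly on non-excluded space, rejecting overlaps
with the exclusion set and with already-placed intervals — the
width-matched null for all overlap statistics. `fisher_overlap()`
builds the 2×2 table with the genome-segmentation heuristic
$n_{22} = \text{genome bp}/\text{mean width} - n_{11} - n_{12} - n_{21}$;
measured against shuffled nulls this heuristic is anticonservative, so
the package treats the shuffled-null comparison as the primary
significance device and the Fisher p as a descriptive companion.

## Differential enrichment

`nb_differential()` tests each peak for increased normalized counts in
targeted libraries: counts over size factors, a per-peak
method-of-moments negative-binomial dispersion from the pooled
within-group variance, shrunk halfway toward the *mean* dispersion
across peaks (floored at 1e-8), a Wald statistic on the log2 fold
change of group means (pseudo-count 0.5) under the NB variance
$\mu + \phi\mu^2$, two-sided normal reference, and Benjamini–Hochberg
adjustment. The shrinkage target is the mean rather than the median
deliberately: with three replicates per group the moment estimator is
strongly right-skewed, its median underestimates the pooled dispersion,
and median-shrinkage inflates the type-I error to ~0.08 in the
package's own null calibration; mean-shrinkage keeps it near 0.066
(target 0.05 ± 0.02), while a t reference would overshoot conservative
(~0.02). All-zero peaks are kept with p = 1 so row counts are
conserved. "Significant up" means FDR < 0.05 *and* log2FC > 0, the
one-directional count; the total significant count is reported
alongside because the two are easy to conflate.

`complexity_contrast()` runs the test twice — deduplication only,
versus downsample-to-limiting-complexity then deduplication — and
returns both significant-up counts.

## The default scenario

`run_scenario()` wires the stages into the two headline synthetic
experiments: three targeted replicates (150,000 unique molecules,
`p_target = 0.6`) and three matched untargeted replicates (30,000
unique molecules, `p_target = 0`) on one genome and site map. The 5:1
depth asymmetry mirrors the consistent observation that targeted
libraries are sequenced much deeper than their untargeted controls.
Sizes were chosen so that after complexity normalization per-peak
molecule counts land in the tens — the sparse regime real
complexity-normalized CUT&Tag occupies — rather than in the hundreds,
where every true site would be overwhelmingly significant and
normalization would have nothing to change.

On this scenario, with fixed seeds:

* threshold-mode consensus peaks at `f = 0.01` recover most true G4
  sites with moderate precision, while control-mode calls against the
  matched untargeted controls are far fewer, near-perfectly precise,
  and recover far fewer true sites — the precision-for-recall trade;
* the significant-up count after complexity normalization never
  exceeds the dedup-only count. The synthetic *magnitude* of that
  collapse is modest, unlike the order-of-magnitude collapse seen on
  real libraries: the simulator enforces globally distinct molecule
  coordinates and therefore has no positional saturation of Tn5
  insertion sites, which is a known nonlinearity of real deduplicated
  hot loci. This is a stated limitation, not an oversight — modelling
  insertion-site saturation would entangle the complexity estimator's
  exactness guarantee.

All stage seeds derive from one scenario seed via `stage_seed()`
(stage-name hashing), so any stage can be rerun in isolation and the
whole bundle is reproducible byte for byte.

```{r scenario, eval = FALSE}
res <- run_scenario(scenario_config(seed = 1))
res$summary
```

## What passing tests do and do not show

The generator emulates accessibility-driven background, targeted
capture with per-site efficiency, PCR duplication, replicate noise and
depth asymmetry. It does not emulate sequence content, Tn5 insertion
motifs or positional saturation, nucleosome positioning, chromatin
contact structure, or mapping artifacts. Tests passing on this
simulator therefore validate the *analysis machinery* — estimators
recover their own model's parameters, callers implement their stated
rules, directional phenomena follow from the stated mechanism — and
cannot certify numerical agreement with any real library. Real-data
magnitudes (peak counts, significant-site counts) depend on library
scale and biology that desk-scale synthesis deliberately does not
reproduce.

## Numerical choices

* Root finding for $\hat\lambda$: `uniroot` on a bracketing interval,
  tolerance ~1e-10 relative; the no-duplicates boundary returns a
  flagged fallback.
* Quantile rule for threshold calling: top-$k$, $k=\lceil fn\rceil$,
  ties retained (see above).
* Control-mode stringent tie-break: largest maximizing threshold.
* Overlap criterion: ≥1 bp everywhere; "directly adjacent" merging is
  gap-0 (book-ended) only.
* Pseudo-count 0.5 in fold changes; dispersion floor 1e-8.
* Midpoint of an even-length fragment: left-biased.
* The limiting library in complexity normalization is thinned at
  p = 1 (identity), not excluded.
* Empty-set statistics (precision with no query peaks, Jaccard of two
  empty sets) are flagged `NA`, never silent zeros.
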