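# tagbench

Benchmarking untargeted Tn5 tagmentation background in targeted CUT&Tag
peak calling.

## The problem

CUT&Tag maps chromatin targets by steering a Protein A/G–Tn5 fusion to
an antibody-bound epitope. Tn5 also tagments accessible chromatin on its
own — the signal ATAC-seq is built on — so every CUT&Tag library carries
an untargeted background concentrated at open chromatin. For targets
that themselves require open chromatin, notably G-quadruplex (G4) DNA
structures, that background colocalizes with the true signal. Untargeted
(IgG / no-antibody) control libraries then stop being neutral: using
them during peak calling removes genuine target peaks along with
background, and differential targeted-vs-untargeted testing collapses
once library complexity is normalized between the groups.

tagbench is an R package for studying these effects quantitatively,
entirely on synthetic data, for computational epigenomics researchers
and pipeline developers who need every analysis rule explicit and
testable:

* **Synthetic tagmentation data** — `simulate_genome()`,
  `simulate_library()`: accessible-site maps with true-G4 subsets,
  three-way fragment mixture (targeted capture / accessibility-driven
  background / uniform noise), Poisson PCR duplication, replicate
  noise, reproducible from a seed.
* **Library complexity** — `dup_histogram()`, `estimate_complexity()`
  (zero-truncated Poisson maximum likelihood: solves
  `lambda / (1 - exp(-lambda)) = R/u`, reports `N_hat = R/lambda_hat`),
  `downsample_library()` (per-read Bernoulli thinning at
  `p = target / N_hat`), `deduplicate_library()`, `filter_min_unique()`.
* **Coverage and counting** — `fragments_to_coverage()` (span/midpoint,
  raw/CPM), `frip()`, `count_matrix()`, `background_size_factors()`
  (median-of-ratios over 15 kb background bins), `correlation_matrix()`.
* **Sparse-enrichment peak calling** — `find_signal_blocks()` (maximal
  positive runs, AUC-scored), `call_peaks_threshold()` (top
  `ceiling(f*n)` blocks, ties kept), `call_peaks_control()` (AUC-scaled
  control, best separating threshold), `threshold_sweep()`.
* **Interval benchmarking** — `multi_consensus()`,
  `precision_recall_f1()`, `jaccard_index()`, `shuffle_intervals()`
  (width-preserving nulls), `fisher_overlap()`.
* **Differential enrichment** — `nb_differential()` (negative-binomial
  Wald test with moment/shrinkage dispersion and BH correction),
  `ma_table()`, `complexity_contrast()`.
* **Scenario driver** — `run_scenario()`, `scenario_config()`,
  `make_fixtures()`.

Interval sets are `GenomicRanges::GRanges`; fragment files are
plain-text BED/BEDPE; tracks export as bedGraph.

## Worked example

```r
library(tagbench)

res <- run_scenario(scenario_config(seed = 1))
str(res$summary)
#> List of 5
#>  $ n_true_g4   : int 125
#>  $ threshold   :List of 5
#>   ..$ f        : num 0.01
#>   ..$ n_peaks  : int 119
#>   ..$ precision: num 0.874
#>   ..$ recall   : num 0.832
#>   ..$ f1       : num 0.852
#>  $ control     :List of 5
#>   ..$ stringency: chr "stringent"
#>   ..$ n_peaks   : int 19
#>   ..$ precision : num 1
#>   ..$ recall    : num 0.152
#>   ..$ f1       : num 0.264
#>  $ differential:List of 3
#>   ..$ n_regions                  : int 195
#>   ..$ n_sig_dedup_only           : int 107
#>   ..$ n_sig_complexity_normalized: int 107
#>  $ seed        : int 1
```

Reading the numbers: the scenario plants 125 true G4 sites among 500
accessible sites and simulates three targeted replicates (150k unique
molecules, 60% capture) against three matched untargeted replicates
(30k molecules, pure background). Calling peaks per replicate at the
0.01 AUC threshold and intersecting replicates recovers 83% of the true
sites at 87% precision. Calling the same targeted tracks *against their
matched untargeted controls* instead returns only 19 peaks: every one
overlaps a true G4 (precision 1.0) but 85% of true sites are lost —
the background shared between targeted signal and untargeted control
buys precision at a steep recall cost. In the differential branch, 107
of 195 peak regions show a significant targeted excess when libraries
are only deduplicated; normalizing library complexity first
(downsampling the 5×-deeper targeted libraries to the untargeted
level) can only hold or lower that count (here unchanged at 107 — the
synthetic collapse is modest, see the vignette's limitations section).

`vignettes/tagmentation-background.Rmd` documents the generative model,
every tunable parameter, the numerical choices, and what these
synthetic results do and do not say about real libraries.

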