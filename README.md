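# mitocov

Strand-resolved coverage-bias analysis and heteroplasmy QC for massively
parallel resequencing of the human mitochondrial genome.

Resequencing the 16,569-bp circular mtDNA after long-range PCR enrichment
is a routine diagnostic assay, but amplification-driven bias can collapse
the read depth of the reference (plus / light, C-rich) strand across whole
regions of the genome.  Where the plus strand drops out, low-level
heteroplasmic variants become indistinguishable from sequencing error.
`mitocov` provides the desk-side analysis for this problem, for anyone
validating an mtDNA sequencing protocol or pipeline:

* **strand-resolved relative coverage** — per position, the depth divided
  by the mean depth, computed per strand:
  `rc_s(i) = d_s(i) / (Σ_j d_s(j) / L)`, so every series has mean 1 and
  protocols of different total depth are directly comparable;
* **coverage-fraction tables** — the percentage of positions with
  `rc < 0.50, 0.25, 0.10, 0.05, 0.01`, per strand (the standard
  protocol-comparison table);
* **base-class bias curves** — the content of a two-letter base class
  (e.g. "AC-rich" = % of positions that are A or C) in fixed 150-nt bins,
  against each bin's mean relative coverage, grouped in 10-point content
  bands.  This is the analysis that localizes plus-strand dropout to
  AC/CT-rich motifs;
* **error-baseline calibration** — the mean per-position non-reference
  base fraction of a control (or self) sequence, with a configurable
  policy (`max(floor, multiplier × mean error)`, rounded up to a whole
  percent) mapping the baseline to a heteroplasmy detection threshold;
* **variant concordance** — m.-notation parsing (`m.7989T>C`,
  `m.5899_5900insC`), detected / false-negative / extra bookkeeping
  against a truth panel, pooled detection rates, and per-variant
  heteroplasmy means ± n−1 standard deviations across methods;
* **a synthetic-data generator** — circular references with exact
  segment-level base-class composition, and a pileup simulator with
  independent per-strand Poisson depth, content-dependent plus-strand
  suppression, uniform substitution error and heteroplasmic variants,
  emitting a truth manifest.  The whole pipeline is testable with no
  external download.

## Worked example

Simulate a 16,569-bp genome with a pure-AC block (positions 7351–9450,
aligned to 150-nt bins) in a composition-balanced background, suppress the
plus strand where local AC content reaches 80% (weight 0.02), sequence at
mean depth 6000 with 0.2% substitution error, then down-sample to 3000:

```r
library(mitocov)

segments <- data.frame(pair_class = c("AC", "AC", "AC"),
                       target     = c(0.5, 1.0, 0.5),
                       length     = c(7350, 2100, 7119))
ref  <- generate_reference(16569, segments, seed = 1, name = "synthetic_mt")
bias <- bias_model("AC", window = 150, weight_fn = step_weight(0.8, 0.02))
sim  <- simulate_base_counts(ref, sim_config(6000, error_rate = 0.002,
                                             seed = 2), bias = bias)
counts <- downsample_counts(sim$counts, 3000, seed = 3)
rc <- relative_coverage(counts)
coverage_fraction_table(rc)
#>  threshold Total  Plus  Min
#>      <0.50  0.00 12.52 0.00
#>      <0.25  0.00 12.52 0.00
#>      <0.10  0.00 12.52 0.00
#>      <0.05  0.00 12.52 0.00
#>      <0.01  0.00  0.00 0.00
```

12.5% of the genome — the AC block plus its window-width flanks — has
plus-strand relative coverage below 0.05, while the minus strand and the
pooled total are unaffected: the signature of strand-specific dropout.
The bias curve pins it to the high-AC content bands:

```r
bins <- binned_composition(ref, 150)   # 111 bins of 150 nt, bin 111 wraps
subset(as.data.frame(bias_curve(bins, rc, "AC", strand = "plus")),
       n_bins > 0)
#>    band_low band_high    mean_rc n_bins
#> 4        30        40 1.13776955      1
#> 5        40        50 1.13936716     38
#> 6        50        60 1.14013368     58
#> 10       90       100 0.03673489     14
```

Bins at ≥90% AC content average rc ≈ 0.04 on the plus strand — "dropped
almost to zero" — while bins at background content sit at the re-normalized
unbiased level.  Calibration and concordance close the loop:

```r
summ <- average_error_rate(position_error(sim$counts, ref))
detection_threshold(summ)   # 0.2% baseline * 5 -> ceil to 2%
#> [1] 0.02

heteroplasmy_summary(c(12, 12, 23))$rounded   # three methods, one variant
#> mean   sd
#> 15.7  6.4
```

A thin CLI over the same functions is installed at
`system.file("cli", "mitocov.R", package = "mitocov")` with subcommands
`simulate`, `coverage`, `bias`, `calibrate`, `concord`, `plot`; all
randomized subcommands take `--seed` and are byte-reproducible.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package: the biased-genome simulation, down-sampling, the
coverage-fraction table, the AC bias curves, error calibration on a
2,686-nt control at depth 30,000, and the concordance / heteroplasmy
summaries recomputed from the per-method count tables bundled under
`inst/extdata/`.  Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
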