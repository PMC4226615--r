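---
title: "Methods: strand-resolved coverage bias, error calibration and heteroplasmy QC"
author: "mitocov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-resolved coverage bias, error calibration and heteroplasmy QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocov)
```

## The problem

Long-range-PCR-enriched resequencing of the 16,569-bp circular human
mitochondrial genome can show severe strand-specific coverage loss: over
sizeable regions the reference (plus / light, C-rich) strand drops to a
small fraction of its mean depth while the complementary (minus / heavy)
strand is unaffected.  The dropout tracks local sequence composition —
windows rich in A+C (and C+T) bases — and is thought to originate in the
DNA polymerases used in the amplification rounds of library preparation,
not in the fragmentation chemistry.  Wherever the plus strand is
underrepresented, callers that require support on both strands lose
sensitivity, and low-level heteroplasmies approach the sequencing-error
floor.  `mitocov` implements the complete analysis used to detect,
localize and quantify this failure mode, plus the error-baseline and
concordance machinery used to validate variant calling around it.

## Relative coverage and the threshold table

For strand $s \in \{+,-,\text{total}\}$ with per-position depth $d_s(i)$
over $L$ positions, the relative coverage is

$$\mathrm{rc}_s(i) = \frac{d_s(i)}{\tfrac1L \sum_{j=1}^{L} d_s(j)},$$

each series normalized by its own mean, so $\overline{\mathrm{rc}_s} = 1$
exactly (to floating tolerance) on every input and profiles from runs of
different total depth are directly comparable.  A strand with zero
coverage everywhere is reported as *undefined* rather than divided by
zero.  The coverage-fraction table reports, for descending thresholds
$t \in \{0.50, 0.25, 0.10, 0.05, 0.01\}$, the percentage of positions with
$\mathrm{rc}_s(i) < t$ (strict inequality, matching the table-notation
convention `<0.50`).  Columns are non-increasing as $t$ decreases, a
property asserted on every run.

Depth is counted at base level: a read contributes to a position only if
it has an aligned base there, so positions deleted in a read add to
neither depth nor base counts.  This keeps the denominator of the error
index (below) equal to observed bases.  Alignment ingestion (SAM/BAM via
`Rsamtools`) skips unmapped, secondary and supplementary records; the
package's own pileup TSV dialect is the canonical interchange format and
round-trips byte-identically.

Down-sampling to a common mean (default 3000) is per-base binomial
thinning with retention probability `target / current mean`, preserving
strand and base proportions in expectation.  When input is an alignment
file the natural alternative is read-level subsampling; the pileup-level
thinning is the tested default because the package's core data model is
the pileup.

## Base-class composition and bias curves

"AC-rich" is interpreted as two-letter base-**class** content — the
fraction of positions in a window whose base is A or C — not
adjacent-dinucleotide (ApC) frequency.  Only the class reading allows
statements like "80% AC-rich"; adjacent-pair frequency cannot approach
such values in genomic sequence, and the strand asymmetry of the
phenomenon (C-rich light strand vs G-rich heavy strand) is a base-class
property.  The six unordered classes satisfy the complement identities
GC + AT = AC + GT = CT + AG = 100 per window, checked per bin to 1e-9.
Contents are computed on the plus (reference) strand; minus-strand
contents follow from the identities (AC↔GT, CT↔AG under reverse
complement) rather than being recomputed.

Composition is tabulated in consecutive non-overlapping bins of 150 nt
starting at position 1.  16,569 = 110 × 150 + 69, so on the circular
genome the 111th bin wraps around the origin (positions 16,501–16,569
plus 1–81), keeping every bin exactly 150 nt wide — the band statistics
assume equal-width bins.  The no-wrap truncated-final-bin mode is
available (`wrap = FALSE`) for linear references.  The wrap rule is this
package's choice; nothing in the underlying analysis prescribes remainder
handling.

A bias curve groups bins by their class content into bands of 10
percentage points (left-closed, right-open, the top band closed at 100)
and reports each band's mean of the bins' mean relative coverage and its
bin count.  Empty bands carry `n_bins = 0` and an undefined mean.  Under
plus-strand suppression at ≥80% AC content, the ≥80% bands of the
plus-strand AC curve collapse (mean rc well below 0.1) while the same
bands of the minus-strand curve stay near 1 — and on an unbiased run no
band deviates from 1 beyond Poisson noise, which the tests check at three
standard errors using the theoretical bin-mean error
$\mathrm{se} = 1/\sqrt{\text{bin size} \times \text{mean depth}}$.

## The synthetic world

The generator states the sequencing conditions the analysis was designed
for; its defaults are not tuning knobs.

* **Reference**: circular, built from segments with *exact* class content
  (`round(target × length)` in-class positions per segment), so realized
  composition is within half a base of target and bin-level content is
  known by construction.
* **Depth**: per position, plus and minus depths are independent
  $\mathrm{Poisson}(\tfrac{D}{2} w_i)$ and $\mathrm{Poisson}(\tfrac{D}{2})$
  draws, with $D$ the configured mean (3000–6000 in the analyses here;
  down-sampling targets 3000) and $w_i \in [0,1]$ the bias weight at the
  local class content of a centered, circularly wrapped 150-nt window.
  Independent strands — rather than a binomial split of a fixed total —
  are essential: biased plus-strand reads are *lost*, they do not reappear
  on the minus strand, so minus-strand relative coverage stays near 1
  under suppression, as observed in real data.  With no bias the expected
  total is exactly $D$, split 50/50.
* **Bias weight**: monotone non-increasing, $w(0)=1$, user-supplied.  The
  mechanism (amplification enzymes) has no published quantitative model,
  so the package ships a step function (`step_weight(0.8, 0.02)`) that
  reproduces the observed "drops almost to zero at ≥80% AC" phenomenology.
* **Errors**: each sequenced base substituted with probability
  `error_rate` (0.2–0.8% is the realistic platform range; 0.2–0.3% is the
  MiSeq-like default used in the tests), uniformly over the three
  alternatives, strand-symmetric.  Indel and homopolymer error modes are
  deliberately out of scope — the downstream error index counts
  non-reference bases without typing them.
* **Heteroplasmy**: alt alleles assigned per read at the configured
  fraction (1–60% is the range of interest) *before* error, so truth
  fractions are well defined; the manifest records realized per-variant
  fractions and the realized genome-wide error rate.

In the tests and the acceptance run, the AC-rich block (content 1.0,
length 2100) is aligned to bin boundaries inside a content-0.5 background.
This is a deliberate design choice: it keeps bin contents bimodal (~50%
vs 100%), so no bin mixes suppressed and unsuppressed positions while
sitting in a ≥80% band, and the band assertions test the statistic rather
than boundary geometry.  A green bias-curve test therefore establishes
that the pipeline recovers a known generative bias and invents none on
null data — it does not certify behaviour on real mtDNA composition,
where content varies continuously and boundary bins land in intermediate
bands.

A read-level mode (`simulate_reads()` + `write_sam()`) exists for
alignment-ingestion round-trips; its reads do not wrap across the
circular origin (a single SAM record cannot represent that), so read
starts are confined to $[1, L - \ell + 1]$ and the pileup-level model
remains the tested default.

## Error baseline and detection threshold

The error index at a covered position is the pooled-strand fraction of
observed bases differing from the reference; positions carrying true
variants are excluded via a mask so genuine heteroplasmy does not inflate
the baseline.  The average error rate is the unweighted mean over
unmasked covered positions; across samples, per-sample means aggregate
with an n−1 standard deviation.  Strands are pooled (a per-strand
breakdown would be diagnostic only).

No published formula links the baseline to a detection threshold — the
historical 5% working point was carried over between studies — so the
package states an explicit, configurable policy:

$$\text{threshold} = \left\lceil 100 \cdot \max(\text{floor},\;
\text{multiplier} \times \bar e) \right\rceil / 100,$$

default multiplier 5 and floor 1%, the ceiling taken to the next whole
percent.  At MiSeq-like baselines (0.19–0.35%, across-sample means around
0.23–0.3%) this yields the 2% working point; at exactly $\bar e = 0.002$
the product 1.0% is already a whole percent and the threshold is 1% — the
policy's worked example (0.3% → 1.5% → 2%) pins the ceiling semantics.  A
candidate allele fraction is callable iff *strictly above* the threshold.

## Variant concordance

Variants use mtDNA m.-notation; parsing is total and round-trips to
canonical text.  Truth/call matching is exact on (position, kind,
alleles).  The known ambiguity of the 302–316 homopolymeric region —
equivalent C-insertions placed at different positions by different
platforms — is handled by an optional interval list that matches
insertions inside a declared interval by net inserted length; the default
remains exact matching, which counts such a case as one false negative,
mirroring how it is scored in practice.  Detection rate is pooled:
$100 \sum \text{detected} / \sum \text{truth}$.  Heteroplasmy summaries
use the arithmetic mean and the n−1 standard deviation (the printed
reference tables are consistent with n−1, not the population formula),
with presentation rounding half-up to one decimal; full precision is kept
internally.  Allele fractions are reported as printed, in percent, and
values above 50% are not folded to the minor allele.

## Numerical and interface conventions

Coordinates are 1-based and inclusive everywhere.  Strict `<` for
threshold-table membership; strict `>` for callability.  Rounding for
display is half-up (base R's `round()` is half-even); two decimals for
coverage tables, one for rates and heteroplasmy.  All randomized
operations take integer seeds and are byte-reproducible; output TSVs
carry `#key=value` metadata headers (tool version, seed, parameters) and
no timestamps.  The circular plot is a simplified two-ring polar
rendering — the asserted surface is the underlying binned series, never
pixels — with a linear radial scale by default and a log option, since
the scale of the original circular figures is not documented.

## Limitations

The package consumes alignments or pileups; it does not align reads or
call variants (an oracle caller thresholding pooled alt fractions is used
only to close the testing loop).  The simulator omits flow-space /
homopolymer errors, PCR duplicates, chimeras and paired-end geometry.
The original sequencing runs behind the reference analysis are not
publicly deposited, so run-level coverage tables and bias figures are not
reproducible from data; the package instead reproduces the printed
count-table arithmetic exactly and validates the coverage/bias machinery
against its own generative model.
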