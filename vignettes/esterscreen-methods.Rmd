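---
title: "Methods: the two-library test, the candidate screen, and the assay analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-library test, the candidate screen, and the assay analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esterscreen)
```

## The model and its assumptions

The design this package targets is the classical pooled digital gene
expression comparison: one sequencing library per condition, no biological
replicates. With N~1~ and N~2~ total uniquely aligned reads in the two
libraries, a gene's read count in one deeply sequenced library is modeled
as Poisson — each gene captures a small fraction of a very large read
total. Conditioning on the observed count *x* in library 1 removes the
unknown Poisson rate and leaves an exact, parameter-free distribution for
the count *y* in library 2:

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!}
\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

a negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$ (`ac_pmf()`, `ac_cumulative()`). The two-sided p-value is
the doubling rule on the lower cumulative $s=\sum_{i\le y} p(i\mid x)$:
$2s$ when $s \le 0.5$, otherwise $2(1-s)$ (`ac_two_sided_p()`).

The assumptions worth stating plainly:

* **Poisson sampling.** Technical (sequencing) variability only. With one
  pooled library per condition there is no way to estimate biological
  dispersion; p-values quantify evidence against "same relative
  transcription in the two pools", not against "same expression across
  biological replicates". The generator's `overdispersion` knob exists
  precisely to show how anti-conservative the test becomes when counts are
  negative-binomial instead (the test suite demonstrates a >20% empirical
  type-I rate at dispersion 0.5).
* **Uniqueness of alignment.** N~1~, N~2~ and the per-gene counts must all
  refer to uniquely aligned reads, the normalizer the statistic assumes.
* **Discreteness.** The test is conservative: for discrete counts
  `P(p < α) ≤ α`, with the gap largest at shallow depth.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fold_threshold` | 2 | strict cutoff on the normalized ratio; exactly 2.0 is *not* differential ("more than twofold") |
| `alpha` | 0.05 | level applied to the BH FDR (or to raw p with `use_fdr = FALSE`); `alpha = 1` gives the pure fold rule |
| `pseudocount` | 0.5 | added to *both* counts only when either is zero, so nonzero ratios stay exact |
| `use_fdr` | TRUE | multiplicity control across the gene table |

Fold change is computed on library-size-normalized counts,
$(x/N_1)/(y/N_2)$ — the same $N_2/N_1$ weighting the statistic itself
uses. "Up-regulated" means a higher normalized level in group 1, the
condition of interest (e.g. the optimized culture), and candidates are
drawn from up-regulated genes only.

The screen (`screen_candidates()`) matches annotations by exact accession
equality against the whitelist — 13 KEGG K-numbers and 7 GO accessions
covering lipase, esterase, carboxylesterase, pectinesterase and related
hydrolase/lyase activities (`default_whitelist()`). No GO-graph ancestor
propagation is attempted: the screened annotations are flat leaf
accessions, and propagating ancestors would admit essentially every
hydrolase. Genes whose KEGG field is `NA` are matched on GO terms alone.
Ties in the fold-change ordering are broken lexicographically by gene id
so output is deterministic.

## Numerical choices

* All factorials go through `lgamma`; pmf, cumulative and tail sums are
  assembled by log-sum-exp, so the contract holds for counts up to about
  10^7^ without overflow or underflow.
* The upper branch of the doubling rule is computed by **direct summation
  of the upper tail** (in 512-term chunks, stopping past the conditional
  mean once terms are negligible), never as $1-s$: small p-values keep
  full relative accuracy instead of being destroyed by cancellation.
* At the branch boundary $s = 0.5$ both branches equal 1 analytically;
  this point is attained exactly for $x=y$ with $N_1=N_2$. Since the
  floating-point sum lands within a few ulp of 0.5, any p within 10^-12^
  of 1 is snapped to exactly 1.0.
* `round_half_up()` implements decimal rounding with halves away from
  zero, the convention of the reported assay percentages and folds
  (base R's `round()` rounds half to even). Rounding is applied only at
  the reporting layer; machine-readable outputs keep full precision.
* A degenerate standard curve (fewer than 3 distinct concentrations, or
  zero slope at inversion time) is an error; negative quantified
  concentrations — expected from blank drift near the detection limit —
  are clipped to 0 with a warning rather than rejected.
* A ratio of exactly `fold_threshold` is not differential; a cumulative
  exactly 0.5 gives p = 1; an all-zero activity series has no defined
  relative-activity profile and errors.

## What the synthetic-data generator emulates

`simulate_counts()` reproduces the statistical structure of a pooled
two-condition experiment: ~24,319 genes (a typical de-novo fungal
assembly), per-gene baseline rates from a gamma distribution
(shape 0.7 — strongly skewed, like real transcriptomes), a minority of
genes with planted uniform fold changes, Poisson counts scaled so each
library's expected total equals its target size, and annotations in which
planted candidates carry whitelist terms, a fraction of null genes carry
decoy whitelist terms, and a small fraction of genes have no annotation
record at all. One global seed drives three named substreams (rates,
counts, annotations), so regenerating one phase leaves the others
untouched.

Defaults were chosen once to mirror the targeted study conditions:
library sizes of 2×10^6^ reads, 23 planted whitelist-annotated candidates
with folds in [4, 16], and a floor (`planted_min_mean = 50`) on a planted
candidate's expected baseline count so planted signal is detectable at the
simulated depth — without the floor a gamma-distributed baseline can make
a "planted" gene invisible at any realistic depth.

What it does **not** emulate: read-level artifacts (the generator starts
from counts, not FASTQ), assembly ambiguity, biological replicate
variability (unless the `overdispersion` knob is turned), GC/length
biases, and annotation errors beyond simple missingness. Passing the
recovery tests therefore shows the pipeline is correct *given its model*;
it does not show the Poisson model is adequate for any particular real
dataset.

One emergent property worth knowing: because each group is scaled to a
fixed expected total, planting strong one-sided fold changes slightly
deflates every null gene's relative level in that group — a real
compositional effect, not a bug. Raw null p-values are therefore
calibrated only on all-null data; in the planted simulations the strict
fold filter is what keeps false candidate calls rare.

`simulate_assay()` emits serial-dilution standards under a known linear
detector response and measurement responses encoding known conversion
ratios (defaults: the four-ester panel at 7.87, 29.20, 94.80 and 85.20%
from 10 mM acid, the post-optimization operating point), optionally with
Gaussian response noise. With zero noise the assay pipeline inverts
exactly; with noise, recovery is unbiased.

## Design choices where the design was open

* **Normalization of the fold change.** Defined on library-size-normalized
  counts rather than FPKM: it is the only normalization already implied by
  the statistic's own $N_2/N_1$ weighting, and transcript lengths are not
  part of the two-library comparison.
* **Significance policy.** The strict fold rule is the published decision
  rule; a p-value/FDR threshold is additionally applied by default
  (BH at 0.05) because a fold rule alone makes no error guarantee at low
  counts. `alpha = 1` restores the fold-only behaviour.
* **Conversion ratio.** Defined as mol ester formed per mol acid initially
  supplied, ×100 — the only definition consistent with quantifying esters
  against their own standard curves from a known initial acid charge.
* **No control subtraction by default.** Whether reported conversions are
  negative-control-subtracted is an assay-protocol choice; the pipeline
  quantifies what the curve sees, and control handling is left to the
  caller (`preference_fold()` expresses the enzyme/control comparison).
* **Problem sizes in the test suite.** The null-calibration suite uses
  5,000 genes at 10^6^-read depth and the recovery suite 24,319 genes at
  2×10^6^ — sizes at which Monte-Carlo error is well below the decision
  margins while the whole suite stays interactive.

## Known limitations

* No replicate-aware dispersion modelling: this is by design the pooled
  single-library-per-group statistic. For replicated designs use an
  NB-based framework (edgeR/DESeq2) instead.
* The published 23-gene shortlist itself is not re-derivable without the
  deposited raw libraries; the package reproduces the *rule* (and recovers
  planted truth exactly in simulation), not the original curation.
* The screen performs no GO enrichment statistics and no ortholog
  inference; it is a deterministic whitelist filter.
* Chromatogram peak integration is upstream of the assay analytics: inputs
  are detector responses, not raw chromatograms.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
sim <- simulate_counts(n_genes = 5000, n1 = 1e6, n2 = 1e6,
                       de_fraction = 0.01, planted_candidates = 10, seed = 42)
res <- run_pipeline(sim$counts, sim$annotations, out_dir = tempdir())
res$candidates
estimate_error_rates(res$fit, sim$truth, candidates = res$candidates)
```
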