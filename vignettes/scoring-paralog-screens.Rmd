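---
title: "Scoring genetic interactions in multiplex paralog knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions in multiplex paralog knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogGI)
```

## The model

A multiplex paralog screen measures, for each gene pair (A, B), the
fitness of the double knockout alongside the two single knockouts, across
one or more cell lines. Under the additive null model of genetic
interaction, the expected double-knockout log2 fold change is the sum of
the single-knockout LFCs; the residual

$$\mathrm{dLFC}_{k,j} = \mathrm{LFC}^{obs}_{AB,j} - (\mathrm{LFC}_{A,j} + \mathrm{LFC}_{B,j})$$

for pair $k$ in screen $j$ measures interaction strength. Synthetic
lethality is a strongly negative dLFC in a pair whose double knockout
itself drops out of the population.

Raw dLFC values are not comparable across screens: each screen has its own
noise level, and depth renormalization shifts the whole dLFC distribution
(when essential constructs drop out, reads are redistributed to everything
else, inflating endpoint counts by a screen-specific constant; the pair
term carries one copy of that constant and the summed singles two, so dLFC
inherits a net location shift). The package therefore fits two null models
per screen:

1. **LFC mixture null.** All guide-level LFCs are modeled as a
   two-component Gaussian mixture. The higher-weight component captures
   the majority of guides with no fitness effect; its mean and sd
   standardize any LFC into a ZLFC. The lower-weight, lower-mean, wider
   component absorbs fitness-defect guides.
2. **dLFC null.** The pair dLFC distribution is modeled as a single
   Gaussian after discarding outliers beyond the Tukey fences
   $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ (quartiles
   computed on the full vector). The retained values' mean and sd (n−1)
   define ZdLFC. Trimming matters because the genuine interactions sit in
   the tails and would otherwise inflate the null sd.

The supervised RdLFC score additionally uses the dLFC values that a
positive-control reference set of known synthetic-lethal pairs attains in
the same screen:

$$\mathrm{RdLFC}_{k,j} = \frac{\mathrm{dLFC}_{k,j} - \mu_{null,j}}{\mu_{null,j} - \mathrm{median}\{\mathrm{dLFC}_{r,j} : r \in \mathrm{ref}\}}$$

which pins the null mean to 0 and the reference median to −1, putting all
screens on a common supervised scale. The reference median is computed per
screen, never pooled: the anchor must reflect what a known synthetic
lethal looks like *in that screen*.

### Hit calling

All thresholds are strict upper bounds and all rules are conjunctions with
a viability condition on the pair construct itself:

| method | interaction condition | viability condition |
|--------|----------------------|---------------------|
| dlfc   | dLFC < −1            | pair LFC < −1       |
| zdlfc  | ZdLFC < −2           | pair ZLFC < −2      |
| rdlfc  | RdLFC < −0.7         | pair ZLFC < −2      |

The RdLFC cut of −0.7 is deliberately calibrated to produce roughly as
many hits as the ZdLFC rule, so that cross-method consistency comparisons
are not confounded by hit-set size. Consistency across screens is the
median pairwise Jaccard coefficient of hit sets; each pairwise comparison
is restricted to pairs scoreable in both screens.

## Parameters that matter

| parameter | default | units | why |
|-----------|---------|-------|-----|
| `pseudocount` | 5 | reads | stabilizes log ratios of low-count arrays |
| `depth` | 1e7 | reads/sample | fixed normalization target |
| mixture floor `min_n` | 50 | values | below this a 2-component fit is not identifiable in practice |
| dLFC null floor `min_n` | 20 | values | quartiles on fewer points are too unstable |
| `qtype` | 7 | — | quantile rule for Q1/Q3 (linear interpolation, the common default); configurable because the fences move with it |
| `zdlfc_cut`, `zlfc_cut` | −2 | sd units | two-sigma rule on the standardized scales |
| `dlfc_cut`, `lfc_cut` | −1 | log2 | one full halving beyond expectation |
| `rdlfc_cut` | −0.7 | ref units | matches ZdLFC hit-set size (see above) |

## Numerical choices

- The mixture is fitted by EM with k-means initialization, 10 restarts
  from seeds derived from the user seed, relative log-likelihood tolerance
  1e-6 and a 500-iteration cap; the best restart by log likelihood wins,
  making the fit deterministic given data and seed. If the two weights tie
  exactly, the component with the larger mean is the null (no-effect
  guides sit near zero; the defect component lies below).
- Degenerate inputs fail loudly: zero-variance LFC vectors, zero dLFC
  variance inside the fences (possible when more than half the values are
  identical, collapsing the IQR to zero), a reference median at or above
  the null mean (the RdLFC denominator would be non-positive), and missing
  T0 normalized counts at pseudocount 0.
- Replicate endpoint samples are averaged at the guide-LFC level, not the
  count level, so each replicate keeps its own depth normalization.
- Screen QC (Cohen's D) uses gene-level control LFCs by default
  (guide-level available via `level = "guide"`); the pooled sd uses the
  sample (n−1) convention throughout, including the stratum effect sizes
  in the evaluation helpers.
- The LFC mixture is fitted on all arrays of a screen — single-gene and
  pair constructs alike — since the ZLFC viability condition is applied to
  pair constructs.
- Gene symbols are opaque case-sensitive strings; pairs are keyed
  order-invariantly by lexicographic (C-locale) canonical order.

## What the simulator emulates — and what it does not

`simulate_screens()` generates the full study structure: a library of
single-gene and pair constructs (4 arrays per target) plus 50 + 50
essential/nonessential control singles; true single-knockout LFCs (0 for
most genes, −2 for a 10% essential fraction); true pair dLFCs (0 for null
pairs, −2 for a 10% synthetic-lethal fraction, of which 20% are
context-specific and active in a single random screen); per-guide Gaussian
effect noise (sd 0.3 log2 units); and negative-binomial sequencing counts
(size 50, i.e. ~14% extra CV; `Inf` gives Poisson) at 10⁷ reads per
sample, with T0 drawn around a uniform per-array depth and endpoint means
scaled by $2^{\text{effect}}$. Counts, controls, screen number and effect
sizes mirror a mid-sized production screen; the noise and dispersion
values are chosen as field-realistic round numbers. All randomness flows
from one root seed through fixed per-screen substreams
(`(seed + 104729 * stream) mod (2^31 - 1)`), so individual screens are
independently reproducible.

Deliberately not modeled: copy-number artifacts, guide-efficiency
variation, off-target effects, batch structure between screens, and —
importantly — between-screen heterogeneity in noise level or library
composition: all simulated screens are statistically identical replicas.
Passing tests on this generator therefore demonstrate correctness of the
scoring machinery and its calibration under a clean additive model, not
performance on real screens. One consequence worth stating plainly: the
practical advantage of Z-standardization over raw dLFC thresholds comes
from exactly the between-screen location/scale heterogeneity this
generator omits, so on simulated replicas raw dLFC hit sets are at least
as internally consistent as ZdLFC ones — the methods' cross-screen
rankings on such data should not be read as a statement about real
screens.

## Problem sizes

The test suite and the acceptance script run the generator at its default
size (4 screens × 2,600 targets × 4 arrays) and smaller; parameter-recovery
checks use 10,000 draws for the trimmed null and 20,000 for the mixture.
These sizes keep every run in seconds while leaving estimator standard
errors an order of magnitude below the asserted tolerances.

## Worked run

```{r example}
sim <- simulate_screens(sim_config(seed = 42L))
fit <- paralog_gi(sim$counts, sim$annotation, refs = sim$refs, seed = 42L)
print(fit)
coef(fit)
consistency(hits(fit, "zdlfc"))
truth_metrics(hits(fit, "zdlfc"), sim$truth)
```

## Known limitations

- Only pairwise interactions are scored; higher-order knockouts (triples,
  quads) present in some array libraries are out of scope.
- No symbol mapping: annotation, reference sets and expression matrices
  must agree on gene symbols.
- The mixture component count (2) and dLFC null component count (1) are
  fixed; no model selection is performed.
- RdLFC requires the reference pairs to be scoreable in each screen; a
  screen with no scoreable reference pair gets no RdLFC values (with a
  warning) rather than a pooled anchor.
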