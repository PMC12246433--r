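---
title: "Methods: endothelial secretome miRNA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endothelial secretome miRNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secmiR)
```

# The analysis model

`secmiR` analyses single-channel miRNA microarray intensities from an
endothelial-secretome study design: cultured endothelial cell pellets
(intracellular miRNA), their conditioned media (secreted miRNA), blank media
(background), blood serum/plasma, and white-blood-cell cultures as the main
non-endothelial blood contributor. The statistical core is deliberately
simple and transparent; the value of the pipeline is in the disciplined
order of operations and the contracts between them.

## Probe quality control on a dilution series

A probe useful for quantitative comparison must respond linearly to RNA
input. For each probe, the Pearson correlation between raw intensity and
input amount (ng) across the serial-dilution arrays is tested two-sided;
probes with *p* ≥ α or with undefined correlation (zero intensity variance,
e.g. a fully saturated response) are removed from **all** downstream
analysis. We use the configured α (default 0.05) because no separate
filtering level is ever stated for this step; the per-probe *r*, *p* and
pass flag are reported so the choice is auditable. At least three distinct
inputs are required — below that the correlation *p*-value does not exist.

## The detection threshold

Arrays do not measure "zero"; they measure down to a sensitivity floor.
Walking up the dilution series, the probes that flip from absent to present
between consecutive inputs are exactly the probes sitting at that floor, so
the mean intensity of these *first-detection events* estimates the minimal
trustworthy signal. We pool the events across all steps into one arithmetic
mean (the simplest reading of "average intensity of newly detected
miRNAs"), and also report per-step sets and means for transparency.
Detection is then a strict comparison, `intensity > threshold`: a probe
exactly at threshold is undetected, a deterministic tie rule stated once.
Present/absent calls for the derivation itself prefer an explicit
detection-flag matrix (as exported by the array vendor's feature-extraction
software, see `read_agilent_fe()`) and fall back to "signal > 0".

One configured threshold is applied uniformly to culture and blood samples;
whether blood arrays deserve their own threshold is unresolved in the field,
and the assumption is recorded in the output metadata by construction (a
single `threshold` per analysis).

## Background subtraction

Conditioned medium carries signal from the unconditioned medium itself, so
blank media processed identically are subtracted probe-wise (mean over
blanks, matched by culture medium, pooled-mean fallback when a medium has no
matched blank), floored at zero. Cell pellets, serum, plasma and WBC samples
receive no subtraction: no meaningful blank exists for them. It is an error
to analyse conditioned media with no blanks at all.

## Fraction-of-total normalisation

Each sample's intensities are divided by the sample's total over QC-passing
probes, optionally (and by default) after zeroing undetected entries. The
result is a composition: nonnegative fractions summing to one. Two
properties make this the pipeline's core transform:

* it is *exactly* invariant to per-sample multiplicative rescaling, so
  comparisons tolerate substantial variation in RNA input without spike-ins
  or external standards;
* compositions from different samples are directly comparable by rank
  correlation regardless of their absolute signal levels.

Whether to normalise over all QC-passing probes or detected ones only is
genuinely open; both are supported (`mask` argument), detection masking is
the default because signatures are defined over detected miRNAs.

## Signatures, partition, blood classification

A group signature is the arithmetic mean of member fractions (undetected =
0) renormalised to sum one — mean-then-renormalise keeps the signature on
the simplex whatever the per-sample supports. Support membership requires
detection in at least `min_detect_samples` group members (default 1: a
miRNA "detected across" a sample set).

The origin partition is plain set algebra on detected unions:
intracellular-only = cells \ media, secreted-only = media \ cells, both =
intersection. Blood classification marks each blood sample's detected
miRNAs endothelial or non-endothelial by membership in a reference union —
the cell-sample union by default, with the media union and the combined
union selectable (`endothelial_reference`), since secretion is the more
plausible route into blood for an intact endothelium.

## Correlation comparison

Signature comparisons use Spearman's ρ. The default subset policy is
*union-with-zeros*: the two supports are united and absences count as zero,
so non-overlap is penalised — compare whole patterns, not just the shared
part. Intersection is available for sensitivity analysis. *p*-values use
the exact small-sample null distribution (n ≤ 10, no ties, via
`stats::cor.test`) and the t approximation otherwise; ties get average
ranks.

Correlation matrices are summarised per named block as the mean of the
pairwise coefficients and the population-style SD around that mean
(within-group blocks over unique off-diagonal pairs only). Coefficient
groups are compared with Student's t, Welch's t and Mann-Whitney tests; all
three are computed and labelled rather than guessing which a reader wants.
PCA is `stats::prcomp` on samples-as-observations, centred and unscaled.

## Time-course trends

Per detected miRNA, the Pearson correlation of expression with time in raw
minutes (no transform) is computed after averaging technical replicates per
time point; `increasing` / `decreasing` at *p* < α by the sign of *r*,
`unchanged` otherwise. Zero-variance series are `unchanged` — an undefined
correlation never counts as significant. No multiple-testing correction is
applied to the categories (the raw *p* < 0.05 convention of this analysis
style); Benjamini-Hochberg q-values accompany every record for users who
want them. Using every array as a point instead of averaging replicates is
exposed as an option. Both normalised (fraction) and raw-intensity modes
exist, because composition trends and secretion-rate trends answer
different questions; `cross_reference()` joins the secretory and
intracellular tables to expose synchronous changes.

# The synthetic generator

`generate_world()` draws a fully specified ground truth; `simulate_arrays()`
renders arrays from it. The signal model per probe and sample is

```
intensity = slope_p x input_eff x scale x abundance_p(sample)
            x donor_mult x medium_mult x accumulation(t)
            + intercept_p + background + noise,  floored at 0,
            censored to 0 below the sensitivity floor
```

* **Abundance profiles** are Dirichlet draws on each compartment's support
  (concentration 1 — the realistically sparse regime where a few miRNAs
  dominate). The endothelial intracellular and secretory supports overlap
  by design (`overlap_design`, default 155 intracellular-only / 166
  secreted-only / 253 shared). The pooled dilution isolate covers the whole
  probe universe with the same concentration, keeping a low-abundance tail
  at the detection limit.
* **Probe model:** log-normal slopes (sdlog 0.3); a configurable minority
  (default 2.7%) of probes saturate at `saturation_ng` (default 10 ng,
  below the dilution minimum, so their dose response is flat and QC can
  remove them); intercepts default to 0 because feature-extracted signals
  are already spot-level background corrected.
* **Donor and medium effects** are independent log-normal multipliers per
  (miRNA, donor) and (miRNA, medium) with `medium_effect_sd` (0.30) twice
  `donor_effect_sd` (0.15): culture environment perturbs signatures more
  than genetic background, which is what makes within-medium correlations
  exceed within-line ones downstream.
* **Blood samples** are convex mixtures over the endothelial-secretory,
  WBC-secretory, WBC-intracellular and "other" pools. Serum's
  endothelial-secretory weight (0.75) exceeds plasma's (0.40); the rest is
  spread over the non-endothelial pools.
* **Noise and measurement floor:** Gaussian noise with SD = 10% of signal
  plus an additive floor (0.1 units), then flooring at zero, then a scanner
  sensitivity floor (`censor_floor`, 0.5 units) below which values read as
  0. The censoring is what makes low-abundance probes appear stepwise along
  the dilution series — the substrate of threshold derivation. Noise-free
  simulations disable the censor together with the noise terms: "no noise"
  means an ideal measurement.
* **Time trends** are built directly in fraction space:
  `fraction(t) = f + delta x tau(t)` with `tau` linear from 0 to 1 over the
  time grid. Down-trending miRNAs take the largest base fractions
  (reserves secreted early, decreasing from initially high proportions);
  up-trending ones are drawn from the low-abundance half (newly induced
  secretion rising from low baselines). The deltas satisfy two balance
  constraints — plain mass (profiles stay on the simplex) and
  effective-slope-weighted mass (the fraction-of-total denominator stays
  constant) — so *flat* miRNAs have exactly constant normalised expression
  and zero-noise recovery is exact. Within those constraints the mass
  shares are abundance-proportional (equal relative change, the declared
  `trend_strength`, default 1 = doubling over the course); the
  slope-balance correction uses a closed-form minimal blend for the ups and
  a minimax allocation (bisection on peak relative loading) for the downs,
  with the balance target grid-searched to maximise the weakest up-member's
  shift. Conditioned media additionally accumulate total secreted signal
  linearly in time; cell-pellet totals stay level.

Grids not printed anywhere authoritative are parameters with documented
defaults: dilution inputs {12.5, 25, 50, 75, 100, 150} ng (spans the
stated range, includes the 100 ng standard, six points) and time points
{15, 30, 60, 120, 240} min (spans 15 min-4 h, denser early where secretion
dynamics change fastest).

## What the generator does and does not emulate

It emulates: per-probe linear dose response with probe-specific slopes and
a filterable non-linear minority; detection censoring; compartment
signatures with controlled intracellular/secretory overlap; donor and
medium effects with medium dominant; serum/plasma as mixtures with tunable
endothelial weight; WBC contributions; blank-medium background; monotone
secretion trends with conserved fractions.

It does not emulate: carrier heterogeneity (vesicular vs protein-bound
miRNA), haemolysis artefacts, probe cross-hybridisation, spatial array
artefacts, batch effects between hybridisation rounds, or non-monotone
temporal dynamics. Passing tests on synthetic data therefore demonstrate
the *pipeline's* correctness and the qualitative recoverability of the
designed effects — not that real arrays satisfy the generative assumptions.

# Numerical choices

* Fraction columns must sum to 1 within 1e-9; rescaling invariance is
  tested to 1e-12.
* `trend_classify()` treats a series whose relative SD is below 1e-9 as
  zero-variance (`unchanged`): balanced flat fractions are constant only up
  to floating-point summation error, and 1e-15-scale jitter must not reach
  the significance test.
* Detection ties break downward (strict `>`); undefined correlations are
  reported as `NA`, never coerced.
* Block SDs divide by *n* (population style): they describe the spread of
  the listed coefficients, not an estimator's standard error.
* The Mann-Whitney and Spearman implementations delegate to `stats`
  (`wilcox.test`, `cor.test`); the test suite cross-checks them against
  exhaustive permutation enumeration (group sizes ≤ 6) and a
  rank-then-Pearson brute force to 1e-12, keeping implementation and oracle
  on separate routes.

# Problem sizes in the test suite

The packaged tests run the full design at 800 probes (the 155/166/253
overlap), the time-course recovery at 150 probes with a secretory support
of 100 (39 up / 7 down / 54 flat), stochastic properties over 10 fixed
seeds, and oracle comparisons over 1000 random vectors — sizes chosen to
exercise every code path at comfortably interactive runtimes while keeping
binomial error bands on recovered fractions tight enough to be meaningful.

# Known limitations

* The dose-response test assumes homoscedastic Gaussian errors per probe;
  heavy-tailed probe noise would argue for a rank-based alternative.
* Fraction normalisation makes features compositional; correlations between
  fractions carry the usual closure effects, which the union-with-zeros
  policy partially mitigates but does not remove.
* The detection threshold is a single global scalar; per-array or
  per-compartment thresholds are not modelled.
* Trend classification is linear-in-time by design; saturating or pulsed
  secretion dynamics will land in `unchanged` or be misclassified, and
  belong to a spline/breakpoint extension that is deliberately out of
  scope.
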