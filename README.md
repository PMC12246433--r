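# secmiR

Tools for attributing blood-circulating miRNA signatures to the endothelial
secretome from probe-level miRNA microarray data.

The vascular endothelium both *contains* miRNAs (released into blood on
injury) and *actively secretes* a largely different miRNA panel into its
environment. Conditioned medium over endothelial cultures is the in vitro
proxy for blood; comparing cell-pellet profiles (intracellular, "int-miR")
with conditioned-medium profiles (secretory, "sec-miR"), and both against
serum and plasma, lets one ask which circulating miRNAs are endothelial and
by which route they got there. `secmiR` implements that analysis as a
reusable, tested pipeline for anyone profiling a cellular secretome on
single-channel arrays: QC, normalisation, signature building, blood-origin
classification, correlation comparison and time-course trend analysis.

## The method

For a probe *p* and sample *s* with measured intensity *I(p, s)*, the
pipeline computes, in order:

1. **Dose-response QC.** Over a serial dilution of a pooled isolate
   (12.5-150 ng around the 100 ng protocol standard), each probe's Pearson
   correlation between intensity and RNA input is tested; probes without
   significant correlation (two-sided *p* ≥ α, default 0.05) are discarded
   as non-quantitative.
2. **Detection threshold.** Walking up the dilution series, probes absent
   at one input but present at the next are *newly detected*; the threshold
   *T* is the mean intensity of all first-detection events. A probe is
   detected when *I(p, s) > T* (strict).
3. **Background subtraction.** Blank (unconditioned) medium processed
   identically is the background for conditioned-medium arrays:
   *I′ = max(I − mean(blank), 0)*, matched by culture medium.
4. **Fraction-of-total normalisation.** *F(p, s) = I′(p, s) / Σₚ I′(p, s)*
   over QC-passing (and by default detected) probes. Every sample becomes a
   point on the simplex; the transform is exactly invariant to per-sample
   rescaling, which is what tolerates variable RNA input.
5. **Signatures and partition.** Group signatures are mean-then-renormalised
   fraction vectors. Detected miRNAs split into intracellular-only,
   secreted-only, and both; blood miRNAs are classified endothelial (present
   in the reference set) or non-endothelial.
6. **Comparison.** Spearman ρ between whole signatures (union support,
   zero-filled), correlation-matrix blocks reported as mean ± SD of the
   pairwise coefficients, Student/Welch/Mann-Whitney tests between
   coefficient groups, and PCA (`prcomp`) of fraction profiles.
7. **Time course.** Per-miRNA Pearson correlation of (replicate-averaged)
   expression with time in minutes; categories *increasing / decreasing /
   unchanged* by sign at *p* < α.

A first-class synthetic generator (`generate_world()`, `simulate_arrays()`,
`preset_designs()`) emulates the full study design — donor × medium culture
grid, dilution series, secretion time course, serum/plasma/WBC blood panel —
with serialised ground truth, so every stage is testable end-to-end against
known answers.

## Worked example

```r
library(secmiR)

cfg   <- generator_config(seed = 42)          # the study's design conditions
world <- generate_world(cfg)
sheet <- sample_sheet(rbind(
  preset_designs("huvec_grid", cfg),          # 4 donors x 4 media, cells + media
  preset_designs("dilution_series", cfg),     # 6-point pooled dilution
  preset_designs("blood_panel", cfg)))        # paired serum/plasma + WBC
mat <- simulate_arrays(world, sheet, seed = 42)

res <- run_pipeline(mat, sheet, analysis_config())
print(res)
```

```
secretome_analysis
  QC: filtered fraction 0.0338; derived detection threshold 0.8436
  partition: 140 int-only / 267 both / 184 sec-only (universe 591)
  int vs sec signature: rho = -0.168 (p = 4.93e-05)
  block rho(serum, sec_sig) = 0.852 (+/- 0.002, 4 pairs)
  block rho(plasma, sec_sig) = 0.596 (+/- 0.007, 4 pairs)
  block rho(serum, int_sig) = 0.133 (+/- 0.003, 4 pairs)
  block rho(plasma, int_sig) = 0.107 (+/- 0.006, 4 pairs)
  block rho(serum, plasma) = 0.880 (+/- 0.008, 16 pairs)
```

Reading the output: ~3% of probes fail dose-response QC; the detection
threshold derived from first-detection events is 0.84 intensity units; the
detected miRNA universe splits into intracellular-only / both / secreted-only
sets; the averaged intracellular and secretory signatures are nearly
uncorrelated (the endothelium secretes a different panel than it keeps); and
serum tracks the secretory signature far more closely than plasma does,
while neither resembles the intracellular signature — the behaviour the
generator's mixture weights encode.

Individual stages are plain functions (`probe_dose_response()`,
`derive_detection_threshold()`, `subtract_background()`, `call_detection()`,
`normalize_total()`, `average_signature()`, `partition_origin()`,
`classify_blood()`, `spearman_cor()`, `block_stats()`, `trend_classify()`,
...) usable on your own matrices; `read_intensity_matrix()`,
`read_sample_sheet()` and `read_agilent_fe()` load TSV exports. A thin
command-line wrapper lives at `inst/scripts/secmir`
(`secmir simulate ... | secmir run all ...`).

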