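# ervscape

Quantitative analyses of endogenous retroviral element (ERV) regulation in
chromatin, plus the binding biophysics that accompanies such studies.

Heterochromatin factors such as KAP1 (TRIM28) and the HP1 proteins silence
ERV families (IAPEz, MERVK10C, ETn) in embryonic stem cells. Asking *which*
repeat families a factor occupies, and *what happens to chromatin
accessibility* at their LTRs when the factor is perturbed, requires a small
but exacting set of statistics. `ervscape` implements them as a tested,
reusable R package, together with synthetic-data generators that emulate the
statistical structure of every input, so the entire pipeline runs and is
verifiable without any external downloads.

## What it computes

**Repeat-family enrichment (families × datasets heatmap statistic).** For
each annotated locus of each repeat family, depth-normalized ChIP over
depth-normalized input:

    FE_i = (chip_i / N_chip) / (input_i / N_input)        (CPM ratio)

after removing low-coverage loci with less than 1 input read. Family
enrichment is the median FE over its loci; medians are then z-scored per
dataset (sample sd, so each column has mean 0, sd 1) and clustered
hierarchically with distance `1 − Spearman ρ`, average linkage.

**LTR profiles and differential accessibility.** LTRs are deduplicated so
that an integration carrying both a 5′ and 3′ LTR is represented by the 5′
LTR only; orphan (solo) LTRs are kept. Coverage is averaged in 50-bp bins
across a strand-aware −1,500/+8,000 bp window anchored at the LTR. Per-family
accessibility differences between two conditions are tested with two-sided
Wilcoxon rank-sum tests on per-anchor counts, Benjamini–Hochberg adjusted
across the families tested.

**Genome-bin correlation.** Per-base tracks summed into fixed 5-kb bins tiled
from coordinate 0, then Spearman-correlated (exact permutation p for n ≤ 9
tie-free values, t-approximation otherwise).

**Binding biophysics.**
- Ligand-depletion (quadratic) binding isotherm, fit by nonlinear least
  squares for (K_d, ΔI_max):

      ΔI = ΔI_max · ((L + P + K_d) − √((L + P + K_d)² − 4 P L)) / (2 P)

  with replicate summaries reported as mean K_d ± SD.
- NMR chemical shift perturbations per residue:
  Δδ = √(ΔδH² + (ΔδN/5)²) and Δδ_combined = |ΔδH| + 0.105·|ΔδN|,
  with apo/bound HSQC peak matching (globally optimal one-to-one assignment
  within a tolerance ellipse) and disappeared-peak calling.
- Half-bleach FRAP dip depth: Savitzky–Golay smoothing of the non-bleached
  half and `1 − min(smoothed)` around each probe time.

## Worked example

```r
library(ervscape)

fams <- sprintf("family_%02d", 1:5)
cfg <- simulationConfig(
  seed = 7, n_families = 5, loci_per_family = 20, genome_length = 5e6,
  enrichment_factors = list(chip1 = setNames(c(1, 2, 8, 1, 2), fams)),
  library_sizes = list(chip1 = list(chip = 2e6, input = 1e6)))
ann <- simulateRepeatAnnotation(cfg)
cnt <- simulateCountTable(ann, cfg)
fe  <- runEnrichmentPipeline(ann, cnt, cluster = FALSE)
round(cbind(median = rawMedian(fe), z = zscores(fe)), 3)
#>           chip1  chip1
#> family_01 0.875 -0.626
#> family_02 1.782 -0.330
#> family_03 8.217  1.763
#> family_04 1.000 -0.585
#> family_05 2.116 -0.222
```

The family with the planted 8× enrichment (family_03) has a raw median fold
enrichment near 8 and by far the largest z-score; factor-1 families sit near
1. Fitting a noiseless titration recovers its parameters to machine
precision:

```r
ts <- simulateTitration(kd = 0.5, delta_i_max = 1, p_total = 1,
                        ligand_series = c(0.1, 0.25, 0.5, 0.75, 1, 1.5,
                                          2, 3, 4, 6, 8, 10))
fitBindingIsotherm(ts)
#> TitrationFit: Kd = 0.5 +/- 5.66e-16, dImax = 1 +/- 2.01e-16 (converged)
```

And the planted FRAP dip is read back from a noisy curve:

```r
cur <- simulateFrapCurve(dip_depth = 0.25, dip_time = 15,
                         noise_sd = 0.01, seed = 2)
frapDipDepth(cur, probe_times = 15)
#>   probe_time dip_depth t_min
#> 1         15 0.2415859 15.25
```

`runAll(system.file("extdata", "demo_config.txt", package = "ervscape"))`
executes every stage (simulate → enrich → LTR → bins) and writes a manifest
of MD5 hashes; the same config and seed reproduce it byte-identically.

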