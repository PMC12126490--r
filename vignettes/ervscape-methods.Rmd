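---
title: "ervscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ervscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervscape)
```

# Scope

`ervscape` implements the statistics used to characterise silencing of
endogenous retroviral elements (ERVs) by heterochromatin factors, and the
biophysical readouts used to characterise the protein interactions behind
that silencing. The package deliberately begins *after* read alignment:
its genomics inputs are per-locus fragment counts and per-base coverage
tracks, not FASTQ or BAM files. Trimming, alignment, duplicate filtering and
peak calling are out of scope.

# The enrichment statistic

For locus $i$ in dataset $d$ with ChIP count $c_i$, input count $n_i$ and
library totals $N_c$, $N_n$:

$$\mathrm{FE}_i = \frac{c_i / N_c}{n_i / N_n}.$$

Three conventions matter and are fixed in the code:

* **Low-coverage filter.** Loci with less than 1 input read are removed
  before anything else. This is also the (only) guard against division by
  zero — no pseudocount is added, so the fold-enrichment scale is not
  distorted at well-covered loci.
* **Family summary.** The per-family statistic is the *median* FE over its
  surviving loci (mean of the two central order statistics at even $n$).
  The median tolerates the minority of extreme loci that repeat families
  always contain; the tests verify that 5 planted 100× outlier loci among
  100 move it by less than 10%.
* **Z-score transform.** Family medians are standardized per dataset
  ("each dataset is normalized to itself") using the sample (n−1) standard
  deviation. The population/sample choice is not externally fixed; sample sd
  is this package's convention and the one R's `sd()` implements. Every
  z-score column therefore has mean 0 and sd 1 to numerical precision, which
  the test suite asserts at 1e−9.
* **Empty families.** A family with no surviving locus in some dataset is
  dropped from the matrix with a warning rather than imputed, keeping every
  z-score column well defined over the same family set.

Clustering of the resulting matrix uses the dissimilarity
$d(u,v) = 1 - \rho_\mathrm{Spearman}(u,v)$ with average linkage
(`stats::hclust`). Rows are sorted lexicographically before clustering so
leaf order is deterministic under ties; identical rows and monotone
transforms of a row merge at height 0, and a reversed ranking sits at the
maximal distance 2.

# LTR anchors, profiles and differential accessibility

A full-length ERV integration carries a 5′ LTR, internal segment and 3′ LTR;
many integrations have decayed to solitary ("orphan") LTRs. For LTR-anchored
analyses, an integration with both LTRs present is represented by its 5′ LTR
only; orphan LTRs are anchors in their own right. "Same integration" is
resolved by the annotation's `integration_id`. The anchor coordinate is the
strand-aware 5′ boundary of the kept LTR (interval start on `+`, end on `-`)
— the asymmetric window below reads naturally as "from just upstream of the
LTR into the element body".

Profile matrices average per-base coverage in bins across
$[-1500, +8000)$ bp around the anchor, reflected on the minus strand so
"upstream" is biological upstream. Defaults: 50 bp bins (190 columns). The
window extent is the analysis convention for these elements; the bin width
is this package's default since none is externally fixed. Window bins that
reach past a chromosome end are masked (`NA`) rather than clipped to zero:
zero-filling would drag column means down at edge anchors. Column summaries
report mean ± SEM over unmasked cells.

Differential accessibility between two conditions is tested per family with
a two-sided Wilcoxon rank-sum test on per-anchor counts (independent
samples — the conditions are different cell lines; an exact null is used for
combined $n \le 25$ without ties, otherwise the normal approximation with
continuity and tie correction), followed by Benjamini–Hochberg adjustment
across the family set in that invocation. Cross-assay adjustment is out of
scope. The suite checks the textbook case A = (1,2,3) vs B = (4,5,6)
(exact two-sided $p = 2/\binom{6}{3} = 0.1$), null calibration at
200 families × 30 anchors, and ≥90% detection of a planted 4× count
reduction at $n = 30$ anchors over 50 seeds.

# Genome-bin correlation

Tracks are summed into fixed-width bins (default 5,000 bp) tiled from
coordinate 0 with the last bin truncated, conserving total signal exactly.
Bins with zero signal in both tracks are retained — no filtering is applied
before correlation. Spearman's $\rho$ uses midranks for ties. The p-value is
computed by full permutation enumeration for $n \le 9$ tie-free vectors and
by the t-approximation otherwise: an exact Spearman p is combinatorially
infeasible at genome-wide $n$, and any "exact" setting in standard tools
silently falls back there too. The tests verify the exact branch against
`cor.test(..., method = "spearman", exact = TRUE)` and check that the
approximation preserves significance ordering at small $n$.

# Binding isotherm

The titration model is the ligand-depletion (quadratic) isotherm

$$\Delta I = \Delta I_{\max}\,
\frac{(L + P + K_d) - \sqrt{(L + P + K_d)^2 - 4 P L}}{2P},$$

valid when protein concentration is comparable to $K_d$, as in fluorescence
titrations of a protein domain with a peptide. Numerically, the discriminant
is clamped at zero within 1e−12 so exact stoichiometric saturation with
$K_d = 0$ returns $\Delta I_{\max}$ instead of NaN. Fitting uses
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with $K_d \ge 0$
bounded, initialized at $\Delta I_{\max} = \max \Delta I$ and $K_d$ at the
ligand concentration nearest half-maximal response. Concentration units are
caller-supplied and only required to be consistent. Replicate experiments
are summarised as mean $K_d$ ± sample SD. Self-consistency holds across four
decades of $K_d$ (relative error < 1e−6 on noiseless data), and the median
relative $K_d$ error under 1% Gaussian noise is below 5% over 100
simulations.

# Chemical shift perturbation and peak matching

Two per-residue CSP metrics are provided:

* Euclidean-weighted: $\Delta\delta = \sqrt{\Delta\delta_H^2 +
  (\Delta\delta_N/5)^2}$;
* weighted absolute (Hamming-distance form):
  $\Delta\delta_\mathrm{combined} = |\Delta\delta_H| +
  \alpha\,|\Delta\delta_N|$ with $\alpha = 0.105$, the ratio of backbone
  ¹H to ¹⁵N chemical shift ranges in an HSQC spectrum.

Both are absolutely homogeneous (scaling both shift components by $c \ge 0$
scales the metric by $c$); no fixed inequality links them.

Apo peaks (assigned) are matched to bound peaks (unassigned) one-to-one. A
pair is admissible when its displacement lies inside the
$(\mathrm{tol}_H, \mathrm{tol}_N)$ ellipse — defaults 0.05 and 0.5 ppm,
conventions surfaced in the arguments since disappearance is reported
qualitatively in practice. Among admissible assignments the package computes
the global optimum (maximum number of matches, then minimum total
Euclidean-weighted distance), found exactly per connected component of the
admissibility graph; components are tiny for realistic spectra, so this is
fast even for crowded regions, and it equals an exhaustive-assignment oracle
on every random instance tested. An unmatched apo residue is called
*disappeared* when no bound peak of at least `intensity_floor` (default 0.2)
times its apo intensity lies in its ellipse, and *unassigned* when a
sufficiently intense bound peak exists but was claimed by another residue.

# FRAP dip depth

In half-bleach FRAP of a liquid-like compartment, the *non-bleached* half
transiently loses intensity as molecules mix internally; the depth of that
dip is the readout. The trace (pre-bleach baseline normalized to 1) is
smoothed with a Savitzky–Golay filter (defaults: window 11 frames, order 3)
and the dip at probe time $t$ is $1 - \min(\text{smoothed})$ within a
symmetric ±5 s window around $t$, clamped to $[0,1]$. Only this readout is
implemented; the full mechanistic FRAP model it derives from is out of
scope, and the probe window is this package's choice since the readout
window is not externally specified.

# Synthetic data: what it emulates, what it does not

The generators produce inputs with the statistical structure the analyses
assume, each seeded independently per operation (a hash of the seed and the
operation name) so reusing one config across generators never couples their
draws. Byte-identical outputs under a fixed seed are asserted in the tests.

* **Annotation**: one synthetic chromosome; non-overlapping full-length
  integrations (5′ LTR – internal – 3′ LTR, contiguous, one strand, shared
  integration id) and orphan LTRs, placed uniformly over valid
  configurations via sorted uniform spacings. Defaults (350 bp LTRs, 5 kb
  internal segments, 30% orphans) are realistic magnitudes for rodent ERVs.
* **Counts**: negative binomial with mean = planted enrichment × input mean
  × library-size scale and a `size` (dispersion) parameter, defaulting to 10
  — ChIP-seq counts are overdispersed, and no dataset-specific dispersion is
  externally given; `size ≥ 1e6` switches to the Poisson branch. Library
  sizes differ between ChIP and input so CPM normalization is exercised
  non-trivially.
* **Titrations, peak lists, FRAP curves**: exact forward models plus
  Gaussian noise; peak positions are drawn on an amide-shift grid whose
  spacing far exceeds matching tolerances, and shifts/disappearances are
  planted explicitly.

What the synthetic data does **not** emulate: mappability artifacts, GC and
copy-number bias, fragment-length structure, spatial autocorrelation of
coverage, spectral overlap of real crowded HSQCs, or photobleaching drift.
Passing tests therefore demonstrate the *statistics* are implemented
correctly and recover planted truth under their own assumptions — not that
those assumptions hold in any particular real dataset.

Problem sizes in the tests and the acceptance script (20 families × 100
loci × 3 datasets for enrichment recovery; 200 families × 30 anchors for
null calibration; 100 noisy titrations; 50 seeds for detection power) are
the package's chosen desk-scale study conditions: large enough that sampling
error is far from the asserted margins, small enough to run in seconds.

# Degenerate inputs and errors

Zero-variance medians make the z-score undefined — error naming the dataset.
Constant rows make Spearman clustering undefined — error naming the row.
A family emptied by filtering in one condition of the differential test —
error naming the family. Annotations with overlapping loci, two 5′ LTRs in
one integration, or start ≥ end are rejected at construction/read time with
offending lines listed. Flat titrations and non-convergent fits error with
diagnostics rather than returning silently absurd parameters.
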