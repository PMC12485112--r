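---
title: "Methods: quantifying the LNP protein corona and its effect on uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the LNP protein corona and its effect on uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coronaquant)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices behind them,
and what the synthetic-data layer does and does not emulate.

## The measurement problem

Lipid nanoparticles incubated in plasma acquire an adsorbed protein layer
(the corona). Because plasma contains endogenous particles of similar
buoyant density — chiefly lipoproteins — a naive analysis of "proteins found
with the LNPs" is dominated by abundant plasma proteins rather than by
proteins that actually bind the particle. The workflow separates protein–LNP
complexes on a continuous density gradient, selects the LNP-containing
fractions by fluorescence, and quantifies proteins *relative to a
plasma-alone control separated and fractionated identically*. The
control-normalized fold change, not the within-sample relative abundance, is
the enrichment readout; `rank_comparison()` exists precisely to show how
little the two agree.

## Fraction selection

A gradient run yields per-fraction fluorescence (tracking the LNP's tagged
lipid), absorbance and refractive index. `check_gradient_linearity()` fits
OLS of absorbance or refractive index against fraction index; the default
acceptance threshold is R² ≥ 0.98, over all fractions unless a linear
sub-region is given. A constant measure is reported as R² = 0 with a
warning (no gradient formed). Window recovery is the windowed share of total
fluorescence; blank subtraction is available but **off by default**, since
plasma autofluorescence at the rhodamine wavelengths used for LNP tracking
is negligible; when a blank is supplied, background-corrected values below
zero are clipped to zero before summing. `select_fractions()` enumerates all
contiguous width-k windows and breaks ties toward the earlier window — the
low-density side where intact LNPs ride, away from late free-fluorophore
signal.

## Hi3 quantification and enrichment

Within one run (condition × technical replicate × batch), a protein's
absolute amount is the spiked-standard amount (default 50 fmol per 5 µL of
digest, E. coli ClpB, accession P63284) times the ratio of the protein's to
the standard's mean top-3 peptide intensity. Numerical conventions:

* Top-3 ties break by `peptide_id` lexicographic order, so results are
  permutation-invariant.
* Proteins with fewer than three usable peptides are quantified from all
  available peptides and flagged rather than dropped.
* Peptides missing in more than one replicate of a condition × batch are
  excluded from that condition × batch entirely (logged); isolated missing
  values simply don't contribute to their run.
* fmol values follow the per-5-µL spike convention; no volume rescaling is
  attempted. Per-run values are reported and can be averaged per condition
  downstream — both views are available from the per-run table.

Enrichment compares log2 abundances between conditions with Welch's t-test
and Benjamini–Hochberg correction across all tested proteins. The
per-protein test behind vendor-software q-values is not part of any open
specification; Welch on log2 abundances was chosen as a transparent,
unequal-variance-robust standard for label-free data, and the suite verifies
its calibration directly (null FDR ≤ 0.05 over 200 simulated null
proteomes). Two deliberate edge policies:

* Zero abundances are floored at half the smallest nonzero abundance of the
  same run before taking logs (reported via a message), the usual
  half-minimum imputation.
* Proteins detected in only one condition are *not* given infinite fold
  changes; they are reported separately (`lnp_only` / `plasma_only`
  attributes).

Cross-batch consistency (`consistent_enrichment()`) intersects the enriched
classifications of independently processed batches; proteins enriched in
every batch are the robust hard-corona candidates. Term over-representation
uses the EASE score: the one-sided Fisher exact p with one protein removed
from the query–term overlap (same margins), which penalizes terms supported
by very few proteins; defaults `min_count = 5`, `p ≤ 0.05` follow the
conventional annotation-analysis thresholds.

## Imaging quantification

Per field of view: nuclei are counted by Otsu thresholding plus 8-connected
component labeling with a minimum-area filter; the membrane (cytoplasmic
stain) channel is thresholded into a cell mask; the cargo (Cy5) channel is
background-corrected by subtracting the median intensity *outside* the cell
mask, without clipping, so zero-mean noise cancels in the in-mask sums.
Per-cell uptake is the in-mask Cy5 sum divided by the nuclei count —
deliberately a per-FOV measure, not a per-cell-instance distribution.

The inner/outer partition erodes the cell mask n = 10 times with a full 3×3
structuring element; the outer mask is the exclusive disjunction of the cell
mask and the inner mask. Two implementation details matter:

* Pixels outside the image count as background: the mask is zero-padded by
  one pixel per iteration and cropped back, so masks touching the image
  border erode there too. Without this, a border-touching cell would never
  lose its rim on that side. The suite verifies the partition against an
  independent Chebyshev distance-transform oracle
  (inner ⇔ distance-to-background > n) on hundreds of random blob masks.
* Thresholded masks are cleaned by a 3×3 opening plus hole filling before
  erosion. Shot noise otherwise punches pinholes into the stained region,
  and a single interior hole carves a (2n+1)×(2n+1) void out of the eroded
  inner mask.

The membrane dye used for the cell mask is cytoplasmic, so the "membrane
mask" is interpreted as whole-cell area — the erosion analysis only makes
sense under that reading — and the rim is attributed to surface-associated
signal. This interpretation is flagged here rather than asserted as the only
one possible. FOVs with zero detected nuclei or zero in-mask signal are
excluded with a warning (an explicit policy; exclusion rules are rarely
stated in imaging methods). FOV values are mean-aggregated to technical
replicates (three FOVs per technical replicate in the emulated acquisition)
and then to biological replicates, keeping both levels for nested
statistics.

## Statistical layer

`normalize_to_control()` divides each value by the mean control value of its
own biological replicate, cancelling plate-scale effects.

`nested_anova_dunnett()` treats condition as fixed and biological replicate
as the nested error stratum: F = MS(condition)/MS(replicate-within-condition),
so technical pseudo-replication cannot inflate significance. Dunnett
comparisons use biological-replicate means as the error unit; for balanced
designs this is algebraically the same stratum, and for unbalanced designs
it is the documented fallback (no Satterthwaite machinery is attempted).
With a single sub-value per replicate the procedure reduces exactly to
one-way ANOVA on replicates (verified to 1e-9).

`rm_anova_gg_dunnett()` handles complete blocks. The Greenhouse–Geisser
epsilon is computed from the sample covariance matrix of the
subject × condition measurements,
ε = (k(s̄_d − s̄))² / ((k−1)(ΣΣ s_ij² − 2k Σ s̄_i² + k² s̄²)), clamped to
[1/(k−1), 1], and both F degrees of freedom are multiplied by ε; with two
conditions ε = 1 identically. The implementation is cross-checked against
`car::Anova`'s GG output in the suite.

Dunnett adjusted p-values are computed from the multivariate-t distribution
with the many-to-one correlation structure
(λ_i = √(n_i/(n_i + n_0))) via `mvtnorm::pmvt` with deterministic
Genz–Bretz quadrature (absolute tolerance 2e-4 under a fixed internal seed)
— accurate far beyond the α = 0.05 decisions it feeds, and cheap enough to
calibrate by simulation: the suite checks the family-wise type-I error of
the full procedure over 2000 null repetitions (5 conditions × 3 biological
× 4 technical replicates) against 0.05 ± 3 Monte-Carlo SE. Adjusted
p-values are floored at the unadjusted p to guard against quadrature noise
violating monotonicity.

`flow_gate()` sets the positive gate at a quantile of untreated-control
events. The gate quantile is a free parameter of any such gating scheme;
0.995 (a 0.5% control false-positive rate) is the package default and is
exposed in every interface. MFI is reported over all events, with the
gated-events variant alongside.

## The synthetic-data layer

Every input has a generator with recorded ground truth, so each analysis
stage is testable end to end. All randomness flows from one seed through
labelled sub-streams; identical config + seed gives bit-identical output.

* **Fractions.** Fluorescence is a discretized-Gaussian sharp early peak
  plus a broad late peak (free dye dissociating from the particle — its
  shape is not constrained by any physical model, so both peaks are free
  parameters) on a flat baseline with clipped Gaussian noise. Defaults put
  68% of total mass in the early peak centered at fraction 4 (σ = 0.9
  fractions) and 32% in the late peak (center 16, σ = 4), the
  characteristic split for rhodamine-tagged LNPs on a 24-fraction iodixanol
  gradient; the baseline is zero (plasma autofluorescence is negligible)
  and noise σ = 0.2 a.u. Absorbance and refractive index are linear ramps
  (0.02→0.35 a.u.; 1.335→1.430) with small noise. The truth stores the
  exact noiseless component masses, so the true windowed percentage is
  recomputable to machine precision.
* **Peptides.** Intensity = abundance × per-peptide response factor ×
  mean-preserving log-normal noise with σ² = ln(1 + CV²) — the standard
  multiplicative model for MS intensities. Response factors are drawn once
  per peptide, log-uniform on [0.2, 5], so top-3 selection is nontrivial.
  Technical CVs differ by condition; the defaults are calibrated so the
  *observed* median sample CV at n = 3 replicates is 11.8% (LNP) and 19.0%
  (plasma): a sample CV from n replicates underestimates the population CV
  by ≈ √(χ²₀.₅(n−1)/(n−1)) (≈ 0.833 at n = 3), inverted by
  `calibrate_cv()`. The default truth over 56 proteins has 39 enriched
  (log2 FC uniform in [1.2, 4.5]), 14 depleted ([−4, −1.2]) and 3 null —
  the composition of a typical corona-vs-plasma comparison; base abundances
  are log-uniform on [5, 500] fmol.
* **FOVs.** Disk nuclei inside non-overlapping disk cells, an optional
  lysosome channel of small interior disks, and Cy5 puncta
  (Poisson-counted per cell per compartment, fixed integrated amplitude)
  blurred by a Gaussian PSF with Gaussian shot noise of sd
  ∝ √intensity — the Poisson-approximating noise model for photon
  counting. Because n-fold 3×3 erosion is a Chebyshev-metric operation, a
  disk loses up to n√2 px of Euclidean radius at the box corners; inner
  puncta and lysosomes are placed at radius < cell_radius − √2·rim_width
  (minus a blur margin) so placements are classified consistently by the
  erosion partition. The truth records every placement, per-compartment
  counts, true per-cell signal and true outer fraction.
* **Flow.** Normal control events and location-shifted treated events; the
  truth stores the exact fraction of treated events above the empirical
  control gate.

What the generators do **not** emulate: spectral bleed-through, z-structure
or depth effects, chromatography, spectra or peptide identification,
gradient sedimentation physics, cell-shape heterogeneity, or heavy-tailed
flow populations. Passing tests therefore demonstrate that the analysis
code recovers known truth under idealized-but-noisy conditions; they do not
certify segmentation or quantification performance on real micrographs or
real LC-MS/MS output.

## Problem sizes used by the checks

The suite and `scripts/acceptance.R` use: 500 random blob masks for the
erosion/distance-transform equivalence; 200 simulated proteomes each for
the null-FDR and the log2-FC-recovery calibrations; 12 FOVs per condition
for imaging fold-change (rates 5 vs 25) and outer-fraction (1:9 split)
recovery; 2000 (suite) / 1000 (script) null repetitions for the nested
Dunnett family-wise error; 20 000 events per flow sample. These sizes give
Monte-Carlo errors comfortably below the assertion tolerances.

## Known limitations

* Protein inference stops at accession-level aggregation; no peptide
  sharing or protein grouping.
* The nested ANOVA does not fit random-effect variance components
  (no REML); unbalanced designs fall back to replicate means.
* Only Dunnett many-to-one comparisons are provided.
* Flow gating has no compensation/spillover handling.
* Imaging is strictly 2D and per-FOV; no single-particle tracking or
  per-cell-instance distributions.
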