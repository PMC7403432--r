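---
title: "Models and methods behind glycomn"
author: "glycomn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycomn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

glycomn analyses three assays around one biological question: what a
hypo-functioning SLC39A8 (ZIP8) manganese transporter genotype does to
serum manganese, to plasma protein N-glycosylation, and to regional brain
T2w/T1w MRI signal. This vignette documents the models, the tunable
parameters, the synthetic-data generators and the numerical choices, and
states what the tests do and do not demonstrate.

## 1. Permethylated glycan mass model

A permethylated N-glycan observed as a singly charged sodiated ion has

m/z = Σ counts × m(residue) + m(end groups) + m(Na⁺),

where the permethylated residue masses are computed from elemental
formulas (HexNAc C11H19NO5, Hex C9H16O5, dHex C8H14O4, NeuAc C16H27NO8 —
the NeuAc carboxyl is methyl-esterified during derivatization) and the
end-group correction is net H2O + 2 CH2 (the methylated anomeric hydroxyl
plus the non-reducing terminus). Nothing is hard-coded beyond the
formulas: masses derive from atomic monoisotopic masses at run time. The
test suite re-derives every mass by a second, independent route (explicit
molecular-formula assembly from fully methylated free monosaccharides,
removing H2O + 2 CH2 per glycosidic bond) and checks agreement to 1e-6 Da.

Hex pools Man and Gal: they are isobaric, and mass spectrometry alone
cannot separate them. Likewise a bisected n-antennary composition equals
an (n+1)-antennary one, and core versus antenna fucose are isobaric.
These ambiguities are resolved by curated structural labels on the panel
(the approach used in practice: deductive reasoning plus prior MS/MS
knowledge); the composition-based heuristics in `classifySpecies()` apply
only to unlabeled compositions.

## 2. The 57-species panel

`buildDefaultPanel()` ships a curated panel of 57 plasma N-glycan species
as a versioned JSON document. The species set and its baseline (reference
genotype) profile were assembled from the well-characterized human plasma
N-glycome: dominated by the disialylated bi-antennary species A2G2S2,
with category totals mono-antennary 1.09%, bi-antennary 88.0%,
tri-antennary 6.77%, tetra-antennary 0.574%, high-mannose 3.4%, hybrid
0.166%, bisecting 7.83% and antenna-fucosylation 2.09%. The first four
and the anchor species values (A2G1S1 0.439%, A3G3S3 3.68%, A3FG3S3
1.58%) are the reference values this package is calibrated to; the
high-mannose/hybrid split is our choice, because the printed reference
category values are rounded and do not sum exactly to 100 — the panel
baseline must (and does) sum to exactly 100. Panel invariants enforced by
the class validity: unique names, m/z within 0.01 Da of the mass engine,
all species inside the 1500–5000 acquisition window, and pairwise m/z
separation greater than twice the annotation tolerance (the actual
minimum spacing in the panel is ~5 Da).

## 3. Synthetic spectra and quantification

Spectra are rendered on a uniform m/z grid (default step 0.1 Da) as
Gaussian peaks centered at each species' theoretical m/z with area
proportional to abundance, plus a flat baseline and white Gaussian noise.
Defaults: peak sigma 0.5 Da (reflectron-like widths at this mass range),
baseline 20 and noise SD 5 against a total signal of 1e6 area units.
Isotope envelopes and matrix/adduct artifacts are deliberately not
simulated — quantification uses one annotated monoisotopic peak per
species, so the envelope would add realism but no information.

Peak picking finds local maxima above (median intensity) + SNR × (MAD)
and refines each apex by three-point parabolic interpolation in log
intensity. The logarithm of a Gaussian is exactly quadratic, so for a
noise-free peak this recovers centroid and apex height to machine
precision — this is why the noise-free synthesize→pick→annotate→normalize
round trip is an identity to better than 1e-6 percent, a property the
acceptance tests assert. The reported intensity is the interpolated apex
height above baseline (the common "peak intensity" reading; area is what
synthesis controls, and height = area/(σ√2π) with a common σ, so the two
are proportional and normalization cancels the difference).

Annotation assigns each picked peak to the nearest panel m/z within a
±0.5 Da tolerance (panel spacings are ≥5 Da, so this is conservative);
exact ties go to the lower-m/z species; unassigned peaks are returned in
a QC side channel. Relative abundance is 100 × species signal / total
panel signal, so every profile sums to 100 by construction.

## 4. Group statistics

All genotype comparisons follow one scheme: one-way ANOVA (classic
equal-variance F, df = groups − 1, i.e. 2 for CC/CT/TT) followed by
pairwise Welch (unequal-variance) two-sided t-tests, with per-group means
and SEMs, percent change relative to the reference genotype, and
significance stars at 0.05/0.01/0.001. No multiple-testing correction is
applied across the 57 glycans in the primary tables — raw p-values with
stars are the convention being reproduced — but a Benjamini–Hochberg FDR
column is emitted alongside for transparency. Heat-map matrices clip at
±50 percentage points for relative change (±5 for absolute change) for
display only; unclipped values are retained. Monosaccharide contribution
is count-based (each residue counts equally within its glycan); a
mass-weighted variant is available via `weight = "mass"` since the
convention is not uniquely determined.

## 5. Trace elements

The MDL convention is the EPA-style single-sided 99% Student-t bound:
MDL = t₀.₉₉,ₙ₋₁ × SD of n = 7 replicate low-level QC runs (multiplier
3.143 at n = 7, computed from the t distribution); a plain 3 × SD
alternative is provided. Inclusion uses a strict mean > MDL rule over all
samples. Sub-MDL measurements are retained as measured in statistics by
default (matching the practice of plotting values against an MDL line
rather than censoring); `censor = TRUE` substitutes MDL/2.

The generator draws lognormal concentrations (positive, right-skewed)
per element. Only Mn carries a genotype effect by default, with means
0.814/0.732/0.669 μg/L for CC/CT/TT. The common CV defaults to 20%: this
is back-computed from the reference significance pattern (a CC-vs-TT
Welch p ≈ 4e-4 at group sizes 46/25 implies a standardized difference
near 0.9, i.e. CV ≈ 0.20); a larger CV would not reproduce that pattern
at those sample sizes. Seven designated elements (Be, Cd, Ni, Pt, Te,
Tl, W) have configured means at 0.25 × their MDLs, and included elements
sit at ≥3 × MDL, so the 16/7 inclusion split is stable against the
sampling noise of an SD estimated from 7 runs (the probability of a flip
is < 1e-3 per panel).

## 6. T2w/T1w neuroimaging

The ratio image T2w/T1w cancels any per-subject multiplicative intensity
factor applied to both acquisitions (coil loading, body size), which is
the reason to analyze the ratio rather than either raw image; the
generator applies a random ×[0.8, 1.2] global scale to both volumes of
each subject precisely to exercise this invariance. Voxel-wise contrasts
use Welch t-tests vectorized over in-mask voxels with BH-FDR control
across in-mask voxels only, two-sided, no cluster-extent thresholding.
Registration and ROI drawing are out of scope: volumes are assumed
co-registered and the ROI label map given (the generator emits aligned
data by construction).

ROI inference is one-way ANOVA plus Dunnett's many-to-one test with the
reference genotype as control. The Dunnett adjustment is computed by
seeded Monte-Carlo integration of the equicoordinate multivariate-t
distribution (default 2e5 draws; the one-factor correlation
ρjk = λjλk, λj = √(nj/(nj+n0)) admits an exact shared-factor construction,
so no general multivariate integration is needed). Monte-Carlo standard
error on an adjusted p near 0.05 is ≈ 5e-4 at the default draw count.
With one comparison the exact pooled-variance t-test p is returned. The
implementation was validated against mvtnorm's equicoordinate quantiles
(k = 2, df = 20: 2.379) and against multcomp's adjusted p-values.

Genotype classification is a Fisher linear discriminant on standardized
ROI features, with ridge regularization only if the within-class
covariance is singular (a warning is raised). The ROC is traced over the
discriminant score and the AUC computed from the Mann–Whitney rank
statistic; leave-one-out scoring is available because resubstitution AUC
is optimistically biased (and LOO is known to be mildly pessimistic
under the null — the held-out point repels its own class mean).

The MRI generator is schematic: a 64³ spherical brain with ellipsoidal
GPi/SN/LPut blobs and a white-matter shell, chosen for desk-scale speed,
not anatomy. Genotype effects are additive ratio offsets inside ROIs
(TT: GPi −0.026, SN −0.014, LPut +0.024, WM +0.012; CT same directions,
smaller), with per-subject ROI-level random effects and voxel noise. The
ROI-level SDs (GPi 0.029, SN 0.016, LPut 0.027) are calibrated so each
configured CC-vs-TT contrast is a standardized effect of ≈0.9. We note
the reference values could not be matched simultaneously in both their
dispersions and their p-values (the printed SDs imply much weaker
standardized effects than the printed Dunnett p-values do); we calibrate
to the significance pattern, which is the property the recovery tests
consume.

## 7. Synthetic cohorts and what passing tests mean

`generateCohort()` draws one base age/sex/BMI covariate set and shares it
across genotypes before jittering — "perfect matching plus noise" — which
emulates a matched biobank selection without modelling selection itself.
Glycome profiles are Dirichlet draws (concentration 150, back-computed
from the reference bi-antennary contrast at the reference group sizes)
around genotype mean profiles built by proportionally rescaling panel
species inside each antennarity category to hit the configured category
means (CT/TT shift tri/tetra-antennary mass toward bi-antennary), then
renormalizing to 100. Every generator returns its ground truth and is
bit-reproducible given (config, seed).

Problem sizes used by the tests and the acceptance script — chosen as
desk-scale analogues of the reference cohorts: glycome 33/31/25 samples, elements
46/46/25 (n = 117), MRI 46/44/43 subjects on the 64³ grid; effect-recovery
suites use 20–100 seeded replicates per assay; the voxel-wise null
calibration uses 20 replicates of 8-vs-8 subjects.

What the generators do *not* emulate: isotope envelopes and instrument
artifacts, batch effects, real covariate–outcome correlations,
anatomical geometry, registration error, and any between-assay
correlation within subject. Passing recovery tests therefore shows that
the analysis stages correctly detect the statistical structure they are
pointed at, under clean compositional/lognormal/Gaussian noise — not that
they would be robust to the full messiness of real acquisitions.

## 8. Numerical choices and degenerate inputs

- Annotation tolerance ±0.5 Da, configurable; ties break to the lower
  m/z, documented and tested.
- Empty compositions, all-zero profiles (an uninterpretable low-signal
  spectrum), groups with fewer than 2 samples, empty ROIs, constant
  covariates and a missing control group all raise informative errors
  rather than propagating NaN.
- Zero-variance features return F = 0, p = 1 (identical-group
  convention) instead of 0/0.
- Relative change against a zero reference mean is flagged NA with a
  warning rather than reported as infinite.
- Sub-seeds for per-subject simulation streams are drawn below 2³¹ from
  the master seed, and all seeded code restores the caller's RNG state.

## 9. Known limitations

- The packaged panel is a faithful, constraint-satisfying stand-in for
  a full reference species table, not a verbatim copy of one;
  per-species values beyond the documented anchors are plausible rather
  than authoritative.
- Spectrum quantification assumes well-separated single peaks; heavily
  overlapping species or shifted calibration would need recalibration
  and deisotoping, which are out of scope.
- The Dunnett Monte-Carlo p is stochastic at the 1e-3 level; supply
  `nsim` and `seed` where exact reproducibility across calls matters.
- SVM classification, nonlinear registration, volumetrics and O-glycan /
  glycolipid analysis are deliberately out of scope.
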