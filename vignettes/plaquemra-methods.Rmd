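---
title: "Quantifying targeted iron-particle binding in carotid MR angiography: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying targeted iron-particle binding in carotid MR angiography: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Atherosclerotic plaques rupture and cause stroke when they are inflamed,
not merely when they are large. Microparticles of iron oxide (MPIO)
conjugated to antibodies against the endothelial adhesion molecules
VCAM-1 and P-selectin bind to inflamed endothelium and, being strongly
paramagnetic, extinguish the bright blood signal of time-of-flight MR
angiography (TOF-MRA) wherever they accumulate. In the cuff-implanted
ApoE-deficient mouse, a tapered peri-arterial cuff on the right common
carotid artery (RCCA) creates reproducible shear-stress zones along a
single vessel: low shear upstream (vulnerable, inflamed plaques), high
shear inside the cuff (disease-free), oscillatory shear downstream
(stable plaques). The left carotid (LCCA) is untouched and serves as the
within-animal control.

`plaquemra` implements the quantitative chain that turns a pair of
pre-/post-contrast 3D volumes into a per-region scalar measure of bound
particles, plus the histological metrics and statistics used to validate
that measure, and a synthetic phantom generator that makes the whole
chain testable without animal data.

## The signal statistic

For one artery the pipeline is:

1. **Realignment** — a pure axis permutation/reversal brings the
   cranio-caudal axis last, slice index increasing from the
   brachiocephalic branch.
2. **Registration** — the post-contrast volume is aligned to the
   pre-contrast reference by exhaustive search over integer-voxel
   translations within a window (default ±5 voxels), maximizing the
   Pearson correlation of intensities over the overlap. Ties resolve to
   the smallest translation, so identical volumes register at zero
   shift. Out-of-field voxels are filled with the mode of the border
   intensities.
3. **Threshold selection** — Otsu's between-class-variance criterion on a
   256-bin histogram of the control carotid; the same threshold is then
   used for every carotid of the scan session. An absolute override is
   available.
4. **Binarization** — voxels strictly above the threshold are "on".
5. **ROI delineation** — the 26-connected component of the pre-contrast
   mask containing a seed voxel (by default the brightest voxel of the
   branch slice); disjoint bright structures are excluded.
6. **Area curves** — per slice, the count of on-voxels inside the ROI
   (optionally scaled by pixel area to mm²).
7. **Region partition** — from four landmark slices (branch, proximal and
   distal cuff ends, bifurcation): the branch-to-cuff span is split into
   equal thirds R1/R2/R3 (remainders to the most proximal regions), R4 is
   the closed in-cuff interval, R5 runs from below the cuff to the
   bifurcation.
8. **ΔAUC** — per region, the area under the per-slice area curve
   (rectangle rule, unit slice width) for pre minus post. Bound particles
   darken lumen voxels, so binding yields a positive ΔAUC in units of
   pixel·slices; negative values are permitted and flagged.

The rectangle rule rather than a trapezoid is deliberate: on binary data
it makes ΔAUC equal a voxel count, so the generator's ground truth (how
many lumen-wall voxels were flipped) is an *exact* oracle, and the
statistic is invariant to any threshold strictly between the background
and lumen intensity modes.

When several serial post-injection scans are supplied, the one with the
largest total ΔAUC over R1–R5 after registration is retained (the scan
with the largest hypointense effect) and the choice is recorded in the
result's provenance attribute, together with the threshold, shift,
correlation and ROI size.

## Histological metrics

* **Vulnerability index** = (%macrophage + %necrotic core) /
  (%smooth-muscle cells + %collagen); higher is more unstable. The index
  is undefined (an error) at a zero denominator, and strictly monotone in
  each argument.
* **AHA lesion typing** is rule-based on six feature flags with a
  "highest applicable type wins" precedence: surface defect or
  haemorrhage → VI; necrotic core → V; lipid core → IV; lipid pools →
  III; foam cells → II; nothing → I. The precedence reading and the OR
  between surface defect and haemorrhage are interpretive choices
  consistent with reported composite sections (type-VI plaques that also
  carry necrotic cores); type I is emitted for feature-free sections so
  null synthetic data remain classifiable.
* **Per-region type distributions** are per-section percentages, rounded
  to one decimal with a largest-remainder correction so each region sums
  to exactly 100.

## Statistics

Two-sided two-sample Student's t-tests (pooled variance; Welch behind a
flag) compare regions pairwise among R1, R2, R3, R5 — the in-cuff R4 is
excluded as the disease-free athero-protective zone — and
treated-vs-untreated arms per region and week. Raw p-values are reported
at α = 0.05; a Holm-adjusted column is added for rigour but is not used
for the significance flag, matching the original analysis. Degenerate
input has a defined answer: two identical constant samples give t = 0,
p = 1; constant samples with different means give p = 0. Signal-biomarker
relationships use the Pearson product-moment correlation (Spearman
optionally). Box-and-whisker summaries follow the Tukey convention
(1.5 × IQR whiskers).

## The synthetic cohort: what it emulates

The phantom is a bright tube (lumen ~100, background ~20 by default) on a
dark background with additive Gaussian noise (default σ = 5% of the
lumen-background gap; Rician noise available as an option — at
bright-blood TOF SNR the Gaussian approximation is adequate and keeps the
noise-free oracles exact). Plaque narrows the lumen radius per region
(defaults 30%/30%/15%/0%/5% for R1–R5). Binding is placed on the
outermost ~1.5-voxel lumen-wall ring — endothelial adhesion, not bulk
lumen — as a seeded random subset of ring voxels whose size is the
region's binding fraction; the flipped count per region is recorded as
ground truth.

The cohort design mirrors the study arms (8/8/5/5 animals; weeks
10/15/20/30; RCCA cuffed, LCCA control; histology at the final week).
The untreated dual-targeted arm follows a non-decreasing binding
trajectory in R1/R2 (means 0 → 0.15 → 0.30 → 0.45 of ring voxels) and a
modest one in R3 (0 → 0.05 → 0.08 → 0.10); each animal's fraction is
drawn from a truncated normal with 20% relative spread, which is the
between-animal variability that powers the group comparisons. Three
modelling choices deserve emphasis:

* **R5 is modelled as a configured null.** The study describes binding in
  the downstream stable-plaque zone as negligible/minimal, and its
  treated-vs-untreated comparison in R5 as non-significant; any
  persistent non-zero offset against an exactly-zero treated arm would
  make that comparison significant at these noise levels. Histology R5
  remains low-but-non-zero.
* **The statin arm's quantifiable binding is zero at every week.** The
  study reports no significant inter-region signal differences in the
  statin arm at any stage; a jointly non-significant pattern across six
  region pairs and four weeks is only compatible with a degenerate
  (no-signal) arm, so the generator models complete suppression of
  adhesion-molecule-mediated binding. Transiently visible "mild" signal
  on images is below quantification and not modelled.
* **Linear signal-biology coupling.** No quantitative relation between
  biomarker burden and bound-particle count is published; the phantom's
  monotone coupling (binding fraction tracking region risk) is our
  modelling choice.

Histology distributions are truncated normals on [0, 100] whose means
order the regions as reported (inflammation and lipid: R1 ≈ R2 > R3 > R5
untreated; statin reduces R1–R3 inflammation to 40% and R2/R3/R5 SMC to
60% of untreated; collagen is carried with an invented distribution
because the vulnerability index requires it). AHA feature flags are
independent Bernoulli draws with per-(arm, region) probabilities chosen
to reproduce the reported per-region type compositions (e.g. untreated
R1: P(surface defect) = 0.41, P(necrotic core) = 1).

What the phantom does *not* emulate: partial-volume boundaries, flow and
susceptibility artefacts, T2* blooming (a bound particle darkens exactly
one voxel), vessel curvature, deformable motion, and any quantitative
link between stain area and feature flags. Passing tests therefore
demonstrate the correctness of the measurement chain and the statistical
machinery under the design's assumptions, not the biological fidelity of
MPIO imaging.

## Numerical choices and edge cases

* Otsu ties (empty bins between well-separated modes) resolve to the
  middle of the tied plateau, landing the threshold mid-gap; a constant
  image is a degenerate-input error.
* Registration ties resolve to the smallest translation (L1, then
  lexicographic); flat volumes are degenerate-input errors; a best
  correlation below 0.8 sets a `low_correlation` flag (the true
  displacement may lie beyond the window).
* A perfectly axially-uniform cylinder makes axial shifts unidentifiable
  (any axial translation matches over the overlap); region-dependent
  narrowing in realistic phantoms provides the axial structure that
  breaks this degeneracy, and the tie-break returns the smallest shift
  for the degenerate case. Relatedly, landmarks must not sit at the
  volume edge: if heavily darkened slices touch the border, an axial
  shift can crop them out of the NCC overlap and spuriously win, so the
  phantom keeps a margin before the branch and after the bifurcation,
  as a real neck acquisition does.
* Slice indices are 0-based in all landmark/partition interfaces
  (matching the slice-number axis of the area curves); array coordinates
  in R code are 1-based and documented as such.
* The 26-connected component extraction is a compiled flood fill; R4/R5
  boundary slices belong to the cuff interval (closed), and three-way
  split remainders go to R1 (and R2).
* NIfTI round-trips double precision exactly and is the canonical
  format; TIFF stacks follow the unit-range float convention of the TIFF
  library and round-trip at single precision.

## Problem sizes

The default phantom grid is the study's acquisition matrix
(256 × 256 × 64). The packaged tests and the acceptance script use
reduced grids — 64 × 64 × 32 for the oracle-equivalence loop,
40 × 40 × 32 for cohort-scale pattern checks (20 simulated cohorts),
32 × 32 × 24 for registration recovery (50 + 50 cases), and 200
reduced-size null cohorts for type-I calibration — sizes chosen so the
full suite completes in minutes on one core while exercising identical
code paths. Type-I calibration runs on the null histology design, where
the four regions are exactly exchangeable; the imaging route would mix
unequal region sizes (hence unequal count variances) into a
pooled-variance calibration check.

## Known limitations

* Registration is integer-voxel translation only; same-session scans
  need no rotation or deformation, but inter-session drift beyond the
  window is only flagged, not corrected.
* ΔAUC conflates particle binding with any other pre/post lumen-area
  change (e.g. vasomotion); the control artery and IgG arms bound this
  in the design but cannot remove it per-voxel.
* The per-section AHA percentages weight every section equally; a
  per-animal weighting would differ when section counts vary.
* The acceptance patterns are statements about the synthetic design's
  statistical behaviour, with thresholds fixed in advance by that
  design; they are not estimates of in-vivo effect sizes.
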