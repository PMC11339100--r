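---
title: "Phantom-based comparison of flat-panel and multidetector CT perfusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based comparison of flat-panel and multidetector CT perfusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctperf)
```

## What this package is for

Flat-panel detector CT perfusion (FDCTP), acquired on the angiography
C-arm, is an attractive alternative to conventional multidetector CT
perfusion (MDCTP) in acute stroke because it can be obtained in the
intervention suite. The two acquisitions differ radically in temporal
sampling: an MDCTP-like protocol collects ~30 volumes of ~0.5 s each over
~48 s, while a flat-panel C-arm performs 10 rotational sweeps of 5 s with a
1 s turnaround (6 s pitch), the first two serving as unenhanced mask runs.
Clinically, hypoperfusion volumes delineated visually on Tmax/TTP maps agree
well between the techniques, absolute thresholded volumes (Tmax > 6 s,
rCBF < 30%) agree much less, and hemispheric median normalization largely
restores the agreement for Tmax.

`ctperf` makes that comparison reproducible end-to-end on synthetic data: a
digital perfusion phantom renders the same ground-truth scene under both
protocols, a deconvolution engine computes Tmax/TTP/CBF/CBV/MTT maps, a
volumetry stage applies the standard absolute, relative and normalized
thresholds, and an agreement battery (Pearson r with Fisher CI, ICC,
Bland-Altman, mixed-model method contrast, Wilcoxon-Mann-Whitney) quantifies
between-protocol agreement across a simulated cohort.

## The phantom

`make_default_scene()` builds a 64 x 64 x 24 grid at 2 x 2 x 4 mm (a
desk-scale size chosen so the whole pipeline runs in seconds while a
~100 ml lesion remains representable): an ellipsoidal brain (gray-matter
rim, white-matter centre) inside a skull shell surrounded by air, one
wedge-shaped hypoperfused lesion in the right hemisphere, and a 3 x 3 x 5
voxel artery in the left hemisphere. Tissue values are the conventional
physiologic ones: CBF 60 (gray) / 25 (white) ml/100g/min, MTT 4 / 5 s,
baseline 35 / 30 HU. Labels are mirror-symmetric about the sagittal
midline, so every lesion voxel has a homologous contralateral partner.
Healthy tissue does not enhance simultaneously: on top of small
gray/white arrival offsets (0.3 / 0.7 s) a linear anterior-to-posterior
gradient spreads healthy arrival over ~1.5 s, as territory and drainage
differences do in vivo; without that spread all healthy curves would share
one bolus phase and sampling artifacts would hit them coherently, which no
real brain exhibits.

The lesion multiplies CBF by `lesion_cbf_fraction` (default 0.4) over the
hypoperfused extent and by `core_cbf_fraction` (default 0.15) in a deep
white-matter core, and adds `lesion_delay` seconds of bolus delay. Transit
time lengthens as flow falls (MTT/fraction, capped at 6 s: longer transit
would push lesion curve tails past the ~48 s acquisition, and the truncated
tails would masquerade as extra flow). The core is placed in deep white
matter deliberately: the rCBF reference tissue is the contralateral
centrum-semiovale-like white matter, so the < 30% core criterion compares
like with like.

Two scene parameters deserve explanation:

* **`delay_taper`** (default 0). Real penumbrae are graded: the delay is
  severe at the centre and mild at the rim. With taper `a`, the added delay
  is `lesion_delay * (1 - a * edge_frac)`. The default 0 gives the
  homogeneous lesion used in the recovery tests (the whole extent delayed by
  exactly `lesion_delay`); cohort simulations draw `a` from U(0.75, 0.9),
  calibrated so that the simulated MDCTP Tmax > 6 s volume is roughly half
  the visible volume, the proportion reported for real stroke cohorts.
* **`vessel_partial_volume`** (default 0.3). Tissue is perfused by the true
  arterial concentration while the vessel voxels (and hence the detected
  AIF) record only this fraction of it - the familiar partial-volume
  underestimation of the AIF in coarse voxels. With a measured AIF peak of
  ~200 delta-HU this gives gray/white tissue peaks of ~25/~11 delta-HU,
  matching clinical CT perfusion; without it the phantom's tissue
  enhancement would be several-fold weaker than any real acquisition.

The bolus is a gamma-variate `A (t - t0)^alpha exp(-(t - t0)/beta)` with
alpha = 3 and amplitude solved for a requested peak (`aif_model()`,
default 200 delta-HU measured). The constructor defaults (`t0 = 5 s`,
`beta = 1.5 s`) suit stand-alone bolus modelling; the pipeline uses
`beta = 3 s` - a first-pass width of ~12 s FWHM, the clinical scale for a
6 s injection plus vascular dispersion; a 6 s-wide bolus would be aliased
beyond recognition by 6 s rotational sweeps - and `t0 = 18 s` (cohort draws
U(16, 20)) because with injection at acquisition start - how the flat-panel
protocol is run - the arm-to-brain transit puts cerebral arrival after the
two 6 s mask sweeps. The multidetector scan, by contrast, is triggered
8 s before cerebral arrival (`mdctp_protocol(start = t0 - 8)`), as a
clinical prep delay does. delta-HU is taken proportional to contrast
concentration with proportionality 1; all CBF/CBV values are therefore
relative, which is all the downstream analysis uses.

`render()` integrates each voxel's noiseless curve over every frame's
integration window (0.1 s quadrature grid), adds the per-label baseline HU
and i.i.d. Gaussian noise (2 HU for MDCTP-like, 4 HU for the noisier
flat-panel geometry; both configurable). Mask frames carry baseline only.
Because the scene is piecewise constant, curves are computed once per
distinct (CBF, MTT, delay) region. A rigid motion can be injected per frame
to exercise registration; it is off by default.

What the phantom does **not** emulate: beam hardening, scatter, metal
artifacts, contrast recirculation, anatomical variability, spatially
correlated noise, or the partial-volume mixing of real cortical anatomy.
Passing tests on this phantom therefore demonstrate algorithmic
correctness and protocol-induced effects, not clinical performance.

## The perfusion engine

`compute_perfusion_maps()` mirrors the standard flat-panel postprocessing
chain and applies the same chain to both protocols:

1. **Registration** (`register_frames()`, optional, default off): rigid
   6-DOF intensity-based alignment of every frame to the first, with a
   coarse integer-translation search followed by Nelder-Mead refinement on
   a mean-squared-difference cost and trilinear resampling.
2. **Background subtraction** (`subtract_mask()`): the mask-run mean is
   subtracted and mask frames dropped. Protocols without mask runs use the
   mean of the frames before the automatically detected bolus arrival
   (first frame whose whole-head mean enhancement exceeds 3 x the sd of the
   preceding frames' means) - the same template idea the mask runs give the
   flat-panel protocol for free.
3. **Nonlinear filtering** (`nonlinear_filter()`): a 3D median with radius
   1. The chain default applies it twice; iterating the small-radius median
   strengthens noise suppression at minimal resolution cost, approximating
   the considerably stronger edge-preserving filters of clinical perfusion
   software, whereas a radius-2 median was found to blur a ~20 ml core
   measurably. The single-pass operation remains available.
4. **Temporal resampling** (`resample_1s()`): cubic splines (not-a-knot end
   conditions, so cubic signals are reproduced exactly) through each
   voxel's frame-center samples, evaluated on the integer-second grid
   `0..floor(last center)`; values outside the knot span hold the nearest
   knot (polynomial extrapolation of a bolus curve diverges), and negative
   interpolants are clipped to 0.
5. **Tissue masking** (`make_tissue_mask()`): keep voxels with baseline HU
   in [-100, 200] (excludes air and bone) and peak enhancement below 50% of
   the arterial peak (excludes vessels, including the AIF voxels).
6. **AIF detection** (`detect_aif()`): vessel candidates (peak above 50% of
   the global maximum and above an absolute 50 delta-HU floor) ranked by
   peak / (time-to-peak x FWHM); the top 5 curves are averaged. Ties break
   on voxel index, so detection is deterministic. The phantom's vessel tube
   is 3 x 3 x 5 voxels so its centre survives the median filter, as a real
   large artery does.
7. **Deconvolution** (`deconvolve()`): delay-insensitive block-circulant
   SVD with zero-padding to 2N. By default the amplitude (CBF) uses a
   per-voxel truncation: walking a ladder of thresholds (0.4 down to 0.02
   of the largest singular value), each voxel takes the lightest truncation
   whose residue's second-difference oscillation index stays below 0.035 -
   clean curves keep temporal detail, noisy curves get strong
   regularization (controlling the noise-driven overestimation of low CBF
   that would otherwise defeat the rCBF < 30% core threshold). Peak
   *timing* (Tmax), by contrast, is read from one consistent truncation
   (`psi = 0.15`) for every voxel: timing must share a single temporal
   point-spread function across the brain, or per-voxel regularization
   flips would jitter the map's time scale. A fixed threshold everywhere
   (`adaptive = FALSE`) is retained for reference and for noiseless oracle
   tests, where a tiny `psi` makes the inversion exact.

Map definitions: CBF = max of the residue k(t) (peak position refined to
sub-grid resolution by parabolic interpolation - the 1 s argmax grid would
otherwise quantize Tmax and destabilize medians); Tmax = position of that
peak, earliest sample on ties; CBV = sum(c)/sum(AIF); MTT = CBV/CBF;
TTP = argmax of the pre-deconvolution tissue curve minus the AIF's argmax,
floored at 0. TTP is AIF-relative by default (`ttp_relative = FALSE` gives
the absolute convention); comparisons always use one convention.

Known estimator properties, measured on the phantom and worth stating
plainly: absolute Tmax carries a positive offset of roughly 1.5-2 s (peak
broadening from truncation plus the temporal smoothing of the
integrate-then-interpolate chain). The offset largely cancels in
lesion-minus-healthy contrasts, which is what the recovery tests assert,
and is one of the reasons absolute thresholds transfer poorly between
protocols while normalized ones transfer better - the very phenomenon the
package exists to reproduce. CBV on a 1 s grid equals CBF times the
rectangle-rule residue sum (the discrete analogue of CBF x MTT); tests
against exact discrete convolutions use that discrete value.

## Volumetry

`segment_hypoperfusion()` reproduces the standard segmentation battery:

* **Visible extent** (`visible_extent()`): the stand-in for a reader's
  manual delineation. The Tmax map is pooled over a 2-voxel-radius
  neighbourhood (readers judge coherent colour regions, not voxels; pooling
  also averages out map quantization), thresholded at the
  healthy-hemisphere median + 1 s, restricted to the affected hemisphere,
  and reduced to its largest 6-connected component. Ground-truth mode
  returns the phantom's true extent for recovery tests. The heuristic is an
  explicit reader stand-in and is labelled as such; it does not model
  inter-rater variability.
* **Absolute threshold**: Tmax > 6 s, applied within the visible extent (as
  the clinical workflow restricts thresholds to the manual segmentation).
* **Relative CBF core** (`rcbf_reference()`): CBF divided by the mean over
  three 3.5 mm-radius spherical ROIs in the contralateral deep white matter
  (7 mm "size" read as diameter; anterior/middle/posterior placement
  supplied by `default_reference_rois()` on phantom work - there is no
  anatomy atlas). Cores at rCBF < 30% and < 45%, again within the visible
  extent.
* **Hemispheric normalization** (`normalize_hemispheric()`): the healthy
  hemisphere is the one with lower mean Tmax (higher mean CBF as the
  secondary criterion; Tmax decides on conflict - the tie rule is a
  documented choice, the workflow description does not state one). The
  normalization factor is the median of the map over healthy-hemisphere
  tissue; maps are expressed in percent of it, so the healthy median
  normalizes to 100%. Thresholds: normalized Tmax > 150%, normalized
  CBF < 30%, identical cuts for both protocols. "Brain tissue" for these
  statistics is the engine's tissue mask (HU window minus vessels).
* **Volumes** (`compute_volumes()`): ml = voxels x voxel volume / 1000;
  the four extent/core mismatch combinations as minuend - subtrahend,
  floored at 0 (cores are subsets of the extent by construction, so the
  floor is defensive).

## The simulated cohort

`protocol_comparison_batch()` draws one subject per seed: lesion delay
U(8, 16) s (M1-occlusion scale), extent CBF fraction U(0.30, 0.50), core
fraction U(0.10, 0.20), delay taper U(0.75, 0.9), bolus arrival
U(16, 20) s, plus seeded wedge geometry (direction, angular width, radial
reach), rendered under both protocols with their default noise. Crucially,
the two acquisitions of one subject are modelled as what they were
clinically: two *separate injections* about three quarters of an hour
apart. The flat-panel scan uses a double, longer bolus (its gamma-variate
scale stretched by U(1.15, 1.5), emulating 60 vs 30 ml), arrives
U(-2, 2) s differently, and sees a lesion whose added delay has evolved by
U(-1.5, 1.5) s; the lesion geometry and all masks are identical. These
ranges emulate a middle-cerebral-artery stroke cohort (extents of order
70-140 ml, cores of order 10-30 ml) and were calibrated once against the
published cohort structure; they are not tuned per analysis.

On such cohorts the package reproduces the qualitative protocol
comparison: visible-extent volumes agree best across protocols (the reader
stand-in is relative and subtractive, so per-scan bolus and timing
differences cancel), absolute Tmax > 6 s volumes agree least (the 6 s
contour lands inside the lesion, where inter-scan physiology shifts and
the flat-panel protocol's coarse sampling move it subject by subject), and
hemispheric normalization improves the agreement of thresholded volumes
(dividing by the healthy-side median removes the per-scan scale shifts the
absolute cut is exposed to). The acceptance tests assert exactly this
ordering of correlations; numbers come from the runs themselves, not from
this text.

## Agreement statistics

All estimators are implemented against closed-form definitions and are
cross-checked in the test suite against independent oracles (`cor.test`,
closed-form balanced ANOVA, the paired t-test, exact `wilcox.test`,
sort-based quantiles):

* `pearson_ci()`: product-moment r, Fisher-z 95% CI, t-based two-sided p.
* `icc_mixed()`: one-way random-effects ICC (subject intercepts, methods as
  replicates), REML via `lme4` with the ANOVA ICC(1,1) estimator as
  fallback; CI from the exact F interval. On balanced two-replicate tables
  REML and ANOVA agree to numerical precision - that equality is a test.
* `bland_altman()`: bias = mean(A - B), limits bias +/- 1.96 sd(diff),
  bias CI via 1.96 sd/sqrt(n).
* `method_contrast()`: the fixed method effect from
  `volume ~ method + (1 | subject)`; on balanced paired data it equals the
  paired-t mean difference, which is both the oracle and the fallback.
* `wilcoxon_mwu()`: exact two-sided p by full enumeration of group
  assignments for pooled n <= 12 without ties, otherwise the normal
  approximation with tie and continuity corrections.
* `summarize_volumes()`: median and IQR with type-7 (linear interpolation)
  quantiles, the convention recorded in the output.

Two-sided tests, alpha = 0.05, no multiplicity correction (none is used in
the workflow being modelled). The multi-rater "overall agreement"
coefficient reported in some studies is not implemented: the phantom has no
raters.

## Reproducibility plumbing

`run_pipeline()` executes simulate / maps / segment / compare for a
configured number of subjects, writes every artifact (per-frame NIfTI with
a JSON timing sidecar, maps, volume tables, agreement report, the YAML
config itself) under one output directory, and emits a manifest with the
package version, seeds and per-file MD5 checksums; identical config and
seed reproduce identical checksums for the deterministic artifacts. The
interface of the package is its R functions plus `scripts/acceptance.R`;
there is no shell entry point - users of an analysis package like this one
drive it from R.

Problem sizes used by the shipped tests and the acceptance script - the
default 64 x 64 x 24 grid (48 x 48 x 16 where a smaller scene suffices),
20-subject cohorts, 1000-replicate coverage simulations - were chosen so a
full run completes in minutes on one CPU while keeping every quantity
measurably away from its tolerance.

## Known limitations

* Absolute CBF/CBV are relative units; no ml/100g/min calibration.
* Because of the absolute Tmax offset, the simulated Tmax > 6 s volumes
  are a larger share of the visible volumes than published stroke cohorts
  report; the between-protocol *pattern* is reproduced, the absolute
  threshold-to-visible proportion is not.
* The reader stand-in is a fixed rule; it emulates one consistent reader,
  not inter-rater spread.
* Absolute Tmax has the documented positive offset; analyses should use
  contrasts or normalized maps, as the clinical comparison itself
  concludes.
* The registration is phantom-scale (small rigid motions, clean contrast);
  it is not a clinical registration tool.
* FDCTP acquisitions whose bolus arrives during the mask runs violate the
  protocol's design assumption; the pipeline's arrival-time defaults avoid
  this, but hand-built configurations can recreate it (and will produce
  the garbage maps such an acquisition deserves).
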