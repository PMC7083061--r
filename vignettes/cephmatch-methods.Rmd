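---
title: "Methods: automated structural superimposition and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated structural superimposition and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephmatch)
```

## The registration model

Serial lateral cephalograms of one patient, taken on the same machine at the
same magnification, are related on any rigid anatomical structure by a 2-D
rigid transform: a rotation θ and a translation (tx, ty), no scale or shear.
`cephmatch` estimates that transform from keypoint correspondences that are
deliberately confined to rectangles enclosed by landmarks on structures
treated as stable during growth and treatment:

| region | defining landmarks |
|---|---|
| anterior cranial base | URP, S, Pt, N |
| maxilla | Pt, PNS, ANS, A |
| mandible | LM, Pg, Me, Go |

The rectangle is the axis-aligned bounding box of the four landmarks plus a
margin (default 10 px), half-open with the max side extended by one pixel so
the extreme landmark is inside. The "enclosed by landmarks" construction is
stated in the source material only as a rectangle; the bounding-box reading
is the simplest faithful one, and the margin keeps keypoints near the box
boundary describable. Everything outside the rectangle is invisible to the
pipeline by construction, which is what shields the estimate from the
dentition and from soft-tissue or background changes.

## Feature pipeline

**Detection.** FAST segment test on each level of a smoothed image pyramid
(8 levels, scale 1.2): a pixel is a corner when at least 9 contiguous of the
16 circle pixels (radius 3) are all brighter than centre + t or all darker
than centre − t, with t = 0.08 of the normalized dynamic range.
Non-maximum suppression runs on the segment-test score in 3×3
neighbourhoods; surviving corners are ranked by the Harris measure
(7×7 window, k = 0.04) and capped at 500 per ROI, allocated across pyramid
levels proportionally to level area. Keypoint positions stay at integer
pixel centres of their detection level and are mapped to full resolution by
the level scale — no sub-pixel refinement.

**Orientation and description.** Orientation is the intensity-centroid
angle atan2(m01, m10) over a radius-15 circular patch. Descriptors are
256 pairwise intensity comparisons on a Gaussian-distributed pair table
(σ = patch/5 in a 31×31 patch), rotated by the keypoint orientation and
sampled on a σ = 2 smoothed image. The pair table is generated once from a
fixed seed and cached, so descriptors are bit-identical across runs and
platforms; learned pair-table optimization is out of scope. Strict `<`
comparisons mean a constant patch yields the all-zero descriptor.

**Matching.** Every T2 descriptor is paired with its Hamming-nearest T1
descriptor — no ratio test, no distance cutoff, ties to the lowest index.
The match filter downstream is designed to consume abundant raw
nearest-neighbour matches, so pre-filtering here would only starve it.

**GMS filtering.** For a match in cell pair (i, j), the support is the
number of other matches sending the 3×3 cell neighbourhood of i onto the
correspondingly placed neighbourhood of j; the match is kept when
support > α·√n, where n is the mean match count per in-grid A-cell of the
neighbourhood (cells off the grid contribute nothing, and the divisor counts
only in-grid cells — a convention mirrored exactly by the brute-force oracle
in the tests). Defaults G = 20, α = 6, with the four half-cell-shifted
grids evaluated and a match accepted under any of them. Rotated-grid
variants exist in the literature for large in-plane rotations; serial
cephalograms are near-upright, so they are not applied (`with_rotation` is
reserved). One practical note: the support statistic needs a few matches
per cell, so G should be matched to the expected match density. G = 20 is
appropriate for the ~300–600 raw matches produced on a cephalogram ROI;
property tests that spread only 200 synthetic matches over a full frame use
proportionally coarser grids (G = 6–10) for the same reason.

**Rigid estimation.** With correspondences p (T2) and q (T1), the
least-squares rigid fit centres both sets and takes the closed-form 2-D
orthogonal-Procrustes angle θ = atan2(Σ(x y′ − y x′), Σ(x x′ + y y′)),
which is always a proper rotation (no reflection branch in 2-D with this
form). A consensus-sampling wrapper (500 trials of 2-point minimal
hypotheses, 2 px inlier tolerance, fixed seed, refit on the best consensus)
sheds any residual false matches; with ≤ 4 pairs it falls back to the plain
fit. The phrase "offset distances and rotation angles of each pair" admits a
per-pair reading as well; a per-pair circular-median estimator
(`estimate_rigid_perpair`) ships for comparison, but the joint fit is the
default because a single pair does not define a rotation and the median
variant discards information. A registration with fewer than 10 GMS inliers
is reported as a failure rather than a guess.

## Synthetic study conditions

No clinical films are distributed, so validation runs on seed-deterministic
phantoms that reproduce the properties the pipeline actually depends on —
not radiographic physics:

* smooth low-frequency background (coarse uniform field, bilinearly
  upsampled);
* 6–10 curvilinear high-contrast "bony edge" strokes (splines through
  seeded control points, Gaussian cross-section, amplitude 0.25–0.4);
* band-limited speckle at two spatial frequencies (blur σ 0.8 and 2.5,
  SDs 0.085 and 0.05) standing in for trabecular texture;
* the 21 landmarks at anatomically ordered positions on an 800×640 canvas
  (default), jittered ±8 px per seed, chosen so all three ROIs are valid
  for every seed and stay in frame under the perturbations used in
  validation.

The texture amplitudes were fixed once so that each ROI yields at least 200
FAST corners at the default threshold, then frozen. A pair is produced by
resampling the T1 phantom under the inverse of the ground-truth transform
(rotation about the canvas centre), applying a gamma of 1.1 and additive
Gaussian noise of σ = 0.01 — mild photometric perturbations of the kind the
binary comparisons should shrug off. All randomness flows from one spec
seed through named substreams (landmarks, texture, noise, corruption,
jitter), so a manifest reproduces every output bit-identically.

What passing these conditions does *not* show: robustness to genuine
anatomical change between films (growth, remodelling inside the ROI),
film-specific artefacts (collimator edges, labels), or large exposure
differences. The phantom validates the geometry and the statistics of the
method, not its clinical error level.

Simulated operators displace every landmark by independent per-coordinate
Gaussian jitter (default SD 0.5 mm — the order of reported inter-operator
tracing variability). The difference of two such jitters is Rayleigh with
scale σ√2, giving the closed-form mean pairwise T2LD of σ√π ≈ 0.886 mm at
σ = 0.5, which the generator reproduces within Monte-Carlo error.

## Evaluation protocol

For k operators and c complete cases, pairwise operator differences pool
c·k(k−1)/2 values per landmark (3 operators × 28 cases = 84); consensus
truth is the per-landmark coordinate-wise operator mean; hand and automated
accuracies are distances to that truth with n = c each. The paired t-test
compares, per landmark and per case, the mean of the operators' distances
to truth against the automated distance — pairing per case keeps the pairs
independent; an operator-replicated pooling (n = c·k) is available behind a
flag. Sample SDs use the n−1 denominator throughout.

The null calibration deserves a note. The per-case hand accuracy is the
mean of three distances to a consensus the operators themselves define:
each operator's deviation from the consensus has per-coordinate SD σ√(2/3),
not σ. For the comparison to be null (equal expected accuracy), the
automated error is drawn with per-coordinate SD σ/√3 about the generating
truth, which makes its deviation from the consensus — jitter minus the mean
operator jitter — match the operators' σ√(2/3) distribution exactly. With
that construction the per-landmark paired t-test at α = 0.05 is
non-significant in ≈ 95% of replicates, as a calibrated test should be.
Drawing the automated jitter at the full σ instead would build in a real
accuracy difference and the test would (correctly) reject.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, origin top-left, x rightward, y downward;
  rotations are positive from +x towards +y (clockwise on screen). All
  angles are wrapped to (−π, π].
* Images are min-max normalized to [0, 1] on load; zero-variance images are
  rejected. Colour inputs collapse to Rec. 601 luminance.
* Default calibration 25.4/600 mm/px (600-dpi original-size scans),
  overridable per film.
* Replicate padding is used for orientation/descriptor sampling at ROI
  borders; the warp fills out-of-source pixels with 0 and tolerates ~1e−6
  of rounding at exact borders (so exact 90° rotations stay lossless).
* Tie-breaks are deterministic everywhere: lowest index for matching,
  (y, x) lexicographic for equal corner scores, lowest B index for Hamming
  ties.
* Degenerate cases raise typed errors: coincident point sets, sub-32×32
  ROIs, fewer than 2 pairs for the rigid fit; fewer than 10 matches makes
  the GMS statistic undefined and rejects everything with a warning.

## Problem sizes used in validation

The recovery grid is θ ∈ {0°, 1°, 3°, 5°} × |t| ∈ {0, 5, 20} px × 3 seeds
(36 pipeline runs, maxillary region) at noise σ = 0.01 and gamma 1.1,
judged at 0.3° and 1.0 px. Because a rotation about the canvas centre has
large origin-referenced translation components, translation error is
measured as the displacement of the canvas-centre point under
recovered∘truth⁻¹ — the error that actually lands on transferred
landmarks. Rotation covariance of the feature stage is summarized by the
median residual of GMS-inlier matches under the known rotation
(5°, 10°, 15°); individual matches detected at coarse pyramid levels carry
integer-centre quantization of up to ±scale/2 ≈ ±1.8 px per endpoint at
level 7, which is why the median, not the maximum, is the meaningful
statistic absent sub-pixel refinement. Oracle equivalences (matcher, GMS,
rigid fit) are exact; the t-test calibration uses 100 replicates of 28
cases × 7 maxillary landmarks.

## Known limitations

* Rigid-only: true anatomical change inside an ROI biases the fit rather
  than failing it; the rms residual and inlier count in the result are the
  diagnostics to watch.
* No automatic landmark detection — landmark files are inputs, as in the
  manual protocol the method replaces.
* The GMS grid granularity is density-sensitive (see above); extremely
  small ROIs fall back to fewer pyramid levels and may need a coarser grid.
* Scale is fixed at 1; films digitized at different resolutions must be
  resampled to a common mm/px first.
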