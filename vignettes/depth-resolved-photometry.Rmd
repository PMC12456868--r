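---
title: "Depth-resolved fiber photometry of amyloid plaque signals"
author: "plaquefp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved fiber photometry of amyloid plaque signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquefp)
```

## The problem

Amyloid plaques in mouse models of Alzheimer's disease are classically
quantified post mortem. Fiber photometry offers a live alternative: after a
systemic injection of Methoxy-X04 — a blood-brain-barrier-permeable dye that
binds beta-sheet amyloid and is excited near 405 nm — the bulk fluorescence
collected through an implanted optical fiber reports the local plaque load.
Two acquisition geometries are supported by this package:

* **Flat fiber, acute.** A flat-cleaved fiber is lowered through the brain in
  100-µm steps from the surface to 4000 µm (41 depths). At each depth the
  light source is pulsed and the detector demodulated, yielding a
  fluorescence-versus-depth profile that can be compared with the
  histological plaque distribution along the same penetration.
* **Tapered fiber (TF), chronic.** A fiber with a ~1.8-mm optically active
  taper is chronically implanted. The angle at which light is injected —
  set by a galvo mirror voltage — selects the axial position along the
  taper where light is emitted and collected, so one galvo sweep samples
  ~1.6 mm of tissue depth in a freely behaving animal.

The package implements the full analysis for both geometries, the
histological validation chain, a genotype classifier, and a synthetic-data
generator that produces every input with known ground truth so each stage is
testable end to end.

## Demodulation of multiplexed recordings

Both rigs pulse the light source 10 ms on / 5 ms off (67% duty cycle) and
record detector, sync and galvo channels at 5000 Hz. `demodulate()` (flat)
and `demodulateScan()` (TF) locate ON windows from the sync channel, discard
one sample at each pulse edge as a slew guard (a 10-ms pulse contributes 48
of its 50 samples), and average the interior. TF pulses are assigned to one
of 41 analysis levels spanning 0–4.5 V (0.1125 V spacing) by their galvo
voltage; the −1 to 0 V segment of each sweep points the light outside the
tissue and is discarded. Each scan is timestamped at its onset; the
synthetic generator evaluates its per-level model at the same instant and
holds it within the scan, which is why the noiseless
simulate-then-demodulate round trip is exact rather than merely close.

Repetitions are combined by the mean (the median is selectable via
`statistic`); nothing in the protocol mandates one or the other, and the
choice is recorded in the call.

## Flat-fiber depth profiles

Per-depth fluorescence (440-nm channel at the maximum power by default) is
z-scored against the superficial baseline,

$$dF = \frac{F - \mathrm{mean}(F_0)}{\mathrm{sd}(F_0)},$$

where $F_0$ collects the depths in the closed window 0–400 µm (five depths
on the 100-µm grid). A zero baseline standard deviation raises an error
rather than emitting infinities. Profiles are smoothed with a moving median
of window 4. An even window has no canonical alignment; `movingMedian()`
uses $[i-1, i+2]$, truncated at the edges, and documents it so the choice is
reproducible rather than implicit.

## Histological depth profiles

`detectPlaques()` finds plaque particles in fluorescence section images:
morphological opening (a rolling-ball equivalent) estimates the background,
the 99th-percentile quantile of the background-subtracted image sets the
threshold, and connected components are kept if their equivalent diameter
$2\sqrt{A/\pi}$ lies between 11 and 20 µm. The quantile rule makes detection
invariant to rescaling the image by a positive constant. No published value
exists for the threshold or the opening radius; the defaults (0.99, 30 µm)
are explicit arguments, not constants.

The penetration track is reconstructed by `fitFiberTrack()` as the
least-squares 3-D line through per-section annotations, parameterized by
depth (DV). Because the implanted hemisphere is damaged by the fiber, the
track is projected onto the contralateral hemisphere
(`mirrorTrack()`, reflection about ML = 0 in registered coordinates,
assuming hemispherically homogeneous pathology). For the TF analysis the
track is additionally shifted 600 µm up (`shiftTrack()`) to compensate a
systematic overestimate of the penetration depth; whether that shift should
precede or follow mirroring is not specified anywhere, so it is applied
after mirroring and carried as an explicit, removable track attribute.

`profileCounts()` counts plaque centroids within 250 µm of the track point
at every grid depth. The counting volume is described in two ways in the
source protocol — a cylinder of radius 250 µm, and "plaques within 250 µm of
each depth measure"; the package implements per-depth 3-D balls (the second
reading) because the density normalization is explicitly per spherical
volume, $\rho = n / \tfrac{4}{3}\pi r^3$, and the union of balls along the
track approximates the cylinder. `addTiebreakNoise()` adds i.i.d.
uniform(0, 1e-10) to the counts so rank statistics remain defined for
plaque-free control animals without disturbing any pair of counts that
differ by one or more.

Photometry and histology profiles are compared with Spearman's rho
(`correlateProfiles()`).

## Genotype classification

Each unsmoothed dF profile is z-scored within itself and stacked into a
samples x 41 matrix (`buildProfileMatrix()`); PCA reduces the 41 depths to 3
scores (`pcaReduce()`, column-centered, deterministic sign convention); a
linear SVM with cost 1 is trained leave-one-out and the held-out predictions
are tallied into a confusion matrix with *affected* as the positive class
(`looClassify()`, `clfMetrics()`). The kernel and cost are not prescribed by
the protocol this follows; the linear kernel with unit cost is the
smallest-assumption default for 24 samples in 3 dimensions, and both are
arguments.

Fitting the PCA once on all samples before the leave-one-out loop follows
the study design this package mirrors, but lets the held-out sample
influence the (unsupervised) projection. `classifyGenotypes(pcaPerFold =
TRUE)` refits the projection inside every fold for a leak-free variant; with
three components on clearly separated cohorts the two routes agree.

A caution on permutation controls: under label permutation, leave-one-out
accuracy is systematically *below* 0.5 (each held-out sample's label is
underrepresented in its training fold), and the 24 held-out predictions of a
run are mutually dependent. The package's tests therefore compare the mean
permuted accuracy against the binomial chance band of a single 24-sample
run, not against a band that pretends 200 x 24 independent coin flips.

## Tapered-fiber analysis

* **Power calibration.** In a uniform dye bath the demodulated fluorescence
  per level is proportional to the taper's transmission at that level.
  `calibratePower()` converts it to the relative required power
  $PR = (1/F) \div \min(1/F)$, so the brightest level gets exactly 1 and
  dimmer levels get proportionally more power. Applying powers proportional
  to PR in the generator's dye model equalizes fluorescence across levels —
  the closed calibration loop is asserted in the tests.
* **Autofluorescence.** Day 0 (no dye) gives, per level, a linear drift
  model $AF = a\,t + b$ fit by twofold cross-validation on interleaved
  odd/even timepoints; coefficients are averaged across folds and the mean
  held-out squared error is kept per level. Day-1 tracer signal is
  $F_m = F - (a\,t + b)$ with $t$ on the day-1 session clock
  (`fitAutofluorescence()`, `subtractAf()`); sessions share their structure,
  so measuring both clocks from session start is the only coherent
  alignment.
* **Binning and dynamics.** $F_m$ is averaged in 5-min bins
  (`binTimecourse()`; a partial trailing bin is kept and flagged; bins are
  timestamped by their mean scan time so a linear signal keeps its value at
  the bin timestamp exactly). The levels with the maximum and minimum median
  signal over 30–240 min (`extremaDepths()`, ties to the lower level index)
  are z-scored against the first 25 min and smoothed with a moving median of
  window 3 (`zscoreTrace()`); the max-versus-min contrast at 90 min
  post-injection is tested per genotype with a Wilcoxon signed-rank test
  (`pairedExtremaTest()`, exact by full sign-flip enumeration for n <= 25 —
  implemented here because the standard exact path cannot handle tied
  differences).
* **Depth profile.** The 210–240 min window average per level
  (`depthProfileWindow()`) is the late, near-plateau tracer profile compared
  against histology. Galvo voltage maps affinely onto the active span
  (0 V at the shallow end by default); the sweep direction is not knowable
  from the protocol alone, so the orientation is an argument.

## The ex vivo photometry-stack computation

With a TF inserted in a brain slice under a two-photon microscope, the
package reproduces the simulated-photometry computation:
`preprocessStack()` (per-frame background subtraction, clipping, global max
normalization), `illuminationCentroid()`/`stackCentroids()` (axial
projection after subtracting the terminal-angle baseline — the mean of the
first and last frames, a symmetric reading of "terminal input angles"),
`photometryStack()` ($P(x,y,V) = C(x,y) \times I(x,y,V)$ pixel by pixel,
with $P \le C$ asserted), `photometryProfile()` (frame integrals positioned
at the centroids), and `roiCountProfile()` (plaque counts in a 250-µm
circle moved along the fiber axis in 40-µm steps — 2-D here, unlike the
3-D balls of the in vivo histology, because the ex vivo context is a
slice). The registration of camera-acquired illumination frames onto the
fiber-channel image is irreproducible by hand; the package requires
pre-aligned grids instead and validates them.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions under which every stochastic claim in the test suite is
evaluated.

* **Plaque fields** (`makePlaqueField()`): an inhomogeneous Poisson point
  process whose intensity varies with depth only, realized by thinning.
  The default depth template (`defaultPlaqueDensity()`) is a 15 plaques/mm³
  cortical baseline plus a Gaussian hotspot of +110 plaques/mm³ at 2800 µm
  (width 500 µm), emulating dense subicular pathology along a penetration
  that ends in the hippocampal formation. No quantitative density for this
  region is published alongside the protocol the package follows, so the
  template is a free parameter chosen once to give plausible per-ball
  counts (tens of plaques at the hotspot), not a literature calibration.
  Diameters are uniform on 11–20 µm so the detection filter passes all of
  them; out-of-range distractors are opt-in, keeping geometry tests
  separate from filter tests.
* **Section images** (`renderSectionImage()`): plaques whose centroids fall
  in the slab are drawn as filled unit-amplitude disks at pixel centers
  $(i - 0.5)\,\mathrm{px}$, plus Gaussian background noise.
* **Taper fields** (`makeIlluminationStack()`, `makeCollectionField()`):
  phenomenological, not ray-traced. Illumination frames are Gaussian bands
  (axial sd 60 µm, lateral sd `widthUm`/2) whose centers move affinely with
  voltage across the active span; the amplitude envelope is $\sin^2(\pi u)$
  so terminal angles deliver near-zero light, and it is replaceable (the
  tests use a plateau variant where envelope shape is not the property
  under test). Collection decays exponentially with radial distance
  (default constant 150 µm); the fiber footprint mask defaults to zero
  width — the stated field is both maximal on the axis and zero inside the
  footprint, which only coexist for a zero-measure footprint, so masking is
  opt-in.
* **Recordings** (`simulateRecording()`, `simulateFlatSession()`,
  `simulateDyeCalibration()`): per level,
  $F(t) = a\,t + b + \mathrm{gain}\cdot\mathrm{density}\cdot(1 -
  e^{-(t - t_{inj})/\tau})$ for $t \ge t_{inj}$, multiplexed into pulsed
  detector traces with sync and galvo channels. The tracer rise uses
  $\tau = 30$ min, reaching ~95% of plateau 90 min post-injection — chosen
  to reproduce the observed differential signal ~1.5 h after injection
  without asserting a pharmacokinetic model nobody measured. Defaults:
  autofluorescence intercept ~1 a.u. with small per-level scatter, slow
  bleaching drift (−2e−5 a.u./s), gain 0.004 a.u. per plaque/mm³ (hotspot
  plateau ~0.5 a.u.), detector noise sd 0.05 a.u. per sample. Flat sessions
  hold the plaque term at plateau (the dye was injected the day before the
  acute experiment). The dye-calibration transmission profile is strictly
  positive, unlike the in-tissue illumination envelope, because the power
  calibration requires F > 0 at every level.

What the generator does **not** emulate: optical scattering and absorption,
vasculature, registration error between histology and photometry
coordinates, animal motion, and any cross-level optical crosstalk. Passing
tests therefore demonstrate that the analysis code inverts its stated
forward model and satisfies the published arithmetic — not that the pipeline
is robust to every nuisance in real tissue.

## Problem sizes and determinism

The stochastic tests and the acceptance script run, as the package's chosen
study conditions: 20 affected + 20 control synthetic flat-fiber animals;
12 affected + 7 control TF recordings of 245 min at one scan per 5 min with
single-power sweeps (the analysed 120-µW subset; multi-power demodulation is
exercised separately on short fixtures); a 13 + 11 classification cohort
with 200 label permutations; and 100-seed brute-force equivalence loops for
the counting oracles. Every stochastic quantity is seeded; generators save
and restore the global RNG state, and all analysis operations are
deterministic given their inputs.

## Known limitations

* Depth along the track is parameterized by DV, which is exact for the
  near-vertical penetrations simulated here and approximate for strongly
  angled tracks.
* The quantile threshold in `detectPlaques()` assumes foreground occupies
  less than the complementary quantile of the image; extremely dense
  sections would need a lower quantile.
* `correlateProfiles()` requires grids that already share a step; it
  matches by nearest depth and refuses misaligned grids rather than
  resampling.
* The exact Spearman permutation p-value is restricted to n <= 10 (3.6M
  arrangements); larger n use the t approximation, which is standard but
  approximate in the presence of heavy ties.
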