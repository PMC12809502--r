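---
title: "Methods: batch reduction of small-wedge 3D electron diffraction data"
author: "edbatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch reduction of small-wedge 3D electron diffraction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edbatch)
```

## The problem

Continuous-rotation 3D electron diffraction (3D ED / microED) collects
rotation data from sub-micrometre crystals in a transmission electron
microscope. Because beam damage limits the dose per crystal, a structure is
usually assembled from *many small wedges* — dozens of datasets, each
covering 15–120 degrees of rotation — that must be screened, brought to a
common indexing convention, selected by quality, scaled together and merged.
`edbatch` implements that reduction pipeline on unmerged reflection files:
per-dataset quality indicators, Laue-symmetry machinery, two dataset
clusterings, iterative scaling/merging with outlier-frame exclusion,
detector-geometry utilities, and a polling state machine for screening or
merging *while data are still being collected*. A synthetic-data generator
with exact ground truth backs the whole test surface.

## Statistics on symmetry-equivalent observations

All merging statistics operate on orbits of symmetry-equivalent
observations. The canonical orbit representative is the lexicographically
greatest image of `(h, k, l)` under the Laue-group operators; Friedel pairs
are always merged (anomalous signal is out of scope for ED quality
screening). Operator sets for the 11 Laue classes (both trigonal settings,
hexagonal axes) are generated by closure from explicit generators and
checked against the group axioms by brute force in the test suite.

* **Rint** is `sum |I - <I>| / sum I` over orbits with at least two
  observations; **Rmeas** multiplies each orbit's numerator by
  `sqrt(n/(n-1))`, removing the redundancy bias. Singleton orbits enter
  neither sum, and negative intensities are kept throughout — truncation
  would bias the sums.
* **CC1/2** follows the random half-set definition: each orbit's
  observations are split into two random halves (an odd observation joins a
  random half) and the Pearson correlation of the half-mean vectors is
  reported in percent. The split seed is fixed (default 42) and reported,
  so batch reports are reproducible; significance is a one-sided t-test of
  `CC > 0` at `alpha = 0.01` on `n - 2` degrees of freedom.
* **ISa**, the asymptotic signal-to-noise, comes from the two-parameter
  error model `var(I) = a (sigma^2 + b I^2)`: `ISa = 1/sqrt(a b)` is the
  I/sigma an infinitely strong reflection would reach. The model is fitted
  to binned per-orbit sample variances (10 equal-count intensity bins) by
  least squares, with bins reweighted by the sampling variance of a mean of
  chi-square variates (`var(s^2) = 2 sigma'^4/(n-1)`) over a few reweighted
  passes — without the reweighting the strongest bin dominates and the fit
  is visibly noisier. A fit with non-positive parameters (e.g. noise-free
  input) reports ISa as missing with a diagnostic rather than a number.
* **Completeness** is the observed fraction of the theoretically measurable
  unique set, enumerated exactly over the limiting sphere with
  centering-extinct indices removed.
* **Shells** are equal-volume in `1/d^3` (default 10), so observation
  counts are balanced for data uniform in reciprocal volume; the data's own
  resolution limits bound the binning.
* The **resolution cutoff** scans shells from low to high resolution and
  stops at the first shell failing any of: CC1/2 at or above 30% *and*
  significant, mean I/sigma at least 1, Rint defined. The 30% CC1/2 default
  is the conventional live-report criterion for merged ED data; both
  thresholds are configuration keys. If every shell passes, the cutoff is
  the data's own high-resolution limit — the expected outcome for strongly
  diffracting small-molecule crystals.

## Dataset selection and scaling

Datasets are selected by thresholds on ISa (> 5), CC1/2 (> 95%) and
completeness (> 80%) — the standard promising-dataset rule for
single-dataset structure determination. The real-time profile relaxes
CC1/2 to 90% and drops completeness, because small wedges are individually
incomplete by design. A missing indicator counts as a failure and the
reason is recorded.

Scaling uses the smallest model that supports the workflow: one linear
scale `k_i` per dataset, optionally one isotropic `B_i` applied as
`exp(-2 B_i s^2)` with `s = 1/(2d)`. Alternating weighted least squares
(update scales given merged means, re-merge, repeat) runs to a relative
change below `1e-6`; the gauge is fixed to geometric mean `k = 1` and mean
`B = 0`. Connectivity of the dataset graph (pairwise common orbits at or
above `min_common = 20`) is checked by union-find first — scaling a
disconnected graph silently corrupts scales. Merged intensities are
inverse-variance weighted means; merged sigmas are inflated by the error
model fitted on the scaled observations.

Outlier frames (blocked beam, grid bars, ice) are detected from per-frame
relative scales: the median ratio of each frame's observations to
leave-one-out orbit means, log-transformed, detrended by a running median
(window 15 frames) and flagged beyond `max(3 robust SD, 0.3)`. Two details
matter and were set by construction, not tuning-to-pass: the *leave-one-out*
reference keeps one bad frame from dragging its orbit partners' frames over
the threshold, and the absolute floor of 0.3 log units (~35%) keeps
statistically tight data from producing spurious exclusions — a pure
MAD rule flags frames that are merely a few noise standard deviations off a
very precise trend. The running median absorbs smooth dose decay, so beam
damage alone never triggers exclusions; damage correction belongs to
scaling, not rejection.

## Symmetry estimation and clustering

The Laue class of a dataset is scored per candidate with four indicators:
Rmeas under the candidate; its ratio to the Friedel-only Rmeas (rejection
above 2); CC1/2 under the candidate with its significance; and the
correlation between candidate-merged and Friedel-merged means. `-1` is the
reference hypothesis and always survives — with pure noise nothing else
does. Accepted candidates within 2 CC-percentage-points of the best are
ranked highest symmetry first, which resolves the usual near-tie between a
true class and its subgroups.

Cell clustering works on Euclidean distances between feature vectors
`(a, b, c, 0.5*alpha, 0.5*beta, 0.5*gamma)` of Niggli-reduced cells
(Krivy–Gruber reduction, implemented natively), so axis-permuted
descriptions of one lattice compare as identical. The angle weight of
0.5 Å/degree balances typical ED cell and angle errors and is
configurable. Intensity clustering converts pairwise correlations over
common unique reflections to distances `sqrt(1 - CC^2)` (missing pairs at
maximum distance); both clusterings use average linkage and cut at a
user-chosen threshold, naming groups `disX-clsY` with Y ordered by size.
Threshold choice is deliberately left to the user — the stepwise-threshold
table exists precisely to support that decision.

## Detector geometry

Beam-centre finding has two modes. Without a beamstop, the centre is the
intensity centroid of the bright central blob above half the smoothed
maximum. With a beamstop the direct beam is invisible, so the Friedel
(180-degree rotational) symmetry of the diffraction pattern is used: the
masked normalised cross-correlation between the image and its rotated copy
(shadow pixels excluded; Padfield-style normalisation over the actual
overlap) is maximised over integer shifts via FFTs and refined to sub-pixel
precision by parabolic interpolation.

Spot centroids map to reciprocal space through the exact Ewald construction
(`v = k' - k0`, `|v| = 2 sin(theta)/lambda`) and are rotated back by their
frame angle into the common crystal frame.

For rotation-axis refinement several cylindrical-projection histogram
scores (Shannon entropy and variance, 1-D azimuthal and 2-D angular, 36–180
bins) were implemented and measured first; on realistic spot lists their
landscapes are flat and biased at the degree scale, which is consistent
with their reported use as coarse, indexing-validated estimators. The
package therefore uses a sharper, cell-free objective built on Friedel
self-consistency: because the Ewald sphere is nearly flat for electrons, a
reflection and its Friedel mate cross it at slightly different rotation
angles, and their back-rotated reciprocal vectors sum to zero *only* under
the correct spindle azimuth. A coarse 2-degree grid scores candidates by
the fraction of points whose antipode coincides within `2e-3` 1/Å; matched
pairs are then refined by least squares on the mean squared pair residual,
re-pairing once at the refined axis. Centroid jitter adds an
azimuth-independent floor to the objective, so it does not bias the
minimiser; planted azimuths are recovered to about 0.01 degrees at 0.3 px
jitter. Axis tilt out of the detector plane is not refined.

## The real-time state machine

The monitor is a pure state transition `rt_poll(state, config, now)` with
an injectable clock, wrapped by a sleep loop — every contract
(exactly-once processing, append-only history, crash-resume) is testable
without timers. A reflection file is complete when its size/mtime signature
has been unchanged for the quiescence time (default 10 s) or a `.done`
sentinel exists; completion triggers are acquisition-software-specific, and
quiescence is the vendor-neutral choice. In merging mode a dataset joins
the valid set when CC1/2 > 90% and ISa > 5 in the known cell and Laue
group; scaling and merging are re-run from scratch over all valid datasets
each iteration — correctness over speed at desk scale — and the run flags
stop when merged completeness at the preset resolution reaches the target
(default 95%). Invalid datasets are never revisited and eviction of
previously valid datasets is not implemented; a manual rescan covers both.
State persists to a JSON sidecar after every poll, and a resumed run
reproduces the uninterrupted statistics exactly because each iteration is
recomputed from the files on disk.

## The synthetic generator

Ground truth draws one exponential (Wilson, acentric) intensity per
asymmetric-unit orbit — the simplest model under which every statistic has
a known expectation; no twinning, no anomalous signal. A wedge dataset
observes exactly the symmetry mates whose reciprocal points cross the Ewald
sphere during the rotation range: crossings are solved in closed form
(`A cos(phi) + B sin(phi) = -lambda |x|^2 / 2`), which makes completeness
oracles exact rather than binned. Planted corruptions cover everything the
pipeline must detect: linear scales, B factors, the `a, b` error model (the
reported sigma is `sigma_floor + sigma_frac * I`, and the noise actually
drawn inflates it through the planted model), outlier frames (intensities
times 0.1), orbit thinning, exponential dose decay and deliberate
mis-indexing. Beam images are Poisson background plus either a Gaussian
direct beam or a Friedel-symmetric spot field with a wedge-shaped shadow;
spot lists carry exact crossing positions with 0.3 px centroid jitter.

What passing tests on this substrate do **not** show: dynamical scattering
(the dominant ED systematic), profile-integration errors, detector
distortions, or non-Wilson intensity statistics. The generator validates
the *reduction machinery* — formulas, bookkeeping, convergence, state
transitions — not the physics of electron scattering.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately desk-scale
problems: truths of 600–8000 unique orbits, wedges of 2000–50000
observations, batches of 4–12 datasets. These sizes were chosen so every
statistic is estimated with comfortable Monte-Carlo headroom while the full
suite stays fast enough to run on every change. Tie-breaks and degeneracies
are handled explicitly: scaling refuses disconnected graphs instead of
returning a gauge-ambiguous answer; the error-model fit reports degeneracy
instead of clamping; the resolution rule has defined behaviour when the
first shell fails (innermost d_max, with a warning) and when nothing fails
(the data's own limit); cluster groups are named largest-first with the
threshold embedded in the name.

## Configuration

The run configuration is one YAML file (`work_dir`, plus `instrument`,
`processing` and `realtime` blocks); YAML was chosen because a typed,
widely-supported parser ships with the installed R stack. A converter
ingests legacy `Input_parameters.txt` key=value files. All thresholds named
in this vignette are configuration keys with the stated defaults.

## Known limitations

No integration engine: the package consumes unmerged reflection files and
cannot re-integrate images, so indicators that require integration
internals (indexing rate, profile quality) are absent. Reflection-level
outlier rejection is not implemented (frame-level only). Local,
resolution-dependent scaling surfaces and zero-dose extrapolation are out
of scope. Rhombohedral-setting transforms are the caller's responsibility;
trigonal classes are served on hexagonal axes.
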