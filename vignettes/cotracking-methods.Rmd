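---
title: "Quantifying receptor dimerization by dual-colour single-molecule co-tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor dimerization by dual-colour single-molecule co-tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotrackr)
```

## The measurement

Cytokine receptors such as the IL-17 receptor subunits signal through
ligand-induced assembly on the plasma membrane. Whether two receptor
chains actually form a complex on a live cell can be read out by
dual-colour single-molecule TIRF imaging: each receptor species (or, for
homodimerization, a 50/50 two-colour labelling of one species) is imaged
in its own spectral channel, and a physical complex reveals itself as a
pair of emitters — one per channel — that stay together *while
diffusing*. Transient spatial coincidence happens by chance; sustained
co-diffusion does not.

`cotrackr` implements this computation end to end:

1. **Registration.** A 6-parameter affine transform mapping channel B
   into channel-A coordinates is estimated by least squares from
   fiducial-marker calibration data. Dual-view splitters introduce
   scale and shear as well as translation, which is why the full affine
   family is used rather than a rigid or similarity transform.
2. **Localization.** Emitters are detected per frame as local maxima of
   a Laplacian-of-Gaussian-filtered image above a robust
   (median + k·MAD) per-frame threshold and refined by least-squares
   fitting of a pixel-integrated 2D Gaussian.
3. **Tracking.** Localizations are linked frame to frame by the
   one-to-one assignment minimizing total squared displacement, with
   links forbidden beyond a search radius; track ends are then joined
   across short gaps. Immobile emitters (surface-stuck particles,
   endocytosed receptors) are removed by a radius-of-gyration filter.
4. **Co-tracking.** Channels are co-localized frame by frame within a
   100 nm cutoff (again by optimal assignment), match midpoints are
   linked into co-trajectories with the same linker, and a co-trajectory
   persisting for **10 or more matched frames** is called a dimer.
5. **Quantification.** Per cell: the relative dimerization level,
   diffusion constants from mean-squared-displacement (MSD) regression,
   the immobile fraction, and the intensity-based higher-order fraction.
6. **Statistics.** Conditions are compared cell-wise by two-sample
   Kolmogorov–Smirnov tests and summarized by five-number (box-plot)
   summaries. The statistical unit is always the cell.

The acquisition regime the defaults encode: 150-frame movies at 32 ms
per frame (4.8 s), at least 10 cells per experiment, receptor mobility
in the 0.01–0.3 µm²/s range, localization error of 10–30 nm.

## The synthetic-data generator

No real movie ships with the package. Instead, every stage is validated
by parameter recovery on synthetic data whose statistical structure
mirrors the imaging regime:

* **Geometry.** A square membrane patch (default 20 × 20 µm) with
  complexes at 0.2 /µm² total (≈ 0.1 /µm² per channel for a monomer
  mix), placed uniformly.
* **Complex types.** Monomers of either receptor, homodimers, the
  heterodimer, the 2:2 ternary complex, and a hexameric array (for the
  higher-order intensity analysis). Composition is *static* within a
  movie: at 4.8 s the assay measures equilibrium dimerization levels,
  not binding kinetics, so no association/dissociation is simulated.
* **Motion.** Complex centres perform 2D Brownian motion with per-axis
  per-step variance 2·D·Δt and reflecting boundaries; D depends on
  complex size (defaults 0.10 / 0.07 / 0.04 µm²/s for monomer / dimer /
  larger) and an immobile subpopulation (default 10%) has D = 0. Member
  protomers ride the shared centre plus 10 nm bond jitter per axis.
* **Photophysics.** Each protomer is labelled with probability 0.85,
  starts ON, blinks (off 0.05, on 0.3 per frame), bleaches irreversibly
  (0.005 per frame) and is detected per frame with probability 0.9.
  Emitter intensities are Normal with 20% CV around the photon budget.
  Protomers of one complex in one channel are closer than the
  diffraction limit and coalesce into a single localization of summed
  intensity — the physical basis of the intensity-multiplicity analysis.
* **Observation.** Isotropic Gaussian localization error (15 nm),
  a chromatic affine on channel B (translation (120, −80) nm + 0.1%
  scale, representative of dual-view splitters), and uniform false
  positives (0.2 /frame/channel).
* **Rendering (optional).** Pixel-integrated Gaussian PSF (σ 130 nm on
  100 nm pixels), Poisson photon and background noise, camera gain and
  Gaussian read noise, clamped to 16 bit — used to validate the
  detection stage.

Where the imaging literature gives a regime rather than a number
(surface density, photon budget, blink rates), the defaults above are
assumptions chosen once to be typical of single-molecule receptor
imaging, and they are stated as such — not inferences from any
particular dataset.

What the generator deliberately does **not** emulate: spectral
crosstalk between channels, anomalous or confined diffusion, membrane
topography (3D), photophysics beyond two-state blinking plus bleaching,
and non-uniform illumination. Passing recovery tests therefore
demonstrates the correctness of the computation under the stated model,
not robustness to every artefact of real data.

## Design choices that were genuinely open

**Denominator of the relative dimerization level.** The per-cell level
is `n_dimers / min(N_A, N_B)`, with N the mobile tracks living longer
than 10 frames. The minimum makes the fully paired limit equal 1 under
both labelling schemes (heterodimer: every A paired with a B; homodimer
with 50/50 two-colour labelling: the rarer colour saturates first). Raw
counts are always emitted alongside so any other normalization can be
recomputed. Whether the original assay counts particles or
co-trajectories in the numerator is not documented; this implementation
counts co-trajectories and exports everything needed to recount.

**Fragmentation and labelling make the level relative, not absolute.**
Blinking fragments tracks; only doubly labelled complexes are
two-colour detectable (0.85² ≈ 72% of heterodimers; ~50% of two-colour
labelled homodimers). Numerator and denominator are inflated/deflated
nearly proportionally, so the estimate scales monotonically — close to
linearly through the origin — with the true dimer proportion, but with
a slope below 1. That is exactly why dimerization levels are compared
*between conditions* rather than interpreted absolutely, and the
recovery experiment (`run_recovery_experiment()`) checks monotonicity
and linearity rather than absolute equality.

**Immobile filtering.** Implemented as a radius-of-gyration threshold
(75 nm, tracks observed ≥ 10 frames) rather than density-based
spatiotemporal clustering; at D ≥ 0.01 µm²/s and 150 frames the two are
operationally equivalent and the Rg filter has two transparent
parameters. Tracks too short to classify stay in the mobile partition.
Classification accuracy against ground truth exceeds 95% within the
validated density regime (≤ ~0.3 /µm²/channel).

**Linker simplifications.** Full multi-hypothesis tracking cost models
(birth/death costs, motion priors) are reduced to Hungarian assignment
on squared displacement with a hard 500 nm radius and post-hoc gap
closing (1 frame, radius scaled by √(gap+1)). At single-molecule
densities the assignment is usually trivial; a property-based test
checks the solver against brute-force enumeration on every small
instance. Crowded fields (> ~1 /µm²) are outside the validated range.
Assignment ties are broken deterministically.

**Detection.** Single-emitter fits with non-maximum suppression within
2σ; overlapping-emitter deconvolution is out of scope. Emitters a few
hundred nanometres apart — resolvable, but close enough to contaminate
each other's fit window — are handled by a Voronoi mask: pixels closer
to another candidate are excluded from a candidate's fit. The detection
threshold (4 robust SDs of the LoG response, per frame) is a
config-exposed default: per-frame median/MAD adaptation makes it robust
to bleaching-driven intensity drift. Candidates whose fit window is
clipped by the frame border are discarded (with the reason recorded),
so detection metrics are defined on the frame interior; localization
RMSE is additionally defined on isolated emitters (nearest neighbour
beyond 4σ), since unresolvable pairs are a detection ambiguity rather
than a localization error.

**Intensity multiplicity and its truth.** A co-trajectory's per-channel
multiplicity is its intensity at the *first matched frame* divided by
the per-cell monomer reference (median intensity of mobile,
non-co-localized tracks of that channel), optionally divided by the
channel's observable emission duty cycle, rounded; multiplicity ≥ 2 in
either channel marks a higher-order complex. Initial intensity is used,
as in subunit-counting practice, because blinking and bleaching erode a
complex's brightness over the movie. For the same reason the recovery
oracle counts the members *actually emitting* when the co-trajectory
starts: a dark fluorophore carries no intensity information, so the
observable stoichiometry of an array genuinely decays with time. Against
this recoverable truth the classifier is unbiased to within about one
percentage point; against the nominal complex type it would appear
biased low by construction.

**KS p-value convention.** The D statistic is computed exactly at every
pooled jump point (and is checked against a brute-force double-loop
oracle); the p-value uses the asymptotic Kolmogorov distribution with
the Stephens finite-sample correction
λ = (√nₑ + 0.12 + 0.11/√nₑ)·D, nₑ = n₁n₂/(n₁+n₂). Because D is
discrete, the realized test size wobbles with the group size: computed
exactly, it is ≈ 3.1–3.6% for 12–30 cells per condition (mildly
conservative) and ≈ 5.4% at 40 cells. The calibration check therefore
runs at 40 cells per group, matching the larger imaging experiments;
p-value conventions differ across software, which is why D itself is
the primary comparison quantity.

## Numerical and degenerate-input choices

* MSD fitting uses lags 1–5 with pair-count weights; short lags
  minimize confinement and statistical bias. A negative fitted slope is
  truncated to D = 0 and flagged; a negative intercept floors σ at 0.
* Per-trajectory D (for the immobile fraction) comes from the lag-1 to
  lag-2 MSD difference, which cancels the localization-error offset.
* Zero qualifying tracks in a channel make the dimerization level a
  *missing value*, never 0; a cell with no detections at all still
  passes through the pipeline and appears in the report with NAs.
* Configuration validation is strict (mixture proportions sum to 1,
  probabilities in [0, 1], positive geometry); readers reject malformed
  files with the offending column or row named rather than coercing.
* All randomness derives from one run seed through a deterministic
  Lehmer-style substream derivation per cell and stage, so runs are
  bit-for-bit reproducible and cells are statistically independent.

## Problem sizes used in the validation suite

The test suite simulates at the sizes the method targets where that is
cheap (150-frame movies, 10–20 cells per condition, 200 trajectories
for diffusion recovery) and at reduced field sizes (10–15 µm patches)
where a property does not depend on the field. The acceptance script
reruns the headline experiments — diffusion recovery, the
dimerization-gradient recovery at {0, 0.1, 0.3, 0.6}, the
chance-co-localization null, the 20-vs-20-cell power comparison, the
registration, linker and KS oracles, oligomer recovery, and the
rendered-movie detection benchmark — from scratch at full movie length.

## Known limitations

* Densities above ~1 emitter/µm² break the single-emitter detection
  model and increase linking ambiguity; the pipeline is validated for
  the single-molecule regime only.
* The assignment linker has no motion model; highly anisotropic or
  directed motion would benefit from one.
* Intensity multiplicities saturate in usefulness around 3–4× the
  monomer reference at 20% intensity CV; the hexamer level is the
  largest multiplicity the generator exercises.
* The relative dimerization level is not corrected for labelling
  efficiency; cross-condition comparisons assume equal labelling, as
  the underlying assay does.
* Co-trajectories inherit the 100 nm cutoff: complexes transiently
  separated beyond it (e.g. by localization error spikes) fragment, and
  the 10-frame rule then discards short fragments — a conservative
  bias shared with the original measurement.
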