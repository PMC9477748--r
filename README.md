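# cotrackr

Quantification of membrane-receptor homo- and heterodimerization from
dual-colour single-molecule TIRF movies, by two-colour co-tracking.

## The problem

Cytokine receptors assemble on the plasma membrane: a ligand can drive
two receptor chains into a dimer or a larger array, and that assembly —
not the mere presence of the chains — is the signalling event. On a live
cell this can be measured at the single-molecule level: label the two
receptor species (or one species with two colours) with spectrally
distinct fluorophores, image both channels simultaneously by TIRF
microscopy, and ask which emitters *co-diffuse*. Spatial coincidence
within one frame happens by chance; a pair that stays within 100 nm for
10 or more consecutive matched frames while moving through the membrane
is a physical complex.

`cotrackr` is for researchers who have such dual-channel data (or want
to prototype the analysis before acquiring it). It implements the full
chain — channel registration from fiducial markers, single-emitter
localization, trajectory linking with gap closing, immobile-emitter
filtering, frame-by-frame co-localization, co-trajectory building, dimer
calling, diffusion and intensity analysis, and per-cell nonparametric
statistics — together with a synthetic movie generator that emulates the
imaging physics, so every stage is validated by parameter recovery
without any external data.

## The quantities it computes

For each cell:

* **Relative dimerization level** — dimer-called co-trajectories over
  `min(N_A, N_B)` qualifying mobile tracks (lifetime > 10 frames). A
  relative quantity, compared across conditions by two-sample
  Kolmogorov–Smirnov tests on per-cell values.
* **Diffusion constants** — from the pooled time-averaged MSD by
  weighted linear regression, `MSD(τ) = 4Dτ∆t + 4σ²`, over lags 1–5:
  the slope gives D, the intercept the localization error σ.
* **Immobile fraction** — share of trajectories with per-track
  D < 0.01 µm²/s (lag-1/lag-2 MSD difference, which cancels σ).
* **Higher-order fraction** — share of co-diffusing complexes whose
  initial per-channel intensity is ≥ 2× the cell's monomer reference.

Key procedure constants (all config-exposed defaults): 150 frames at
32 ms, 100 nm co-localization cutoff, ≥ 10 co-diffusing frames per dimer
call, track lifetime > 10 frames to qualify, 500 nm linking radius with
1-frame gap closing, 75 nm radius-of-gyration immobile filter.

## Worked example

Simulate one stimulated cell (30 % of complexes are heterodimers) and
analyze it with the chromatic registration estimated from a simulated
fiducial calibration:

```r
library(cotrackr)

cfg <- sim_config(complex_mix = c(monomer_A = 0.35, monomer_B = 0.35,
                                  heterodimer_AB = 0.30),
                  seed = 7)
res <- simulate_and_analyze_cell(cfg)
print(res$result, digits = 3)
```

```
  cell_id condition n_tracks_a n_tracks_b n_dimers relative_dimerization D_um2s
1   cell1   default         85        136       36                 0.424  0.081
  D_cotrack_um2s immobile_fraction oligomer_fraction
1         0.0644             0.153                 0
```

Reading: of the qualifying mobile tracks (`n_tracks_a`, `n_tracks_b`),
`n_dimers` co-trajectories persisted ≥ 10 matched frames within 100 nm,
giving the per-cell relative dimerization. The pooled D of co-tracked
complexes (`D_cotrack_um2s`) is below the overall mobile D
(`D_um2s`) because dimers diffuse more slowly. The estimate is
*relative*: sub-stoichiometric labelling (85 % per channel) and track
fragmentation scale it below the ground-truth 0.30, linearly — which is
why conditions are compared against each other.

A two-condition experiment with per-cell KS statistics:

```r
rep <- run_pipeline(
  list(resting    = list(config = sim_config(
         complex_mix = c(monomer_A = 0.475, monomer_B = 0.475,
                         heterodimer_AB = 0.05)), n_cells = 12),
       stimulated = list(config = sim_config(
         complex_mix = c(monomer_A = 0.35, monomer_B = 0.35,
                         heterodimer_AB = 0.30)), n_cells = 12)),
  seed = 1)
print(rep)
```

```
Co-tracking report ( relative_dimerization ), conditions: resting, stimulated 
  resting        n=12  median 0.044 [0.000, 0.114]
  stimulated     n=12  median 0.259 [0.179, 0.402]
  resting vs stimulated: D = 1.000, p = 2.31e-06 ****
```

The `analysis/` directory holds the narrative workflow as numbered
scripts (registration calibration, the two-condition co-tracking
experiment, dimerization-gradient recovery, diffusion analysis,
higher-order intensity analysis); each writes its tables under
`results/`.

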