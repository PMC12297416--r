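# sptHMM

Diffusional hidden Markov models for single-molecule tracking in bacteria.

## What this package is for

Fluorescently labeled molecules tracked in live bacterial cells — translation
initiation factors, tRNAs, ribosomal subunits — switch between diffusion
states as they bind and release their partners: a factor bound to a ribosome
diffuses at ≲1 µm²/s, a free factor at several µm²/s. From thousands of short
2D trajectories recorded under stroboscopic illumination (e.g. 3 ms laser
pulses in 5 ms camera frames), sptHMM estimates how many molecules are in
each state, how long they stay there, and where in the cell they are.

The core model: displacements of a molecule in state *k* over *n* frame
intervals are isotropic Gaussians with per-dimension variance

    v = 2 D_k (n Δt) (1 − 2R/n) + 2 σ²,     R = t_E / (6 Δt)

where `D_k` is the state's diffusion coefficient, `σ` the localization error,
and `R` the motion-blur factor of a uniform exposure pulse of duration `t_E`.
Hidden states follow a Markov chain with per-frame transition matrix `A`;
a detection gap of `g` missing frames is marginalized exactly via the
transition operator `A^(g+1)` and the `n = g+1` emission variance. All
trajectories are fitted jointly by maximum likelihood (Baum–Welch EM with
multiple random starts), model sizes K = 1..9 are compared by AIC, and the
fitted states are lumped by diffusion thresholds (1 µm²/s for bound/free,
8 µm²/s for fast cleavage artifacts, 0.25/0.05 µm²/s for bound sub-states)
into classes with stationary occupancies `occ`, flux-based mean dwell times
`dwell = occ / outward flux`, and a factor cycle time
`cycle = dwell_bound / occ_bound`. Because dwell times come from fitted
transition frequencies, not observed segment durations, binding events longer
than the trajectories themselves are estimable.

A self-contained simulator generates synthetic datasets with the full
physics — multi-state Brownian motion confined to spherocylindrical cells,
sub-step exposure averaging, localization noise, geometric photobleaching,
detection gaps — plus ground-truth state paths, so every estimator in the
package is validated by parameter recovery.

## Worked example

```r
library(sptHMM)

sim <- simulate_spt(sim_config(n_traj = 300), seed = 42)  # study-like defaults
ds  <- filter_trajectories(sim$dataset)   # keep tracks longer than 5 frames
#> filter_trajectories: removed 54 of 300 trajectories

fit <- dhmm(ds, K = 2, n_starts = 4, seed = 1, sigma_loc = 0.03)
fit
#> Diffusional HMM fit: 2 state(s), 246 trajectories, 8243 steps
#>  state D_um2_s occupancy
#>      1  0.1016    0.3513
#>      2  2.4190    0.6487
#> sigma_loc = 0.03 um (fixed), logL = 13088.80, AIC = -26169.59

cg <- coarse_grain(fit, thresholds = 1)
cg
#> Coarse-grained model (2 states -> 2 classes)
#>  class D_interval occupancy dwell_s
#>  bound     (0, 1]    0.3513  0.2730
#>   free   (1, Inf]    0.6487  0.5042

cycle_time(cg$occ["bound"], cg$dwell["bound"])
#>     bound
#> 0.7772128
cycle_threshold(0.20)   # factor at 20% of ribosome concentration, 10 s cycle
#> [1] 2
```

The data were generated with two states (0.1 and 3 µm²/s, occupancies
0.3/0.7, dwells 0.3/0.7 s) in 0.8 × 3 µm cells. The fit recovers the slow
state and the occupancies; the free-state coefficient reads low (2.4 instead
of 3 µm²/s) because confinement in a cell barely wider than a diffusion
length slows apparent motion — the expected behavior for apparent diffusion
states in bacteria, quantified in the methods vignette. The cycle time of
0.78 s is well below the 2.0 s threshold for a factor present at 20% of the
ribosome concentration, i.e. such a factor must bind more than once per
translation cycle.

Multi-size scans, replicate statistics, and spatial maps follow the same
pattern: `dhmm_scan()`, `aggregate_kinetics()` + `compare_kinetics()`, and
`occupancy_heatmap()`; `run_pipeline()` chains all stages with seeds and
provenance. See the methods vignette (`vignettes/diffusional-hmm.Rmd`) for
the model, its assumptions, and the numerical choices.

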