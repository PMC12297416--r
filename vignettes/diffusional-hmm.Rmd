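---
title: "Diffusional HMM analysis of single-molecule tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusional HMM analysis of single-molecule tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the model

A fluorescently labeled molecule in a bacterial cell is imaged at short
camera frames (Δt, typically 5 ms) under stroboscopic laser illumination
(pulse t_E ≤ Δt, typically 3 ms). Localization software reports its position
in each frame to within a localization error σ (tens of nanometers), and a
tracker links positions into trajectories, tolerating short detection gaps.
The molecule itself interconverts between biochemical states — bound to a
large complex, diffusing freely, occasionally a proteolytic fragment — each
with its own apparent diffusion coefficient.

sptHMM models a trajectory's displacement sequence as a hidden Markov chain
over K diffusion states. The displacement across n frame intervals in state
k is an isotropic bivariate Gaussian with per-dimension variance

v = 2 D_k (n Δt) (1 − 2R/n) + 2 σ²,  with blur factor R = t_E / (6 Δt).

Three corrections are folded into this emission model:

* **Motion blur.** The camera reports the average position over the
  illumination pulse, which shortens apparent displacements. For a uniform
  pulse the per-step variance loses 4 D Δt R; because blur acts only at the
  two sampled frames, the loss does not grow with the span n, hence the
  2R/n term.
* **Localization error.** Both end points carry independent error σ,
  adding 2σ². A single global σ is fitted by default (or fixed by the
  caller); per-point uncertainties, when the data carry them, are used as
  fixed additive variances instead.
* **Missing positions.** A gap of g missed frames is marginalized exactly:
  emission variance with n = g + 1, transition operator A^(g+1).

The hidden chain has per-frame transition matrix A; the state of the first
displacement is drawn from the stationary vector of A. Tying the initial
distribution to stationarity (rather than treating it as free parameters)
reflects the steady-state assumption of the experiment and removes K − 1
parameters that short trajectories could not constrain anyway.

All trajectories of a dataset are fitted **jointly**: the log-likelihood is
the sum of per-trajectory forward-algorithm log-likelihoods, maximized by
Baum–Welch EM. The M-step for A uses exact expected per-frame transition
counts, decomposed through the composite operators A^m for gapped steps; the
diffusion coefficients and σ are updated by one-dimensional likelihood
maximization (their M-step has no closed form once blur, gaps, and σ mix in
the variance). Because the initial-state term is tied to stationarity and
left out of the A update, the algorithm is a generalized EM: in practice the
log-likelihood is monotone to numerical precision, and the tests enforce
monotonicity with a slack of 1e-6 relative.

**What the emission model neglects.** Consecutive displacements share a
blurred end point and its localization error, which correlates them; the
likelihood treats steps as conditionally independent given the states. This
diagonal approximation keeps EM exact and fast; its bias is quantified by
the recovery tests against the simulator, which implements the full physics.
Confinement is likewise not in the likelihood: the model fits *apparent*
diffusion states. In study-sized cells (0.8 × 3 µm) a molecule at
3 µm²/s fits at ≈2.4 µm²/s because the cell wall folds its excursions back;
slow states are essentially unaffected. This is a property of the data, not
a defect of the estimator — occupancies and dwell times, the quantities the
kinetic conclusions rest on, are recovered accurately under confinement.

## Fitting, model size, and coarse-graining

`dhmm()` runs EM from several random initializations (D log-uniform on
0.005–20 µm²/s, self-transitions uniform on 0.8–0.99; 10 starts by default
under a master seed) and keeps the best converged fit (relative
log-likelihood change < 1e-8 or 500 iterations). States are reported sorted
by D, ties broken by occupancy. `dhmm_scan()` fits K = 1..9; by AIC
(2p − 2logL with p = K + K(K−1) (+1 when σ is fitted)), larger models keep
improving on real-like heterogeneous data — the biological reading comes
from coarse-graining, not from a single "true" K.

`coarse_grain()` lumps states by diffusion thresholds: 1 µm²/s separates
complex-bound from free molecules, 8 µm²/s splits off fast cleavage
artifacts of fusion constructs, and `subcluster_split()` adds 0.25 and
0.05 µm²/s to resolve bound sub-states (mRNA-engaged vs idle complexes,
very slow nucleoid-associated binding). A state exactly at a threshold joins
the slower class — an arbitrary but documented convention. Class occupancy
is the stationary mass of members; the class-to-class flux is
Σ π_i A_ij / Δt, and the mean dwell is occupancy / outward flux. This
flux-based dwell is deliberately *not* the mean duration of observed binding
segments: segment durations are censored by trajectory length
(photobleaching) and biased low as soon as dwells approach the track length;
`dwell_segments()` implements that estimator only so the bias can be
measured. Coarse fluxes between bound sub-states are model-size dependent at
5 ms exposure (short segments under-resolve slow-slow transitions), so the
per-model-size tables are reported rather than hidden.

## Kinetic summaries

The cycle time of a factor is dwell_bound / occ_bound, the bound-plus-free
period at stationarity. Comparing it to a concentration-scaled ribosome
translation cycle (`cycle_threshold()`: ratio × the 10 s lower bound of the
10–17 s window — the lower bound makes the flag conservative) tells whether
the factor must bind more than once per translation event. Replicates are
summarized by `aggregate_kinetics()` with means and sample SDs *across
independent experiments* (never across pooled steps), and conditions are
compared with a two-sided unpaired Student t-test (`compare_kinetics()`;
Welch variant by flag) using the conventional star coding. The pooled cycle
time is computed from pooled mean occupancy and dwell, not by averaging
per-experiment cycles; for small between-experiment spread the two agree to
first order, and the pooled form is stable when an experiment has a small
bound class.

## The simulator and what passing tests mean

`simulate_spt()` draws, per trajectory: a cell (spherocylinder; length
lognormal around 3 µm, width 0.8 µm), a start point uniform in its volume,
an initial state from the stationary distribution of the switching-rate
matrix, and then propagates 3D Brownian motion with reflecting boundaries at
50 sub-steps per frame, freezing the state within a sub-step (rate × sub-step
≪ 1 is enforced with a warning). The emitted localization is the mean of
sub-step positions in the pulse window at the start of the frame (the window
phase is irrelevant under the uniform-pulse approximation), projected to 2D
(z discarded — imaging integrates over the ~0.8 µm cell depth) and perturbed
by Gaussian error σ. Trajectory length is geometric with mean 30 frames
(photobleaching as termination, not intensity decay); frames are then
dropped independently with probability 0.1, with the middle frame of any
run of more than 3 missing frames restored so the tracker's gap rule holds.
Defaults mirror the live-cell study conditions: two states at 0.1 and
3 µm²/s with dwells 0.3/0.7 s (occupancies 0.3/0.7), 5 ms frames, 3 ms
pulses, σ = 30 nm, ≥3 independent experiments.

The simulator reproduces the statistical structure the fitter assumes plus
the physics it neglects (confinement, blur-induced correlations). It does
not emulate camera noise models, PSF shape, z-dependent localization error,
or molecule misassignment by the tracker; passing recovery tests therefore
validate the estimator chain downstream of localization and linking, not
those upstream steps.

Two geometry regimes appear in the tests, deliberately: recovery suites run
in a weakly confining cell (10 × 30 µm) so that fitter accuracy is measured
against the model it implements, and the confinement bias is quantified
separately under study-sized cells. Robustness checks (occupancy stability
across K = 2..6) and end-to-end pipeline tests use the study geometry.

## Numerical choices and degenerate inputs

* Forward–backward uses per-step scaling; emissions are max-shifted before
  exponentiation. Zero forward mass raises an error naming the trajectory.
* D updates maximize the expected log-likelihood on a log grid via Brent
  search (tolerance 1e-11 on log D); σ likewise on log σ in [1e-4, 1] µm.
* The stationary vector comes from the eigen decomposition of Aᵀ with a
  power-iteration fallback; rows of A that receive no expected transitions
  keep their previous values.
* Trajectories with fewer than 2 localizations are skipped with a warning;
  a coarse class with zero occupancy reports dwell NA and is flagged rather
  than producing infinities; identical comparison groups return t = 0,
  p = 1 instead of erroring on zero variance.
* Filtering conventions: "longer than 5 frames" is a strict inequality on
  the number of localizations; a gap is the count of missing frames between
  consecutive localizations, at most 3; a larger gap rejects the trajectory
  on read (the tracker convention), with splitting available as an option.
* Problem sizes in the test suite (up to 1000 trajectories × ~30 frames,
  20 seeded replicates, 10⁶-step chain oracles, 2000 t-test replicates) were
  chosen so the full suite exercises every estimator at Monte-Carlo errors
  well below the asserted tolerances.

## Known limitations

* The likelihood is free-diffusion; apparent D of fast states is
  confinement-biased in small cells (quantified above, shared by any
  unconfined-likelihood fit of in-cell data).
* Step-to-step covariance from blur and shared localization error is
  neglected; a covariance-aware emission model is a possible extension.
* Spatial maps approximate nucleoid-based cell sorting by cell-length
  windows; nucleoid imaging itself is out of scope.
* The per-frame transition matrix is embedded from, and reported at, the
  acquisition frame interval; kinetics faster than Δt are aliased into the
  apparent rates, which is why bound-sub-state fluxes at 5 ms are reported
  per model size rather than interpreted.
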