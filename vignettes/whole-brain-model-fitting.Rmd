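---
title: "Whole-brain model fitting and connectome-based classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain model fitting and connectome-based classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

## The problem

Whole-brain dynamical models turn a subject's structural connectome —
streamline counts (SC) and average path lengths (PL, mm) between
parcellated brain regions — into simulated regional activity, and from
there into simulated BOLD and a simulated functional connectome (sFC).
Comparing sFC with a subject's empirical functional connectome (eFC) over
a grid of the two free global parameters, the coupling strength C and the
delay-per-metre tauGlobal, yields a goodness-of-fit (GoF) landscape whose
maximum validates the model for that subject (*neuroimaging model
fitting*).  Maximising instead the *between-group* effect size of the GoF
values selects parameters where patients and controls differ most
(*behavioural model fitting*).  Scalar connectome relationships — Pearson
correlations between the strict upper triangles of eFC, eSC and sFC — then
serve as features for classifying patients against controls with a
leakage-safe nested cross-validation and L1-penalised logistic regression.

Clinical MRI data cannot be redistributed, so `dynconn` ships a
synthetic-cohort generator whose "empirical" BOLD is produced by the same
forward model at hidden, group-dependent ground-truth parameters.  Planted
differences are therefore recoverable, which is what the test suite and
the acceptance script measure.

## The electrical model

Each region holds an excitatory and an inhibitory population with
postsynaptic potentials (PSPs) `y_e`, `y_i` (mV) and currents `z_e`,
`z_i`.  The kernels are critically damped second-order systems with rate
constants `a = 100` and `b = 50` 1/s, amplitudes `A = 3.25` and
`B = 22` mV, scaled in frequency by a factor `R = 2.2`:

```
y'_e = z_e
z'_e = A a R^2 sigmoid_e((C/N) sum_m C_nm y_e,m(t - tau_nm) - C_ei y_i)
       - 2 a R z_e - (a R)^2 y_e + eta_e
y'_i = z_i
z'_i = B b R^2 sigmoid_i(C_ie y_e) - 2 b R z_i - (b R)^2 y_i + eta_i
```

with `sigmoid(v) = Fmax / (1 + exp(r (v0 - v)))` (`Fe = 100`, `Fi = 50`
1/s, `r = 0.56` 1/mV, `v0 = 6` mV) and intra-regional couplings
`C_ie = C_ei = 6`.  Inter-regional weights are normalised streamline
counts `C_nm = w_nm / W`, where `W` averages the counts over all
off-diagonal pairs, and delays are `tau_nm = tauGlobal * L_nm` (PL in mm
converted to metres).  The noise `eta` is uniform on ±1.5 V/s² per
population, region and step; since the PSP equations are written in mV the
integrator converts the bound to 1500 mV/s².  Without that conversion the
forcing would be four orders of magnitude below the sigmoid scale and the
model would be numerically static.

Two typesetting ambiguities are resolved explicitly: the coupling sum is
scaled by `C/N` (a `couplingScaledByN = FALSE` switch gives plain `C`),
and `R` is one global scalar.

### Numerical scheme

Fixed-step Euler with a stored EPSP history as the delay buffer; delays
round to the nearest step; the history before t = 0 holds the zero initial
state; the first 20 s are discarded.  The default `dt` is 1 ms, which
resolves the fastest kernel time constant `1/(aR) ≈ 4.5 ms`; grid searches
in the tests run at 2 ms, which still gives ~25 steps per cycle of the
~20 Hz network oscillation and changes deterministic trajectory statistics
by well under the few-percent level (the suite asserts < 2% when halving
1 ms).  The noise is a bounded forcing redrawn each step and added without
a `sqrt(dt)` factor, honouring its stated amplitude and units; this makes
the stationary PSP variance proportional to `dt`, which is why comparisons
across `dt` in the tests are run with the noise off.  All randomness flows
through R's RNG, so every simulation is bit-reproducible given its seed.

### Where the model lives dynamically

With these parameters an uncoupled node rests at a low-activity fixed
point (`y_e* ≈ 0.0088 mV`, from the algebraic equilibrium equations; the
frequency-scaling factor cancels at rest) with a very shallow sigmoid
slope.  Couplings of order one leave the network numerically inert — the
measured simulated FC does not change between `C = 0` and `C = 1.5`.  The
network's dynamical repertoire unfolds at couplings of order 10²: around
`C ≈ 55–90` (for typical generated connectomes) the excitatory feedback
through the connectome destabilises the low state, producing
noise-sustained oscillations (~10–25 Hz, scaling with `R`) and slow
state-switching that carry connectome-specific correlation structure into
the BOLD band; above that the sigmoid saturates and the network falls
silent again.  The default fitting grid therefore spans C in [0, 120]
(64 points; 16 at desk scale) and tauGlobal in [0, 0.42] s/m (43 points;
11 at desk scale), keeping the electrophysiologically feasible delay band
0.06–0.25 s/m interior.

## Hemodynamics

The Balloon–Windkessel system maps a dimensionless neural drive `x` to
BOLD per region: vasodilatory signal `s' = x - kappa s - gamma (f - 1)`,
inflow `f' = s`, venous volume `tMTT v' = f - v^(1/alpha)`,
deoxyhemoglobin `tMTT q' = f (1-(1-E0)^(1/f))/E0 - v^(1/alpha) q / v`,
observation `V0 (k1 (1-q) + k2 (1-q/v) + k3 (1-v))` with
`k1 = 4.3 theta0 E0 TE`, `k2 = epsilon r0 E0 TE`, `k3 = 1 - epsilon` and
the standard 3 T parameter values.  Initial state `[0, 1, 1, 1]` is an
exact fixed point under zero input.

The drive is the per-region z-scored EPSP multiplied by a gain.  The gain
default is 0.05: the balloon equations require `f, v, q > 0`, and
unit-gain z-scored oscillatory EPSP drives `f` through zero at a small but
non-negligible fraction of grid points (measured: ~1% of landscape points
at gain 0.1, none in several thousand simulations at 0.05).  Violations
raise an error naming the time and region rather than being clipped.
`bwBold` integrates with RK4 at the input step; inside the forward model
the drive is block-averaged to a 25 ms step first — the balloon time
constants are of order seconds, and the suite checks RK4 tracks an
adaptive-step reference integrator to 10⁻⁴ relative error and that halving
the step moves the trajectory by far less than 0.5%.  BOLD is sampled at
the integration step nearest each multiple of TR (2.21 s; 300 samples in a
663 s scan).

## Band-pass filtering and connectome relationships

Four conditions: NF (none), BF (0.01–0.1 Hz), LF (0.01–0.05 Hz), HF
(0.05–0.1 Hz), applied identically to empirical and simulated BOLD as an
order-6 Butterworth, forward and backward for zero phase.  Edge transients
of these very-low-frequency filters ring over ~1/(low·TR) samples, so the
signal is odd-reflection padded by ten of those lengths before filtering.
The analytic check maps probe frequencies through the bilinear transform
onto the analog prototype's magnitude response.  All connectome
relationships are Pearson correlations between strict upper triangles;
SC enters as raw streamline counts (the alternative of log-transformed
counts is not used; nothing in the pipeline depends on monotone
transformations of SC except through ranks).

## Behavioural fitting and random-field thresholding

Per grid point a two-tail Wilcoxon rank-sum test (normal approximation
with tie and continuity corrections — group sizes here are ≥ 20; exact
enumeration backs the implementation in tests) compares the groups' GoF
values; the signed effect size is `z/sqrt(n)`, positive where controls
exceed patients.  The z map is smoothed with a 2D Gaussian kernel
(FWHM 3 grid steps by default).  For thresholding, the smoothing uses
zero-padded convolution renormalised by the convolved mask, and the
smoothed map is divided by its exact per-pixel null standard deviation, so
under the null the smoothed field is unit-variance everywhere including
the edges; a plain reflect-boundary smoother (`gaussianSmooth2D`) is
exported for general map smoothing.  The family-wise threshold solves
`2 E[EC(u)] = alpha` where the expected Euler characteristic of the
rectangular search region combines the 2D, 1D (perimeter) and 0D resel
counts at the kernel FWHM.  Monte-Carlo simulation of stationary smooth
null fields in the suite confirms the realised family-wise error sits
within binomial error of the nominal 5%.  The behavioural optimum is the
point of maximal |effect size| inside the significant area — absolute
rather than signed, because group difference, not direction, defines the
discriminative parameter region (in practice the detected direction is
patients > controls for the planted effects).  An empty mask yields no
optimum; cross-validated feature assembly then falls back to the maximal
|effect size| on the training set.

## The classification protocol

Ten features: per parcellation ("schaefer_like", 114 regions by default;
"desikan_like", 82), corr(eFC, eSC); corr(eFC, sFC) and corr(eSC, sFC) at
the subject's own neuroimaging optimum; and the same two at the
behavioural optimum.  Conditions shuffle the complementary feature groups
column-wise across subjects (multisets preserved), re-drawn each repeat.
The nested CV runs 50 repeats of a stratified 5-fold outer split: 250
outer-fold tests and, at the 116-subject default, 5800 subject-level
predictions per condition.  Stratification keeps both classes in every
fold at desk scale; ties at the 0.5 threshold classify as patient.  Inside each outer fold: behavioural optima are recomputed on the
training subjects only; the age confound is regressed out per feature with
training-fitted OLS coefficients applied to training and test subjects;
the logistic LASSO is fitted along a 50-value auto-scaled lambda path with
the penalty minimising the inner 10-fold cross-validated deviance
(`glmnet`).  Disjointness of training and test sets is asserted at
runtime, and the landscape provider asserts that only training subjects
enter the behavioural fit.

Evaluation: confusion metrics at threshold 0.5, threshold-sweep ROC/AUC
(equal to the Mann–Whitney statistic; asserted), probability calibration
in ten equal-width bins, the Brier score, and the exact 1-Wasserstein
distance between the predicted probabilities and the uniform distribution
on [0, 1] computed by empirical-CDF integration.

## The synthetic cohort

Defaults emulate the study conditions: 51 controls / 65 patients; ages
normal with HC mean 55.02 (SD 9.69) and PD mean 62.00 (SD 9.62), redrawn
below the 18-year floor; male proportions 30/51 and 45/65; scans of 663 s
at TR 2.21 s.  SC is symmetric, zero-diagonal, integer, with edges present
at density 0.35 and log-normal counts (meanlog 4, sdlog 1) — heavy-tailed
like tractography counts; PL for present edges is gamma-distributed
(shape 3, mean 90 mm) truncated to the tracking limits [2.5, 250] mm.
Ground truths sit inside the informative coupling window and on desk-grid
points: HC (C = 64, tau = 0.168 s/m), PD (C = 80, tau = 0.21 s/m).
"Empirical" BOLD is the forward model at the group's ground truth,
per-region unit-variance normalised, plus Gaussian measurement noise
(SD 0.1).  One master seed derives stable per-subject and per-stage
sub-seeds by hashing text tags, so any slice of a cohort is reproducible
in isolation.

What the generator does *not* emulate: spatial geometry of real
parcellations, distance-dependent connection probability, hemispheric
symmetry, subject-level parameter heterogeneity within a group, scanner
drift or motion artefacts.  Passing tests therefore demonstrate that the
pipeline recovers what it plants under its own forward model — a
self-consistency and correctness statement, not a claim about real
Parkinson's data.

## Problem sizes used in the tests

The suite runs the parameter-recovery study with 10 subjects of 20
regions on the 16 × 11 desk grid, 200 s simulations at `dt = 2` ms
(empirical scans at the full 663 s), recovering the planted grid point
within one grid cell for at least 8 of 10 subjects.  Behavioural-fitting
calibration uses 200 precomputed null cohorts (mask non-empty in at most
5% plus two binomial standard errors) and 200 planted-block cohorts (≥ 90%
optima inside the block).  The classification checks run the full
protocol shape — 116 subjects, 50 repeats, 5 outer folds — on cached
features.  The acceptance script repeats these computations at slightly
reduced Monte-Carlo sizes and writes the resulting quantities as JSON.

## Known limitations

- The coupling grid upper bound (120) is calibrated to the generator's
  connectome statistics; connectomes with very different mean streamline
  counts shift the informative window (weights are count-normalised, so
  only the distribution shape matters, but strongly different shapes may
  require a custom grid).
- One stochastic realisation per grid point (configurable seeds) keeps
  landscapes noisy at short simulation lengths; the recovery tests absorb
  this by the one-grid-cell criterion.
- The Euler delay integrator targets robustness and speed, not weak-order
  accuracy; quantitative spectra at `dt` coarser than ~2 ms drift
  visibly.
- Only the two-population model variant is implemented; no regional
  heterogeneity beyond the connectome, and no EEG forward model.
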