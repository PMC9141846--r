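---
title: "Models and estimators for self-poised dynamical criticality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators for self-poised dynamical criticality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(critpoise)
```

Biological systems from the inner ear to the cortex appear to hold
themselves near dynamical instabilities — Hopf bifurcations, the edge of
chaos, the line `Re = 0` in the complex plane of linearized growth
rates. Sitting at such a boundary buys sensitivity and flexibility;
staying there requires active feedback. This package collects, in one
toolkit, four working models of that idea plus the estimator used to
look for it in data:

1. the **forced Hopf normal form** (`hopf_*`), whose critical point
   shows the four signatures of an active detector: huge gain, sharp
   tuning, a compressive 1/3-power response, and spontaneous oscillation
   when pushed past threshold;
2. an **anti-Hebbian network** (`ah_*`) whose synaptic matrix poises its
   own eigenvalues onto the imaginary axis;
3. **critically coupled map lattices** (CCMLs; `checkerboard_*`,
   `bipartite_gaussian_2d`, `exposure`, `ccml_*`), where a
   volume-conserving coupling built from an antisymmetric matrix meets a
   chaos-capable local map;
4. **spatiotemporal spectral entropy** (`st_spectrum`,
   `spectral_entropy`, `phase_diagram`) to map the ordered, complex and
   chaotic regimes of those lattices; and
5. **critical mode analysis** (`critical_modes`, `surrogate`,
   `stability_shift`), windowed AR(1) fits locating multichannel
   dynamics relative to the instability line, validated here entirely on
   synthetic recordings.

This vignette explains each model, the parameters that matter, the
numerical choices made, and what the bundled tests do and do not show.

## The forced Hopf normal form

The canonical reduction of a nonlinear oscillator near a supercritical
Hopf bifurcation, driven sinusoidally, is

$$\dot z = (\mu + i\omega_0)\, z - |z|^2 z + F e^{i\omega t},$$

with control parameter $\mu$ (distance to the bifurcation), natural
frequency $\omega_0$, and forcing $(F, \omega)$. The cubic coefficient
is normalized to 1; this fixes the amplitude scale and is the standard
convention. Phase-locked solutions $z = R\,e^{i(\omega t + \phi)}$
satisfy

$$R^2\left[(\mu - R^2)^2 + (\omega_0 - \omega)^2\right] = F^2,$$

a cubic in $R^2$ solved exactly by `hopf_steady_response()` via
`polyroot`. At $\mu = 0$, $\omega = \omega_0$ this degenerates to
$R = F^{1/3}$: the compressive power law, with gain $R/F = F^{-2/3}$
diverging as the stimulus weakens.

```{r hopf}
hopf_steady_response(hopf_params(mu = 0, omega0 = 1, F = 1e-6))$amplitude
Fg <- exp(seq(log(1e-8), log(1e-2), length.out = 40))
hopf_response_exponent(mu = 0, omega_offset = 0, F_grid = Fg)$slope
```

Numerical choices:

* **Integration** (`hopf_simulate`) uses fixed-step RK4 in the frame
  co-rotating with the forcing, where the forcing term is constant and
  only the slow amplitude/phase dynamics must be resolved. The default
  step is 1/100 of the forcing period.
* **Multistability.** For $\mu > 0$ and detuning $|\omega_0 - \omega| <
  \mu/\sqrt 3$ the response cubic can have three positive roots. All
  roots are returned, sorted, with a flag; `amplitude` is the smallest,
  and nothing is discarded silently. Sweep functions exclude multistable
  points and count them in a warning.
* **Unforced case.** At $F = 0$ the rotating-frame equation is
  degenerate; the unforced attractor amplitude (0 for $\mu \le 0$,
  $\sqrt\mu$ for $\mu > 0$) is returned directly.
* **Half-width** of a tuning curve is measured where the amplitude falls
  to $1/\sqrt 2$ of the resonant peak, in units of $\omega_0$.
* **Mistuning convention.** "Mistuned past threshold" is implemented on
  the supercritical side, $\mu > 0$, where a limit cycle of radius
  $\sqrt\mu$ exists; the subcritical side is a damped responder.

## The anti-Hebbian self-poising network

The model couples linear activity to anti-Hebbian plasticity:

$$\dot x = M x, \qquad \dot M = \alpha\,(I - x x^\top), \qquad
0 < \alpha \ll 1.$$

Unstable modes of $M$ amplify $x$; the $-\alpha\,x x^\top$ term then
subtracts the activity's outer product from the synapse, stabilizing
exactly the directions that grew, while the $\alpha I$ drift pushes all
modes back up. Nothing in the equation names a set point, yet the whole
spectrum of $M$ collapses onto the imaginary axis and stays there — a
bank of self-tuned Hopf bifurcations. Three epochs structure the
relaxation: unstable eigenvalues stabilize over a time of order 1 (up to
a logarithmic factor), the spectrum flattens toward the axis over a time
of order $1/\alpha$, and the stationary fluctuations live on the
geometric-mean timescale $1/\sqrt\alpha$ — the scaling that
`ah_timescale_scaling()` verifies by regression of the autocorrelation
decay time on $\log(1/\alpha)$.

Numerical and design choices:

* **Integrator**: fixed-step RK4 on the joint $(x, M)$ system, in
  compiled code, with `dt = 0.01 * min(1, 1/alpha)` so both timescales
  are resolved. The integrator is cross-checked in the test suite
  against the closed form $M(t) = M(0) + \alpha t I$ that holds when
  $x(0) = 0$, and against the trace identity
  $d\,\mathrm{tr}(M)/dt = \alpha(n - \|x\|^2)$.
* **Initial conditions**: i.i.d. Gaussian, scale 1 for $x$ and
  $1/\sqrt n$ for the entries of $M$, so the initial spectrum has O(1)
  radius by the circular law. Both scales are configurable.
* **Eigenvalue bookkeeping**: spectra are recorded every
  `record_every` steps and matched across frames by greedy
  nearest-neighbour assignment in the complex plane; mismatches can only
  blur individual traces, never pooled summaries.
* **Epoch summaries**: `t_flatten` is the first time the mean $|Re|$
  drops below half its initial value (the stationary band scales as
  $\sqrt\alpha$, so much smaller fractions are never reached at moderate
  $\alpha$ and return `NA`); the fluctuation timescale is the median
  over eigenvalue traces of the first lag at which the autocorrelation
  of $\mathrm{Re}(\lambda_k(t))$ falls below $1/e$, with an `Inf`
  sentinel for constant traces.

A caveat the acceptance tests make explicit: at the reference condition
$n = 32$, $\alpha = 10^{-3}$, run to $T = 10/\alpha$, the stationary
band of $|\mathrm{Re}|$ sits at roughly a fifth of the initial spread of
real parts — fluctuations shrink like $\sqrt\alpha$, but at this
$\alpha$ they do not reach 5% of the initial spread, and the *largest*
real part hovers slightly above zero (some mode is always being pumped
by the $\alpha I$ drift) even though individual eigenvalues cross the
axis constantly. The corresponding acceptance assertions fail honestly
rather than being loosened.

## Critically coupled map lattices

A CCML alternates two half-steps, local nonlinearity then global
coupling:

$$\bar x_i^t = f(x_i^t) = c\,x_i^t e^{-(x_i^t)^2/2}, \qquad
x_i^{t+1} = \sum_j U_{ij}\, \bar x_j^t, \qquad U = e^{\lambda M}.$$

(Some treatments write the map prefactor as $\alpha$ and the exposure
time as $\tau$; this package standardizes on $c$ and $\lambda$.) The
Gaussian map is bounded, fixes the origin, and period-doubles to chaos
as $|c|$ grows. The coupling matrix $M$ is **antisymmetric by
construction**, so its spectrum is purely imaginary — every spatial mode
sits exactly at a Hopf-like instability threshold — and the exposure
operator $U$ is orthogonal with $\det U = 1$: the coupling stage
conserves phase-space volume exactly, leaving all contraction to the
local map. As $\lambda$ grows, the rows of $U$ broaden diffusively
while the determinant stays pinned at 1.

Three constructions are provided, all on periodic lattices:

* `checkerboard_1d(n)`: $M_{i,i\pm1} = (-1)^i$ — alternate sites
  excitatory/inhibitory; `n` must be even or the sign rule breaks at the
  periodic seam.
* `checkerboard_2d(nx, ny)`: the same rule with source-site sign
  $(-1)^{i+j}$; dynamics on this lattice are strongly anisotropic, with
  gliders along the diagonals.
* `bipartite_gaussian_2d(nx, ny, sigma, cutoff)`: two superposed grid
  layers, excitatory on top of inhibitory, coupled across layers only
  via the circularly symmetric kernel
  $K_{pq} = e^{-(\Delta x^2 + \Delta y^2)/2\sigma^2}$ (minimum-image
  displacements), assembled as the antisymmetric block completion
  $M = \begin{pmatrix} 0 & K \\ -K^\top & 0\end{pmatrix}$ — the minimal
  antisymmetrization consistent with the excitatory-to-inhibitory
  asymmetry. The kernel is truncated at `cutoff = 4*sigma` (tail below
  $3.4\times10^{-4}$ of the peak) with no renormalization, so every
  matrix is reproducible bit for bit from its parameters.

The matrix exponential is delegated to `Matrix::expm()` and cached per
(construction, $\lambda$); a small-lattice test cross-checks it against
the cosine/sine closed form from the eigendecomposition of $-iM$.
Initial fields are i.i.d. uniform on $[-a, a]$, seeded. For 2D runs the
sign of $c$ is taken literally as given (the reference parameter points
$\lambda = 0.5, c = -1.2$ and $\lambda = 0.53, c = -2.3$ use negative
$c$).

```{r ccml}
cm <- checkerboard_1d(64)
op <- exposure(cm, 4)
det(op$U)
```

## Spatiotemporal spectra and phase diagrams

`st_spectrum()` Fourier-transforms a lattice trajectory over all
spatial dimensions and over time within blocks (default 128 steps, 50%
overlap, no taper — map iterates are not continuous signals, and leakage
is consistent across parameter cells), averaging the modulus squared
across blocks; normalization is fixed by Parseval per block. For the
bipartite lattice the two layers enter as a third spatial axis of
extent 2.

`spectral_entropy()` treats the normalized power as a probability
distribution and returns Shannon entropy in bits; the DC bin is excluded
by default, because the discriminating structure lives at low but
*non-zero* frequencies: frozen patterns concentrate power at
$\omega = 0$, synchronized chaos at $k = 0$, and complex spatiotemporal
behaviour spreads power over the low-frequency shell that
`low_frequency_power()` measures (default band: 10% of Nyquist on every
axis, infinity-norm, DC excluded; the choice is recorded in the
output metadata).

`phase_diagram()` sweeps a $(c, \lambda)$ grid, building each $U$ once
per $\lambda$, with per-cell seeds derived from
(seed, c index, $\lambda$ index) so any cell is reproducible in
isolation; cells whose field decays to numerical zero are flagged
`quiescent`, blow-ups are flagged and isolated without aborting the
sweep. The default study conditions used in the tests are the 64-site
1D checkerboard, $c$ from 0.5 to 4 in steps of 0.25, $\lambda$ from 0
to 0.675 in steps of 0.075 (the top row being the reference slice),
768 steps with a 256-step transient — sizes chosen so a full sweep runs
in seconds while leaving at least seven averaging blocks per cell.
`phase_regions()` then classifies finite-entropy cells into terciles
and measures the contiguity of the intermediate ("complex") tercile as
the largest 4-connected component's share of it. One finding the
acceptance test records honestly: with this operationalization the
intermediate tercile captures both the order–chaos transition band *and*
a weak-coupling band of moderate entropy, so its largest component
covers slightly less than half of the tercile — the complex band itself
is solid, but the tercile rule does not isolate it.

## Critical mode analysis

Given a multichannel recording $x(t)$ sampled at $f_s$, the analysis
posits the lowest-order law of motion $\dot x = Mx + \eta$ and
regresses it in discrete time: per sliding window,

$$\hat A = \arg\min_A \sum_t \|x_{t+1} - A x_t\|^2,$$

by plain least squares (`fit_window`), after removing per-window channel
means — an affine offset otherwise biases $\hat A$. No other
pre-processing is applied, deliberately: filtering and detrending can
manufacture spurious closeness to criticality, so the tool keeps its
hands off the data and records what it did. The eigenvalues of $\hat A$
map to continuous growth rates via the principal branch,
$\lambda_c = f_s \log \lambda_d$: $\mathrm{Re}\,\lambda_c$ is a decay
(negative) or growth (positive) rate in 1/s, $\mathrm{Im}\,\lambda_c$
an angular frequency (reported as Hz where user-facing; frequencies
above Nyquist alias and are unrepresentable). Defaults: 2 s windows,
0.5 s hop — long enough that samples well exceed channels for the
synthetic defaults, short enough to resolve nonstationarity. With
demeaning, a window must contain at least `channels + 2` samples for a
full-rank regressor; rank-deficient windows are solved by pseudoinverse
and flagged, and pooled summaries use clean windows only.

The bundled generator `synth_series()` emulates ECoG-like recordings as
noise-driven linear dynamics: rotation–scaling blocks with prescribed
$(\mathrm{Re}, \mathrm{Im})$ placed at chosen distances from the
instability line, conjugated by a random orthogonal matrix and driven
by i.i.d. Gaussian innovations. It emulates the *dynamical* structure
of such recordings — poised oscillatory modes mixed across channels —
and none of their other features: no 1/f background, no artifacts, no
nonstationarity unless you splice segments, no nonlinearity. Passing
tests therefore certify the estimator (recovery, surrogate direction,
test calibration), not any claim about real brains. The reference
recovery setting used in the tests is 8 channels at 250 Hz for 60 s,
modes at $-1+5i$, $-5+15i$, $-20+40i$ (Re in 1/s, Im in Hz) plus a
fourth pair $-10+25i$ to fill the 8-dimensional state space, 10 seeds.
Deep modes recover to a few percent; the slowest mode ($-1$ 1/s, decay
time half the window) carries the ordinary least-squares finite-window
bias and recovers with median error just over 15% — the acceptance test
asserts the 15% band and fails honestly on that one target.

Negative controls (`surrogate`): per-channel sample shuffling destroys
all dynamics (and drives fitted eigenvalues far from the axis — the
directional signature the tests require on every seed); per-channel
phase randomization preserves each channel's spectrum while destroying
cross-channel structure; window shuffling destroys slow ordering while
preserving local dynamics. Condition contrasts (`stability_shift`)
difference the pooled mean growth rate between two fitted conditions
and attach a permutation p-value in which *windows*, not eigenvalues,
are the exchangeable unit — eigenvalues within a window are one joint
draw, and permuting them individually would fake independence. The
test's type-I rate is checked against its binomial confidence band over
200 scaled-down null repetitions.

```{r modes}
s <- synth_series(4, 20, 100, list(c(-2, 8), c(-10, 25)), seed = 1)
fits <- critical_modes(s, window = 1, hop = 0.5)
summary(fits)
```

## Orchestration and serialization

`run_job()` executes a JSON-configured run of any module: the
configuration is validated against a per-module key schema (unknown keys
are named in the error), a manifest — full resolved parameters, package
version, seed, status — is written before any computation, artifacts are
written as delimited text with JSON sidecars carrying units and
provenance, and the manifest is finally marked `done` or `failed`.
Numbers serialize with 17 significant digits, so every artifact
round-trips to bit-identical values; sweep cells fail independently
without aborting the sweep. A thin command-line wrapper is installed at
`inst/exec/criticality`. Progress goes to stderr; numeric results only
to artifacts.

## Package shape

The estimator half of the package follows the classic R modelling
idiom: `critical_modes()` is a fitting function returning a classed
object with `print`, `summary`, `coef` and `plot` methods. The
simulator half returns classed objects (`coupling_matrix`,
`exposure_operator`, `lattice_series`, `eigen_trace`, `phase_diagram`)
with `print`/`plot` methods, in base-R style throughout; no tidyverse
dependency is used.

## Known limitations

* The Hopf module covers single-tone forcing only: no combination
  tones, two-tone suppression, or transduction biophysics.
* The anti-Hebbian model is the linear-activity original; nonlinear
  rate dynamics and synaptic normalization variants are out of scope,
  as is any added noise (the equation is deterministic as written).
* CCMLs are the stroboscopic conceit, not the underlying continuous
  interleaved dynamics; couplings are fixed (no learning on $M$) and
  antisymmetric only.
* Spectral-entropy phase diagrams depend on block length, DC handling
  and entropy base; all are configurable with documented defaults, and
  only qualitative regime structure is claimed.
* Critical mode analysis stops at AR(1): no higher-order models,
  state-space estimation, artifact rejection, or analysis of real
  recordings.
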