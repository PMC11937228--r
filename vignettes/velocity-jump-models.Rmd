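---
title: "Velocity-jump models under discrete-time noisy observation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-jump models under discrete-time noisy observation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vjump)
```

## The model and its assumptions

`vjump` works with a one-dimensional, `n`-state velocity-jump process. The
hidden state `S(t)` is a continuous-time Markov chain: the holding time in
state `s` is exponential with rate `λ_s > 0` (units 1/time), and on leaving
`s` the next state is drawn from row `s` of the embedded transition matrix
`P` (zero diagonal, unit row sums). While in state `s` the agent moves with
constant velocity `v_s` (length/time), so its position is the
piecewise-linear integral of the velocity along the state path. We assume
the chain is irreducible — the directed graph of positive `p_su` is strongly
connected — so the stationary law `π` (the unique solution of `πQ = 0` with
`Σπ = 1`, where `Q` is the generator with `q_su = λ_s p_su`, `q_ss = −λ_s`)
exists and is unique, and we assume the process is started from it: the
observer has no information about the initial state.

The data-collection model reflects tracking experiments: positions are
recorded every `Δt` time units with independent Gaussian localization error
of standard deviation `σ`. A track of `N` increments is the `N + 1`
positions `y_j = x(jΔt) + ε_j`. Because each increment `Δy_j` differences
two independent errors, `Δy_j | Δx_j ~ N(Δx_j, 2σ²)`, and consecutive noisy
increments share an endpoint error (covariance `−σ²`). The hidden state is
never observed, and the position alone is not Markov — this is what makes
the likelihood intractable exactly and motivates the approximations below.

## The up-to-m-switch approximation hierarchy

Let `W` be the number of switches in one frame interval. The marginal
density of a stationary increment expands over `W`; the expansion has
infinitely many terms with no general closed form, so the order-`m`
approximation treats every interval with more than `m` switches as if it
had exactly `m`:

```
P_m(Δy) = Σ_{w<m} P(Δy | W=w) P(W=w)  +  P(Δy | W=m) P(W≥m).
```

This keeps the total mass exactly 1 (unlike simply truncating the series)
and is accurate when switches are infrequent relative to `Δt`, i.e.
`λ_s Δt` small. The package implements `m = 1` and `m = 2`; beyond that the
number of ordered state sequences per interval grows combinatorially and is
out of scope.

Conditioning each term on the visited states makes every piece exact:

* **No switch** (weight `e^{−λ_s Δt}`): the increment is `v_s Δt` plus
  noise, a Gaussian with variance `2σ²`.
* **One switch `s₁ → s₂`** (weight `P(W=1|s₁,s₂) =
  λ₁(e^{−λ₂Δt} − e^{−λ₁Δt})/(λ₁−λ₂)`): conditional on exactly one switch,
  the switching time has a truncated-exponential density `∝ e^{−(λ₁−λ₂)t₁}`
  on `[0, Δt]`. The increment `Δx = v₁t₁ + v₂(Δt−t₁)` is its monotone image
  (Jacobian `1/|v₁−v₂|`), supported between `v₁Δt` and `v₂Δt`. Convolving
  with the Gaussian noise gives an exponential-times-erf closed form (next
  section). If `v₁ = v₂` the increment is deterministic and the noisy
  density is the shared-velocity Gaussian.
* **Two switches `s₁ → s₂ → s₃`** (weight `P(W≥2|s₁,s₂)`, the
  hypoexponential CDF of `τ₁+τ₂` at `Δt`, independent of `s₃`): conditional
  on exactly two switches, `(t₁, t₂)` has density
  `∝ e^{−(λ₁−λ₃)t₁} e^{−(λ₂−λ₃)t₂}` on the triangle
  `{t₁, t₂ > 0, t₁+t₂ < Δt}`. Sifting the Dirac delta of
  `Δx = v₁t₁ + v₂t₂ + v₃(Δt−t₁−t₂)` over `t₂` leaves a one-dimensional
  integral of an exponential in `t₁` over a domain `A = [E₀(Δx), E₁(Δx)]`.
  Rather than transcribing piecewise-linear endpoint formulas case by case,
  the implementation intersects the three linear constraints
  (`t₁ ∈ [0, Δt]`, `t₂*(t₁) ≥ 0`, `t₂*(t₁) ≤ Δt − t₁`) directly, which
  yields the same piecewise-linear endpoints for every ordering of the three
  velocities and evaluates the antiderivative in closed form. The special
  case `s₃ = s₁` (and any velocity tie) collapses the increment to a
  function of a single time variable, and the corresponding one-dimensional
  marginal (e.g. of `t₂` given `W = 2`) is used instead.

The three weights partition unity for every `(s₁, s₂)`, which is what makes
`∫P_m = 1` automatic; this identity is property-tested rather than imposed.

## Closed forms, quadrature, and numerical choices

* **One-switch noisy density.** The truncated-exponential × Gaussian
  convolution has the closed form
  `C e^{−αΔy + α²s²/2} [Φ((b−m)/s) − Φ((a−m)/s)]` with
  `α = (λ₁−λ₂)/(v₁−v₂)`, `s² = 2σ²`, `m = Δy − αs²`. It is evaluated in log
  space with a tail-stable `log Φ` difference, so far tails underflow to 0
  instead of producing `Inf × 0`. The derivation was verified against
  adaptive quadrature of the defining convolution (the tests assert
  agreement to `1e−8` on 101-point grids, and a quadrature fallback remains
  available via `method = "quadrature"`).
* **Two-switch noisy density.** The exact (pre-noise) two-switch density is
  closed-form; its Gaussian convolution is evaluated by adaptive quadrature
  over the support, split at the interior velocity breakpoint where the
  exact density has kinks, with the branch recorded in the returned
  metadata. A fully symbolic piecewise-erf expansion is possible but adds
  many cases for little accuracy gain; quadrature at `rel.tol 1e−9` is
  well inside the `1e−6` agreement asserted against the defining
  double-integral oracle.
* **Equal-rate and velocity-tie branches.** Rate differences enter
  denominators, so near-equal rates switch to limit forms; wherever
  possible the implementation uses `expm1`-based expressions such as
  `(1 − e^{−x})/x` that are uniformly stable, and the explicit branch
  threshold `|λᵢ−λⱼ|Δt < 1e−8` is used where a genuine two-case formula
  remains. Velocities are considered tied when they differ by less than
  `1e−12 · max(1, |v|_max)`; tied configurations use the exact degenerate
  laws rather than ill-conditioned Jacobians.
* **Stationary distribution.** `π` is the null space of `Qᵀ`, taken from an
  SVD; if the second-smallest singular value is below `1e−8 ‖Q‖` the kernel
  is flagged as degenerate (non-unique stationary law). Round-off negatives
  below `1e−12` are clipped before renormalization.
* **Strong connectivity** is checked on the boolean graph of `p_su > 0`
  with an exact zero threshold: configuration values are user-specified
  numbers, not computed quantities.

## The track likelihood and its filter

The joint density of a track's increments factorizes into one-step
conditionals. Conditioning on the hidden state at the start of each interval
makes an interval independent of the past, so a forward filter over that
state computes the approximation recursively: with the pairwise kernel

```
k(Δy, s, u) = e^{−λ_sΔt} f_N(v_sΔt, 2σ²)(Δy)            if u = s
            = p_su (1 − e^{−λ_sΔt}) f̃_{s,u}(Δy)          if u ≠ s
```

(the up-to-one-switch approximation of `P(Δy_j, S^{j+1}=u | S^j=s)`), the
filter starts at `b₁ = π`, forms `m[s,u] = k(Δy_j, s, u) b_j[s]`, records
the evidence `e_j = Σ m`, and renormalizes `b_{j+1} = colSums(m)/e_j`. The
log evidence accumulates in log space, so long tracks cannot underflow; the
recursion itself is exact algebra given the kernel, which the tests confirm
against exhaustive state-sequence enumeration to `1e−12` relative error.
The state at the end of the final interval is marginalized (summed over),
consistent with the factorized form of the joint density. The order of the
kernel is fixed at 1 — simpler and much cheaper than order 2, and the
kernel interface is the single place a higher-order extension would plug
into.

Two deliberate approximations are documented as known biases:

* **Noise-increment correlation is neglected.** Each emission uses variance
  `2σ²` and the `−σ²` covariance between `Δε_j` and `Δε_{j+1}` is dropped;
  empirical joint densities of two subsequent increments therefore show
  slightly oval peaks where the approximation's are round. This is what
  makes the filter analytic.
* **More-than-one-switch intervals** are folded into the one-switch branch,
  as in `P₁`.

The naive baseline `Σ_j log P₁(Δy_j)` discards the hidden-state correlation
entirely; the paired comparison between filter and baseline on simulated
low-rate tracks (a property test, and a reported acceptance quantity) shows
the filter's mean per-increment log evidence is higher.

## Simulation and what the synthetic data does (not) emulate

`sample_state_path()` is an exact Gillespie simulation that overshoots the
requested duration by one holding time and truncates. `observe_track()`
computes frame positions by exact piecewise-linear integration — there is no
time-discretization error anywhere in the simulator — and counts switches
per half-open interval `(t_{j−1}, t_j]` (a jump exactly at a frame time,
a measure-zero event, deterministically belongs to the earlier interval).
`draw_stationary_increments()` simulates many independent single intervals
started from `π` in a vectorized sweep; marginally this is the same law as
consecutive increments of a long stationary track, and a two-sample
Kolmogorov–Smirnov property test checks that equivalence. Marginal
comparisons default to whichever mode the caller asks for; joint
(two-increment) comparisons always use consecutive increments of long
tracks, since only those carry the cross-interval correlation.

The generator emulates exactly the assumptions of the model: exponential
holding times, instantaneous switches, constant within-state velocities,
i.i.d. Gaussian localization noise, no missing frames. Real tracking data
violate several of these — localization error varies with signal intensity,
motion blur correlates noise with speed, detectors drop frames, and motion
is rarely perfectly one-dimensional — so passing tests demonstrate
correctness of the mathematics under the model, not robustness to those
artifacts.

Reproducibility contract: every randomized function takes an explicit
`seed`, restores the caller's RNG state afterwards, and the CLI records the
seed, a config checksum and the package version in a JSON sidecar next to
each output file.

## Example networks and default parameters

`example_network()` ships four topologies used throughout the tests: a
two-state forward/backward switcher; a three-state network adding a
long-permanence stationary state (SL); a four-state network adding a
short-permanence stationary state (SS), with forward and backward not
directly connected and SL always handing over to SS (total pause time
hypoexponential); and a six-state cyclic network whose pause states PF/PB
mostly return to the previous direction of travel.

The numeric defaults are this package's placeholder choices, stamped as such
in the emitted provenance field, picked once to represent a realistic
tracking scenario rather than any particular experiment: velocities `±1`
(moving) and `0` (stationary) length units per time unit, `Δt = 1`,
`σ = 0.05` (peaks separated by ≈ 14 noise s.d., as in good-quality tracking
data), moving-state rates `0.2` (so `λΔt = 0.2`, the infrequent-switching
regime the approximations target), `SL` rate `0.05`, `SS` rate `1`, pause
rates `2`. The `rate_multiplier` override scales all rates by a common
factor — equivalent to lengthening `Δt` — and is the device used to probe
the frequent-switching regime (×5, ×10). A convenient consequence of equal
two-state rates is that the two-state switch count is exactly Poisson
(alternation makes the switch process Poisson when rates are equal), so at
×10 the tail `P(W > 2) = 1 − 5e^{−2} ≈ 0.3233` is a closed-form check on the
whole simulation pipeline.

## Problem sizes and tolerances used in the checks

The test-suite and acceptance-script problem sizes are the package's chosen
design points: `1e5` Monte-Carlo intervals for switch-count laws and
rejection-oracle histograms (per-bin binomial-s.e. comparisons, with an
explicit multiple-comparison allowance across ~40 bins), `5e5`–`1e6`
increments for empirical-density error norms, 100 random models for
algebraic property tests, 20 random instances for the enumeration-oracle
check, and `1e4` increments (10 tracks of 1000) for the
maximum-likelihood recovery experiment at `λΔt = 0.1`, which recovers
velocities to a few tenths of a percent and rates to a few percent at the
fixed seeds used. Optimization uses Nelder–Mead on transformed parameters
(raw `v`, `log λ`, `log σ`, multinomial-logit free transition entries) with
multiple perturbed restarts, because state relabelings make the surface
multimodal; reported states are canonically ordered by velocity.

## Known limitations

* Orders `m ≥ 3` and the mass-dropping truncated variant are not
  implemented (the former is combinatorially explosive, the latter less
  accurate than the mass-preserving form).
* The track filter is order-1 only; at `λΔt ≳ 1` both the marginal and the
  joint approximations degrade, which the acceptance comparisons quantify.
* Neglected noise correlation biases the joint density near its peaks.
* One spatial dimension, Gaussian noise, exponential (Markov) holding
  times, fixed per-state velocities; none of the extensions (2-D/3-D,
  angular reorientation, diffusive states, velocity distributions,
  non-Markov waiting times) are in scope.
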