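---
title: "Separating and linking preparatory and movement subspaces in motor cortex populations"
author: "orthospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating and linking preparatory and movement subspaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthospace)
```

## The scientific question

During a delayed reach, a single motor-cortex population performs two
different computations a few hundred milliseconds apart: it first prepares the
upcoming movement and then drives its execution. At the single-neuron level
the transition looks chaotic — a neuron's tuning for reach direction during
preparation says little about its tuning during movement. At the population
level three structures could underlie this complexity:

* **overlapping** — both computations occupy the same neural subspace, so
  pairwise correlations between neurons are preserved across epochs;
* **independent** — the computations occupy orthogonal subspaces and the
  condition-wise organization of activity in one epoch is unrelated to the
  other;
* **orthogonal-but-linked** — the subspaces are orthogonal, yet the state the
  population reaches during preparation lawfully determines the state it will
  occupy during movement.

`orthospace` implements the population-level statistics that discriminate
these structures, together with a latent dynamical generator model that
realizes each one, so every statistic can be exercised and calibrated on data
with known ground truth.

## The analysis chain

### Preprocessing

Trial-averaged firing rates (neurons × conditions × time, 10 ms sampling) are

1. **soft-normalized**: each neuron is divided by its firing-rate range plus
   5 spikes/s, so strong neurons have roughly unit range without blowing up
   weak ones; and
2. **mean-centered**: at every timepoint the mean across conditions is
   subtracted per neuron, leaving the condition-dependent (tuned) part of the
   response.

Two fixed 300 ms analysis epochs are used throughout: a *preparatory* epoch
beginning 150 ms after target onset and a *movement* epoch beginning 50 ms
before movement onset. Each epoch is unfolded into an `N × (C·T)` matrix
(condition-major, time-minor column order, fixed so every downstream result is
bit-reproducible) whose row covariance (divisor `C·T − 1`; all reported
statistics are ratios in which the divisor cancels) feeds the subspace
analyses.

### Correlation structure and the epoch-preference index

`correlation_structure()` computes the Pearson correlation between all neuron
pairs across the epoch columns, separately per epoch, and summarizes their
across-epoch similarity by the squared correlation of the paired
upper-triangle entries. Confidence intervals come from a bootstrap over
*neurons* (pairs sharing a neuron are dependent, so resampling pairs would be
anticonservative); 1,000 resamples by default, and the reported spread is the
bootstrap standard deviation with the full distribution retained.

The epoch-preference index asks whether the apparent reorganization could be
explained by disjoint populations of preparation-only and movement-only
neurons. Tuning strength per epoch is the maximum over epoch timepoints of
the cross-condition firing-rate range, divided by the neuron's mean range over
all times ("maximum range in the epoch" is read as the max over per-time
ranges rather than the range of the flattened epoch; the two are close, and
one reading is fixed for determinism). After normalizing each epoch's
strengths by their mean across neurons — so the globally stronger movement
activity does not shift the scale — the index is the bounded contrast

$$\mathrm{index}_i = \frac{\hat S_{\mathrm{prep}}(i) - \hat S_{\mathrm{move}}(i)}
                          {\hat S_{\mathrm{prep}}(i) + \hat S_{\mathrm{move}}(i)},$$

which is +1 for preparation-only neurons, −1 for movement-only neurons, and 0
for a neuron with the population-average ratio. This contrast form is the
unique standard form satisfying those boundary properties; it was adopted as
the package's definition. Bimodality of the index distribution is tested with
Hartigan's dip statistic (below).

### The alignment index and its random-subspace null

With `C_prep` the preparatory-epoch covariance and `D_move` the top-`d`
principal components of the movement epoch, the alignment index is

$$A \;=\; \frac{\operatorname{tr}\!\left(D_{\mathrm{move}}^{\top} C_{\mathrm{prep}} D_{\mathrm{move}}\right)}
               {\sum_{i=1}^{d} \sigma_i\!\left(C_{\mathrm{prep}}\right)},$$

the preparatory variance captured by the movement subspace, normalized by the
most that *any* `d`-dimensional subspace could capture. `A = 0` means
orthogonal subspaces; `A = 1` means the movement PCs capture as much
preparatory variance as the preparatory PCs themselves.

A small index is only meaningful relative to chance: in a high-dimensional
space, two random subspaces are nearly orthogonal anyway. The null model
draws random subspaces *weighted by the data*: `d` vectors
`v_k = C_full^{1/2} w_k` with standard normal `w_k` (where `C_full` is the
covariance of responses at all task times), orthonormalized by QR. These
draws concentrate on directions the population actually visits, which makes
the null far more conservative than uniformly random directions. The
observed index is located in the Monte Carlo null (10,000 samples by
default), with a one-tailed p-value in the misalignment direction (fraction
of null indices at or below the observed one). The denominator of the index
is always the data denominator — the quantity the ratio is defined against —
rather than being recomputed per draw.

For cortical-scale recordings `d = 10` is the conventional choice; for the
four-latent generator model the package uses `d = 2`, since ten PCs would
exhaust the model's rank and trivialize the index. `d` is always explicit in
calls and echoed into outputs.

### Simultaneous orthogonal subspace identification

Rather than greedily orthogonalizing one epoch's PCs against the other's —
which privileges whichever epoch is fitted first — `identify_subspaces()`
maximizes

$$f(Q_p, Q_m) = \frac{1}{2}\left[
  \frac{\operatorname{tr}(Q_p^{\top} C_{\mathrm{prep}} Q_p)}{\sum_{i \le d_p} \sigma_i(C_{\mathrm{prep}})} +
  \frac{\operatorname{tr}(Q_m^{\top} C_{\mathrm{move}} Q_m)}{\sum_{i \le d_m} \sigma_i(C_{\mathrm{move}})}
  \right]$$

over *jointly orthonormal* `[Q_p, Q_m]`. The normalization by the top
singular values makes the two terms commensurate even though movement
activity is stronger and higher-dimensional than preparatory activity.

The optimizer alternates block eigen-updates: with one block held fixed, the
other block's exact optimum is the top eigenvectors of its covariance
compressed into the fixed block's orthogonal complement. Each half-step can
only increase the objective, so the iteration is monotone; it stops when the
relative change falls below 1e-10 (500 sweep cap), and the best of 20
restarts (one seeded from the movement PCs, the rest random orthonormal
frames) is returned. Ties resolve to the highest objective. A manifold
-gradient method would find the same optima; the alternating scheme was
chosen because it is monotone, dependency-free and exact at each half-step.
Two identities pin down correctness: with disjoint epoch eigen-supports the
optimum is exactly 1, and with `C_prep = C_move = C` and equal block sizes
`d` the optimum equals \(\sum_{i \le 2d} \sigma_i / (2 \sum_{i \le d}
\sigma_i)\), the even split of the top-`2d` eigenspace. Both are asserted in
the test suite against brute-force searches.

Within each identified subspace the axes are ordered by captured variance and
their signs fixed so the largest-magnitude loading is positive; all reported
statistics (objective, captured variance, decoder fits) are invariant to
within-block rotations, so this is pure output hygiene. Defaults are
`d_prep = 2, d_move = 4` for cortical-scale data (capturing roughly 70% of
each epoch's variance) and 2/2 for the generator model. Display-oriented
post-rotations of the movement plane (for example, rotating it to exhibit
oscillatory structure) change no reported statistic and are not performed.

### The preparatory-to-movement link

The population state in the preparatory subspace at the end of preparation
(450 ms after target onset) is regressed, without an intercept (states are
cross-condition centered by construction; this is asserted at fit time),
onto the state in the movement subspace at the middle of movement (100 ms
after movement onset):
one column per condition, least squares, minimum-norm when rank-deficient.
Fit quality is a single pooled
\(R^2 = 1 - \lVert X_m - W X_p \rVert_F^2 / \lVert X_m \rVert_F^2\) (pooled
over all matrix entries rather than averaged per dimension, giving one scalar
per fit). Generalization is measured by leave-one-out cross-validation over
conditions, and significance by a null that permutes each preparatory
dimension independently across conditions (1,000 shuffles; the tail count
uses ≥, the conservative convention). With 8 conditions, 2 preparatory
dimensions and 4 movement dimensions, each output dimension is fit with 8
observations against 2 coefficients and leave-one-out retains 7 — feasibility
is asserted as a precondition.

## The generator model

The synthetic module implements a two-stage latent linear dynamical system —
the simplest mechanism that produces orthogonal-but-linked population
structure:

$$\frac{d}{dt}\begin{bmatrix} x_{\mathrm{prep}} \\ x_{\mathrm{move}} \end{bmatrix}
 = \begin{bmatrix} J_{\mathrm{prep}} & 0 \\ g_t\, J_{\mathrm{FF}} & J_{\mathrm{move}} \end{bmatrix}
   \begin{bmatrix} x_{\mathrm{prep}} \\ x_{\mathrm{move}} \end{bmatrix}
 + (1 - g_t) \begin{bmatrix} B\,u(c,t) \\ 0 \end{bmatrix},
 \qquad r = C\,x .$$

The preparatory plane is a leaky integrator driven by the condition's target
position, so each condition settles to its own fixed point
\(-J_{\mathrm{prep}}^{-1} B\, u^{*}(c)\). The gate `g_t` is 0 before the go
cue and rises to 1 just before movement onset (a step smoothed with a 20 ms
s.d. Gaussian); it simultaneously switches the input off and feeds the
preparatory state into an oscillatory movement plane, which turns each
initial condition into a rotation of condition-specific phase and amplitude.
Neurons read the four latents out through a loading matrix with i.i.d.
`N(0, 50²)` entries.

Default parameter choices, with reasoning:

| parameter | default | why |
|---|---|---|
| `d_prep`, `d_move` | 2, 2 | planar integrator and oscillator, the minimal linked pair |
| `J_prep` | −I/100 ms | 100 ms leak: settles well within the 500 ms delay |
| `J_move` | 2π·2.5 Hz rotation | strong rotational structure within a 300 ms movement epoch |
| `J_FF` | I/50 ms | transfers the preparatory state within the ~100 ms gate window |
| timeline | target 0, go 500, move 650, end 950 ms | fixed 500 ms delay, 150 ms reaction time |
| gate | center 600 ms, s.d. 20 ms | exactly 0 before go; ≈1 just before movement onset |
| input ramp | center 60 ms, s.d. 20 ms | smooth rise from 0 right after target onset |
| loading | `N(0, 50²)`, N = 127 | population of order 10² with dense mixed selectivity |
| integration | forward Euler, 1 ms, decimated to 10 ms | linear, stable at the default leaks |

The exact dynamics matrices are reconstructions consistent with the model's
verbal description (leaky integrator, oscillatory pattern generator, gated
feed-forward transfer); every matrix is config-overridable, and all of these
values were fixed once, before the test suite existed. The seed is mandatory:
it determines the loading matrix and all downstream spike emission.

`make_scenario()` derives the three benchmark structures from one simulation:
`orthogonal_linked` orthogonalizes the movement loading columns against the
preparatory plane (the projection of i.i.d. Gaussian columns onto the
complement, so the planted planes are *exactly* orthogonal and recovery can
be tested at sub-degree tolerances); `overlapping` reads the movement latents
out through the same neuron-space plane as the preparatory ones, with a fixed
condition reordering; `independent` additionally permutes the
condition-to-state assignment of the movement latents, severing the lawful
link while preserving all marginal statistics. `simulate_population()` keeps
the raw i.i.d. loading — that unmodified model is what the headline alignment
number is computed from.

What the generator emulates — and what it does not. It reproduces the
population-level geometry (orthogonal planes, gated transfer, lawful
condition ordering), realistic mixed single-neuron selectivity and the right
epoch structure. It does *not* emulate trial-to-trial variability of real
recordings (analyses run on trial averages; Poisson spiking and kernel
re-estimation are exercised separately), variable delays with dual-alignment
splicing, nonlinearities such as firing-rate rectification in the analyzed
signal, or realistic cross-neuron noise correlations. Passing tests on the
generator therefore validate the estimators' geometry and calibration, not
their robustness to every property of cortical data.

One subtlety worth knowing: soft-normalization is a per-neuron rescaling,
i.e., a diagonal linear map of neuron space, and diagonal maps do not
preserve orthogonality. The planted planes are exactly orthogonal in the raw
space, and after soft-normalization they remain *nearly* orthogonal (the
rescaled planes sit a few degrees off). Planted-recovery tests therefore run
on mean-centered but unnormalized covariances, where recovery is exact to
well under a degree; pipeline-level tests on fully preprocessed data assert
the statistical conclusions instead of sub-degree geometry.

## The dip statistic

No dip-test implementation is available in the package's dependency
environment, so Hartigan's statistic is computed from first principles: the
dip of an empirical cdf is the smallest `δ` such that some unimodal cdf
(convex below its mode, concave above, an atom allowed at the mode) stays
within a `δ`-tube around it. For a candidate `δ` the tube induces per-knot
value bands, and a convex branch exists inside bands exactly when the
greatest convex minorant of the upper bounds stays above the lower bounds
(dually for the concave branch via the least concave majorant). Branch
feasibility is monotone in the mode position, so each candidate `δ` is
checked by binary search over modes, and the dip itself by bisection on `δ`
(both mode-at-knot and mode-within-gap placements are checked; the branch
feasibility conditions determine the statistic). The implementation is in
C++ for speed and is validated against hand-derived exact values: any
two-point sample has dip 1/4 (the maximal value), an equally spaced sample
has dip `1/(2n)`, and two well-separated clusters with lighter-cluster mass
`q` have dip `q/2`. P-values come from a Monte Carlo null of uniform samples
of the same size — the classical least-favourable unimodal reference — with
10,000 draws by default; because the observed statistic and its null are
computed by the same procedure, the test is exactly calibrated by
construction.

## Numerical choices and degenerate inputs

* Covariances are symmetrized eigen-problems; negative eigenvalues from
  roundoff are clipped at zero, and requested dimensionalities are checked
  against the effective rank (relative tolerance 1e-12).
* Orthonormality of bases is asserted with Gram tolerance 1e-8 before any
  projection or variance computation.
* Neurons with exactly zero variance in an epoch have undefined correlations;
  they are excluded from correlation analyses and reported, but retained for
  the epoch-preference analysis, where excluding them would bias the index
  toward zero.
* Neurons silent in both epochs have an undefined preference index and are
  returned as `NA`.
* Edge effects in spike-train smoothing are handled by renormalizing the
  truncated kernel to unit mass inside the observation window, so integrated
  rate equals spike count and rates do not droop at the window edges.
* Zero-spread preparatory states make the shuffle null degenerate (shuffles
  change nothing); this is detected and flagged rather than silently
  reported.
* Identification restarts are seeded; with equal objectives the first-found
  optimum (lowest restart index) is kept.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the generator's native scale (127
neurons, 8 conditions, 96 timepoints). Null distributions use 10,000 draws
where a tail quantile is asserted (alignment-null calibration, dip test) and
200–1,000 draws where only coarse behaviour is checked. The scenario
-discrimination property runs 100 replicates of all three scenarios at
reduced resampling counts (300-sample nulls, 300 shuffles, 3 restarts),
sizes chosen to keep each replicate under a second while leaving the
classification margins wide.

## Limitations

* The analyses operate on trial-averaged rates; single-trial state estimation
  is out of scope.
* Epoch windows are fixed offsets from events; datasets with variable delays
  must be aligned (spliced) upstream.
* The alignment null conditions on the full-task covariance of the same
  dataset; comparing indices across datasets with very different
  dimensionalities requires care.
* The linear link is evaluated at one preparatory and one movement timepoint;
  time-resolved sweeps are deliberately not implemented.
* I/O is long-format CSV plus a JSON sidecar; binary containers are not
  supported.
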