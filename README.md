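# orthospace

Population-level analysis of how one motor-cortex population performs two
different computations — preparing a reach and executing it — within a few
hundred milliseconds. At the single-neuron level the transition looks
arbitrary: a neuron's direction tuning during preparation says little about
its tuning during movement. `orthospace` provides the statistics that resolve
what happens at the population level: whether the two computations share a
neural subspace (*overlapping*), occupy unrelated subspaces (*independent*),
or occupy orthogonal subspaces whose states are nevertheless lawfully related
(*orthogonal-but-linked*).

It is aimed at systems neuroscientists working with trial-averaged firing
rates (neurons × conditions × time) from delayed-movement paradigms, and at
modelers who need a calibrated reference implementation of these statistics.

## What it computes

Given soft-normalized (`rate / (range + 5)`), cross-condition mean-centered
rates and two 300 ms epochs (preparatory: target onset + 150 ms; movement:
movement onset − 50 ms):

* **Correlation-structure similarity** — Pearson correlation matrices between
  neurons per epoch, and the squared correlation of their paired entries
  across epochs, with a bootstrap-over-neurons confidence interval.
* **Epoch-preference index** — a bounded contrast of normalized tuning
  strength, +1 for preparation-only neurons, −1 for movement-only neurons,
  with Hartigan's dip test for bimodality (the dip statistic is computed
  exactly from its definition; see the vignette).
* **Alignment index** — with `D_move` the top-`d` movement-epoch principal
  components and `C_prep` the preparatory-epoch covariance,

  `A = trace(D_move' C_prep D_move) / sum_{i<=d} sigma_i(C_prep)`,

  i.e. the preparatory variance captured by the movement subspace relative to
  the most any `d`-dimensional subspace could capture. `A` is compared with a
  Monte Carlo null of random subspaces drawn according to the full-task
  covariance (`v_k = C^(1/2) w_k`, QR-orthonormalized; 10,000 samples).
* **Orthogonal subspace identification** — jointly orthonormal bases
  `Q_prep, Q_move` maximizing normalized captured variance
  `½ [tr(Q_p'C_p Q_p)/Σσ_i(C_p) + tr(Q_m'C_m Q_m)/Σσ_i(C_m)]`
  by monotone alternating eigen-updates with restarts, plus per-epoch
  variance tables with random-subspace significance.
* **Preparatory→movement link** — a no-intercept least-squares map from the
  late-preparatory state (target + 450 ms) to the mid-movement state
  (movement + 100 ms), with pooled R², leave-one-out cross-validation over
  conditions, and a condition-shuffle null.
* **A gated feed-forward generator model** — a leaky-integrator preparatory
  plane driven by radial target inputs, feeding an oscillatory movement plane
  through a go-signal gate, read out by 127 neurons with Gaussian loadings.
  It realizes all three population structures with known ground truth
  (`make_scenario()`) and supports Poisson spike emission and kernel
  re-estimation end to end.

## Worked example

```r
library(orthospace)

## simulate the generator model and run the preprocessing + PCA chain
gp <- generator_params(seed = 1)
pp <- mean_center(soft_normalize(simulate_population(gp)))
Cp <- extract_epoch(pp, prep_epoch())$covariance
Cm <- extract_epoch(pp, move_epoch())$covariance
alignment_index(Cp, epoch_pcs(Cm, 2)$vectors, 2)
#> [1] 0.01009719
```

The movement principal components capture ~1% of the preparatory variance
that the preparatory PCs would capture: the two computations occupy
near-orthogonal subspaces. The full pipeline adds the nulls, the subspace
identification and the link:

```r
report <- run_pipeline(pipeline_config(scenario = "orthogonal_linked", seed = 42))
report
#> <pipeline_report>
#>   scenario: orthogonal_linked -> classified: orthogonal_linked
#>   corr R^2 = 0.033, dip p = 0.365
#>   alignment index = 0.021 (null median 0.526, percentile 0.00%)
#>   identification objective = 0.9920
#>   link R^2 = 1.000 (LOOCV 1.000, shuffle p = 0)
```

Reading the report: pairwise correlations reorganize almost completely across
epochs (R² = 0.03) although the neurons form one population (unimodal
epoch-preference index, dip p = 0.37); the observed alignment index (0.021)
sits below the entire covariance-matched random null (median 0.53), so the
subspaces are *more* orthogonal than chance; the identification objective near
1 confirms that orthogonal bases sacrifice almost no variance; and yet the
preparatory state predicts the movement state essentially perfectly
(LOOCV R² = 1.00, shuffle p < 1/500): orthogonal-but-linked structure.

Recorded datasets enter the same pipeline as long-format CSV
(`neuron, condition, time_ms, rate` plus a JSON sidecar with event times)
via `pipeline_config(scenario = "data", data_path = ...)`, or directly
through `read_dataset()`. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

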