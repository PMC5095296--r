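#' Reach-target input vectors
#'
#' Returns the per-condition input vectors of the generator model: `C` points
#' equally spaced on a circle of the given radius, mimicking radially arranged
#' reach targets around a central touch point.
#'
#' @param C number of conditions (reach directions).
#' @param radius_mm target distance from the touch point (mm).
#' @return a `2 x C` matrix; column `c` is the target position of condition `c`.
#' @export
make_targets <- function(C = 8, radius_mm = 130) {
  if (C < 1) stop("`C` must be at least 1")
  ang <- 2 * pi * (seq_len(C) - 1) / C
  rbind(radius_mm * cos(ang), radius_mm * sin(ang))
}

#' Parameters of the gated feed-forward generator model
#'
#' A two-stage latent linear dynamical system: a leaky-integrator preparatory
#' plane receives the target input and settles to a condition-specific fixed
#' point; around movement onset a go-signal gate `g_t` switches the input off
#' and feeds the preparatory state forward into an oscillatory movement plane,
#' which sets the amplitude and phase of movement-epoch rotations. Simulated
#' neurons read the four latents out through a random loading matrix.
#'
#' Dynamics default to a leak time-constant of 100 ms, a 2.5 Hz rotation
#' (strong rotational structure within a 300 ms movement epoch), a 50 ms
#' feed-forward time-constant, and i.i.d. `N(0, 50^2)` loading entries. All
#' matrices are overridable.
#'
#' @param n_neurons number of simulated neurons.
#' @param d_prep,d_move latent dimensionalities (defaults 2 and 2).
#' @param J_prep,J_move,J_FF dynamics matrices in 1/ms: preparatory leak,
#'   movement rotation, feed-forward transfer.
#' @param B input loading matrix (`d_prep x 2`), restricting input to the
#'   preparatory latents.
#' @param loading_sd s.d. of the Gaussian neuron loading entries.
#' @param loading optional explicit `n_neurons x (d_prep + d_move)` loading
#'   matrix; drawn from the seed when omitted.
#' @param gate_center_ms,gate_sd_ms center and s.d. of the Gaussian-smoothed
#'   step gate `g_t`; the gate is exactly 0 before the go cue and reaches 1
#'   just before movement onset.
#' @param input_onset_ms,input_sd_ms center and s.d. of the smoothed input
#'   onset ramp after target onset.
#' @param targets per-condition input vectors (`2 x C`), see [make_targets()].
#' @param dt_ms forward-Euler integration step (must be <= 1 ms).
#' @param seed integer seed, mandatory: fixes the loading matrix (and spike
#'   emission downstream).
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_neurons = 127, d_prep = 2, d_move = 2,
                             J_prep = -diag(d_prep) / 100,
                             J_move = (2 * pi * 2.5 / 1000) *
                               matrix(c(0, -1, 1, 0), 2, 2),
                             J_FF = diag(1, nrow = d_move, ncol = d_prep) / 50,
                             B = diag(d_prep),
                             loading_sd = 50, loading = NULL,
                             gate_center_ms = 600, gate_sd_ms = 20,
                             input_onset_ms = 60, input_sd_ms = 20,
                             targets = make_targets(),
                             dt_ms = 1, seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility")
  if (dt_ms > 1) stop("`dt_ms` must be <= 1 ms")
  if (any(Re(eigen(J_prep, only.values = TRUE)$values) >= 0))
    stop("J_prep must be a leak: eigenvalues with negative real part")
  if (is.null(loading)) {
    loading <- withr::with_seed(seed,
      matrix(rnorm(n_neurons * (d_prep + d_move), 0, loading_sd),
             n_neurons, d_prep + d_move))
  }
  if (!all(dim(loading) == c(n_neurons, d_prep + d_move)))
    stop("`loading` must be n_neurons x (d_prep + d_move)")
  structure(list(n_neurons = n_neurons, d_prep = d_prep, d_move = d_move,
                 J_prep = J_prep, J_move = J_move, J_FF = J_FF, B = B,
                 loading_sd = loading_sd, loading = loading,
                 gate_center_ms = gate_center_ms, gate_sd_ms = gate_sd_ms,
                 input_onset_ms = input_onset_ms, input_sd_ms = input_sd_ms,
                 targets = targets, dt_ms = dt_ms, seed = seed),
            class = "generator_params")
}

#' Default simulation timeline
#'
#' Target onset at 0 ms, go cue at 500 ms (a fixed 500 ms delay), movement
#' onset at 650 ms (a 150 ms reaction time), simulation end at 950 ms, so the
#' default 300 ms movement epoch (starting 50 ms before movement onset) fits
#' inside the simulated window.
#'
#' @return named list with `target_onset_ms`, `go_cue_ms`, `move_onset_ms`,
#'   `end_ms`.
#' @export
default_timeline <- function() {
  list(target_onset_ms = 0, go_cue_ms = 500, move_onset_ms = 650, end_ms = 950)
}

gate_signal <- function(t, timeline, params) {
  ifelse(t < timeline$go_cue_ms, 0,
         pnorm(t, params$gate_center_ms, params$gate_sd_ms))
}

#' Integrate the generator model's latent dynamics
#'
#' Forward-Euler integration (default 1 ms step) of the gated two-block linear
#' system: the preparatory block evolves as
#' `dx_prep/dt = J_prep x_prep + (1 - g_t) B u(c, t)` and the movement block
#' as `dx_move/dt = g_t J_FF x_prep + J_move x_move`,
#' where the input `u` ramps smoothly from 0 to the condition's target vector
#' after target onset, and the gate `g_t` (0 before the go cue) switches the
#' input off and the feed-forward transfer on around movement onset. The
#' trajectories are decimated to the 10 ms analysis grid.
#'
#' @param params a [generator_params()].
#' @param timeline see [default_timeline()].
#' @return an object of class `latent_trajectories`: `x` (array
#'   `[(d_prep+d_move) x C x T]`), `time_ms`, `partition` (index sets of the
#'   preparatory and movement latents), `events`.
#' @export
simulate_latents <- function(params, timeline = default_timeline()) {
  stopifnot(inherits(params, "generator_params"))
  dt <- params$dt_ms
  tt <- seq(timeline$target_onset_ms, timeline$end_ms, by = dt)
  C <- ncol(params$targets)
  dp <- params$d_prep; dm <- params$d_move
  gate <- gate_signal(tt, timeline, params)
  ramp <- pnorm(tt, timeline$target_onset_ms + params$input_onset_ms,
                params$input_sd_ms)
  x <- matrix(0, dp + dm, C)
  ip <- seq_len(dp); im <- dp + seq_len(dm)
  keep <- which((tt - tt[1]) %% 10 < dt / 2)
  out <- array(0, c(dp + dm, C, length(keep)))
  k_out <- 1L
  for (k in seq_along(tt)) {
    if (k_out <= length(keep) && k == keep[k_out]) {
      out[, , k_out] <- x
      k_out <- k_out + 1L
    }
    g <- gate[k]
    u <- (1 - g) * ramp[k] * (params$B %*% params$targets)
    dx <- rbind(params$J_prep %*% x[ip, , drop = FALSE] + u,
                g * (params$J_FF %*% x[ip, , drop = FALSE]) +
                  params$J_move %*% x[im, , drop = FALSE])
    x <- x + dt * dx
    if (any(abs(x) > 1e9))
      stop("latent integration unstable (|x| > 1e9); reduce `dt_ms`")
  }
  structure(list(x = out, time_ms = tt[keep],
                 partition = list(prep = ip, move = im),
                 events = timeline[c("target_onset_ms", "go_cue_ms",
                                     "move_onset_ms")]),
            class = "latent_trajectories")
}

#' Read latent trajectories out into simulated firing rates
#'
#' `r(t, c) = loading %*% x(t, c)`. The raw readout is linear and signed (it
#' enters the analysis pipeline exactly like recorded rates do, via
#' soft-normalization and mean-centering); an optional positive baseline and
#' rectification are applied only when spike emission is intended.
#'
#' @param latents a [simulate_latents()] result.
#' @param params the matching [generator_params()].
#' @param baseline optional baseline in spikes/s added to every neuron.
#' @param rectify clip negative rates at zero (required before
#'   [emit_spikes()]).
#' @return a [population_response()].
#' @export
emit_rates <- function(latents, params, baseline = NULL, rectify = FALSE) {
  stopifnot(inherits(latents, "latent_trajectories"))
  L <- params$loading
  if (ncol(L) != dim(latents$x)[1])
    stop("loading matrix has ", ncol(L), " columns but there are ",
         dim(latents$x)[1], " latents")
  d <- dim(latents$x)
  rates <- array(0, c(nrow(L), d[2], d[3]))
  for (k in seq_len(d[3])) rates[, , k] <- L %*% latents$x[, , k]
  if (!is.null(baseline)) rates <- rates + baseline
  if (rectify) rates <- pmax(rates, 0)
  population_response(rates, latents$time_ms, latents$events,
                      allow_negative = !rectify)
}

#' Simulate a full synthetic population response
#'
#' Convenience wrapper: integrate the latent dynamics and read them out
#' through the loading matrix. This is the generator model as analyzed
#' (unmodified i.i.d. Gaussian loading).
#'
#' @inheritParams simulate_latents
#' @inheritParams emit_rates
#' @return a [population_response()].
#' @export
simulate_population <- function(params, timeline = default_timeline(),
                                baseline = NULL, rectify = FALSE) {
  emit_rates(simulate_latents(params, timeline), params,
             baseline = baseline, rectify = rectify)
}

#' Emit Poisson spike trains from a rate response
#'
#' Inhomogeneous Poisson emission in 1 ms bins (rates linearly interpolated
#' from the 10 ms grid); expected count per bin is `rate * 0.001`. Spike times
#' are placed uniformly within their bin.
#'
#' @param resp a [population_response()] with non-negative rates in spikes/s.
#' @param n_trials trials per (neuron, condition).
#' @param seed integer seed.
#' @return a [spike_trains()] object.
#' @export
emit_spikes <- function(resp, n_trials, seed) {
  stopifnot(inherits(resp, "population_response"))
  if (any(resp$rates < 0)) stop("rates must be non-negative (rectify first)")
  d <- dim(resp$rates)
  bins <- seq(min(resp$time_ms), max(resp$time_ms), by = 1)
  withr::with_seed(seed, {
    trials <- lapply(seq_len(d[1]), function(n) {
      lapply(seq_len(d[2]), function(cc) {
        lam <- approx(resp$time_ms, resp$rates[n, cc, ], xout = bins)$y * 0.001
        lapply(seq_len(n_trials), function(tr) {
          counts <- rpois(length(lam), lam)
          idx <- rep(seq_along(bins), counts)
          if (length(idx) == 0) numeric(0)
          else sort(bins[idx] + runif(length(idx), 0, 1))
        })
      })
    })
    spike_trains(trials, c(min(resp$time_ms), max(resp$time_ms) + 1))
  })
}

#' Construct the three benchmark population-structure scenarios
#'
#' Builds synthetic populations embodying the three hypothetical relations
#' between two successive computations:
#' * `orthogonal_linked` — the generator model, with the movement loading
#'   columns orthogonalized against the preparatory plane so the two planted
#'   neuron-space planes are exactly orthogonal; the feed-forward transfer
#'   keeps the condition ordering lawful across epochs.
#' * `overlapping` — movement latents are read out through the *same* neuron
#'   -space plane as the preparatory latents (shared loading columns), with a
#'   fixed condition reordering; the occupied subspace is identical across
#'   epochs.
#' * `independent` — orthogonal planes as in `orthogonal_linked`, but the
#'   condition-to-state assignment of the movement latents is randomly
#'   permuted, severing the lawful prep-to-move relation.
#'
#' @param kind one of `"orthogonal_linked"`, `"overlapping"`, `"independent"`.
#' @param params a [generator_params()].
#' @param timeline see [default_timeline()].
#' @return list with `response` (a [population_response()]), `Q_prep_true` and
#'   `Q_move_true` (orthonormal bases of the planted neuron-space planes;
#'   identical for `overlapping`), `latents`, `kind`, and the condition
#'   `permutation` used (if any).
#' @export
make_scenario <- function(kind = c("orthogonal_linked", "overlapping",
                                   "independent"),
                          params, timeline = default_timeline()) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "generator_params"))
  lat <- simulate_latents(params, timeline)
  dp <- params$d_prep; dm <- params$d_move
  L <- params$loading
  Lp <- L[, seq_len(dp), drop = FALSE]
  Qp <- qr.Q(qr(Lp))
  perm <- NULL
  if (kind == "overlapping") {
    # same neuron-space plane for both epochs; conditions reordered in the
    # movement stage so tuning still changes at the single-neuron level
    C <- ncol(params$targets)
    perm <- c(seq(2, C), 1)
    lat$x[lat$partition$move, , ] <- lat$x[lat$partition$move, perm, ]
    L2 <- L
    # reorient the movement readout within the shared preparatory plane
    R <- qr.Q(qr(matrix(withr::with_seed(params$seed + 1L, rnorm(dp * dm)),
                        dp, dm)))[, seq_len(dm), drop = FALSE]
    L2[, dp + seq_len(dm)] <- Lp %*% R
    Qm <- Qp
  } else {
    # exactly orthogonal planted planes: movement columns orthogonalized
    # against the preparatory plane (projection of i.i.d. Gaussian columns)
    Lm <- L[, dp + seq_len(dm), drop = FALSE]
    Lm_orth <- Lm - Qp %*% (t(Qp) %*% Lm)
    L2 <- cbind(Lp, Lm_orth)
    Qm <- qr.Q(qr(Lm_orth))
    if (kind == "independent") {
      C <- ncol(params$targets)
      perm <- withr::with_seed(params$seed + 2L, sample(C))
      lat$x[lat$partition$move, , ] <- lat$x[lat$partition$move, perm, ]
    }
  }
  p2 <- params
  p2$loading <- L2
  resp <- emit_rates(lat, p2)
  list(response = resp, Q_prep_true = Qp, Q_move_true = Qm,
       latents = lat, kind = kind, permutation = perm)
}
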