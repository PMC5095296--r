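#' Trial-averaged population response
#'
#' The universal input of the pipeline: a firing-rate tensor of `N` neurons by
#' `C` reach conditions by `T` timepoints on a regular 10 ms grid, together
#' with the task event times (target onset, go cue, movement onset) expressed
#' on the same clock (ms relative to target onset by convention).
#'
#' @param rates numeric array `[N x C x T]`, spikes/s (or normalized units
#'   once preprocessed).
#' @param time_ms numeric vector of length `T`; strictly increasing with a
#'   constant step (10 ms for recorded data).
#' @param events named list with `target_onset_ms`, `go_cue_ms`,
#'   `move_onset_ms`, all within `range(time_ms)`.
#' @param neuron_ids optional character labels, length `N`.
#' @param normalized,centered logical preprocessing flags.
#' @param allow_negative permit negative rates even when neither preprocessing
#'   flag is set (used for linear latent readouts of the generator model).
#'
#' @return An object of class `population_response`.
#' @seealso [soft_normalize()], [mean_center()], [extract_epoch()]
#' @export
population_response <- function(rates, time_ms, events, neuron_ids = NULL,
                                normalized = FALSE, centered = FALSE,
                                allow_negative = FALSE) {
  if (!is.array(rates) || length(dim(rates)) != 3L)
    stop("`rates` must be a 3-d array [neurons x conditions x time]")
  if (dim(rates)[3] != length(time_ms))
    stop("third dimension of `rates` (", dim(rates)[3],
         ") must match length(time_ms) (", length(time_ms), ")")
  if (!all(is.finite(rates))) stop("`rates` must be finite")
  steps <- diff(time_ms)
  if (length(time_ms) > 1 &&
      (any(steps <= 0) || diff(range(steps)) > 1e-8 * max(abs(steps))))
    stop("`time_ms` must be strictly increasing with a constant step")
  needed <- c("target_onset_ms", "go_cue_ms", "move_onset_ms")
  missing_ev <- setdiff(needed, names(events))
  if (length(missing_ev))
    stop("missing event field(s): ", paste(missing_ev, collapse = ", "))
  ev <- unlist(events[needed])
  if (any(ev < min(time_ms) - 1e-9) || any(ev > max(time_ms) + 1e-9))
    stop("event times must lie within [", min(time_ms), ", ", max(time_ms), "] ms")
  if (!normalized && !centered && !allow_negative && any(rates < 0))
    stop("raw firing rates must be non-negative")
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(dim(rates)[1]))
  if (length(neuron_ids) != dim(rates)[1])
    stop("`neuron_ids` must have one label per neuron")
  structure(
    list(rates = rates, time_ms = as.numeric(time_ms),
         events = as.list(ev), neuron_ids = as.character(neuron_ids),
         normalized = isTRUE(normalized), centered = isTRUE(centered)),
    class = "population_response")
}

#' @export
print.population_response <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<population_response> %d neurons x %d conditions x %d timepoints\n",
              d[1], d[2], d[3]))
  cat(sprintf("  time %g..%g ms (step %g ms); target %g, go %g, move %g ms\n",
              min(x$time_ms), max(x$time_ms),
              if (d[3] > 1) x$time_ms[2] - x$time_ms[1] else NA,
              x$events$target_onset_ms, x$events$go_cue_ms, x$events$move_onset_ms))
  cat(sprintf("  normalized: %s, centered: %s\n", x$normalized, x$centered))
  invisible(x)
}

#' Analysis epoch definition
#'
#' An epoch is a fixed-length window anchored to a task event. The defaults
#' used throughout are a 300 ms preparatory window beginning 150 ms after
#' target onset and a 300 ms movement window beginning 50 ms before movement
#' onset.
#'
#' @param name epoch label, `"preparatory"` or `"movement"` (free-form labels
#'   are allowed for custom windows).
#' @param anchor_event one of `"target_onset_ms"`, `"go_cue_ms"`,
#'   `"move_onset_ms"`.
#' @param start_offset_ms window start relative to the anchor (ms).
#' @param duration_ms window length (ms), must be positive.
#' @return An object of class `epoch_def`.
#' @export
epoch_def <- function(name, anchor_event, start_offset_ms, duration_ms) {
  stopifnot(is.character(name), length(name) == 1)
  if (!anchor_event %in% c("target_onset_ms", "go_cue_ms", "move_onset_ms"))
    stop("unknown anchor event: ", anchor_event)
  if (duration_ms <= 0) stop("`duration_ms` must be positive")
  structure(list(name = name, anchor_event = anchor_event,
                 start_offset_ms = start_offset_ms, duration_ms = duration_ms),
            class = "epoch_def")
}

#' @rdname epoch_def
#' @export
prep_epoch <- function() epoch_def("preparatory", "target_onset_ms", 150, 300)

#' @rdname epoch_def
#' @export
move_epoch <- function() epoch_def("movement", "move_onset_ms", -50, 300)

#' Spike trains container
#'
#' Per-(neuron, condition, trial) lists of spike times in ms, the input of
#' [smooth_and_average()] and the output of [emit_spikes()].
#'
#' @param trials nested list: `trials[[neuron]][[condition]]` is a list of
#'   numeric spike-time vectors, one per trial.
#' @param window numeric length-2, the recorded window in ms.
#' @return An object of class `spike_trains`.
#' @export
spike_trains <- function(trials, window) {
  stopifnot(is.list(trials), length(window) == 2, window[1] < window[2])
  for (n in seq_along(trials)) for (c in seq_along(trials[[n]])) {
    for (tr in trials[[n]][[c]]) {
      if (length(tr) && (any(!is.finite(tr)) ||
                         any(tr < window[1] - 1e-9) || any(tr > window[2] + 1e-9)))
        stop(sprintf("spike times outside window for neuron %d, condition %d", n, c))
    }
  }
  structure(list(trials = trials, window = as.numeric(window)),
            class = "spike_trains")
}

#' Gaussian-kernel smoothing and trial averaging
#'
#' Convolves each trial's spike train with a unit-area Gaussian kernel
#' (default s.d. 20 ms) and averages across trials to produce trial-averaged
#' firing rates (a PSTH) on the requested time grid. At the window edges the
#' truncated kernel is renormalized so that the integrated rate of each trial
#' still equals its spike count, preventing edge droop.
#'
#' @param spikes a [spike_trains()] object.
#' @param kernel_sd_ms Gaussian kernel s.d. in ms (> 0).
#' @param grid time grid in ms (regular spacing) for the output.
#' @param events task event times forwarded to the result.
#' @return A [population_response()] with rates in spikes/s.
#' @export
smooth_and_average <- function(spikes, kernel_sd_ms = 20, grid, events) {
  stopifnot(inherits(spikes, "spike_trains"))
  if (kernel_sd_ms <= 0) stop("`kernel_sd_ms` must be positive")
  w <- spikes$window
  n_neur <- length(spikes$trials)
  n_cond <- length(spikes$trials[[1]])
  rates <- array(0, c(n_neur, n_cond, length(grid)))
  for (n in seq_len(n_neur)) for (cc in seq_len(n_cond)) {
    trs <- spikes$trials[[n]][[cc]]
    if (length(trs) == 0)
      stop(sprintf("no trials for neuron %d, condition %d", n, cc))
    s <- unlist(trs)
    acc <- numeric(length(grid))
    if (length(s)) {
      # kernel mass inside the observation window, for edge renormalization
      w_inv <- 1 / (pnorm(w[2], s, kernel_sd_ms) - pnorm(w[1], s, kernel_sd_ms))
      for (ch in split(seq_along(s), ceiling(seq_along(s) / 20000)))
        acc <- acc + dnorm(outer(grid, s[ch], "-"), sd = kernel_sd_ms) %*% w_inv[ch]
    }
    rates[n, cc, ] <- 1000 * acc / length(trs)  # 1/ms -> spikes/s
  }
  population_response(rates, grid, events)
}

#' Soft-normalize firing rates
#'
#' Divides each neuron's rate trace by its firing-rate range (max minus min
#' over all conditions and times) plus a softening constant, so that strongly
#' responsive neurons end up with approximately unity range while weak or
#' silent neurons are not blown up.
#'
#' @param resp a [population_response()], not yet normalized.
#' @param offset softening constant in spikes/s (default 5).
#' @return The normalized response with the `normalized` flag set.
#' @export
soft_normalize <- function(resp, offset = 5) {
  stopifnot(inherits(resp, "population_response"))
  if (resp$normalized) stop("response is already soft-normalized")
  if (offset < 0) stop("`offset` must be non-negative")
  rng <- apply(resp$rates, 1, function(m) max(m) - min(m))
  resp$rates <- resp$rates / array(rng + offset, dim(resp$rates))
  resp$normalized <- TRUE
  resp
}

#' Cross-condition mean-centering
#'
#' Subtracts, for every neuron and timepoint, the mean rate across conditions,
#' so the remaining signal is purely condition-dependent (tuning).
#'
#' @param resp a [population_response()].
#' @return The centered response with the `centered` flag set.
#' @export
mean_center <- function(resp) {
  stopifnot(inherits(resp, "population_response"))
  mu <- apply(resp$rates, c(1, 3), mean)  # N x T
  for (cc in seq_len(dim(resp$rates)[2]))
    resp$rates[, cc, ] <- resp$rates[, cc, ] - mu
  resp$centered <- TRUE
  resp
}

#' Unfold one epoch into a neurons-by-(conditions x times) matrix
#'
#' Extracts the epoch window, unfolds it into an `N x (C*T_ep)` matrix with a
#' fixed condition-major, time-minor column order, and computes the neuron
#' covariance over columns (rows centred, divisor `C*T_ep - 1`). Neurons with
#' exactly zero variance across the epoch (for example, exactly silent
#' neurons) are flagged in `zero_variance_neurons`; correlation analyses
#' exclude them while the epoch-preference analysis retains them.
#'
#' @param resp a preprocessed (normalized and centered) [population_response()].
#' @param epoch an [epoch_def()].
#' @return An object of class `epoch_matrix` with fields `data`, `epoch`,
#'   `covariance`, `singular_values` (covariance eigenvalues, descending),
#'   `zero_variance_neurons`, `n_conditions`, `n_times`.
#' @export
extract_epoch <- function(resp, epoch) {
  stopifnot(inherits(resp, "population_response"), inherits(epoch, "epoch_def"))
  if (!resp$normalized || !resp$centered)
    stop("`resp` must be soft-normalized and mean-centered before epoch extraction")
  t0 <- resp$events[[epoch$anchor_event]] + epoch$start_offset_ms
  t1 <- t0 + epoch$duration_ms
  if (t0 < min(resp$time_ms) - 1e-9 || t1 > max(resp$time_ms) + 10 + 1e-9)
    stop(sprintf("epoch window [%g, %g) ms exceeds recorded range [%g, %g] ms",
                 t0, t1, min(resp$time_ms), max(resp$time_ms)))
  idx <- which(resp$time_ms >= t0 - 1e-9 & resp$time_ms < t1 - 1e-9)
  if (length(idx) == 0) stop("epoch window contains no samples")
  d <- dim(resp$rates)
  # condition-major, time-minor: columns c1t1..c1tk, c2t1..c2tk, ...
  dat <- matrix(aperm(resp$rates[, , idx, drop = FALSE], c(1, 3, 2)), nrow = d[1])
  cv <- cov(t(dat))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  zero_var <- which(apply(dat, 1, function(r) max(r) - min(r)) == 0)
  structure(list(data = dat, epoch = epoch, covariance = cv,
                 singular_values = sort(pmax(ev, 0), decreasing = TRUE),
                 zero_variance_neurons = zero_var,
                 n_conditions = d[2], n_times = length(idx)),
            class = "epoch_matrix")
}
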