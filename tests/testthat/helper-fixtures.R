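# shared fixtures and small oracles, built in code at test time

# principal angles between column spans, in degrees
principal_angles <- function(A, B) {
  s <- svd(crossprod(qr.Q(qr(as.matrix(A))), qr.Q(qr(as.matrix(B)))))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

# small random population response on the standard timeline
toy_response <- function(N = 3, C = 2, seed = 1, nonneg = TRUE) {
  withr::with_seed(seed, {
    tms <- seq(0, 950, 10)
    rates <- array(runif(N * C * length(tms), if (nonneg) 0 else -1, 10),
                   c(N, C, length(tms)))
    population_response(rates, tms, default_timeline()[1:3],
                        allow_negative = !nonneg)
  })
}

# random PSD matrix with distinct positive eigenvalues
random_psd <- function(N, seed = 1, eigenvalues = NULL) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(N * N), N)))
    ev <- if (is.null(eigenvalues)) sort(runif(N, 0.5, 5), decreasing = TRUE)
          else eigenvalues
    Q %*% (ev * t(Q))
  })
}

# generator-model fixtures are expensive enough to share across tests
.fixture_cache <- new.env(parent = emptyenv())
scenario_fixture <- function(kind, seed = 3) {
  key <- paste0(kind, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_scenario(kind, generator_params(seed = seed))
  .fixture_cache[[key]]
}

# covariance of an epoch on centered-only rates (no soft-normalization), in
# the raw neuron space where the fixture's ground-truth planes are planted
centered_epoch_cov <- function(resp, t0, t1) {
  cc <- mean_center(population_response(resp$rates, resp$time_ms, resp$events,
                                        allow_negative = TRUE))
  idx <- which(cc$time_ms >= t0 & cc$time_ms < t1)
  N <- dim(cc$rates)[1]
  stats::cov(t(matrix(aperm(cc$rates[, , idx, drop = FALSE], c(1, 3, 2)), N)))
}

preprocessed_fixture <- function(kind, seed = 3) {
  key <- paste0("pp_", kind, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <-
      mean_center(soft_normalize(scenario_fixture(kind, seed)$response))
  .fixture_cache[[key]]
}
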