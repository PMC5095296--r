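test_that("constructor enforces the response invariants", {
  tms <- seq(0, 950, 10)
  rates <- array(1, c(2, 3, length(tms)))
  ev <- default_timeline()[1:3]
  expect_s3_class(population_response(rates, tms, ev), "population_response")
  expect_error(population_response(rates, tms[-1], ev), "must match")
  expect_error(population_response(rates, rev(tms), ev), "increasing")
  expect_error(population_response(rates, tms, ev[1:2]), "move_onset_ms")
  expect_error(population_response(rates, tms, list(target_onset_ms = -50,
                                                    go_cue_ms = 500,
                                                    move_onset_ms = 650)),
               "within")
  expect_error(population_response(-rates, tms, ev), "non-negative")
  expect_silent(population_response(-rates, tms, ev, centered = TRUE))
})

test_that("smoothing a single spike gives a unit-area Gaussian bump", {
  grid <- seq(-100, 100, 10)
  st <- spike_trains(list(list(list(c(0)))), window = c(-100, 100))
  resp <- smooth_and_average(st, kernel_sd_ms = 20, grid = grid,
                             events = list(target_onset_ms = 0, go_cue_ms = 0,
                                           move_onset_ms = 0))
  mass <- pnorm(100, 0, 20) - pnorm(-100, 0, 20)
  expect_equal(resp$rates[1, 1, ], 1000 * dnorm(grid, 0, 20) / mass,
               tolerance = 1e-12)
  expect_equal(which.max(resp$rates[1, 1, ]), which(grid == 0))
  # integrated rate equals the spike count despite edge truncation
  expect_equal(sum(resp$rates[1, 1, ]) * 10 / 1000, 1, tolerance = 1e-6)
})

test_that("smoothing handles empty trials and missing trials correctly", {
  grid <- seq(0, 100, 10)
  ev <- list(target_onset_ms = 0, go_cue_ms = 50, move_onset_ms = 80)
  quiet <- spike_trains(list(list(list(numeric(0), numeric(0)))), c(0, 100))
  resp <- smooth_and_average(quiet, 20, grid, ev)
  expect_true(all(resp$rates == 0))
  none <- spike_trains(list(list(list()), list(list(numeric(0)))), c(0, 100))
  expect_error(smooth_and_average(none, 20, grid, ev),
               "neuron 1, condition 1")
})

test_that("Poisson trains recover their rate after smoothing and averaging", {
  rate <- 50; n_trials <- 200
  window <- c(0, 1000)
  trains <- withr::with_seed(11, lapply(seq_len(n_trials), function(i) {
    n <- rpois(1, rate * diff(window) / 1000)
    sort(runif(n, window[1], window[2]))
  }))
  st <- spike_trains(list(list(trains)), window)
  grid <- seq(0, 1000, 10)
  resp <- smooth_and_average(st, 20, grid,
                             list(target_onset_ms = 0, go_cue_ms = 500,
                                  move_onset_ms = 650))
  interior <- resp$rates[1, 1, grid > 100 & grid < 900]
  sem <- sqrt(rate * 1000 / diff(window)) / sqrt(n_trials)
  expect_lt(abs(mean(interior) - rate), 3 * sem)
})

test_that("soft normalization divides by range plus offset", {
  resp <- toy_response(N = 2, C = 2, seed = 5)
  resp$rates[1, , ] <- resp$rates[1, , ] / max(resp$rates[1, , ]) * 45 # range 45
  resp$rates[1, 1, 1] <- 0
  resp$rates[2, , ] <- 7                                              # range 0
  sn <- soft_normalize(resp)
  expect_equal(sn$rates[1, , ], resp$rates[1, , ] / 50, tolerance = 1e-12)
  expect_equal(sn$rates[2, , ], resp$rates[2, , ] / 5, tolerance = 1e-12)
  expect_true(sn$normalized)
  # range 95 with offset 5 -> post-normalization range 0.95
  r2 <- toy_response(N = 1, C = 1, seed = 6)
  r2$rates[] <- seq(0, 95, length.out = length(r2$rates))
  expect_equal(diff(range(soft_normalize(r2)$rates)), 0.95, tolerance = 1e-12)
  expect_error(soft_normalize(sn), "already")
  expect_error(soft_normalize(toy_response(), offset = -1), "non-negative")
})

test_that("mean-centering removes the cross-condition mean exactly", {
  resp <- toy_response(N = 4, C = 5, seed = 7)
  cc <- mean_center(resp)
  mu <- apply(cc$rates, c(1, 3), mean)
  expect_lt(max(abs(mu)), 1e-12)
  # identical traces across conditions -> all zero
  same <- toy_response(N = 2, C = 3, seed = 8)
  for (k in 2:3) same$rates[, k, ] <- same$rates[, 1, ]
  expect_lt(max(abs(mean_center(same)$rates)), 1e-15)
  # two conditions a, b -> (a-b)/2 and (b-a)/2
  two <- toy_response(N = 1, C = 2, seed = 9)
  d <- (two$rates[, 1, ] - two$rates[, 2, ]) / 2
  expect_equal(mean_center(two)$rates[1, 1, ], d, tolerance = 1e-12)
  expect_equal(mean_center(two)$rates[1, 2, ], -d, tolerance = 1e-12)
})

test_that("epoch extraction has the documented shape, order and covariance", {
  gp <- generator_params(n_neurons = 6, seed = 2)
  pp <- mean_center(soft_normalize(simulate_population(gp)))
  em <- extract_epoch(pp, prep_epoch())
  expect_equal(ncol(em$data), 8 * 30)   # 8 conditions x 300 ms / 10 ms
  # condition-major, time-minor ordering
  idx <- which(pp$time_ms >= 150 & pp$time_ms < 450)
  expect_equal(em$data[, 1:30], pp$rates[, 1, idx])
  expect_equal(em$data[, 31:60], pp$rates[, 2, idx])
  # covariance equals the brute-force row-centered covariance
  X <- em$data
  Xc <- X - rowMeans(X)
  expect_equal(em$covariance, (Xc %*% t(Xc)) / (ncol(X) - 1), tolerance = 1e-12)
  expect_error(extract_epoch(pp, epoch_def("late", "move_onset_ms", 200, 300)),
               "exceeds")
  expect_error(epoch_def("zero", "go_cue_ms", 0, 0), "positive")
  expect_error(extract_epoch(soft_normalize(toy_response()), prep_epoch()),
               "centered")
})

test_that("a constant-zero response has zero epoch covariance and is flagged", {
  tms <- seq(0, 950, 10)
  resp <- population_response(array(0, c(3, 2, length(tms))), tms,
                              default_timeline()[1:3],
                              normalized = TRUE, centered = TRUE)
  em <- extract_epoch(resp, prep_epoch())
  expect_true(all(em$covariance == 0))
  expect_equal(em$zero_variance_neurons, 1:3)
})

test_that("preprocessing commutes with condition relabeling", {
  resp <- toy_response(N = 4, C = 5, seed = 12)
  perm <- c(3, 5, 1, 2, 4)
  a <- mean_center(soft_normalize(resp))$rates[, perm, ]
  rp <- resp; rp$rates <- rp$rates[, perm, ]
  b <- mean_center(soft_normalize(rp))$rates
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("datasets round-trip through CSV losslessly", {
  resp <- mean_center(soft_normalize(toy_response(N = 3, C = 2, seed = 13)))
  path <- file.path(withr::local_tempdir(), "data.csv")
  write_dataset(resp, path)
  back <- read_dataset(path)
  expect_identical(back$rates, resp$rates)
  expect_equal(back$events, resp$events)
  expect_identical(back$neuron_ids, resp$neuron_ids)
  expect_true(back$normalized && back$centered)
  # schema violations are reported with field names
  df <- read.csv(path)
  write.csv(df[, -4], path, row.names = FALSE)
  expect_error(read_dataset(path), "rate")
  write_dataset(resp, path)  # restore both files
  meta_path <- sub("csv$", "json", path)
  meta <- jsonlite::read_json(meta_path)
  meta$events <- NULL
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  expect_error(read_dataset(path), "events")
})
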