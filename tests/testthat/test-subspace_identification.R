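test_that("disjoint eigen-supports give a perfect separable optimum", {
  Q <- withr::with_seed(41, qr.Q(qr(matrix(rnorm(36), 6))))
  C_prep <- Q[, 1:2] %*% diag(c(4, 2)) %*% t(Q[, 1:2])
  C_move <- Q[, 3:5] %*% diag(c(5, 3, 1)) %*% t(Q[, 3:5])
  pair <- identify_subspaces(C_prep, C_move, d_prep = 2, d_move = 3,
                             restarts = 5, seed = 1)
  expect_equal(pair$objective, 1, tolerance = 1e-8)
  expect_lt(max(principal_angles(pair$Q_prep, Q[, 1:2])), 1e-4)
  expect_lt(max(principal_angles(pair$Q_move, Q[, 3:5])), 1e-4)
  # joint orthonormality within 1e-10
  J <- cbind(pair$Q_prep, pair$Q_move)
  expect_lt(max(abs(crossprod(J) - diag(5))), 1e-10)
})

test_that("shared covariance forces the blocks to split the top eigenspace", {
  C <- random_psd(6, seed = 42)
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  d <- 2
  pair <- identify_subspaces(C, C, d_prep = d, d_move = d,
                             restarts = 10, seed = 2)
  closed_form <- sum(ev[1:(2 * d)]) / (2 * sum(ev[1:d]))
  expect_lt(pair$objective, 1)
  expect_equal(pair$objective, closed_form, tolerance = 1e-8)
  # brute force over assignments of eigenvectors to the two blocks
  eg <- eigen(C, symmetric = TRUE)
  f <- function(ip, im)
    0.5 * (sum(ev[ip]) / sum(ev[1:d]) + sum(ev[im]) / sum(ev[1:d]))
  combos <- utils::combn(6, d, simplify = FALSE)
  brute <- max(vapply(combos, function(ip) {
    rest <- setdiff(1:6, ip)
    max(vapply(utils::combn(rest, d, simplify = FALSE),
               function(im) f(ip, im), numeric(1)))
  }, numeric(1)))
  expect_equal(pair$objective, brute, tolerance = 1e-8)
})

test_that("alternating updates never decrease the objective", {
  for (seed in 43:45) {
    pair <- identify_subspaces(random_psd(8, seed = seed),
                               random_psd(8, seed = seed + 100),
                               d_prep = 2, d_move = 3, restarts = 3,
                               seed = seed)
    expect_true(all(diff(pair$objective_trace) >= -1e-12))
    expect_true(pair$converged)
  }
})

test_that("the objective is invariant to within-block rotations", {
  C_prep <- random_psd(6, seed = 46)
  C_move <- random_psd(6, seed = 47)
  pair <- identify_subspaces(C_prep, C_move, 2, 2, restarts = 5, seed = 1)
  s_p <- sum(epoch_pcs(C_prep, 2)$var_captured)
  s_m <- sum(epoch_pcs(C_move, 2)$var_captured)
  obj <- function(Qp, Qm)
    0.5 * (sum(diag(t(Qp) %*% C_prep %*% Qp)) / s_p +
           sum(diag(t(Qm) %*% C_move %*% Qm)) / s_m)
  R <- withr::with_seed(48, qr.Q(qr(matrix(rnorm(4), 2))))
  expect_equal(obj(pair$Q_prep, pair$Q_move),
               obj(pair$Q_prep %*% R, pair$Q_move), tolerance = 1e-12)
  expect_equal(obj(pair$Q_prep, pair$Q_move), pair$objective,
               tolerance = 1e-10)
})

test_that("planted subspaces are recovered on the noiseless fixture", {
  fx <- scenario_fixture("orthogonal_linked")
  Cp <- centered_epoch_cov(fx$response, 150, 450)
  Cm <- centered_epoch_cov(fx$response, 600, 900)
  pair <- identify_subspaces(Cp, Cm, 2, 2, restarts = 5, seed = 1)
  expect_lt(max(principal_angles(pair$Q_prep, fx$Q_prep_true)), 1)
  expect_lt(max(principal_angles(pair$Q_move, fx$Q_move_true)), 1)
  # constrained solution sacrifices almost nothing vs unconstrained PCA
  vc_q <- variance_captured(Cp, pair$Q_prep)$total
  vc_pc <- sum(epoch_pcs(Cp, 2)$var_captured)
  expect_gt(vc_q / vc_pc, 0.95)
})

test_that("projection is linear, shape-correct and preserves centering", {
  pp <- preprocessed_fixture("orthogonal_linked")
  fx <- scenario_fixture("orthogonal_linked")
  N <- dim(pp$rates)[1]
  proj <- project(pp, fx$Q_prep_true)
  expect_equal(dim(proj$x), c(2, 8, length(pp$time_ms)))
  # per-time cross-condition means stay zero under linear projection
  expect_lt(max(abs(apply(proj$x, c(1, 3), mean))), 1e-12)
  # projecting onto directions orthogonal to the data span gives zero
  resid <- qr.Q(qr(cbind(fx$Q_prep_true, fx$Q_move_true)), complete = TRUE)
  raw <- mean_center(population_response(fx$response$rates,
                                         fx$response$time_ms,
                                         fx$response$events,
                                         allow_negative = TRUE))
  off <- project(raw, resid[, 5:6])
  expect_lt(max(abs(off$x)), 1e-9 * max(abs(raw$rates)))
  expect_error(project(pp, matrix(1, N, 2)), "orthonormal")
})

test_that("fixture trajectories show the preparatory-then-movement pattern", {
  fx <- scenario_fixture("orthogonal_linked")
  pp <- preprocessed_fixture("orthogonal_linked")
  pair <- identify_subspaces(extract_epoch(pp, prep_epoch())$covariance,
                             extract_epoch(pp, move_epoch())$covariance,
                             2, 2, restarts = 5, seed = 1)
  spread <- function(proj) apply(proj$x, 3, function(m) sum(m^2))
  sp <- spread(project(pp, pair$Q_prep))
  sm <- spread(project(pp, pair$Q_move))
  tms <- pp$time_ms
  # preparatory subspace: spreads after target onset, converges after go
  expect_gt(mean(sp[tms >= 150 & tms < 450]), 10 * mean(sp[tms < 100]))
  expect_lt(mean(sp[tms >= 850]), 0.3 * max(sp))
  # movement subspace: near zero until the go cue, large during movement
  expect_lt(mean(sm[tms < 500]), 0.01 * max(sm))
  expect_gt(mean(sm[tms >= 650 & tms < 900]), 0.2 * max(sm))
})

test_that("the epoch-variance table matches brute force and its null is calibrated", {
  # brute-force check on a small random instance
  C_prep <- random_psd(4, seed = 49)
  C_move <- random_psd(4, seed = 50)
  pair <- identify_subspaces(C_prep, C_move, 1, 2, restarts = 5, seed = 1)
  P <- list(data = NULL, covariance = C_prep)
  M <- list(data = NULL, covariance = C_move)
  vt <- subspace_epoch_variance(pair, P, M, C_full = diag(4),
                                n_samples = 200, seed = 3)
  brute <- 100 * sum(diag(t(pair$Q_move) %*% C_prep %*% pair$Q_move)) /
    sum(diag(C_prep))
  expect_equal(vt$percent["move", "prep"], brute, tolerance = 1e-10)
  # planted fixture: each subspace owns its epoch and avoids the other
  fx <- scenario_fixture("orthogonal_linked")
  Cp <- centered_epoch_cov(fx$response, 150, 450)
  Cm <- centered_epoch_cov(fx$response, 600, 900)
  pair2 <- identify_subspaces(Cp, Cm, 2, 2, restarts = 5, seed = 1)
  Pm <- list(covariance = Cp, data = NULL)
  Mm <- list(covariance = Cm, data = NULL)
  vt2 <- subspace_epoch_variance(pair2, Pm, Mm, C_full = (Cp + Cm) / 2,
                                 n_samples = 400, seed = 4)
  expect_gt(vt2$percent["prep", "prep"], 95)
  expect_lt(vt2$percent["move", "prep"], 1)
  expect_lte(vt2$p_value["prep", "prep"], 0.025)
  expect_lte(vt2$p_value["move", "move"], 0.025)
})
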