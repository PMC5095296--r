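#' Simultaneous identification of orthogonal preparatory and movement subspaces
#'
#' Finds jointly orthonormal bases `Q_prep` (`N x d_prep`) and `Q_move`
#' (`N x d_move`) maximizing the normalized captured variance
#' \deqn{f = 1/2 [ tr(Q_p' C_p Q_p) / \sum_{i \le d_p} \sigma_i(C_p)
#'              + tr(Q_m' C_m Q_m) / \sum_{i \le d_m} \sigma_i(C_m) ],}
#' where the denominators are the best any subspace of that dimensionality
#' could do (the top principal components). The normalization makes the
#' objective insensitive to the relative strength and dimensionality of the
#' two epochs; `f = 1` is attainable only when the two optimal subspaces are
#' already orthogonal.
#'
#' Optimization is by alternating block eigen-updates: holding one block
#' fixed, the other block's optimum is the top eigenvectors of its covariance
#' compressed into the orthogonal complement of the fixed block. Each update
#' can only increase the objective, so convergence is monotone; several
#' restarts (PCA-seeded plus random) guard against local optima.
#'
#' @param C_prep,C_move epoch covariance matrices (same size, PSD).
#' @param d_prep,d_move subspace dimensionalities (defaults 2 and 4, chosen to
#'   capture roughly 70% of each epoch's variance in cortical data).
#' @param restarts number of initializations (default 20).
#' @param seed integer seed for the random restarts.
#' @param max_iter,tol convergence controls: stop when the relative objective
#'   change falls below `tol` or after `max_iter` sweeps.
#' @return object of class `subspace_pair`: `Q_prep`, `Q_move` (axes ordered
#'   by captured variance, sign-fixed), `objective`, `objective_trace` (per
#'   sweep, best restart), `converged`, `d_prep`, `d_move`.
#' @export
identify_subspaces <- function(C_prep, C_move, d_prep = 2, d_move = 4,
                               restarts = 20, seed = 1,
                               max_iter = 500, tol = 1e-10) {
  N <- nrow(C_prep)
  if (!all(dim(C_prep) == dim(C_move)))
    stop("covariances must have the same dimensions")
  if (d_prep + d_move > N)
    stop("d_prep + d_move must not exceed the number of neurons")
  s_p <- sum(sort(pmax(eigen(C_prep, symmetric = TRUE, only.values = TRUE)$values, 0),
                  decreasing = TRUE)[seq_len(d_prep)])
  s_m <- sum(sort(pmax(eigen(C_move, symmetric = TRUE, only.values = TRUE)$values, 0),
                  decreasing = TRUE)[seq_len(d_move)])
  if (s_p <= 0 || s_m <= 0) stop("an epoch covariance has no variance")
  obj <- function(Qp, Qm)
    0.5 * (sum(colSums(Qp * (C_prep %*% Qp))) / s_p +
           sum(colSums(Qm * (C_move %*% Qm))) / s_m)
  # top-d eigenvectors of C compressed into the complement of `fixed`
  best_in_complement <- function(C, fixed, d) {
    Z <- qr.Q(qr(fixed), complete = TRUE)[, (ncol(fixed) + 1):N, drop = FALSE]
    V <- eigen(crossprod(Z, C %*% Z), symmetric = TRUE)$vectors[, seq_len(d), drop = FALSE]
    Z %*% V
  }
  run <- function(Qm0) {
    Qm <- Qm0
    Qp <- best_in_complement(C_prep, Qm, d_prep)
    trace <- obj(Qp, Qm)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Qm <- best_in_complement(C_move, Qp, d_move)
      Qp <- best_in_complement(C_prep, Qm, d_prep)
      f <- obj(Qp, Qm)
      trace <- c(trace, f)
      if (abs(f - trace[length(trace) - 1]) <= tol * max(1, abs(f))) {
        converged <- TRUE
        break
      }
    }
    list(Qp = Qp, Qm = Qm, f = f, trace = trace, converged = converged)
  }
  inits <- withr::with_seed(seed, {
    starts <- list(eigen(C_move, symmetric = TRUE)$vectors[, seq_len(d_move), drop = FALSE])
    while (length(starts) < restarts)
      starts[[length(starts) + 1]] <-
        qr.Q(qr(matrix(rnorm(N * d_move), N, d_move)))[, seq_len(d_move), drop = FALSE]
    starts
  })
  fits <- lapply(inits, run)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "f"))]]
  Qp <- orient_axes(best$Qp, C_prep)
  Qm <- orient_axes(best$Qm, C_move)
  structure(list(Q_prep = Qp, Q_move = Qm, objective = best$f,
                 objective_trace = best$trace, converged = best$converged,
                 d_prep = d_prep, d_move = d_move),
            class = "subspace_pair")
}

# order axes by captured variance and fix signs so the largest-magnitude
# loading of each axis is positive (removes rotation/sign indeterminacy)
orient_axes <- function(Q, C) {
  M <- crossprod(Q, C %*% Q)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  Q <- Q %*% eg$vectors
  for (k in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, k]))
    if (Q[i, k] < 0) Q[, k] <- -Q[, k]
  }
  Q
}

#' @export
print.subspace_pair <- function(x, ...) {
  cat(sprintf("<subspace_pair> d_prep = %d, d_move = %d, objective = %.6f (%s)\n",
              x$d_prep, x$d_move, x$objective,
              if (x$converged) "converged" else "max iterations reached"))
  invisible(x)
}

#' Project a population response onto a basis
#'
#' Per-time, per-condition coordinates of the population state in the given
#' subspace; linear, so cross-condition centering is preserved.
#'
#' @param resp a preprocessed [population_response()].
#' @param basis orthonormal `N x d` matrix.
#' @return object of class `projection`: `x` (`d x C x T`), `time_ms`,
#'   `events`.
#' @export
project <- function(resp, basis) {
  stopifnot(inherits(resp, "population_response"))
  basis <- as.matrix(basis)
  check_orthonormal(basis)
  if (nrow(basis) != dim(resp$rates)[1])
    stop("basis rows must match the number of neurons")
  d <- dim(resp$rates)
  out <- array(0, c(ncol(basis), d[2], d[3]))
  for (k in seq_len(d[3])) out[, , k] <- crossprod(basis, resp$rates[, , k])
  structure(list(x = out, time_ms = resp$time_ms, events = resp$events),
            class = "projection")
}

#' Variance table of a subspace pair across epochs
#'
#' Percentage of each epoch's variance captured by each identified subspace
#' (a 2 x 2 table: subspace by epoch) together with one-tailed Monte Carlo
#' p-values against random subspaces of the same dimensionality drawn from the
#' full-task covariance: the fraction of random subspaces capturing at least
#' as much variance as the identified one.
#'
#' @param pair an [identify_subspaces()] result.
#' @param P,M [extract_epoch()] results for the preparatory and movement
#'   epochs.
#' @param C_full covariance used by the random-subspace sampler; defaults to
#'   the covariance of the concatenated epoch columns.
#' @param n_samples Monte Carlo draws.
#' @param seed integer seed.
#' @return list with `percent` (2 x 2 matrix, rows = prep/move subspace,
#'   columns = prep/move epoch) and `p_value` (same layout).
#' @export
subspace_epoch_variance <- function(pair, P, M, C_full = NULL,
                                    n_samples = 1000, seed = 1) {
  stopifnot(inherits(pair, "subspace_pair"))
  if (is.null(C_full)) C_full <- cov(t(cbind(P$data, M$data)))
  covs <- list(prep = P$covariance, move = M$covariance)
  bases <- list(prep = pair$Q_prep, move = pair$Q_move)
  percent <- sapply(covs, function(cv)
    sapply(bases, function(b) variance_captured(cv, b)$percent_total))
  cs <- cov_sqrt(C_full)
  null_draws <- withr::with_seed(seed, {
    lapply(c(prep = pair$d_prep, move = pair$d_move), function(d)
      replicate(n_samples, sample_random_subspace(cs, d), simplify = FALSE))
  })
  p_value <- percent * NA
  for (b in c("prep", "move")) for (e in c("prep", "move")) {
    null_var <- vapply(null_draws[[b]], function(rb)
      variance_captured(covs[[e]], rb)$percent_total, numeric(1))
    p_value[b, e] <- mean(null_var >= percent[b, e])
  }
  list(percent = percent, p_value = p_value)
}
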