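#' Principal components of one epoch
#'
#' Top-`d` eigenvectors of the epoch covariance (each neuron treated as a
#' variable), with the variance captured by each component.
#'
#' @param epoch an [extract_epoch()] result, or a covariance matrix.
#' @param d number of components.
#' @return object of class `pc_basis`: `vectors` (`N x d`, orthonormal),
#'   `singular_values` (all covariance eigenvalues, descending), `var_captured`
#'   (per-component), `epoch` (name, when available).
#' @export
epoch_pcs <- function(epoch, d) {
  cv <- if (inherits(epoch, "epoch_matrix")) epoch$covariance else epoch
  name <- if (inherits(epoch, "epoch_matrix")) epoch$epoch$name else NA_character_
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-12)
  if (d > rank)
    stop("requested d = ", d, " exceeds the effective rank (", rank, ")")
  structure(list(vectors = eg$vectors[, seq_len(d), drop = FALSE],
                 singular_values = ev, var_captured = ev[seq_len(d)],
                 epoch = name),
            class = "pc_basis")
}

check_orthonormal <- function(basis, tol = 1e-8) {
  g <- crossprod(basis)
  if (max(abs(g - diag(ncol(basis)))) > tol)
    stop("basis is not orthonormal (Gram deviation ",
         format(max(abs(g - diag(ncol(basis))))), ")")
  invisible(TRUE)
}

#' Variance captured by a basis
#'
#' Per-dimension and total data variance captured by an orthonormal basis,
#' as a percentage of the total variance (trace of the covariance).
#'
#' @param cov covariance matrix.
#' @param basis orthonormal `N x d` matrix.
#' @return list with `per_dim` (variance per column), `total`,
#'   `percent_per_dim`, `percent_total`.
#' @export
variance_captured <- function(cov, basis) {
  basis <- as.matrix(basis)
  check_orthonormal(basis)
  per <- colSums(basis * (cov %*% basis))  # diag(t(B) C B)
  tot <- sum(diag(cov))
  list(per_dim = per, total = sum(per),
       percent_per_dim = 100 * per / tot, percent_total = 100 * sum(per) / tot)
}

#' Alignment index between an epoch covariance and a tested subspace
#'
#' `A = trace(D' C_prep D) / sum(top-d eigenvalues of C_prep)`: the fraction
#' of preparatory-epoch variance captured by the tested `d`-dimensional basis,
#' normalized by the most that any `d`-dimensional subspace could capture
#' (the top-`d` principal components). `A = 0` when the tested basis is
#' orthogonal to the span of the data, `A = 1` when it captures as much as the
#' top-`d` PCs do.
#'
#' @param C_prep covariance whose variance is being captured.
#' @param D_move orthonormal `N x d` tested basis (for example move-PCs).
#' @param d subspace dimensionality; defaults to `ncol(D_move)`.
#' @return the alignment index, in `[0, 1]`.
#' @export
alignment_index <- function(C_prep, D_move, d = ncol(D_move)) {
  D_move <- as.matrix(D_move)
  if (ncol(D_move) != d) stop("`D_move` must have exactly d columns")
  check_orthonormal(D_move)
  ev <- eigen(C_prep, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  rank <- sum(ev > max(ev) * 1e-12)
  if (d > rank)
    stop("requested d = ", d, " exceeds the effective rank (", rank, ")")
  num <- sum(colSums(D_move * (C_prep %*% D_move)))
  num / sum(ev[seq_len(d)])
}

#' Draw a random subspace weighted by the data covariance
#'
#' Samples `d` directions `v_k = C^(1/2) w_k` with standard normal `w_k` and
#' orthonormalizes them by QR. The resulting random subspaces concentrate on
#' the high-variance directions of `C_full`, so they represent "random
#' dimensions within the space occupied by the data" rather than uniformly
#' random directions.
#'
#' @param C_full positive semidefinite covariance (typically of the responses
#'   at all times of the task), or a prefactored [cov_sqrt()] object when many
#'   draws are needed.
#' @param d subspace dimensionality; must not exceed `rank(C_full)`.
#' @return orthonormal `N x d` basis.
#' @export
sample_random_subspace <- function(C_full, d) {
  cs <- if (inherits(C_full, "cov_sqrt")) C_full else cov_sqrt(C_full)
  if (d > cs$rank)
    stop("requested d = ", d, " exceeds rank(C_full) = ", cs$rank)
  v <- cs$half %*% matrix(rnorm(cs$n * d), ncol = d)
  qr.Q(qr(v))[, seq_len(d), drop = FALSE]
}

#' Symmetric square root of a covariance matrix
#'
#' Eigenfactored once so repeated covariance-weighted draws do not refactor.
#'
#' @param C positive semidefinite matrix (negative eigenvalues from numerical
#'   noise are clipped at zero).
#' @return object of class `cov_sqrt` with fields `half`, `rank`, `n`.
#' @export
cov_sqrt <- function(C) {
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  structure(list(half = eg$vectors %*% (sqrt(ev) * t(eg$vectors)),
                 rank = sum(ev > max(ev) * 1e-12), n = nrow(C)),
            class = "cov_sqrt")
}

#' Monte Carlo random-subspace null for the alignment index
#'
#' Repeatedly samples random `d`-dimensional subspaces weighted by the full
#' -task covariance ([sample_random_subspace()]) and records the alignment
#' index they produce, giving the baseline alignment expected from the
#' dimensionality of the data alone. The observed indices (preparatory-epoch
#' variance in the top-`d` move-PCs, and symmetrically movement-epoch variance
#' in the top-`d` prep-PCs) are compared against their respective nulls with a
#' one-tailed test in the misalignment direction (observed below null).
#'
#' @param C_full covariance of the responses at all times of the task.
#' @param C_prep,C_move epoch covariances.
#' @param d subspace dimensionality.
#' @param n_samples Monte Carlo samples (default 10000).
#' @param seed integer seed.
#' @return list of two `alignment_result` objects, `prep_onto_move` and
#'   `move_onto_prep`, each with `index` (observed), `d`, `null_distribution`,
#'   `null_median`, `null_ci95`, `percentile` (of the observed index within
#'   the null, in percent) and `p_one_tailed` (fraction of null <= observed).
#' @export
random_alignment_null <- function(C_full, C_prep, C_move, d,
                                  n_samples = 10000, seed = 1) {
  if (!all(dim(C_full) == dim(C_prep)) || !all(dim(C_full) == dim(C_move)))
    stop("covariances must have consistent dimensions")
  if (n_samples < 100)
    warning("n_samples < 100 gives a very coarse null")
  obs_pm <- alignment_index(C_prep, epoch_pcs(C_move, d)$vectors, d)
  obs_mp <- alignment_index(C_move, epoch_pcs(C_prep, d)$vectors, d)
  # factor once; the alignment denominator is fixed by the data, not the draw
  cs <- cov_sqrt(C_full)
  den_p <- sum(epoch_pcs(C_prep, d)$var_captured)
  den_m <- sum(epoch_pcs(C_move, d)$var_captured)
  null_pm <- numeric(n_samples)
  null_mp <- numeric(n_samples)
  withr::with_seed(seed, {
    for (k in seq_len(n_samples)) {
      B1 <- sample_random_subspace(cs, d)
      B2 <- sample_random_subspace(cs, d)
      null_pm[k] <- sum(colSums(B1 * (C_prep %*% B1))) / den_p
      null_mp[k] <- sum(colSums(B2 * (C_move %*% B2))) / den_m
    }
  })
  mk <- function(obs, null) {
    structure(list(index = obs, d = d, n_samples = n_samples,
                   null_distribution = null,
                   null_median = median(null),
                   null_ci95 = unname(quantile(null, c(0.025, 0.975))),
                   percentile = 100 * mean(null <= obs),
                   p_one_tailed = mean(null <= obs)),
              class = "alignment_result")
  }
  list(prep_onto_move = mk(obs_pm, null_pm),
       move_onto_prep = mk(obs_mp, null_mp))
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> index = %.4f (d = %d)\n", x$index, x$d))
  cat(sprintf("  null (n = %d): median %.4f, 95%% CI [%.4f, %.4f]\n",
              x$n_samples, x$null_median, x$null_ci95[1], x$null_ci95[2]))
  cat(sprintf("  observed percentile %.2f%%, one-tailed p = %.4g\n",
              x$percentile, x$p_one_tailed))
  invisible(x)
}

#' @importFrom stats median
#' @importFrom graphics abline hist
#' @export
plot.alignment_result <- function(x, ...) {
  hist(x$null_distribution, breaks = 40,
       main = "Alignment index vs random-subspace null",
       xlab = "alignment index", ...)
  abline(v = x$index, col = "red", lwd = 2)
  invisible(x)
}
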