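#' Pairwise cross-condition correlation matrix of one epoch
#'
#' Pearson correlation between neurons (rows of the epoch matrix) across all
#' condition-time columns. Correlation is undefined for neurons with exactly
#' zero variance across the epoch; those rows are excluded and reported.
#'
#' @param epoch an [extract_epoch()] result.
#' @return list with `corr` (correlation matrix over retained neurons, `NA`
#'   rows/columns for excluded ones), `excluded` (indices of zero-variance
#'   neurons), `retained`.
#' @export
epoch_correlation <- function(epoch) {
  stopifnot(inherits(epoch, "epoch_matrix"))
  if (ncol(epoch$data) < 3) stop("need at least 3 columns to correlate")
  excl <- epoch$zero_variance_neurons
  n <- nrow(epoch$data)
  keep <- setdiff(seq_len(n), excl)
  corr <- matrix(NA_real_, n, n)
  corr[keep, keep] <- cor(t(epoch$data[keep, , drop = FALSE]))
  list(corr = corr, excluded = excl, retained = keep)
}

upper_pairs <- function(m, keep) {
  sub <- m[keep, keep, drop = FALSE]
  sub[upper.tri(sub)]
}

#' Across-epoch similarity of correlation structure
#'
#' Squared Pearson correlation between the paired off-diagonal entries of the
#' preparatory-epoch and movement-epoch correlation matrices: near 1 when the
#' set of neurons that covary together is preserved across epochs, near 0 when
#' it reorganizes. The confidence interval comes from a bootstrap over neurons
#' (pair sets are rebuilt per resample, respecting the dependence between
#' pairs sharing a neuron).
#'
#' @param corr_prep,corr_move correlation matrices over the same neurons
#'   (entries may be `NA` for excluded neurons).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return list with `r_squared`, `ci` (2.5/97.5 percentiles), `sd`
#'   (bootstrap s.d.), `boot` (the bootstrap distribution),
#'   `excluded_neurons`.
#' @export
correlation_similarity <- function(corr_prep, corr_move, n_boot = 1000, seed = 1) {
  if (!all(dim(corr_prep) == dim(corr_move)))
    stop("correlation matrices must have matching shapes")
  n <- nrow(corr_prep)
  keep <- which(!is.na(diag(corr_prep)) & !is.na(diag(corr_move)))
  if (length(keep) < 3) stop("need at least 3 retained neurons")
  r2_of <- function(idx) {
    p <- corr_prep[idx, idx, drop = FALSE][upper.tri(diag(length(idx)))]
    m <- corr_move[idx, idx, drop = FALSE][upper.tri(diag(length(idx)))]
    ok <- which(outer(idx, idx, "!=")[upper.tri(diag(length(idx)))])
    if (length(ok) < 2 || sd(p[ok]) == 0 || sd(m[ok]) == 0) return(NA_real_)
    cor(p[ok], m[ok])^2
  }
  r2 <- r2_of(keep)
  boot <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    r2_of(sample(keep, length(keep), replace = TRUE))
  }, numeric(1)))
  boot <- boot[!is.na(boot)]
  list(r_squared = r2,
       ci = unname(quantile(boot, c(0.025, 0.975))),
       sd = sd(boot), boot = boot,
       excluded_neurons = setdiff(seq_len(n), keep))
}

#' Per-neuron tuning strength within an epoch
#'
#' For each neuron, the maximum over epoch timepoints of its cross-condition
#' firing-rate range, divided by the mean cross-condition range of that neuron
#' over all recorded timepoints. A value of 1 means the neuron is as tuned in
#' this epoch as it is on average across the whole trial.
#'
#' @param resp a [population_response()].
#' @param epoch an [epoch_def()].
#' @return numeric vector, one strength per neuron (0, with a warning, for
#'   neurons whose range is zero at all times).
#' @export
tuning_strength <- function(resp, epoch) {
  stopifnot(inherits(resp, "population_response"), inherits(epoch, "epoch_def"))
  t0 <- resp$events[[epoch$anchor_event]] + epoch$start_offset_ms
  idx <- which(resp$time_ms >= t0 - 1e-9 &
               resp$time_ms < t0 + epoch$duration_ms - 1e-9)
  if (length(idx) == 0) stop("epoch window contains no samples")
  rng_t <- apply(resp$rates, c(1, 3), function(v) max(v) - min(v))  # N x T
  denom <- rowMeans(rng_t)
  s <- apply(rng_t[, idx, drop = FALSE], 1, max) / denom
  if (any(denom == 0)) {
    warning(sum(denom == 0), " neuron(s) with zero range at all times; strength set to 0")
    s[denom == 0] <- 0
  }
  s
}

#' Epoch-preference index
#'
#' A bounded contrast of preparatory versus movement tuning strength. Each
#' epoch's strengths are first normalized by their mean across neurons (so
#' that the globally stronger movement activity does not bias the index), then
#' `index = (S_prep_hat - S_move_hat) / (S_prep_hat + S_move_hat)`. The index
#' is +1 for a neuron tuned only during preparation, -1 for one tuned only
#' during movement, and 0 for a neuron showing the population-average ratio of
#' the two. A bimodal distribution would indicate separate preparatory-only
#' and movement-only subpopulations.
#'
#' @param S_prep,S_move non-negative strength vectors from [tuning_strength()].
#' @return numeric vector in `[-1, 1]`; `NA` where both strengths are zero.
#' @export
epoch_preference_index <- function(S_prep, S_move) {
  stopifnot(length(S_prep) == length(S_move),
            all(S_prep >= 0), all(S_move >= 0))
  if (mean(S_prep) == 0 || mean(S_move) == 0)
    stop("need at least one neuron tuned in each epoch")
  sp <- S_prep / mean(S_prep)
  sm <- S_move / mean(S_move)
  idx <- (sp - sm) / (sp + sm)
  idx[sp + sm == 0] <- NA_real_
  idx
}

#' Hartigan's dip statistic
#'
#' The smallest sup-norm distance between the empirical cdf of `x` and any
#' unimodal cdf, computed exactly by bisection over a band-feasibility
#' characterization (see the methods vignette). Larger values indicate
#' stronger departure from unimodality; the statistic is at most 1/4.
#'
#' @param x numeric vector.
#' @return the dip statistic (0 for fewer than 2 distinct values).
#' @export
dip_statistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(0)
  .dip_stat_cpp(sort(x))
}

#' Dip test for bimodality
#'
#' Tests the observed dip statistic against a Monte Carlo null of uniform
#' samples of the same size (the classical calibration null for the dip test:
#' the uniform is the least-favourable unimodal distribution).
#'
#' @param index numeric vector (at least 10 values).
#' @param n_boot number of uniform null samples (default 10000).
#' @param seed integer seed.
#' @return list with `dip`, `p_value` (fraction of null dips >= observed),
#'   `null` (the null distribution).
#' @export
bimodality_test <- function(index, n_boot = 10000, seed = 1) {
  index <- index[is.finite(index)]
  if (length(index) < 10) stop("need at least 10 values for the dip test")
  d <- dip_statistic(index)
  n <- length(index)
  null <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    .dip_stat_cpp(sort(runif(n)))
  }, numeric(1)))
  list(dip = d, p_value = mean(null >= d), null = null)
}

#' Full correlation-structure analysis of one dataset
#'
#' Convenience wrapper: epoch correlation matrices for the preparatory and
#' movement epochs (excluding zero-variance neurons from either epoch), their
#' across-epoch similarity, and the epoch-preference index with its dip test.
#'
#' @param resp a preprocessed [population_response()].
#' @param prep,move epoch definitions.
#' @param n_boot bootstrap resamples for the similarity CI.
#' @param n_boot_dip uniform null samples for the dip test.
#' @param seed integer seed.
#' @return list with `corr_prep`, `corr_move`, `similarity`, `preference`
#'   (index vector), `dip`.
#' @export
correlation_structure <- function(resp, prep = prep_epoch(),
                                  move = move_epoch(),
                                  n_boot = 1000, n_boot_dip = 10000, seed = 1) {
  ep <- extract_epoch(resp, prep)
  em <- extract_epoch(resp, move)
  cp <- epoch_correlation(ep)
  cm <- epoch_correlation(em)
  sim <- correlation_similarity(cp$corr, cm$corr, n_boot = n_boot, seed = seed)
  idx <- epoch_preference_index(tuning_strength(resp, prep),
                                tuning_strength(resp, move))
  dip <- bimodality_test(idx[is.finite(idx)], n_boot = n_boot_dip,
                         seed = seed + 1L)
  list(corr_prep = cp$corr, corr_move = cm$corr, similarity = sim,
       preference = idx, dip = dip)
}
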