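#' Population state at a fixed time
#'
#' Slices a subspace trajectory at one timepoint (an offset from a task
#' event), returning one state column per condition. Times off the sampling
#' grid are resolved to the nearest sample with a warning.
#'
#' @param traj a [project()] result.
#' @param offset_ms time relative to the anchor event (ms). The canonical
#'   choices are +450 from target onset (end of the preparatory epoch) and
#'   +100 from movement onset (middle of the movement epoch).
#' @param anchor_event one of `"target_onset_ms"`, `"go_cue_ms"`,
#'   `"move_onset_ms"`.
#' @return `d x C` state matrix.
#' @export
state_at <- function(traj, offset_ms, anchor_event = "target_onset_ms") {
  stopifnot(inherits(traj, "projection"))
  t_target <- traj$events[[anchor_event]] + offset_ms
  if (t_target < min(traj$time_ms) || t_target > max(traj$time_ms))
    stop("requested time ", t_target, " ms is outside the trajectory range")
  dists <- abs(traj$time_ms - t_target)
  k <- which.min(dists)
  if (dists[k] > 1e-6)
    warning("time ", t_target, " ms is off the sampling grid; using nearest sample at ",
            traj$time_ms[k], " ms")
  traj$x[, , k, drop = TRUE]
}

#' Least-squares linear map between population states
#'
#' Fits `X_move ~ W X_prep` without an intercept (both state matrices are
#' cross-condition centered by the preprocessing, which is asserted at fit
#' time). The fit quality is a single pooled
#' `R^2 = 1 - ||X_move - W X_prep||_F^2 / ||X_move||_F^2`.
#'
#' @param X_prep `d_prep x C` preparatory states (one column per condition).
#' @param X_move `d_move x C` movement states.
#' @param check_centering warn when `X_move` rows are not cross-condition
#'   centered (disabled internally for leave-one-out subsets, which lose exact
#'   centering by construction).
#' @return list with `W` (`d_move x d_prep`), `r_squared`, `rank_deficient`
#'   flag (minimum-norm solution used when `X_prep` is rank deficient).
#' @export
fit_linear_map <- function(X_prep, X_move, check_centering = TRUE) {
  X_prep <- as.matrix(X_prep); X_move <- as.matrix(X_move)
  C <- ncol(X_prep)
  if (ncol(X_move) != C) stop("state matrices must share conditions")
  if (C < nrow(X_prep) + 1)
    stop("need at least d_prep + 1 conditions to fit the linear map")
  tot <- sum(X_move^2)
  if (check_centering &&
      max(abs(rowMeans(X_move))) > 1e-6 * sqrt(tot / length(X_move)) + 1e-12)
    warning("X_move rows are not cross-condition centered; the no-intercept fit assumes centering")
  # min-norm least squares via the pseudoinverse of X_prep
  sv <- svd(X_prep)
  pos <- sv$d > max(sv$d) * 1e-12
  rank_deficient <- sum(pos) < nrow(X_prep)
  d_inv <- ifelse(pos, 1 / sv$d, 0)
  W <- X_move %*% sv$v %*% (d_inv * t(sv$u))
  r2 <- 1 - sum((X_move - W %*% X_prep)^2) / tot
  list(W = W, r_squared = r2, rank_deficient = rank_deficient)
}

#' Leave-one-out cross-validated R-squared of the linear map
#'
#' Each condition's movement state is predicted by a map fit on the remaining
#' `C - 1` conditions; the pooled `R^2` over held-out predictions measures how
#' well the preparatory-to-movement relation generalizes (it can be negative
#' when there is no relation).
#'
#' @inheritParams fit_linear_map
#' @return the pooled leave-one-out `R^2`.
#' @export
loocv_r2 <- function(X_prep, X_move) {
  X_prep <- as.matrix(X_prep); X_move <- as.matrix(X_move)
  C <- ncol(X_prep)
  if (C < nrow(X_prep) + 2)
    stop("need at least d_prep + 2 conditions for leave-one-out")
  sse <- 0
  for (cc in seq_len(C)) {
    fit <- fit_linear_map(X_prep[, -cc, drop = FALSE], X_move[, -cc, drop = FALSE],
                          check_centering = FALSE)
    sse <- sse + sum((X_move[, cc] - fit$W %*% X_prep[, cc, drop = FALSE])^2)
  }
  1 - sse / sum(X_move^2)
}

#' Condition-shuffle null for the linear map
#'
#' Shuffles each preparatory dimension's values independently across
#' conditions, refits the map, and records the shuffled `R^2`; the one-tailed
#' p-value is the fraction of shuffles with `R^2` at least as large as the
#' observed fit.
#'
#' @inheritParams fit_linear_map
#' @param n_shuffles number of shuffles (at least 100).
#' @param seed integer seed.
#' @return list with `r_squared` (observed), `distribution`, `p_value`,
#'   `median`, `ci95`, `degenerate` flag (set when the preparatory states have
#'   no cross-condition spread, which shuffles cannot disturb).
#' @export
shuffle_null_r2 <- function(X_prep, X_move, n_shuffles = 1000, seed = 1) {
  X_prep <- as.matrix(X_prep); X_move <- as.matrix(X_move)
  if (n_shuffles < 100) stop("`n_shuffles` must be at least 100")
  C <- ncol(X_prep)
  obs <- fit_linear_map(X_prep, X_move)$r_squared
  degenerate <- all(apply(X_prep, 1, function(r) max(r) - min(r)) == 0)
  if (degenerate)
    warning("preparatory states are identical across conditions; shuffle null is degenerate")
  dist <- withr::with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    Xs <- t(apply(X_prep, 1, sample))
    fit_linear_map(Xs, X_move)$r_squared
  }, numeric(1)))
  list(r_squared = obs, distribution = dist,
       p_value = mean(dist >= obs),
       median = median(dist),
       ci95 = unname(quantile(dist, c(0.025, 0.975))),
       degenerate = degenerate)
}

#' Preparatory-to-movement linkage analysis
#'
#' Projects the population response onto the identified preparatory and
#' movement subspaces, takes the late-preparatory state (450 ms after target
#' onset) and the mid-movement state (100 ms after movement onset), and
#' quantifies their linear relation: fit `R^2`, leave-one-out `R^2`, and the
#' condition-shuffle null.
#'
#' @param resp a preprocessed [population_response()].
#' @param pair an [identify_subspaces()] result.
#' @param t_prep_ms preparatory state time, ms after target onset.
#' @param t_move_ms movement state time, ms after movement onset.
#' @param n_shuffles shuffle count for the null.
#' @param seed integer seed.
#' @return object of class `link_result`: `W`, `r_squared`, `r_squared_loocv`,
#'   `shuffle` (the [shuffle_null_r2()] result), `p_value`, `t_prep_ms`,
#'   `t_move_ms`, plus the state matrices `X_prep`, `X_move`.
#' @export
link_analysis <- function(resp, pair, t_prep_ms = 450, t_move_ms = 100,
                          n_shuffles = 1000, seed = 1) {
  stopifnot(inherits(pair, "subspace_pair"))
  X_prep <- state_at(project(resp, pair$Q_prep), t_prep_ms, "target_onset_ms")
  X_move <- state_at(project(resp, pair$Q_move), t_move_ms, "move_onset_ms")
  X_prep <- matrix(X_prep, nrow = pair$d_prep)
  X_move <- matrix(X_move, nrow = pair$d_move)
  fit <- fit_linear_map(X_prep, X_move)
  shuf <- shuffle_null_r2(X_prep, X_move, n_shuffles = n_shuffles, seed = seed)
  structure(list(W = fit$W, r_squared = fit$r_squared,
                 r_squared_loocv = loocv_r2(X_prep, X_move),
                 shuffle = shuf, p_value = shuf$p_value,
                 t_prep_ms = t_prep_ms, t_move_ms = t_move_ms,
                 X_prep = X_prep, X_move = X_move),
            class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat(sprintf("<link_result> R^2 = %.4f, LOOCV R^2 = %.4f\n",
              x$r_squared, x$r_squared_loocv))
  cat(sprintf("  shuffle null median %.4f, 95%% CI [%.4f, %.4f], one-tailed p = %.4g\n",
              x$shuffle$median, x$shuffle$ci95[1], x$shuffle$ci95[2], x$p_value))
  invisible(x)
}
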