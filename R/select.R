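#' Sample-selection configuration
#'
#' @param n_max maximum number of retained samples per channel (even).
#' @param window half-width `n` of the score/energy windows, in samples
#'   (the window spans `2n + 1` samples).
#' @param energy_threshold angular-rate energy threshold `Eth` (rad^2/s^2)
#'   above which accelerometer samples are discarded outright.
#' @param coherence_cutoff coherence level above which a sample counts as
#'   redundant with the dominant direction of the acceleration-constraint
#'   matrix (fixed at 0.5 in the method; exposed for experimentation).
#' @return a list of class `selection_config`.
#' @export
selection_config <- function(n_max = 1000, window = 21,
                             energy_threshold = 1, coherence_cutoff = 0.5) {
  stopifnot(n_max >= 2, n_max %% 2 == 0, window >= 1, energy_threshold > 0,
            coherence_cutoff > 0, coherence_cutoff < 1)
  structure(list(n_max = as.integer(n_max), window = as.integer(window),
                 energy_threshold = energy_threshold,
                 coherence_cutoff = coherence_cutoff),
            class = "selection_config")
}

# signed value of smallest magnitude within [k-n, k+n] (truncated at edges),
# earliest index winning ties
win_min_signed <- function(dw, n) {
  N <- length(dw)
  if (N == 0L) return(numeric(0))
  av <- c(rep(Inf, n), abs(dw), rep(Inf, n))
  sv <- c(rep(0, n), dw, rep(0, n))
  best <- rep(Inf, N)
  out <- numeric(N)
  for (o in -n:n) {
    idx <- seq_len(N) + o + n
    cand <- av[idx]
    upd <- cand < best
    if (any(upd)) {
      best[upd] <- cand[upd]
      out[upd] <- sv[idx][upd]
    }
  }
  out
}

#' Gyroscope informativeness score
#'
#' The per-sample difference in angular-rate magnitude,
#' \eqn{\Delta\omega(k) = \lVert y_{\omega,1}(t_k)\rVert - \lVert
#' y_{\omega,2}(t_k)\rVert}, screened for outliers by taking, at each
#' sample, the signed \eqn{\Delta\omega} of smallest magnitude within a
#' window of `2n + 1` samples (truncated at the recording edges).  Positive
#' scores mark sensor-1-dominant motion, negative scores sensor-2-dominant
#' motion; stationary and stiff-joint motion scores are zero up to noise.
#'
#' @param recording a recording tibble.
#' @param window window half-width `n` in samples.
#' @return a numeric score per sample.
#' @export
gyro_score <- function(recording, window = 21) {
  assert_recording(recording)
  dw <- sqrt(recording$g1x^2 + recording$g1y^2 + recording$g1z^2) -
    sqrt(recording$g2x^2 + recording$g2y^2 + recording$g2z^2)
  win_min_signed(dw, window)
}

select_gyro_from_scores <- function(scores, n_max) {
  N <- length(scores)
  if (N <= n_max) return(seq_len(N))
  ord <- order(-scores, seq_len(N))
  sort(c(head(ord, n_max / 2), tail(ord, n_max / 2)))
}

#' Select gyroscope samples
#'
#' Keeps the `n_max/2` most positive and `n_max/2` most negative scores, so
#' the retained set contains excitation of both sensors; when `N <= n_max`
#' all samples are kept.
#'
#' @param recording a recording tibble.
#' @param cfg a [selection_config()].
#' @return an integer vector of retained row indices, sorted.
#' @export
select_gyro <- function(recording, cfg = selection_config()) {
  select_gyro_from_scores(gyro_score(recording, cfg$window), cfg$n_max)
}

#' Windowed angular-rate energy
#'
#' The mean squared gyroscope magnitude of sensor `sensor` over the
#' `2n + 1`-sample window centred at each sample; samples within `n` of
#' either edge get `+Inf` (no full window exists, so they are never
#' selected).  Low energy marks a stationary sensor -- the regime where the
#' approximate acceleration constraint is accurate.
#'
#' @param recording a recording tibble.
#' @param sensor 1 or 2.
#' @param window window half-width `n` in samples.
#' @return a numeric energy per sample (rad^2/s^2).
#' @export
angular_rate_energy <- function(recording, sensor, window = 21) {
  assert_recording(recording)
  sq <- if (sensor == 1L) {
    recording$g1x^2 + recording$g1y^2 + recording$g1z^2
  } else {
    recording$g2x^2 + recording$g2y^2 + recording$g2z^2
  }
  k <- 2L * window + 1L
  if (length(sq) < k) return(rep(Inf, length(sq)))
  e <- as.numeric(stats::filter(sq, rep(1 / k, k), sides = 2))
  e[!is.finite(e)] <- Inf
  e
}

#' @rdname angular_rate_energy
#' @details `accel_penalty()` is the elementwise minimum of the two
#'   sensors' energies: one stationary sensor suffices for the acceleration
#'   constraint to be usable.
#' @export
accel_penalty <- function(recording, window = 21) {
  pmin(angular_rate_energy(recording, 1L, window),
       angular_rate_energy(recording, 2L, window))
}

# rows of the acceleration-constraint matrix A: (y_a1^T, -y_a2^T)
accel_rows <- function(recording, idx = seq_len(nrow(recording))) {
  cbind(recording$a1x[idx], recording$a1y[idx], recording$a1z[idx],
        -recording$a2x[idx], -recording$a2y[idx], -recording$a2z[idx])
}

#' Coherence with the dominant direction of the constraint matrix
#'
#' For each row \eqn{A_k} of the acceleration-constraint matrix, the
#' normalized alignment \eqn{c_k = |A_k w_1| / (\lVert A_k\rVert \lVert
#' w_1\rVert)} with the first right-singular vector \eqn{w_1} of `A`:
#' 1 when the row is parallel to the dominant direction (redundant
#' information), 0 when orthogonal (novel information).  Zero-norm rows get
#' coherence 0.
#'
#' @param A a numeric matrix with 6 columns (rows \eqn{(y_{a,1}^\top,
#'   -y_{a,2}^\top)}).
#' @return a numeric vector in `[0, 1]`, one value per row.
#' @export
coherence <- function(A) {
  stopifnot(is.matrix(A), ncol(A) == 6L)
  norms <- row_norms(A)
  if (all(norms == 0)) stop("all rows have zero norm", call. = FALSE)
  w1 <- svd(A, nu = 0L, nv = 1L)$v[, 1L]
  ck <- abs(drop(A %*% w1)) / ifelse(norms > 0, norms, Inf)
  pmin(1, ck)
}

# iterative removal: drop the worst-penalty sample among those coherent with
# the dominant direction, recomputing the SVD after each removal; when no
# sample is coherent (the loop would not terminate otherwise), drop the
# worst-penalty sample overall and count the fallback
whittle_accel <- function(recording, idx, sa, cfg) {
  fallbacks <- 0L
  removed <- integer(0)
  while (length(idx) > cfg$n_max) {
    A <- accel_rows(recording, idx)
    ck <- coherence(A)
    elig <- which(ck > cfg$coherence_cutoff)
    if (length(elig) == 0L) {
      elig <- seq_along(idx)
      fallbacks <- fallbacks + 1L
    }
    worst <- elig[order(-sa[idx[elig]], idx[elig])][1L]
    removed <- c(removed, idx[worst])
    idx <- idx[-worst]
  }
  list(idx = idx, removed = removed, fallbacks = fallbacks)
}

#' Select accelerometer samples
#'
#' First discards every sample whose angular-rate energy penalty exceeds
#' `energy_threshold` (likely violation of the acceleration constraint);
#' then, while more than `n_max` samples remain, repeatedly removes the
#' worst-penalty sample among those whose rows are coherent (above the
#' cutoff) with the dominant right-singular direction of the retained
#' constraint matrix -- keeping novel directions and thereby the separation
#' between the matrix's column space and the null space that encodes the
#' axis.
#'
#' @param recording a recording tibble.
#' @param cfg a [selection_config()].
#' @return an integer vector of retained row indices, sorted; the number of
#'   times the coherence fallback fired is in `attr(, "fallbacks")`.
#' @export
select_accel <- function(recording, cfg = selection_config()) {
  sa <- accel_penalty(recording, cfg$window)
  idx <- which(sa <= cfg$energy_threshold)
  res <- whittle_accel(recording, idx, sa, cfg)
  structure(sort(res$idx), fallbacks = res$fallbacks)
}

#' Incremental (online) sample selection
#'
#' `selection_state()` creates an empty state; `update_selection()` brings
#' it up to date with a cumulative recording, computing scores and energies
#' only for samples not seen before (windows straddling the old/new
#' boundary are recomputed).  Gyroscope selection is re-run over all cached
#' scores -- equivalent to batch selection, since a sample outside both ends
#' of the sorted score list can never re-enter them.  Accelerometer
#' whittling runs over the previously retained samples plus the newly
#' admissible ones; samples removed by the coherence loop are not
#' revisited.
#'
#' @return `selection_state()`: an empty object of class `selection_state`
#'   with cached per-sample scores, retained index sets per channel, and
#'   the coherence-fallback counter.
#' @export
selection_state <- function() {
  structure(list(
    n_seen = 0L,
    score = numeric(0),          # cached gyro scores s_omega
    sa = numeric(0),             # cached accel penalties s_a
    gyro_retained = integer(0),
    accel_retained = integer(0),
    accel_removed = integer(0),  # removed by the coherence loop
    fallbacks = 0L
  ), class = "selection_state")
}

#' @rdname selection_state
#' @param state a `selection_state`.
#' @param recording the cumulative recording observed so far (the
#'   previously seen samples must be its leading rows).
#' @param cfg a [selection_config()].
#' @return `update_selection()`: the updated state.
#' @export
update_selection <- function(state, recording, cfg = selection_config()) {
  stopifnot(inherits(state, "selection_state"))
  assert_recording(recording)
  N <- nrow(recording)
  if (N < state$n_seen) {
    stop("cumulative recording shorter than previously seen data",
         call. = FALSE)
  }
  if (N == state$n_seen) return(state)
  n <- cfg$window
  lo <- max(1L, state$n_seen - n + 1L)  # first sample whose window changed

  # recompute gyro scores on the affected slice, with left context
  ctx <- max(1L, lo - n)
  slice <- recording[ctx:N, ]
  sc <- gyro_score(slice, n)
  state$score <- c(state$score[seq_len(lo - 1L)], sc[(lo - ctx + 1L):(N - ctx + 1L)])

  # recompute accel penalties on the affected slice (full windows only)
  sa_slice <- accel_penalty(slice, n)
  state$sa <- c(state$sa[seq_len(lo - 1L)], sa_slice[(lo - ctx + 1L):(N - ctx + 1L)])

  state$gyro_retained <- select_gyro_from_scores(state$score, cfg$n_max)

  fresh <- which(state$sa <= cfg$energy_threshold)
  fresh <- fresh[fresh >= lo]
  cand <- sort(union(
    setdiff(state$accel_retained, which(state$sa > cfg$energy_threshold)),
    setdiff(fresh, state$accel_removed)
  ))
  res <- whittle_accel(recording, cand, state$sa, cfg)
  state$accel_retained <- sort(res$idx)
  state$accel_removed <- c(state$accel_removed, res$removed)
  state$fallbacks <- state$fallbacks + res$fallbacks

  state$n_seen <- N
  state
}
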