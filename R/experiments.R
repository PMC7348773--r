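#' Weight-robustness experiment
#'
#' For each weight ratio `w0`, estimates the joint axis from every
#' initialization of the deterministic 36-point grid on each listed motion
#' preset and records the RMSAE/MAXAE versus the true axes.  The sweep
#' reproduces the characteristic robustness profile: errors are small over
#' a wide band of weights, while extreme gyroscope dominance makes the two
#' sign pairings numerically indistinguishable and errors climb towards
#' 90 degrees as roughly half the starts end on the wrong pairing.
#'
#' @param w0_values numeric vector of weight ratios.
#' @param motions motion preset ids (see [motion_catalog()]).
#' @param cfg a [sim_config()].
#' @param duration per-motion duration, seconds.
#' @return a tibble of class `weight_sweep`: `w0`, `motion`, `rmsae`,
#'   `maxae`, `frac_wrong_pairing`.
#' @export
experiment_weight_sweep <- function(w0_values, motions = c(4, 6),
                                    cfg = sim_config(seed = 1),
                                    duration = 20) {
  starts <- grid_initializations()
  out <- purrr::map_dfr(motions, function(m) {
    rec <- simulate_motion(m, cfg, duration)
    purrr::map_dfr(w0_values, function(w0) {
      ec <- estimator_config(w0 = w0)
      fits <- purrr::pmap(starts, function(theta1, phi1, theta2, phi2) {
        estimate_joint_axis(rec, axis_params(theta1, phi1, theta2, phi2), ec)
      })
      err <- axis_errors(fits, cfg$j1, cfg$j2)
      tibble::tibble(
        w0 = w0, motion = m,
        rmsae = sqrt(mean(c(err$ad1, err$ad2)^2)),
        maxae = max(c(err$ad1, err$ad2)),
        frac_wrong_pairing = mean(err$wrong_pairing)
      )
    })
  })
  class(out) <- c("weight_sweep", class(out))
  out
}

#' Sample-selection benefit experiment
#'
#' Streams a recording through the online sample selection at each sample
#' budget, then estimates the axes once from the final retained sets (best
#' cost over a small set of shared random starts) and compares against
#' estimation on all samples (`n_max = NA` row).
#'
#' @param recording a recording tibble (true axes in `attr(,"truth")` or
#'   given explicitly).
#' @param n_max_values integer sample budgets.
#' @param true_j1,true_j2 true axes for the error columns.
#' @param est_cfg an [estimator_config()].
#' @param window,energy_threshold selection parameters.
#' @param n_starts number of shared random starts.
#' @param batch_seconds selection update granularity.
#' @return a tibble: `n_max` (`NA` = all samples), `ad1`, `ad2`, `n_gyro`,
#'   `n_accel`, plus the retained gyro index set per row in the list column
#'   `gyro_idx`.
#' @export
experiment_sample_size <- function(recording, n_max_values = c(1000, 500),
                                   true_j1 = attr(recording, "truth")$j1,
                                   true_j2 = attr(recording, "truth")$j2,
                                   est_cfg = estimator_config(),
                                   window = 21, energy_threshold = 1,
                                   n_starts = 5, batch_seconds = 1) {
  starts <- purrr::map(seq_len(n_starts), ~random_start())
  t_rel <- recording$t - recording$t[1L]
  ends <- seq(batch_seconds, max(t_rel) + batch_seconds, by = batch_seconds)

  fit_best <- function(d) {
    fits <- purrr::map(starts, ~estimate_joint_axis(d, .x, est_cfg))
    fits[[which.min(purrr::map_dbl(fits, "final_cost"))]]
  }
  row_for <- function(n_max, gi, ai) {
    fit <- fit_best(hinge_data(recording, gi, ai))
    err <- axis_errors(fit, true_j1, true_j2)
    tibble::tibble(n_max = n_max, ad1 = err$ad1, ad2 = err$ad2,
                   n_gyro = length(gi), n_accel = length(ai),
                   gyro_idx = list(gi))
  }

  sel_rows <- purrr::map_dfr(n_max_values, function(nm) {
    cfg <- selection_config(n_max = nm, window = window,
                            energy_threshold = energy_threshold)
    state <- selection_state()
    for (te in ends) {
      m <- sum(t_rel < te)
      if (m > state$n_seen) state <- update_selection(state, recording[seq_len(m), ], cfg)
    }
    row_for(nm, state$gyro_retained, state$accel_retained)
  })
  all_row <- row_for(NA_integer_, seq_len(nrow(recording)),
                     seq_len(nrow(recording)))
  dplyr::bind_rows(sel_rows, all_row)
}

#' Bias-robustness experiment
#'
#' Repeats the full streaming calibration on a scenario with and without
#' artificial constant sensor biases of fixed magnitude and randomized
#' direction, and summarizes the accepted estimates' errors as
#' RMSAE/MAXAE.  With biases the acceptance threshold is tightened, as a
#' conservative guard against premature acceptance of bias-induced minima.
#'
#' @param scenario scenario name for [simulate_scenario()].
#' @param n_runs number of estimation rounds per condition.
#' @param accel_bias_mag,gyro_bias_mag bias magnitudes (m/s^2, rad/s).
#' @param cfg base [sim_config()].
#' @param duration per-motion duration, seconds.
#' @param n_max sample budget.
#' @param e_max_bias acceptance threshold used in the biased condition,
#'   degrees (the unbiased condition uses 3 degrees).
#' @param n_min consecutive-consistency requirement.
#' @param seed integer seed.
#' @return a tibble: `biased`, `run`, `accepted`, `t_accept`, `ad1`, `ad2`.
#' @export
experiment_bias_robustness <- function(scenario = "scenario2", n_runs = 5,
                                       accel_bias_mag = 1,
                                       gyro_bias_mag = pi / 180,
                                       cfg = sim_config(), duration = 10,
                                       n_max = 500, e_max_bias = 1,
                                       n_min = 10, seed = 1) {
  random_unit <- function() {
    v <- rnorm(3L)
    v / sqrt(sum(v^2))
  }
  withr::with_seed(seed, {
    purrr::map_dfr(c(FALSE, TRUE), function(biased) {
      purrr::map_dfr(seq_len(n_runs), function(run) {
        run_cfg <- cfg
        run_cfg$seed <- NULL
        if (biased) {
          run_cfg$accel_bias1 <- accel_bias_mag * random_unit()
          run_cfg$accel_bias2 <- accel_bias_mag * random_unit()
          run_cfg$gyro_bias1 <- gyro_bias_mag * random_unit()
          run_cfg$gyro_bias2 <- gyro_bias_mag * random_unit()
        }
        rec <- simulate_scenario(scenario, run_cfg, duration)
        cal <- run_acceptance(
          rec,
          sel_cfg = selection_config(n_max = n_max),
          est_cfg = estimator_config(),
          unc_cfg = uncertainty_config(
            e_max = if (biased) e_max_bias else 3, n_min = n_min))
        if (cal$accepted) {
          fitlike <- list(j1_hat = cal$j1, j2_hat = cal$j2)
          class(fitlike) <- "axis_fit"
          err <- axis_errors(fitlike, cfg$j1, cfg$j2)
          tibble::tibble(biased = biased, run = run, accepted = TRUE,
                         t_accept = cal$t_accept,
                         ad1 = err$ad1, ad2 = err$ad2)
        } else {
          tibble::tibble(biased = biased, run = run, accepted = FALSE,
                         t_accept = NA_real_,
                         ad1 = NA_real_, ad2 = NA_real_)
        }
      })
    })
  })
}
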