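#' Simulate behavioral outcomes of the signal-detection observer
#'
#' Draws trial outcomes from an equal-variance Gaussian signal-detection
#' observer with sensitivity `dprime` and criterion `criterion`:
#' `P(hit | nonmatch) = pnorm(dprime / 2 - criterion)` and
#' `P(FA | match) = pnorm(-dprime / 2 - criterion)`. Rewarded outcomes (hit,
#' CR) receive a gamma-distributed juice volume whose mean depends on the
#' block reward condition and, separately, on whether the trial is a hit or a
#' CR (distinct hit/CR payoffs keep the criterion near zero and decorrelate
#' single-trial reward from the block condition).
#'
#' @param trial_type Character vector, `"match"` or `"nonmatch"`, one per
#'   trial.
#' @param dprime Instantaneous sensitivity per trial (recycled if scalar).
#' @param criterion Observer criterion (scalar).
#' @param reward_cond `"small"` or `"large"`, per trial (recycled).
#' @param config A [session_config()] supplying reward distributions.
#'
#' @return A tibble with columns `outcome` (`hit`/`miss`/`CR`/`FA`),
#'   `saccade` (1 on hit and FA), and `reward_ul` (0 when unrewarded).
#' @export
#' @examples
#' set.seed(1)
#' simulate_behavior(c("nonmatch", "match"), dprime = 2)
simulate_behavior <- function(trial_type, dprime, criterion = 0,
                              reward_cond = "large",
                              config = session_config()) {
  n <- length(trial_type)
  dprime <- rep_len(dprime, n)
  reward_cond <- rep_len(reward_cond, n)
  stopifnot(all(trial_type %in% c("match", "nonmatch")),
            all(reward_cond %in% c("small", "large")))

  nonmatch <- trial_type == "nonmatch"
  p_sacc <- ifelse(nonmatch,
                   stats::pnorm(dprime / 2 - criterion),
                   stats::pnorm(-dprime / 2 - criterion))
  sacc <- as.integer(stats::runif(n) < p_sacc)
  outcome <- ifelse(nonmatch,
                    ifelse(sacc == 1, "hit", "miss"),
                    ifelse(sacc == 1, "FA", "CR"))

  mean_cond <- ifelse(reward_cond == "large",
                      config$reward_mean_large, config$reward_mean_small)
  mean_rwd <- ifelse(outcome == "hit", mean_cond * config$reward_hit_factor,
                     ifelse(outcome == "CR", mean_cond * config$reward_cr_factor, 0))
  shape <- 1 / config$reward_cv^2
  reward <- numeric(n)
  paid <- mean_rwd > 0
  reward[paid] <- stats::rgamma(sum(paid), shape = shape,
                                rate = shape / mean_rwd[paid])
  tibble::tibble(outcome = outcome, saccade = sacc, reward_ul = reward)
}

#' Draw negative-binomial spike counts
#'
#' Counts follow `NB(mu, theta)` with `E[y] = mu` and
#' `Var[y] = mu + mu^2 / theta`; `theta -> Inf` recovers the Poisson limit.
#' When `eta` (the linear predictor) is given instead of `mu`, the mean is
#' `exp(eta)` and an overflowing predictor raises a generation error naming
#' the offending trial.
#'
#' @param mu Mean counts (vector), or `NULL` if `eta` is supplied.
#' @param theta NB shape parameter(s), positive.
#' @param eta Optional linear predictor; `mu = exp(eta)`.
#' @return Integer vector of counts.
#' @export
#' @examples
#' set.seed(1)
#' mean(simulate_counts(mu = rep(10, 1e4), theta = 2))
simulate_counts <- function(mu = NULL, theta, eta = NULL) {
  if (is.null(mu)) {
    if (any(!is.finite(eta)) || any(eta > 700)) {
      bad <- which(!is.finite(eta) | eta > 700)[1]
      stop("generation error: linear predictor overflows exp() at row ", bad,
           call. = FALSE)
    }
    mu <- exp(eta)
  }
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("generation error: non-finite or negative mean", call. = FALSE)
  }
  if (any(theta <= 0)) stop("configuration error: theta must be > 0", call. = FALSE)
  stats::rnbinom(length(mu), size = theta, mu = mu)
}

#' Simulate the trial-by-trial pupil arousal state
#'
#' The arousal state relaxes toward a reward-condition level with
#' direction-dependent trial constants (`tau_pupil_rise` after small-to-large
#' transitions, `tau_pupil_decay` after large-to-small), plus Gaussian
#' trial-to-trial noise. Each trial carries a trace sampled at
#' `config$pupil_hz` over `config$trace_window` (ms relative to sample
#' onset): state + a stimulus-evoked component (alpha-function time course
#' after onset, amplitude `pupil_evoked`).
#'
#' @param reward_cond Character vector of block reward conditions, one entry
#'   per trial, in session order.
#' @param config A [session_config()].
#' @param start_state Arousal state before the first trial; defaults to the
#'   first condition's asymptote.
#' @param noise_sd Overrides `config$pupil_noise_sd` when given.
#'
#' @return A list: `state` (per-trial arousal state, noiseless dynamics +
#'   noise), `traces` (trials x samples matrix, normalized units), `time`
#'   (sample times, ms), `mean_area` (per-trial mean over 0-400 ms).
#' @export
simulate_pupil <- function(reward_cond, config = session_config(),
                           start_state = NULL, noise_sd = NULL) {
  stopifnot(all(reward_cond %in% c("small", "large")))
  noise_sd <- noise_sd %||% config$pupil_noise_sd
  target <- ifelse(reward_cond == "large", config$pupil_large, config$pupil_small)
  start <- start_state %||% target[1]
  state <- exp_relax(target, config$tau_pupil_rise, config$tau_pupil_decay, start)
  n <- length(state)
  state_noisy <- state + stats::rnorm(n, 0, noise_sd)

  dt <- 1000 / config$pupil_hz
  time <- seq(config$trace_window[1], config$trace_window[2], by = dt)
  # evoked component: alpha function peaking ~250 ms after sample onset
  tt <- pmax(time, 0)
  evoked <- config$pupil_evoked * (tt / 250) * exp(1 - tt / 250)
  traces <- outer(state_noisy, rep(1, length(time))) +
    outer(rep(1, n), evoked)
  win <- time >= 0 & time < 400
  list(state = state_noisy, state_noiseless = state,
       traces = traces, time = time,
       mean_area = rowMeans(traces[, win, drop = FALSE]))
}

#' Generate a complete synthetic recording session
#'
#' Produces one session of the blocked reward-size task with known ground
#' truth for every recoverable parameter. Generation runs in two passes:
#' first the behavioral/physiological sequence (block schedule, aborted
#' trials, signal-detection outcomes with exponential d' dynamics, rewards,
#' pupil state and binocular raw traces), then spike counts drawn from each
#' neuron's negative-binomial GLM using exactly the predictors the analysis
#' will reconstruct (session-normalized pupil area and reward history), so
#' fitted coefficients are directly comparable to truth.
#'
#' @param config A [session_config()].
#' @param seed Integer seed; the session is a deterministic function of
#'   `(config, seed)`.
#' @param spike_times If `TRUE` (default), per-trial spike times are placed
#'   for the sample period (baseline Poisson plus a response-shaped evoked
#'   density carrying the negative-binomial sample-window count), enabling
#'   PSTH, Fano, screening, and pupil-coupling analyses. Set `FALSE` for
#'   count-only sessions (much faster when simulating many sessions).
#'
#' @return A list with class `"v4_session"`: `trials` (trial table including
#'   aborted rows), `counts_sample` and `counts_test1` (completed-trials x
#'   neurons integer matrices), `pupil` (normalized binocular-average traces,
#'   completed trials x samples), `pupil_raw` (per-eye raw traces, device
#'   units), `pupil_time`, `spikes` (tibble trial/unit/time in ms, or NULL),
#'   `units` (per-neuron RF geometry, true coefficients, theta), `truth`
#'   (config plus reward-history kernel and derived quantities), `seed`.
#' @export
#' @examples
#' s <- generate_session(session_config(n_blocks = 2, n_neurons = 3,
#'                                      trials_per_block = 30), seed = 1,
#'                       spike_times = FALSE)
#' dplyr::count(completed_trials(s), reward_cond)
generate_session <- function(config = session_config(), seed,
                             spike_times = TRUE) {
  validate_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1)
  with_seed(seed, generate_session_impl(config, seed, spike_times))
}

generate_session_impl <- function(cfg, seed, spike_times) {
  n_blk <- cfg$n_blocks
  tpb <- cfg$trials_per_block
  conds <- rep(c("small", "large"), length.out = n_blk)

  ## ---- pass 1: behavior ----
  rows <- vector("list", n_blk)
  d_state <- cfg$dprime_small            # first block is small reward
  for (b in seq_len(n_blk)) {
    cond <- conds[b]
    asym <- if (cond == "large") cfg$dprime_large else cfg$dprime_small
    tau <- if (asym >= d_state) cfg$tau_dprime_rise else cfg$tau_dprime_decay
    d_start <- d_state
    p_abort_base <- if (cond == "large") cfg$p_abort_large else cfg$p_abort_small

    blk <- vector("list", tpb * 2L)
    k <- 0L
    for (t in seq_len(tpb)) {
      d_t <- asym + (d_start - asym) * exp(-t / tau)
      # abort probability has an early-block transient on entering small blocks
      p_ab <- p_abort_base +
        if (cond == "small" && b > 1) 0.08 * exp(-t / 4.2) else 0
      n_ab <- stats::rgeom(1, prob = 1 - min(p_ab, 0.95))
      if (n_ab > 0) {
        k <- k + 1L
        blk[[k]] <- tibble::tibble(block = b, trial_in_block = t,
                                   reward_cond = cond, n_row = n_ab,
                                   aborted = TRUE, dprime_t = NA_real_)
      }
      k <- k + 1L
      blk[[k]] <- tibble::tibble(block = b, trial_in_block = t,
                                 reward_cond = cond, n_row = 1L,
                                 aborted = FALSE, dprime_t = d_t)
      d_state <- d_t
    }
    rows[[b]] <- dplyr::bind_rows(blk[seq_len(k)])
  }
  sched <- dplyr::bind_rows(rows)
  sched <- sched[rep(seq_len(nrow(sched)), sched$n_row), ]
  sched$n_row <- NULL

  n_all <- nrow(sched)
  sched$trial_type <- sample(c("match", "nonmatch"), n_all, replace = TRUE)
  sched$test_side <- sample(c("inRF", "outRF"), n_all, replace = TRUE)
  sched$sample_ori <- sample(cfg$sample_oris, n_all, replace = TRUE)
  sched$dori <- as.integer(sched$trial_type == "nonmatch")
  sched$test1_ori <- sched$sample_ori + sched$dori * cfg$delta_ori

  comp <- !sched$aborted
  beh <- simulate_behavior(sched$trial_type[comp], sched$dprime_t[comp],
                           cfg$criterion, sched$reward_cond[comp], cfg)
  sched$outcome <- "aborted"
  sched$outcome[comp] <- beh$outcome
  sched$saccade <- NA_integer_
  sched$saccade[comp] <- beh$saccade
  sched$reward_ul <- 0
  sched$reward_ul[comp] <- beh$reward_ul
  sched$trial <- NA_integer_
  sched$trial[comp] <- seq_len(sum(comp))

  ## ---- pupil (completed trials only carry traces) ----
  pup <- simulate_pupil(sched$reward_cond[comp], cfg)
  # binocular raw traces in device units (affine per eye + sensor noise)
  raw_left <- 900 + 700 * pup$traces +
    matrix(stats::rnorm(length(pup$traces), 0, 2), nrow = nrow(pup$traces))
  raw_right <- 1100 + 650 * pup$traces +
    matrix(stats::rnorm(length(pup$traces), 0, 2), nrow = nrow(pup$traces))
  norm <- normalize_pupil(list(left = raw_left, right = raw_right),
                          time = pup$time)
  sched$pupil_mean <- NA_real_
  sched$pupil_mean[comp] <- norm$mean_area

  ## ---- units: RF geometry + GLM truth ----
  nn <- cfg$n_neurons
  rf_x <- cfg$gabor_center_inRF[1] + stats::rnorm(nn, 0, cfg$rf_scatter_sd)
  rf_y <- cfg$gabor_center_inRF[2] + stats::rnorm(nn, 0, cfg$rf_scatter_sd)
  rf_s <- pmax(stats::rnorm(nn, cfg$rf_sigma_mean, cfg$rf_sigma_sd), 0.3)
  overlap <- vapply(seq_len(nn), function(i) {
    density_overlap(rf_model(rf_x[i], rf_y[i], rf_s[i], rf_s[i], 0),
                    rf_model(cfg$gabor_center_inRF[1], cfg$gabor_center_inRF[2],
                             cfg$gabor_sigma, cfg$gabor_sigma, 0))
  }, numeric(1))

  b0 <- stats::rnorm(nn, cfg$intercept_mean, cfg$intercept_sd)
  b_ori <- stats::rnorm(nn, cfg$beta_ori_mean, cfg$beta_ori_sd)
  b_pupil <- if (cfg$intensity_coupling == "overlap") {
    cfg$beta_pupil_mean * overlap / max(mean(overlap), 1e-6) +
      stats::rnorm(nn, 0, cfg$beta_pupil_sd / 4)
  } else {
    stats::rnorm(nn, cfg$beta_pupil_mean, cfg$beta_pupil_sd)
  }
  b_sacc <- stats::rnorm(nn, cfg$beta_saccade_mean, cfg$beta_saccade_sd)
  b_dori <- stats::rnorm(nn, cfg$beta_dori_mean, cfg$beta_dori_sd)
  theta <- stats::rgamma(nn, shape = cfg$theta_shape, rate = cfg$theta_rate)
  # 10-lag reward-history kernel, exponentially decaying over lags
  rh_kernel <- matrix(cfg$beta_reward_scale * exp(-(0:9) / 3),
                      nrow = nn, ncol = 10, byrow = TRUE)
  # log-rate tuning over the four possible test-1 orientations
  t1_oris <- sort(unique(c(cfg$sample_oris, cfg$sample_oris + cfg$delta_ori)))
  tuning <- matrix(stats::rnorm(nn * length(t1_oris), 0, cfg$tuning_sd),
                   nrow = nn, dimnames = list(NULL, paste0("ori_", t1_oris)))

  units <- tibble::tibble(
    unit = seq_len(nn),
    isolation = sample(c("single", "multi"), nn, replace = TRUE,
                       prob = c(0.3, 0.7)),
    rf_x = rf_x, rf_y = rf_y, rf_sx = rf_s, rf_sy = rf_s, rf_rho = 0,
    overlap = overlap, theta = theta,
    b0 = b0, b_ori = b_ori, b_pupil = b_pupil,
    b_saccade = b_sacc, b_dori = b_dori
  )

  ## ---- pass 2: spike counts from the NB-GLM ground truth ----
  ct <- sched[comp, ]
  n_c <- nrow(ct)
  rhist <- reward_history(ct$reward_ul, n_lags = 10)   # session-normalized
  rhist[is.na(rhist)] <- 0       # early trials lack full history; they are
                                 # excluded from fitting but still need counts
  ori_ind <- as.integer(ct$sample_ori == max(cfg$sample_oris))

  counts_sample <- matrix(0L, n_c, nn)
  counts_test1 <- matrix(0L, n_c, nn)
  for (i in seq_len(nn)) {
    eta_s <- b0[i] + b_ori[i] * ori_ind + b_pupil[i] * ct$pupil_mean +
      as.vector(rhist %*% rh_kernel[i, ]) + b_sacc[i] * ct$saccade
    counts_sample[, i] <- simulate_counts(theta = theta[i], eta = eta_s)
    tune_val <- tuning[i, match(ct$test1_ori, t1_oris)]
    eta_t <- b0[i] + tune_val + b_pupil[i] * ct$pupil_mean +
      as.vector(rhist %*% rh_kernel[i, ]) + b_sacc[i] * ct$saccade +
      b_dori[i] * ct$dori
    counts_test1[, i] <- simulate_counts(theta = theta[i], eta = eta_t)
  }
  rownames(counts_sample) <- rownames(counts_test1) <- ct$trial

  spikes <- if (spike_times) {
    place_spike_times(counts_sample, cfg)
  } else NULL

  trials <- tibble::as_tibble(sched[, c("trial", "block", "trial_in_block",
                                        "reward_cond", "trial_type",
                                        "test_side", "sample_ori", "test1_ori",
                                        "dori", "outcome", "saccade",
                                        "reward_ul", "pupil_mean",
                                        "dprime_t")])
  structure(list(
    trials = trials,
    counts_sample = counts_sample,
    counts_test1 = counts_test1,
    pupil = norm$traces,
    pupil_raw = list(left = raw_left, right = raw_right),
    pupil_time = pup$time,
    spikes = spikes,
    units = units,
    truth = list(config = cfg, reward_kernel = rh_kernel,
                 tuning = tuning, test1_oris = t1_oris,
                 pupil_state = pup$state),
    seed = seed
  ), class = "v4_session")
}

# distribute the sample-window NB count over a response-shaped density and
# add baseline Poisson spikes outside the evoked window
place_spike_times <- function(counts, cfg) {
  n_tr <- nrow(counts); n_un <- ncol(counts)
  w0 <- cfg$trace_window[1]; w1 <- cfg$trace_window[2]
  # evoked density over 60-260 ms: gamma-like rise and decay
  grid <- seq(60.5, 259.5, by = 1)
  wts <- (grid - 60)^1.5 * exp(-(grid - 60) / 60)
  wts <- wts / sum(wts)
  base_rate <- cfg$baseline_rate / 1000          # spikes per ms
  out_tr <- integer(0); out_un <- integer(0); out_t <- numeric(0)
  for (u in seq_len(n_un)) {
    n_ev <- counts[, u]
    ev_times <- sample(grid, sum(n_ev), replace = TRUE, prob = wts) +
      stats::runif(sum(n_ev), -0.5, 0.5)
    ev_tr <- rep(seq_len(n_tr), n_ev)
    # baseline spikes over [w0, 60) and [260, w1)
    len_b <- (60 - w0) + (w1 - 260)
    n_b <- stats::rpois(n_tr, base_rate * len_b)
    b_tr <- rep(seq_len(n_tr), n_b)
    b_t <- stats::runif(sum(n_b), 0, len_b)
    b_t <- ifelse(b_t < (60 - w0), w0 + b_t, 260 + (b_t - (60 - w0)))
    out_tr <- c(out_tr, ev_tr, b_tr)
    out_un <- c(out_un, rep.int(u, length(ev_tr) + length(b_tr)))
    out_t <- c(out_t, ev_times, b_t)
  }
  ord <- order(out_un, out_tr, out_t)
  tibble::tibble(trial = out_tr[ord], unit = out_un[ord], time = out_t[ord])
}

#' Reward history design columns
#'
#' Lag-k reward history: the reward received k completed trials back,
#' normalized within session to `[0, 1]` by the session maximum. Trials with
#' fewer than `n_lags` completed predecessors get `NA` rows (dropped by
#' [build_design()]).
#'
#' @param reward_ul Received reward per completed trial, in session order.
#' @param n_lags Number of lags (default 10).
#' @return A matrix with columns `rhist_1` ... `rhist_<n_lags>`.
#' @export
reward_history <- function(reward_ul, n_lags = 10) {
  r <- reward_ul / max(reward_ul)
  n <- length(r)
  out <- matrix(NA_real_, n, n_lags,
                dimnames = list(NULL, paste0("rhist_", seq_len(n_lags))))
  for (k in seq_len(n_lags)) {
    if (n > k) out[(k + 1):n, k] <- r[1:(n - k)]
  }
  out
}

#' @export
print.v4_session <- function(x, ...) {
  ct <- completed(x$trials)
  cat("<v4_session> seed", x$seed, "\n")
  cat(sprintf("  %d completed trials (%d aborted), %d blocks, %d units\n",
              nrow(ct), sum(x$trials$outcome == "aborted"),
              max(x$trials$block), nrow(x$units)))
  cat(sprintf("  outcomes: %s\n",
              paste(names(table(ct$outcome)), table(ct$outcome),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Completed trials of a session
#'
#' @param session A `v4_session`.
#' @return The trial tibble restricted to completed (non-aborted) trials.
#' @export
completed_trials <- function(session) {
  completed(session$trials)
}
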