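# shared fixture builders (everything generated in code, never stored)

tiny_config <- function(...) {
  session_config(n_blocks = 2, trials_per_block = 40, n_neurons = 3, ...)
}

# minimal hand-built session carrying only what pupil-coupling analyses need
fake_pupil_session <- function(pupil, pupil_time, spikes, n_units = 1) {
  n_tr <- nrow(pupil)
  trials <- tibble::tibble(
    trial = seq_len(n_tr), block = 1L, trial_in_block = seq_len(n_tr),
    reward_cond = rep(c("small", "large"), length.out = n_tr),
    trial_type = "match", test_side = "inRF", sample_ori = 45,
    test1_ori = 45, dori = 0L, outcome = "CR", saccade = 0L,
    reward_ul = 100, pupil_mean = rowMeans(pupil),
    dprime_t = 1
  )
  structure(list(trials = trials, pupil = pupil, pupil_time = pupil_time,
                 spikes = spikes,
                 units = tibble::tibble(unit = seq_len(n_units)),
                 counts_sample = NULL, counts_test1 = NULL,
                 truth = NULL, seed = NA),
            class = "v4_session")
}

# spikes at a constant rate over the whole trace window: evoked equals
# baseline by construction (null for the responsiveness screen)
null_spike_session <- function(n_units, n_trials, rate_hz = 15, seed = 1) {
  withr::with_seed(seed, {
    window <- c(-400, 600)
    n_sp <- stats::rpois(n_units * n_trials, rate_hz * diff(window) / 1000)
    idx <- expand.grid(trial = seq_len(n_trials), unit = seq_len(n_units))
    spikes <- tibble::tibble(
      trial = rep(idx$trial, n_sp), unit = rep(idx$unit, n_sp),
      time = stats::runif(sum(n_sp), window[1], window[2]))
    pupil <- matrix(0.5, n_trials, 3)
    fake_pupil_session(pupil, c(0, 2, 4), spikes, n_units = n_units)
  })
}

# pointwise bivariate normal density (test-side oracle for RF fits)
bvn_grid_test <- function(rf, x, y) {
  dx <- (x - rf$x) / rf$sx
  dy <- (y - rf$y) / rf$sy
  q <- dx^2 - 2 * rf$rho * dx * dy + dy^2
  exp(-q / (2 * (1 - rf$rho^2))) /
    (2 * pi * rf$sx * rf$sy * sqrt(1 - rf$rho^2))
}
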