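test_that("pupil normalization hits its endpoints and averages eyes", {
  time <- seq(0, 398, by = 2)
  n_t <- length(time)
  # eye traces constant at chosen quantiles of each eye's session range
  mk <- function(vals) do.call(rbind, lapply(vals, rep, n_t))
  left <- mk(c(100, 200, 120))    # min 100, max 200 -> norms 0, 1, 0.2
  right <- mk(c(500, 900, 660))   # min 500, max 900 -> norms 0, 1, 0.4
  out <- normalize_pupil(list(left = left, right = right), time)
  expect_equal(out$mean_area, c(0, 1, 0.3))
  expect_equal(out$extrema$pupil_min, c(100, 500))
})

test_that("normalization is idempotent on an already-normalized session", {
  time <- seq(0, 398, by = 2)
  set.seed(5)
  raw <- matrix(runif(20 * length(time), 300, 800), nrow = 20)
  once <- normalize_pupil(raw, time)
  twice <- normalize_pupil(once$traces, time)
  expect_equal(twice$traces, once$traces, tolerance = 1e-12)
})

test_that("flat traces raise a normalization error", {
  time <- seq(0, 398, by = 2)
  flat <- matrix(42, 5, length(time))
  expect_error(normalize_pupil(flat, time), "normalization error")
})

test_that("pupil-spike cross-correlation is null for independent signals", {
  set.seed(61)
  n_tr <- 120
  time <- seq(-400, 600, by = 2)
  pupil <- matrix(0.5 + 0.2 * sin(outer(runif(n_tr, 0, 2 * pi), time / 150,
                                        `+`)), nrow = n_tr)
  n_sp <- rpois(n_tr, 12)
  spikes <- tibble::tibble(trial = rep(seq_len(n_tr), n_sp), unit = 1L,
                           time = runif(sum(n_sp), -400, 600))
  s <- fake_pupil_session(pupil, time, spikes)
  xc <- pupil_spike_xcorr(s, 1)
  expect_true(all(abs(xc$r_corrected) < 3 / sqrt(n_tr / 2) + 0.05,
                  na.rm = TRUE))
})

test_that("a constructed pupil->spike lag appears at the right negative lag", {
  set.seed(62)
  n_tr <- 200
  time <- seq(-400, 600, by = 2)
  phase <- runif(n_tr, 0, 2 * pi)
  pupil <- 0.5 + 0.3 * sin(outer(phase, 2 * pi * (time + 400) / 300, `+`))
  # spike rate follows the pupil 50 ms earlier (pupil leads spikes)
  lagms <- 50
  spikes <- purrr::map_dfr(seq_len(n_tr), function(tr) {
    rate <- 0.5 + 0.3 * sin(phase[tr] + 2 * pi * (time - lagms + 400) / 300)
    keep <- runif(length(time)) < rate * 0.06
    tibble::tibble(trial = tr, unit = 1L, time = time[keep])
  })
  s <- fake_pupil_session(pupil, time, spikes)
  # the 300 ms period aliases at +/- one cycle: search within half a period
  xc <- pupil_spike_xcorr(s, 1, lags = seq(-140, 140, by = 2))
  peak <- xc |>
    dplyr::group_by(lag) |>
    dplyr::summarise(r = mean(r_corrected), .groups = "drop")
  best <- peak$lag[which.max(peak$r)]
  expect_true(abs(best - (-lagms)) <= 30)
})

test_that("shuffle correction removes stimulus-locked common structure", {
  set.seed(63)
  n_tr <- 150
  time <- seq(-400, 600, by = 2)
  evoked <- 0.3 * exp(-(time - 200)^2 / (2 * 120^2))  # shared by all trials
  pupil <- matrix(rep(evoked, each = n_tr), nrow = n_tr) + 0.4 +
    matrix(rnorm(n_tr * length(time), 0, 0.01), nrow = n_tr)
  # spike rate carries the same evoked time course, with no trial-wise link
  spikes <- purrr::map_dfr(seq_len(n_tr), function(tr) {
    keep <- runif(length(time)) < (0.01 + 0.08 * evoked)
    tibble::tibble(trial = tr, unit = 1L, time = time[keep])
  })
  s <- fake_pupil_session(pupil, time, spikes)
  xc <- pupil_spike_xcorr(s, 1, lags = seq(-50, 50, by = 10))
  # raw single-trial correlations inherit the locked component; the
  # trial-shuffled term captures it, and the corrected measure removes it
  expect_gt(mean(xc$r_shuffled, na.rm = TRUE), 0.05)
  expect_lt(abs(mean(xc$r_corrected, na.rm = TRUE)),
            mean(xc$r_shuffled, na.rm = TRUE) / 2)
})

test_that("spike-triggered average pupil behaves under null and coupling", {
  set.seed(64)
  n_tr <- 100
  time <- seq(-400, 600, by = 2)
  pupil <- 0.5 + 0.2 * sin(outer(runif(n_tr, 0, 2 * pi),
                                 2 * pi * (time + 400) / 400, `+`))
  n_sp <- rpois(n_tr, 8)
  spikes <- tibble::tibble(trial = rep(seq_len(n_tr), n_sp), unit = 1L,
                           time = runif(sum(n_sp), 0, 400))
  s <- fake_pupil_session(pupil, time, spikes)
  sta <- sta_pupil(s, 1)
  expect_lt(max(abs(sta$sta_corrected)), 0.08)

  # rate driven by a per-trial pupil level: spikes preferentially sample
  # high-pupil trials, so the corrected STA is positive around lag 0
  lvl <- runif(n_tr, 0.3, 0.9)
  pupil2 <- matrix(rep(lvl, length(time)), nrow = n_tr) +
    matrix(rnorm(n_tr * length(time), 0, 0.01), nrow = n_tr)
  n_sp2 <- rpois(n_tr, 30 * lvl)
  spikes2 <- tibble::tibble(trial = rep(seq_len(n_tr), n_sp2), unit = 1L,
                            time = runif(sum(n_sp2), 0, 400))
  s2 <- fake_pupil_session(pupil2, time, spikes2)
  sta2 <- sta_pupil(s2, 1)
  expect_gt(sta2$sta_corrected[which.min(abs(sta2$lag))], 0.01)

  # constant pupil: corrected STA identically zero
  s3 <- fake_pupil_session(matrix(0.7, n_tr, length(time)), time, spikes)
  sta3 <- sta_pupil(s3, 1)
  expect_true(all(sta3$sta_corrected == 0))
  # too few spikes
  few <- spikes[1:20, ]
  expect_error(sta_pupil(fake_pupil_session(pupil, time, few), 1),
               "insufficient-data")
})

test_that("pupil regression separates intensity from spike coupling", {
  set.seed(65)
  n <- 400
  intensity <- rep(c(0, 1), each = n / 2)
  spikes <- rpois(n, 5)
  pupil <- intensity + rnorm(n, 0, 1e-6)
  r <- regress_pupil(pupil, spikes, intensity)
  expect_equal(r$b, 1, tolerance = 0.01)
  expect_equal(r$a, 0, tolerance = 0.05)
  expect_true(r$significant)
  # pure-noise pupil: nominal false-positive rate
  sig <- replicate(200, {
    regress_pupil(rnorm(100), rpois(100, 5), rep(c(0, 1), 50))$significant
  })
  expect_lt(mean(sig), 0.12)
  expect_error(regress_pupil(rep(1, 10), rpois(10, 5)), "regression error")
})

test_that("pupil matching respects the caliper and one-to-one use", {
  tr <- tibble::tibble(
    trial = 1:8, outcome = "hit",
    reward_cond = rep(c("small", "large"), each = 4),
    pupil_mean = c(0.30, 0.40, 0.50, 0.90, 0.31, 0.42, 0.54, 0.20))
  m <- match_pupil_trials(tr, caliper = 0.05)
  expect_true(all(abs(m$pupil_small - m$pupil_large) <= 0.05))
  expect_equal(anyDuplicated(m$trial_large), 0)
  expect_false(4 %in% m$trial_small)   # 0.90 has no partner within caliper
})
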