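test_that("d' and criterion reproduce the probit closed forms", {
  # symmetric chance performance
  s <- dprime_criterion(10, 10, 10, 10)
  expect_equal(s$dprime, 0)
  expect_equal(s$criterion, 0)
  # rates chosen as exact normal CDF values (fractional counts are fine:
  # only the rates enter)
  s2 <- dprime_criterion(pnorm(1), pnorm(-1), pnorm(1), pnorm(-1))
  expect_equal(s2$dprime, 2, tolerance = 1e-9)
  expect_equal(s2$criterion, 0, tolerance = 1e-9)
  s3 <- dprime_criterion(pnorm(2), 1 - pnorm(2), 0.5, 0.5)
  expect_equal(s3$dprime, 2, tolerance = 1e-9)
  expect_equal(s3$criterion, -1, tolerance = 1e-9)
  # against the quantile oracle for arbitrary counts
  for (counts in list(c(37, 13, 41, 9), c(5, 45, 30, 20))) {
    s4 <- do.call(dprime_criterion, as.list(counts))
    h <- counts[1] / (counts[1] + counts[2])
    f <- counts[4] / (counts[3] + counts[4])
    expect_equal(s4$dprime, qnorm(h) - qnorm(f), tolerance = 1e-12)
    expect_equal(s4$criterion, -(qnorm(h) + qnorm(f)) / 2, tolerance = 1e-12)
  }
})

test_that("rate clipping and empty classes behave as specified", {
  s <- dprime_criterion(20, 0, 15, 5)      # perfect hit rate clipped
  expect_equal(s$hit_rate, 1 - 1 / 40)
  s2 <- dprime_criterion(0, 20, 15, 5)
  expect_equal(s2$hit_rate, 1 / 40)
  expect_error(dprime_criterion(0, 0, 10, 10), "undefined-rate")
})

test_that("(d', c) -> rates -> (d', c) round-trips to machine precision", {
  for (d in c(0.5, 2.03, 3.48)) {
    for (cc in c(-0.4, 0, 0.3)) {
      hit <- pnorm(d / 2 - cc)
      fa <- pnorm(-d / 2 - cc)
      s <- dprime_criterion(hit, 1 - hit, 1 - fa, fa)
      expect_equal(s$dprime, d, tolerance = 1e-12)
      expect_equal(s$criterion, cc, tolerance = 1e-12)
    }
  }
})

test_that("overall d' is the Euclidean combination and is symmetric/monotone", {
  expect_identical(overall_dprime(0, 0), 0)
  expect_identical(overall_dprime(3, 4), 5)
  expect_equal(overall_dprime(2, 2), 2 * sqrt(2))
  grid <- expand.grid(a = c(0, 0.5, 1, 2), b = c(0, 0.5, 1, 2))
  expect_equal(overall_dprime(grid$a, grid$b), overall_dprime(grid$b, grid$a))
  expect_true(all(diff(overall_dprime(c(0, 1, 2, 3), 1)) > 0))
  expect_true(all(overall_dprime(grid$a, grid$b) >= pmax(grid$a, grid$b)))
})

test_that("block alignment starts at the first correct trial", {
  tr <- tibble::tibble(
    trial = 1:6, block = 1L, trial_in_block = 1:6,
    reward_cond = "small", trial_type = "nonmatch", test_side = "inRF",
    sample_ori = 45, test1_ori = 65, dori = 1L,
    outcome = c("miss", "FA", "hit", "miss", "hit", "CR"),
    saccade = c(0L, 1L, 1L, 0L, 1L, 0L), reward_ul = 0, pupil_mean = 0.5)
  al <- align_blocks(tr)
  expect_equal(al$aligned, c(NA, NA, 1L, 2L, 3L, 4L))
  tr2 <- dplyr::mutate(tr, outcome = c("hit", rep("miss", 5)))
  expect_equal(align_blocks(tr2)$aligned, 1:6)
  tr3 <- dplyr::mutate(tr, outcome = "miss")
  expect_warning(al3 <- align_blocks(tr3), "no correct trial")
  expect_true(all(is.na(al3$aligned)))
})

test_that("aligned averages recover a generator step change", {
  cfg <- session_config(n_blocks = 8, n_neurons = 1, pupil_noise_sd = 0.01,
                        tau_pupil_rise = 0.1, tau_pupil_decay = 0.1)
  s <- generate_session(cfg, seed = 13, spike_times = FALSE)
  course <- aligned_course(align_blocks(s), "pupil_mean")
  late <- dplyr::filter(course, aligned >= 20, aligned <= 100)
  lvl <- tapply(late$mean, late$reward_cond, mean)
  expect_gt(lvl["large"] - lvl["small"], 0.8 * 0.6 *
              (cfg$pupil_large - cfg$pupil_small))
})

test_that("exponential fit recovers noiseless parameters to high precision", {
  t <- 1:120
  f <- fit_exponential(1 + 2 * exp(-t / 5), t)
  expect_equal(f$tau, 5, tolerance = 1e-6)
  expect_equal(f$A, 1, tolerance = 1e-6)
  expect_equal(f$B, 2, tolerance = 1e-6)
  expect_false(f$degenerate)
})

test_that("constant series yields a flagged degenerate exponential fit", {
  f <- fit_exponential(rep(2.5, 30))
  expect_true(f$degenerate)
  expect_equal(f$B, 0)
  expect_true(is.na(f$tau))
  expect_error(fit_exponential(c(1, 2, 3)), "8 finite points")
})

test_that("median tau estimate is within 15% under 5% noise", {
  set.seed(41)
  t <- 1:120
  truth <- 10
  y0 <- 2 + 3 * exp(-t / truth)
  taus <- replicate(100, {
    y <- y0 + rnorm(120, 0, 0.05 * diff(range(y0)))
    fit_exponential(y, t)$tau
  })
  expect_lt(abs(median(taus) / truth - 1), 0.15)
})

test_that("tidy/glance expose the exponential fit in broom form", {
  f <- fit_exponential(1 + 2 * exp(-(1:60) / 5))
  td <- tidy(f)
  expect_equal(td$term, c("A", "B", "tau"))
  g <- glance(f)
  expect_true(all(c("tau", "resid_ss", "degenerate") %in% names(g)))
})

test_that("hysteresis mid-point rewards separate exactly as dictated", {
  # closed-form construction: reward relaxes with tau_r = 2 in both
  # directions; the response relaxes with direction-dependent tau
  t <- 0:60            # include the pre-transition state so fast crossings
  lo <- 100; hi <- 500 # fall inside the series
  reward_up <- hi + (lo - hi) * exp(-t / 2)
  reward_dn <- lo + (hi - lo) * exp(-t / 2)
  make_course <- function(tau_up, tau_dn) {
    dplyr::bind_rows(
      tibble::tibble(direction = "to_large", aligned = t,
                     response = 1 + (0 - 1) * exp(-t / tau_up),
                     reward = reward_up),
      tibble::tibble(direction = "to_small", aligned = t,
                     response = 0 + (1 - 0) * exp(-t / tau_dn),
                     reward = reward_dn))
  }
  # response tracking reward dynamics exactly: no hysteresis
  sym <- hysteresis_curve(make_course(2, 2))
  expect_equal(sym$mid_reward[1], sym$mid_reward[2], tolerance = 5)
  # slow rise, fast decay: the rising trajectory crosses its midpoint only
  # after the reward has nearly completed its step, the falling one before
  asym <- hysteresis_curve(make_course(10, 1))
  up <- asym$mid_reward[asym$direction == "to_large"]
  dn <- asym$mid_reward[asym$direction == "to_small"]
  # closed-form oracle: crossing at t* = tau * log(2)
  oracle <- function(tau, from, to) {
    tstar <- tau * log(2)
    to + (from - to) * exp(-tstar / 2)
  }
  expect_equal(up, oracle(10, lo, hi), tolerance = 15)
  expect_equal(dn, oracle(1, hi, lo), tolerance = 15)
  expect_gt(up, dn)
})
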