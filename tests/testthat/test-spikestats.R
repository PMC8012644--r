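test_that("responsiveness screen passes at the nominal rate under the null", {
  s <- null_spike_session(n_units = 400, n_trials = 80, seed = 71)
  sc <- screen_responsive(s)
  expect_gt(mean(sc$keep), 0.0005)
  expect_lt(mean(sc$keep), 0.035)
})

test_that("responsiveness screen keeps driven units and drops silent ones", {
  s <- generate_session(session_config(n_blocks = 2, n_neurons = 10,
                                       trials_per_block = 100), seed = 72)
  sc <- screen_responsive(s)
  expect_true(all(sc$keep))        # evoked rate ~3x baseline by construction
  silent <- s
  silent$spikes <- silent$spikes[silent$spikes$unit != 1, ]
  sc2 <- screen_responsive(silent)
  expect_false(sc2$keep[1])
})

test_that("PSTH kernel has unit mass and reproduces the impulse response", {
  k <- half_gaussian_kernel(sigma = 15, binwidth = 2)
  expect_equal(sum(k) * 2, 1, tolerance = 1e-12)
  expect_true(all(diff(k) <= 0))   # causal, rightward-decaying

  one_spike <- fake_pupil_session(matrix(0.5, 1, 3), c(0, 2, 4),
                                  tibble::tibble(trial = 1L, unit = 1L,
                                                 time = 100))
  p <- psth(one_spike, 1, window = c(0, 300))
  on <- p$rate > 0
  expect_equal(min(p$time[on]), 101)           # nothing before the spike
  expect_equal(sum(p$rate) * 0.002, 1, tolerance = 1e-6)  # area = 1 spike
})

test_that("PSTH of homogeneous Poisson spiking is flat at the true rate", {
  set.seed(73)
  n_tr <- 400
  n_sp <- rpois(n_tr, 20)              # 20 spikes/s over a 1 s window
  spikes <- tibble::tibble(trial = rep(seq_len(n_tr), n_sp), unit = 1L,
                           time = runif(sum(n_sp), -400, 600))
  s <- fake_pupil_session(matrix(0.5, n_tr, 3), c(0, 2, 4), spikes)
  p <- psth(s, 1, window = c(-300, 500))
  mid <- p$rate[p$time > -200 & p$time < 400]
  expect_equal(mean(mid), 20, tolerance = 0.05)
  expect_lt(sd(mid), 3)
})

test_that("neuronal d' is signed, antisymmetric, and flags degenerate input", {
  set.seed(74)
  a <- rpois(300, 8); b <- rpois(300, 8)
  nd <- neuronal_dprime(a, b)
  expect_lt(abs(nd$dprime), 0.3)
  up <- neuronal_dprime(rpois(300, 12), rpois(300, 8))
  expect_gt(up$dprime, 0)
  expect_true(up$significant)
  expect_equal(neuronal_dprime(a, b)$dprime, -neuronal_dprime(b, a)$dprime)
  z <- neuronal_dprime(rep(2, 10), rep(2, 10))
  expect_true(z$undefined)
})

test_that("modulation index follows its ratio definition", {
  expect_equal(modulation_index(3, 1), 0.5)
  expect_equal(modulation_index(1, 3), -0.5)
  expect_equal(modulation_index(2, 2), 0)
})

test_that("population neuronal d' is positive under an intensity gain", {
  s <- generate_session(session_config(n_blocks = 4, n_neurons = 30),
                        seed = 75, spike_times = FALSE)
  nd <- session_neuronal_dprime(s)
  expect_gt(mean(nd$dprime), 0.05)
})

test_that("mean-matched Fano is calibrated for Poisson and NB ensembles", {
  set.seed(76)
  n_units <- 150; n_trials <- 200
  mk_stats <- function(gen) {
    purrr::map_dfr(seq_len(n_units), function(u) {
      purrr::map_dfr(c("small", "large"), function(cond) {
        y <- gen(u, cond)
        tibble::tibble(unit = u, cond = cond, time = 0,
                       mean = mean(y), var = var(y))
      })
    })
  }
  # Poisson, condition-dependent rate distributions exercise the matching
  pois <- mk_stats(function(u, cond) {
    lam <- runif(1, 0.5, 3) * (if (cond == "large") 1.3 else 1)
    rpois(n_trials, lam)
  })
  mm <- mean_matched_fano(pois, bin = 0.25)
  expect_equal(mm$fano, rep(1, 2), tolerance = 0.03)

  # NB(mu = 5, theta = 4): Fano = 1 + mu/theta = 2.25, identical conditions
  nb <- mk_stats(function(u, cond) rnbinom(n_trials, size = 4, mu = 5))
  mm2 <- mean_matched_fano(nb, bin = 0.25)
  expect_equal(mm2$fano_raw, rep(2.25, 2), tolerance = 0.05)
  expect_lt(abs(diff(mm2$fano)), 0.1)

  # doubled per-unit means at matched Fano (overlapping mean distributions):
  # matching removes no real effect
  base_mu <- runif(n_units, 3, 12)
  nb3 <- mk_stats(function(u, cond) {
    mu <- base_mu[u] * (if (cond == "large") 2 else 1)
    rnbinom(n_trials, size = mu / 1.25, mu = mu)   # Fano 2.25 either way
  })
  mm3 <- mean_matched_fano(nb3, bin = 0.5)
  expect_equal(mm3$fano[mm3$cond == "large"], mm3$fano[mm3$cond == "small"],
               tolerance = 0.08)
})

test_that("noise-correlation estimator is exact for identical and null pairs", {
  set.seed(77)
  counts <- cbind(a = rpois(200, 10), b = rpois(200, 10))
  twin <- cbind(counts[, 1], counts[, 1])
  expect_equal(pairwise_noise_corr(twin)$r, 1)
  many <- matrix(rpois(200 * 60, 8), ncol = 60)
  pc <- pairwise_noise_corr(many)
  expect_lt(abs(mean(pc$r)), 3 / sqrt(nrow(pc)))
  # shared gain injected across units raises correlations
  gain <- rnorm(200, 1, 0.15)
  shared <- matrix(rpois(200 * 30, 8 * gain), ncol = 30)
  expect_gt(mean(pairwise_noise_corr(shared)$r), 0.05)
  # zero-variance member skipped and counted
  degen <- cbind(counts, c = rep(3, 200))
  pcd <- pairwise_noise_corr(degen)
  expect_equal(attr(pcd, "n_skipped"), 2)
})

test_that("session noise correlations bin pairs by geometric-mean evoked rate", {
  s <- generate_session(session_config(n_blocks = 2, n_neurons = 12,
                                       trials_per_block = 80), seed = 78)
  nc <- noise_correlations(s)
  expect_true(all(nc$bin %in% seq(0, 25, by = 5)))
  expect_true(all(nc$geo_mean >= nc$bin | nc$bin == 25))
  expect_equal(nrow(nc), 2 * choose(12, 2))
})

test_that("reward-history binning of spike counts tracks the generator", {
  # zero reward-history kernel: flat profile across previous-reward bins
  s0 <- generate_session(session_config(n_blocks = 4, n_neurons = 20,
                                        beta_reward_scale = 0),
                         seed = 79, spike_times = FALSE)
  rm0 <- reward_matched_counts(s0)
  expect_equal(nrow(rm0), 36)        # 9 bins x 2 phases x 2 conditions
  late0 <- dplyr::filter(rm0, phase == "late", !is.na(mean_count))
  expect_lt(abs(cor(late0$bin, late0$mean_count)), 0.6)

  # positive lag-1 kernel: profile increases with previous reward
  s1 <- generate_session(session_config(n_blocks = 4, n_neurons = 20,
                                        beta_reward_scale = 1.5),
                         seed = 79, spike_times = FALSE)
  rm1 <- reward_matched_counts(s1)
  late1 <- dplyr::filter(rm1, phase == "late", !is.na(mean_count))
  slope1 <- coef(lm(mean_count ~ bin, data = late1))[2]
  expect_gt(slope1, 0)
})

test_that("PSTH PCA recovers injected motifs and flags degeneracy", {
  tt <- seq(0, 400, by = 10)
  m1 <- exp(-(tt - 100)^2 / (2 * 30^2))
  m2 <- exp(-(tt - 300)^2 / (2 * 50^2))
  set.seed(80)
  w <- cbind(runif(40), runif(40))
  mat <- w %*% rbind(m1, m2) + matrix(rnorm(40 * length(tt), 0, 0.01), 40)
  units <- rep(1:20, 2)
  conds <- rep(c("small", "large"), each = 20)
  pc <- pca_psth(mat, units, conds)
  expect_gt(sum(pc$explained[1:2]), 0.95)
  expect_false(pc$degenerate)

  # identical rows: degenerate, and identical conditions give slope 1
  same <- matrix(rep(m1, 10), nrow = 10, byrow = TRUE)
  pc2 <- pca_psth(same, rep(1:5, 2), rep(c("small", "large"), each = 5))
  expect_true(pc2$degenerate)
  dup <- rbind(mat[1:20, ], mat[1:20, ])
  pc3 <- pca_psth(dup, units, conds)
  expect_equal(unname(pc3$slopes[1]), 1, tolerance = 1e-8)
})
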