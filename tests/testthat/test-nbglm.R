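test_that("intercept-only fit equals the closed-form ML solution", {
  set.seed(101)
  y <- rnbinom(800, size = 3, mu = 6)
  f <- fit_negbin(matrix(numeric(0), 800, 0), y)
  expect_equal(unname(coef(f)[1]), log(mean(y)), tolerance = 1e-7)
})

test_that("NB fit agrees with an independent ML implementation", {
  set.seed(102)
  n <- 2000
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4), x3 = runif(n))
  y <- simulate_counts(theta = 2.5, eta = 1 + 0.4 * X[, 1] - 0.3 * X[, 2] +
                         0.2 * X[, 3])
  f <- fit_negbin(X, y)
  m <- MASS::glm.nb(y ~ X)
  expect_equal(unname(coef(f)), unname(coef(m)), tolerance = 1e-5)
  expect_equal(f$theta, m$theta, tolerance = 1e-4)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(m)))), tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
})

test_that("coefficients are recovered within reported uncertainty", {
  set.seed(103)
  truth <- c(1.2, 0.35, -0.25)
  hits <- replicate(20, {
    X <- cbind(a = rnorm(2000), b = rbinom(2000, 1, 0.5))
    y <- simulate_counts(theta = 4, eta = truth[1] + truth[2] * X[, 1] +
                           truth[3] * X[, 2])
    f <- fit_negbin(X, y)
    all(abs(coef(f) - truth) <= 3 * f$se)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("theta-capped fits on equidispersed data match the Poisson oracle", {
  set.seed(104)
  found <- 0
  for (r in 1:10) {
    X <- cbind(x = rnorm(3000))
    y <- rpois(3000, exp(1.5 + 0.3 * X[, 1]))
    f <- fit_negbin(X, y)
    if (!f$theta_capped) next
    found <- found + 1
    g <- glm(y ~ X, family = poisson)   # independent IRLS oracle
    expect_lt(max(abs(coef(f) - coef(g))), 1e-4)
  }
  expect_gt(found, 0)
})

test_that("log-likelihood is non-decreasing over alternating iterations", {
  # tracked indirectly: the step-halving guard guarantees monotone ascent,
  # so the final LL must dominate both the Poisson start and the null fit
  set.seed(105)
  X <- cbind(x = rnorm(1000))
  y <- simulate_counts(theta = 1.5, eta = 1 + 0.5 * X[, 1])
  f <- fit_negbin(X, y)
  null <- fit_negbin(matrix(numeric(0), 1000, 0), y)
  pois_ll <- sum(dpois(y, exp(cbind(1, X) %*%
                                coef(glm(y ~ X, family = poisson))), log = TRUE))
  expect_gte(f$loglik, null$loglik)
  expect_gte(f$loglik, pois_ll)
  expect_true(f$converged)
})

test_that("diagnostics satisfy their defining identities", {
  set.seed(106)
  y <- rnbinom(500, size = 3, mu = 5)
  null <- fit_negbin(matrix(numeric(0), 500, 0), y)
  d0 <- nb_diagnostics(null, null_fit = null)
  expect_equal(d0$chisq, 0)
  expect_equal(d0$pseudo_r2, 0)
  # a model predicting each observation exactly has zero deviance
  yc <- rep(4L, 100)
  sat <- fit_negbin(matrix(numeric(0), 100, 0), yc)
  expect_equal(nb_diagnostics(sat, null_fit = sat)$deviance, 0,
               tolerance = 1e-6)
  # strong effects are detected essentially always
  X <- cbind(x = rnorm(500))
  y2 <- simulate_counts(theta = 3, eta = 1 + 0.8 * X[, 1])
  d2 <- nb_diagnostics(fit_negbin(X, y2))
  expect_lt(d2$p_value, 1e-10)
  expect_true(d2$pseudo_r2 > 0 && d2$pseudo_r2 <= 1)
})

test_that("standardized coefficients are scale-invariant", {
  set.seed(107)
  X <- cbind(x = rnorm(1500, sd = 2))
  y <- simulate_counts(theta = 3, eta = 1 + 0.3 * X[, 1])
  f1 <- fit_negbin(X, y)
  f2 <- fit_negbin(X * 2, y)          # doubled predictor scale
  s1 <- standardize_coefs(f1)
  s2 <- standardize_coefs(f2)
  expect_equal(f2$coefficients["x"], f1$coefficients["x"] / 2,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(s1$std_estimate, s2$std_estimate, tolerance = 1e-6)
  # sigma_x = sigma_y leaves the coefficient unchanged
  sx <- sd(X[, 1]); sy <- sd(y)
  expect_equal(s1$std_estimate, s1$estimate * sx / sy)
  # constant column flagged
  f3 <- fit_negbin(cbind(x = X[, 1], const = 1), y, intercept = FALSE)
  expect_warning(s3 <- standardize_coefs(f3), "standardization undefined")
  expect_true(is.na(s3$std_estimate[s3$term == "const"]))
})

test_that("cross-validation error behaves as its variance identity predicts", {
  # constant response (intercept-only design): zero error
  cv0 <- crossval_negbin(matrix(numeric(0), 100, 0), rep(5L, 100), K = 5,
                         seed = 2)
  expect_equal(cv0$error, 0, tolerance = 1e-10)
  # null data: CV error approaches Var(y)
  set.seed(108)
  y <- rnbinom(2000, size = 4, mu = 6)
  X <- cbind(x = rnorm(2000))          # pure noise predictor
  cv <- crossval_negbin(X, y, K = 10, seed = 3)
  expect_equal(cv$error, var(y), tolerance = 0.08)
  # fixed seed reproduces the folds
  cv2 <- crossval_negbin(X, y, K = 10, seed = 3)
  expect_identical(cv$folds, cv2$folds)
})

test_that("tuning filter is flat for untuned units and tracks true tuning", {
  set.seed(109)
  oris <- sample(c(45, 65, 135, 155), 1000, replace = TRUE)
  y_flat <- rpois(1000, 6)
  f <- tuning_filter(y_flat, oris)
  expect_lt(diff(range(f)), 0.2)
  tune <- c(`45` = 0.5, `65` = -0.2, `135` = 0.3, `155` = -0.6)
  y_tuned <- rpois(1000, exp(1.5 + tune[as.character(oris)]))
  f2 <- tuning_filter(y_tuned, oris)
  expect_gt(cor(f2, exp(tune)), 0.9)
  expect_error(tuning_filter(y_flat[oris == 45], oris[oris == 45],
                             levels = c(45, 65)), "filter error")
})

test_that("design matrices honor lag requirements and coding rules", {
  s <- generate_session(session_config(n_blocks = 2, n_neurons = 2,
                                       trials_per_block = 60),
                        seed = 110, spike_times = FALSE)
  d <- build_design(s, 1, "complete")
  ct <- completed_trials(s)
  expect_equal(d$n_dropped, 10)                  # first 10 completed trials
  expect_false(any(ct$trial[1:10] %in% d$trials))
  # lag-1 column equals the previous completed trial's normalized reward
  i <- match(d$trials, ct$trial)
  expect_equal(d$X[, "rhist_1"], ct$reward_ul[i - 1] / max(ct$reward_ul))
  expect_true(all(d$X[, "ori"] %in% c(0, 1)))
  # test-1 design: delta-ori column is exactly the nonmatch indicator
  dt <- build_design(s, 1, "dori")
  it <- match(dt$trials, ct$trial)
  expect_equal(unname(dt$X[, "dori"]), ct$dori[it])
  expect_true(all(ct$test_side[it] == "inRF"))
  # no leakage: the tuning filter ignores trials outside filter_trials
  train <- dt$trials[seq_len(floor(length(dt$trials) / 2))]
  d_tr <- build_design(s, 1, "dori", filter_trials = train)
  s_perm <- s
  heldout <- !(ct$trial %in% train)
  s_perm$counts_test1[heldout, 1] <-
    rev(s_perm$counts_test1[heldout, 1])       # scramble held-out responses
  d_perm <- build_design(s_perm, 1, "dori", filter_trials = train)
  expect_identical(d_tr$filter, d_perm$filter)
})

test_that("predictors of the complete model are not collinear", {
  s <- generate_session(session_config(n_blocks = 4, n_neurons = 2),
                        seed = 111, spike_times = FALSE)
  d <- build_design(s, 1, "complete")
  pc <- predictor_partial_cors(d$X)
  expect_lt(max(abs(pc$partial_cor)), 0.5)
})

test_that("delta-ori screening retains exactly the sub-threshold units", {
  mk_fit <- function(stimfeat, dori) {
    structure(list(coefficients = c("(Intercept)" = 1, stimfeat = 0.5,
                                    dori = 0.4),
                   X = cbind("(Intercept)" = 1, stimfeat = stimfeat,
                             dori = dori),
                   unit = 1L), class = "v4_nbfit")
  }
  set.seed(112)
  ortho <- mk_fit(rnorm(100), rbinom(100, 1, 0.5))
  expect_true(delta_ori_screen(ortho)$retained)
  confounded <- mk_fit(c(rep(0.2, 50), rep(0.9, 50)),
                       c(rep(0, 50), rep(1, 50)))
  expect_false(delta_ori_screen(confounded)$retained)
  # Spearman exactly 0.2 sits on the boundary and is excluded (strict <)
  boundary <- mk_fit(1:5, c(4, 1, 2, 5, 3))
  sc <- delta_ori_screen(boundary)
  expect_equal(sc$r, 0.2)
  expect_false(sc$retained)
})

test_that("session-level encoding recovers generator coefficients", {
  cfg <- session_config(n_blocks = 4, n_neurons = 25)
  s <- generate_session(cfg, seed = 113, spike_times = FALSE)
  gs <- fit_session_glms(s, "complete")
  expect_true(all(gs$summary$converged))
  # pupil coefficients: weak per-unit signal (small pupil range), so only
  # the population-level association is asserted
  est_pupil <- sapply(gs$fits, function(f) coef(f)["pupil"])
  expect_gt(cor(est_pupil, s$units$b_pupil), 0.25)
  ok <- mapply(function(f, u) {
    abs(coef(f)["ori"] - s$units$b_ori[u]) <= 3 * f$se["ori"]
  }, gs$fits, s$units$unit)
  expect_gte(mean(ok), 0.8)
})
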