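#' Negative-binomial log-likelihood
#'
#' Evaluated entirely in log space via `lgamma` (the pmf in its raw form
#' overflows for realistic counts): `sum(lgamma(y + theta) - lgamma(theta) -
#' lgamma(y + 1) + y log mu + theta log theta - (y + theta) log(mu +
#' theta))`.
#'
#' @param y Non-negative integer counts.
#' @param mu Means.
#' @param theta Shape parameter (scalar).
#' @return The summed log-likelihood.
#' @export
nb_loglik <- function(y, mu, theta) {
  mu <- pmax(mu, 1e-12)
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        y * log(mu) + theta * log(theta) - (y + theta) * log(mu + theta))
}

# one IRLS pass for beta at fixed theta (theta = Inf gives Poisson IRLS)
irls_step <- function(X, y, beta, theta) {
  eta <- pmin(pmax(as.vector(X %*% beta), -30), 30)
  mu <- exp(eta)
  w <- if (is.finite(theta)) mu / (1 + mu / theta) else mu
  z <- eta + (y - mu) / mu
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% z)
}

# full Poisson ML by own IRLS (also the theta -> Inf limit of the NB model)
poisson_irls <- function(X, y, tol = 1e-10, max_iter = 100) {
  beta <- c(log(mean(y) + 1e-8), rep(0, ncol(X) - 1))
  for (i in seq_len(max_iter)) {
    beta_new <- irls_step(X, y, beta, Inf)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

#' Maximum-likelihood negative-binomial GLM
#'
#' Fits spike counts `y ~ NB(mu, theta)` with `mu = exp(X beta)` by
#' alternating maximization: iteratively reweighted least squares for `beta`
#' at fixed `theta`, and one-dimensional profile-likelihood maximization for
#' `theta` (on the log scale), until the log-likelihood changes by less than
#' `tol`. `theta` is initialized by method of moments from the Pearson
#' residuals of an initial Poisson fit and capped at `theta_max` (the
#' Poisson limit). Standard errors come from the expected information
#' `X' W X` at the optimum, with `w = mu / (1 + mu / theta)`.
#'
#' @param X Design matrix (no intercept column; one is added first unless
#'   `intercept = FALSE`).
#' @param y Non-negative integer counts, `length(y) > ncol(X)`.
#' @param intercept Add an intercept column (default TRUE).
#' @param theta_max Cap on theta (default 1e6).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum alternating iterations.
#' @return An object of class `v4_nbfit`: `coefficients`, `theta`, `se`,
#'   `vcov`, `loglik`, `fitted`, `X`, `y`, `converged`, `iterations`,
#'   `theta_capped`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' y <- simulate_counts(theta = 3, eta = 1 + 0.5 * x)
#' fit <- fit_negbin(cbind(x = x), y)
#' coef(fit)
fit_negbin <- function(X, y, intercept = TRUE, theta_max = 1e6,
                       tol = 1e-8, max_iter = 200) {
  X <- as.matrix(X)
  if (intercept) X <- cbind("(Intercept)" = 1, X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("fit error: need more rows than columns", call. = FALSE)
  if (any(y < 0) || any(y != floor(y))) {
    stop("fit error: y must be non-negative integers", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))

  beta <- tryCatch(poisson_irls(X, y),
                   error = function(e) stop("fit error: separation or singular design (",
                                            conditionMessage(e), ")", call. = FALSE))
  mu <- exp(pmin(as.vector(X %*% beta), 30))
  disp <- sum((y - mu)^2 - mu) / sum(mu^2)          # MoM for 1/theta
  theta <- if (disp > 1 / theta_max) 1 / disp else theta_max
  theta <- min(max(theta, 1e-2), theta_max)

  ll_of <- function(beta, theta) nb_loglik(y, exp(pmin(as.vector(X %*% beta), 30)), theta)
  ll <- ll_of(beta, theta)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    beta_new <- tryCatch(irls_step(X, y, beta, theta),
                         error = function(e) stop("fit error: singular weighted design",
                                                  call. = FALSE))
    # step-halving guard: IRLS can overshoot for small theta
    step <- 1
    ll_try <- ll_of(beta_new, theta)
    while (!is.finite(ll_try) || ll_try < ll - 1e-12) {
      step <- step / 2
      if (step < 1e-4) { beta_new <- beta; ll_try <- ll; break }
      beta_new <- beta + step * (beta_new - beta)
      ll_try <- ll_of(beta_new, theta)
    }
    beta <- as.vector(beta_new)

    opt <- stats::optimize(function(lt) ll_of(beta, exp(lt)),
                           interval = c(log(1e-3), log(theta_max)),
                           maximum = TRUE, tol = 1e-10)
    # optimize can miss a boundary optimum; keep the cap if it is better
    if (ll_of(beta, theta_max) >= opt$objective) {
      theta <- theta_max
      ll_new <- ll_of(beta, theta_max)
    } else {
      theta <- exp(opt$maximum)
      ll_new <- opt$objective
    }
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  eta <- pmin(as.vector(X %*% beta), 30)
  mu <- exp(eta)
  w <- mu / (1 + mu / theta)
  info <- t(X * w) %*% X
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(pmax(diag(vc), 0))
  names(beta) <- names(se) <- colnames(X)

  structure(list(coefficients = beta, theta = theta, se = se, vcov = vc,
                 loglik = ll, fitted = mu, linear_predictors = eta,
                 X = X, y = y, df_residual = n - k - 1,
                 converged = converged, iterations = it,
                 theta_capped = theta >= theta_max), class = "v4_nbfit")
}

#' @export
print.v4_nbfit <- function(x, ...) {
  cat(sprintf("<v4_nbfit> NB GLM, %d obs, %d coefficients, theta = %.4g%s\n",
              length(x$y), length(x$coefficients), x$theta,
              if (x$theta_capped) " (capped: Poisson limit)" else ""))
  cat(sprintf("  logLik %.3f, %s after %d iterations\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.v4_nbfit <- function(object, ...) object$coefficients

#' @export
logLik.v4_nbfit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = length(object$y), class = "logLik")
}

#' @export
vcov.v4_nbfit <- function(object, ...) object$vcov

#' @rdname fit_negbin
#' @param object,x A `v4_nbfit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.v4_nbfit <- function(x, ...) {
  est <- x$coefficients
  stat <- est / x$se
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(x$se), statistic = unname(stat),
                 p.value = 2 * stats::pnorm(-abs(unname(stat))),
                 importance = abs(unname(stat)))
}

#' @rdname fit_negbin
#' @exportS3Method generics::glance
glance.v4_nbfit <- function(x, ...) {
  d <- nb_diagnostics(x)
  tibble::tibble(theta = x$theta, logLik = x$loglik,
                 deviance = d$deviance, chisq = d$chisq,
                 p.value = d$p_value, pseudo_r2 = d$pseudo_r2,
                 nobs = length(x$y), converged = x$converged)
}

#' Goodness of fit and model comparison for an NB GLM
#'
#' Residual deviance `D = 2[LL(saturated) - LL(model)]` (the saturated model
#' sets each predicted response to the observed response, at the model's
#' fitted theta), likelihood-ratio statistic against the intercept-only null
#' `chisq = 2[LL(model) - LL(null)]` with `df = k` non-intercept predictors,
#' and the Cragg-Uhler pseudo R-squared
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`, which is 0 for the null model and
#' bounded by 1.
#'
#' @param fit A `v4_nbfit`.
#' @param null_fit Optional intercept-only `v4_nbfit` on the same counts
#'   (fitted internally when omitted).
#' @return One-row tibble: `deviance`, `chisq`, `df`, `p_value`,
#'   `significant`, `pseudo_r2`, `flagged` (TRUE if the model likelihood
#'   fell below the null's, which signals an optimization failure).
#' @export
nb_diagnostics <- function(fit, null_fit = NULL) {
  y <- fit$y
  n <- length(y)
  if (is.null(null_fit)) {
    null_fit <- fit_negbin(matrix(numeric(0), n, 0), y, intercept = TRUE,
                           theta_max = max(fit$theta, 1e6))
  }
  ll1 <- fit$loglik
  ll0 <- null_fit$loglik
  flagged <- ll1 < ll0 - 1e-6
  ll_sat <- nb_loglik(y, pmax(y, 1e-12), fit$theta)
  k <- length(fit$coefficients) - 1
  chisq <- max(2 * (ll1 - ll0), 0)
  r2 <- (1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0))
  tibble::tibble(deviance = 2 * (ll_sat - ll1), chisq = chisq, df = k,
                 p_value = stats::pchisq(chisq, df = max(k, 1),
                                         lower.tail = FALSE),
                 significant = stats::pchisq(chisq, df = max(k, 1),
                                             lower.tail = FALSE) < 0.05,
                 pseudo_r2 = min(max(r2, 0), 1), flagged = flagged)
}

#' Standardized coefficients
#'
#' `beta'_j = beta_j * sd(x_j) / sd(y)`: the change in log mean response, in
#' units of response SD, per one-SD change of the predictor. Categorical 0/1
#' columns use the SD of their coding. The intercept is not standardized.
#'
#' @param fit A `v4_nbfit`.
#' @return Tibble: `term`, `estimate`, `std_estimate` (`NA`, flagged, for
#'   constant columns).
#' @export
standardize_coefs <- function(fit) {
  X <- fit$X
  keep <- colnames(X) != "(Intercept)"
  sx <- apply(X[, keep, drop = FALSE], 2, stats::sd)
  sy <- stats::sd(fit$y)
  std <- fit$coefficients[keep] * sx / sy
  std[sx == 0] <- NA_real_
  if (any(sx == 0)) warning("constant predictor column(s): standardization undefined",
                            call. = FALSE)
  tibble::tibble(term = colnames(X)[keep],
                 estimate = unname(fit$coefficients[keep]),
                 std_estimate = unname(std))
}

#' Predictor importance
#'
#' The absolute z-statistic `|beta_j / SE(beta_j)|` of each non-intercept
#' coefficient.
#'
#' @param fit A `v4_nbfit`.
#' @return Tibble: `term`, `importance`.
#' @export
predictor_importance <- function(fit) {
  keep <- names(fit$coefficients) != "(Intercept)"
  tibble::tibble(term = names(fit$coefficients)[keep],
                 importance = abs(fit$coefficients[keep] / fit$se[keep]))
}

#' K-fold cross-validated prediction error
#'
#' Random partition into `K` folds; the model is refit on `K - 1` folds and
#' squared error is accumulated on the held-out counts:
#' `Error = (1/n) * sum over folds and held-out trials of (y - yhat)^2`.
#'
#' @param X Design matrix (no intercept column).
#' @param y Counts.
#' @param K Folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return A list: `error`, `fold_errors`, `folds` (assignment), `n_failed`.
#' @export
crossval_negbin <- function(X, y, K = 10, seed = 1) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(n >= K)
  folds <- with_seed(seed, sample(rep_len(seq_len(K), n)))
  sse <- 0; n_used <- 0; n_failed <- 0
  fold_errors <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    tr <- folds != k
    f <- tryCatch(fit_negbin(X[tr, , drop = FALSE], y[tr]),
                  error = function(e) NULL)
    if (is.null(f)) { n_failed <- n_failed + 1; next }
    Xte <- cbind(1, X[!tr, , drop = FALSE])
    yhat <- exp(pmin(as.vector(Xte %*% f$coefficients), 30))
    fold_errors[k] <- sum((y[!tr] - yhat)^2)
    sse <- sse + fold_errors[k]
    n_used <- n_used + sum(!tr)
  }
  list(error = sse / n_used, fold_errors = fold_errors / table(folds),
       folds = folds, n_failed = n_failed)
}

#' Orientation tuning filter
#'
#' Mean-normalized training-set response per test-1 orientation:
#' `f(o) = mean(y | ori == o) / mean(y)`. The filter value indexed by each
#' trial's test-1 orientation forms the stimulus-feature column of the
#' test-1 design matrices. Estimate it on training trials only to avoid
#' test-fold leakage.
#'
#' @param counts Counts per trial.
#' @param oris Test-1 orientation per trial.
#' @param levels Orientations the filter must cover (default: those present).
#' @param min_per_ori Minimum trials per orientation.
#' @return Named numeric vector of filter values per orientation.
#' @export
tuning_filter <- function(counts, oris, levels = sort(unique(oris)),
                          min_per_ori = 5) {
  tab <- table(factor(oris, levels = levels))
  if (any(tab < min_per_ori)) {
    stop("filter error: orientation(s) with fewer than ", min_per_ori,
         " training trials: ", paste(levels[tab < min_per_ori], collapse = ", "),
         call. = FALSE)
  }
  m <- tapply(counts, factor(oris, levels = levels), mean)
  f <- m / mean(counts)
  stats::setNames(as.numeric(f), levels)
}

#' Build a design matrix for one unit
#'
#' Assembles the predictors of the requested encoding model from a session's
#' trial table. Sample-period models use sample-window counts; test-1 models
#' use test-1-window counts, keep only trials whose test-1 stimulus appeared
#' inside the recorded RFs, and replace the sample-orientation indicator with
#' the tuning-filter stimulus feature.
#'
#' Models: `"complete"` (sample orientation indicator, mean pupil area,
#' saccade indicator, 10 reward-history lags), `"reward"` (reward history
#' only), `"pupil"` (pupil only), `"saccade"` (test-1: stimulus feature,
#' pupil, reward history, saccade), `"dori"` (test-1: stimulus feature,
#' pupil, reward history, orientation change).
#'
#' Trials without a full 10-lag completed reward history are dropped and
#' counted.
#'
#' @param session A `v4_session`.
#' @param unit Unit id.
#' @param model Model name (see above).
#' @param filter_trials Completed-trial ids used to estimate the tuning
#'   filter (training folds); defaults to the included trials themselves.
#' @return A list: `X` (matrix, no intercept), `y`, `trials` (ids), `model`,
#'   `n_dropped`, `var_col` (the decoded-variable column for this model, or
#'   NA), `filter` (tuning filter, test-1 models).
#' @export
build_design <- function(session, unit,
                         model = c("complete", "reward", "pupil",
                                   "saccade", "dori"),
                         filter_trials = NULL) {
  model <- match.arg(model)
  ct <- completed_trials(session)
  cfg <- session$truth$config
  rhist <- reward_history(ct$reward_ul, n_lags = 10)
  ok <- stats::complete.cases(rhist)
  test1 <- model %in% c("saccade", "dori")
  if (test1) ok <- ok & ct$test_side == "inRF"
  n_dropped <- sum(!stats::complete.cases(rhist))

  counts <- if (test1) session$counts_test1 else session$counts_sample
  y <- counts[ok, unit]
  filt <- NULL
  if (test1) {
    levels <- sort(unique(ct$test1_ori))
    ftr <- filter_trials %||% ct$trial[ok]
    fidx <- ct$trial %in% ftr & ok
    filt <- tuning_filter(counts[fidx, unit], ct$test1_ori[fidx],
                          levels = levels)
    stimfeat <- filt[match(ct$test1_ori[ok], levels)]
    X <- cbind(stimfeat = as.numeric(stimfeat),
               pupil = ct$pupil_mean[ok],
               rhist[ok, , drop = FALSE])
    X <- if (model == "saccade") cbind(X, saccade = ct$saccade[ok]) else
      cbind(X, dori = ct$dori[ok])
  } else {
    ori_ind <- as.integer(ct$sample_ori == max(cfg$sample_oris))
    X <- switch(model,
      complete = cbind(ori = ori_ind[ok], pupil = ct$pupil_mean[ok],
                       saccade = ct$saccade[ok], rhist[ok, , drop = FALSE]),
      reward = rhist[ok, , drop = FALSE],
      pupil = cbind(pupil = ct$pupil_mean[ok]))
  }
  var_col <- switch(model, saccade = "saccade", dori = "dori", NA_character_)
  list(X = X, y = y, trials = ct$trial[ok], model = model,
       n_dropped = n_dropped, var_col = var_col, filter = filt)
}

#' Partial correlations among predictors
#'
#' From the inverse correlation matrix; used to confirm the design has no
#' collinear predictors.
#'
#' @param X Design matrix (no intercept).
#' @return Tibble of pairwise partial correlations.
#' @export
predictor_partial_cors <- function(X) {
  R <- stats::cor(X)
  P <- solve(R)
  D <- diag(1 / sqrt(diag(P)))
  pc <- -D %*% P %*% D
  idx <- which(upper.tri(pc), arr.ind = TRUE)
  tibble::tibble(var1 = colnames(X)[idx[, 1]], var2 = colnames(X)[idx[, 2]],
                 partial_cor = pc[idx])
}

#' Fit one unit's encoding model
#'
#' [build_design()] followed by [fit_negbin()]; the returned fit carries the
#' design metadata needed for decoding.
#'
#' @inheritParams build_design
#' @return A `v4_nbfit` with extra fields `unit`, `model`, `trials`,
#'   `var_col`.
#' @export
fit_unit_glm <- function(session, unit, model = "complete",
                         filter_trials = NULL) {
  d <- build_design(session, unit, model, filter_trials)
  fit <- fit_negbin(d$X, d$y)
  fit$unit <- unit
  fit$model <- d$model
  fit$trials <- d$trials
  fit$var_col <- d$var_col
  fit
}

#' Fit an encoding model for every unit of a session
#'
#' @param session A `v4_session`.
#' @param model Model name (see [build_design()]).
#' @param units Unit ids (default: all).
#' @return A list with class `v4_glmset`: `fits` (per unit), `summary`
#'   (tibble: unit, theta, pseudo_r2, p_value, significant), `model`.
#' @export
fit_session_glms <- function(session, model = "complete", units = NULL) {
  units <- units %||% session$units$unit
  fits <- lapply(units, function(u) fit_unit_glm(session, u, model))
  names(fits) <- units
  smry <- purrr::map2_dfr(fits, units, function(f, u) {
    d <- nb_diagnostics(f)
    tibble::tibble(unit = u, theta = f$theta, loglik = f$loglik,
                   pseudo_r2 = d$pseudo_r2, p_value = d$p_value,
                   significant = d$significant, converged = f$converged)
  })
  structure(list(fits = fits, summary = smry, model = model),
            class = "v4_glmset")
}

#' @export
print.v4_glmset <- function(x, ...) {
  cat(sprintf("<v4_glmset> %s model, %d units, %d significant (p < 0.05)\n",
              x$model, nrow(x$summary), sum(x$summary$significant)))
  invisible(x)
}

#' Screen test-1 fits for stimulus-feature / orientation-change confounds
#'
#' Spearman correlation between the stimulus-feature partial prediction
#' (`beta_stimfeat * x_stimfeat`) and the orientation-change partial
#' prediction (`beta_dori * x_dori`); units are retained only when
#' `|r| < 0.2` (strict), isolating the orientation-change coefficient from
#' tuning-related effects.
#'
#' @param fit A `v4_nbfit` from the `"dori"` model.
#' @return One-row tibble: `unit`, `r`, `retained`.
#' @export
delta_ori_screen <- function(fit) {
  stopifnot(all(c("stimfeat", "dori") %in% colnames(fit$X)))
  p_sf <- fit$coefficients["stimfeat"] * fit$X[, "stimfeat"]
  p_do <- fit$coefficients["dori"] * fit$X[, "dori"]
  r <- if (stats::sd(p_sf) == 0 || stats::sd(p_do) == 0) 0 else
    suppressWarnings(stats::cor(p_sf, p_do, method = "spearman"))
  # the 0.2 boundary itself is excluded; guard against float round-off of
  # exact rational rank correlations
  at_boundary <- isTRUE(all.equal(abs(r), 0.2))
  tibble::tibble(unit = fit$unit %||% NA_integer_, r = r,
                 retained = abs(r) < 0.2 && !at_boundary)
}
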