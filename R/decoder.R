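#' Per-trial log-likelihood-ratio decoding of a binary task variable
#'
#' For each trial and each (significantly fit) neuron, the log-likelihood of
#' the observed test-1 spike count is evaluated under both hypothesized
#' values of the decoded variable, holding every other predictor at its
#' observed per-trial value. The summed log-likelihood ratio across neurons
#' gives, with a flat prior, the posterior odds of the variable; the decoded
#' value is the likelihood-maximizing one, with an exact tie broken by a
#' seeded fair coin.
#'
#' @param glmset A `v4_glmset` from the `"saccade"` or `"dori"` model.
#' @param trials Optional completed-trial ids to decode (default: the
#'   trials the fits were built on, or all eligible trials of `newdata`).
#' @param alpha Only units with model p-value below this enter (default
#'   0.05).
#' @param seed Seed for tie-breaks.
#' @param newdata Optional held-out `v4_session`: designs are rebuilt on it
#'   and its counts are decoded with the training-session fits
#'   (cross-validated decoding).
#' @return Tibble: `trial`, `truth`, `llr` (summed log-likelihood ratio for
#'   value 1 vs 0), `posterior` (P(value = 1)), `decoded`, `correct`,
#'   plus attribute `n_neurons`.
#' @export
decode_trials <- function(glmset, trials = NULL, alpha = 0.05, seed = 1,
                          newdata = NULL) {
  keep <- glmset$summary$unit[glmset$summary$p_value < alpha]
  if (length(keep) == 0) stop("decoding error: no significantly fit neuron",
                              call. = FALSE)
  fits <- glmset$fits[as.character(keep)]
  f1 <- fits[[1]]
  vc <- f1$var_col
  stopifnot(!is.na(vc))
  designs <- if (is.null(newdata)) NULL else
    lapply(fits, function(f) build_design(newdata, f$unit, glmset$model))
  ref_trials <- if (is.null(newdata)) f1$trials else designs[[1]]$trials
  use <- trials %||% ref_trials
  idx <- match(use, ref_trials)
  stopifnot(!anyNA(idx))

  llr <- rep(0, length(idx))
  for (j in seq_along(fits)) {
    f <- fits[[j]]
    b <- f$coefficients[vc]
    if (is.null(newdata)) {
      x <- f$X[idx, vc]
      eta <- f$linear_predictors[idx]
      y <- f$y[idx]
    } else {
      d <- designs[[j]]
      x <- d$X[idx, vc]
      eta <- pmin(as.vector(cbind(1, d$X[idx, , drop = FALSE]) %*%
                              f$coefficients), 30)
      y <- d$y[idx]
    }
    mu1 <- exp(pmin(eta + b * (1 - x), 30))
    mu0 <- exp(pmin(eta + b * (0 - x), 30))
    llr <- llr + stats::dnbinom(y, size = f$theta, mu = mu1, log = TRUE) -
      stats::dnbinom(y, size = f$theta, mu = mu0, log = TRUE)
  }
  truth <- if (is.null(newdata)) f1$X[idx, vc] else designs[[1]]$X[idx, vc]
  decoded <- as.integer(llr > 0)
  ties <- which(llr == 0)
  if (length(ties) > 0) {
    decoded[ties] <- with_seed(seed, stats::rbinom(length(ties), 1, 0.5))
  }
  out <- tibble::tibble(trial = use, truth = as.integer(truth), llr = llr,
                        posterior = 1 / (1 + exp(-llr)),
                        decoded = decoded, correct = decoded == truth)
  attr(out, "n_neurons") <- length(fits)
  out
}

#' Paired-trial decoding accuracy
#'
#' Random pairs of trials, one from each class of the decoded variable,
#' drawn without replacement (`min(class sizes)` pairs per repetition,
#' `n_reps` seeded repetitions averaged). A pair counts as correct only when
#' both member trials are decoded correctly, so chance performance is 0.25.
#'
#' @param glmset A `v4_glmset` (`"saccade"` or `"dori"` model).
#' @param trials,alpha,seed,newdata As in [decode_trials()].
#' @param n_reps Pairing repetitions.
#' @return An object of class `v4_decode`: `variable`, `trial_table`,
#'   `accuracy`, `n_pairs` (total over repetitions), `n_neurons`,
#'   `chance` (0.25).
#' @export
decode_pairs <- function(glmset, trials = NULL, alpha = 0.05, n_reps = 10,
                         seed = 1, newdata = NULL) {
  tt <- decode_trials(glmset, trials = trials, alpha = alpha, seed = seed,
                      newdata = newdata)
  i1 <- which(tt$truth == 1)
  i0 <- which(tt$truth == 0)
  if (length(i1) == 0 || length(i0) == 0) {
    stop("decoding error: a class of the decoded variable is empty",
         call. = FALSE)
  }
  npp <- min(length(i1), length(i0))
  correct <- with_seed(seed, {
    unlist(lapply(seq_len(n_reps), function(r) {
      a <- sample(i1, npp)
      b <- sample(i0, npp)
      tt$correct[a] & tt$correct[b]
    }))
  })
  structure(list(variable = glmset$model, trial_table = tt,
                 accuracy = mean(correct), n_pairs = length(correct),
                 n_neurons = attr(tt, "n_neurons"), chance = 0.25),
            class = "v4_decode")
}

#' @export
print.v4_decode <- function(x, ...) {
  cat(sprintf("<v4_decode> %s: accuracy %.3f over %d pairs (%d neurons, chance %.2f)\n",
              x$variable, x$accuracy, x$n_pairs, x$n_neurons, x$chance))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.v4_decode <- function(x, ...) {
  tibble::tibble(variable = x$variable, accuracy = x$accuracy,
                 n_pairs = x$n_pairs, n_neurons = x$n_neurons,
                 chance = x$chance)
}

#' Balance outcome classes by resampling
#'
#' Minority outcome classes (typically misses and FAs) are resampled with
#' replacement until all four classes match the majority count, avoiding
#' decoding bias toward the more frequent choice.
#'
#' @param trials Trial table or `v4_session` (completed trials used).
#' @param seed Seed for the resampling.
#' @return The balanced completed-trial tibble (rows may repeat).
#' @export
balance_classes <- function(trials, seed = 1) {
  if (inherits(trials, "v4_session")) trials <- trials$trials
  ct <- completed(trials)
  classes <- c("hit", "miss", "CR", "FA")
  tab <- table(factor(ct$outcome, levels = classes))
  if (any(tab == 0)) {
    stop("balancing error: outcome class(es) absent: ",
         paste(classes[tab == 0], collapse = ", "), call. = FALSE)
  }
  target <- max(tab)
  with_seed(seed, {
    dplyr::bind_rows(lapply(classes, function(cl) {
      rows <- ct[ct$outcome == cl, ]
      extra <- target - nrow(rows)
      if (extra > 0) {
        rows <- dplyr::bind_rows(rows, rows[sample(nrow(rows), extra,
                                                   replace = TRUE), ])
      }
      rows
    }))
  })
}

#' Decode behavioral choice from the saccade model
#'
#' Saccade decoding is converted to a four-way choice using the known trial
#' type: on nonmatch trials a decoded saccade means hit (else miss); on
#' match trials a decoded saccade means FA (else CR). Pairs are drawn within
#' nonmatch trials (hit vs miss) and within match trials (CR vs FA) from the
#' class-balanced trial set; a pair is correct only when both members are
#' discriminated, so chance is 0.25.
#'
#' @param session A `v4_session` supplying the outcome classes; when it is
#'   not the session the models were fit on, it is also passed to
#'   [decode_trials()] as held-out data.
#' @param saccade_glmset A `v4_glmset` from the `"saccade"` model.
#' @param alpha,seed,n_reps As in [decode_pairs()].
#' @param held_out Set `TRUE` when `session` is not the training session.
#' @return A `v4_decode` with `variable = "choice"`.
#' @export
decode_choice <- function(session, saccade_glmset, alpha = 0.05, n_reps = 10,
                          seed = 1, held_out = FALSE) {
  bal <- balance_classes(session, seed = seed)
  tt <- decode_trials(saccade_glmset, alpha = alpha, seed = seed,
                      newdata = if (held_out) session else NULL)
  bal <- bal[bal$trial %in% tt$trial, ]
  dec <- tt$correct[match(bal$trial, tt$trial)]   # saccade decoded correctly
  pair_sets <- list(c("hit", "miss"), c("CR", "FA"))
  correct <- with_seed(seed + 1, {
    unlist(lapply(seq_len(n_reps), function(r) {
      unlist(lapply(pair_sets, function(ps) {
        a <- which(bal$outcome == ps[1])
        b <- which(bal$outcome == ps[2])
        npp <- min(length(a), length(b))
        if (npp == 0) return(logical(0))
        a <- sample(a, npp); b <- sample(b, npp)
        dec[a] & dec[b]
      }))
    }))
  })
  structure(list(variable = "choice", trial_table = tt,
                 accuracy = mean(correct), n_pairs = length(correct),
                 n_neurons = attr(tt, "n_neurons"), chance = 0.25),
            class = "v4_decode")
}

#' Decoding accuracy as a function of population size
#'
#' Paired-trial accuracy for random neuron subsets of increasing size, with
#' a second-order polynomial least-squares fit and 95% confidence band.
#'
#' @param glmset A `v4_glmset`.
#' @param n_grid Population sizes to probe; values above the number of
#'   significantly fit neurons are truncated with a warning.
#' @param n_subsets Random subsets per size.
#' @param alpha,seed,n_reps As in [decode_pairs()].
#' @return A list: `curve` (tibble `n`, `accuracy`), `fit` (lm of accuracy
#'   on poly(n, 2)), `band` (tibble with fitted values and 95% CI).
#' @export
accuracy_vs_n_neurons <- function(glmset, n_grid = c(1, 2, 5, 10, 20),
                                  n_subsets = 5, alpha = 0.05, n_reps = 5,
                                  seed = 1) {
  sig <- glmset$summary$unit[glmset$summary$p_value < alpha]
  if (any(n_grid > length(sig))) {
    warning("population sizes truncated to ", length(sig),
            " significantly fit neurons", call. = FALSE)
    n_grid <- unique(pmin(n_grid, length(sig)))
  }
  curve <- purrr::map_dfr(n_grid, function(n) {
    accs <- vapply(seq_len(n_subsets), function(s) {
      units <- with_seed(seed + 1000 * n + s, sample(sig, n))
      sub <- glmset
      sub$fits <- glmset$fits[as.character(units)]
      sub$summary <- glmset$summary[glmset$summary$unit %in% units, ]
      decode_pairs(sub, alpha = alpha, n_reps = n_reps, seed = seed + s)$accuracy
    }, numeric(1))
    tibble::tibble(n = n, accuracy = mean(accs), sd = stats::sd(accs))
  })
  fit <- stats::lm(accuracy ~ stats::poly(n, min(2, length(n_grid) - 1)),
                   data = curve)
  band <- if (stats::df.residual(fit) >= 1) {
    pr <- stats::predict(fit, interval = "confidence", level = 0.95)
    dplyr::bind_cols(curve["n"], tibble::as_tibble(pr))
  } else {
    tibble::tibble(n = curve$n, fit = stats::fitted(fit),
                   lwr = NA_real_, upr = NA_real_)
  }
  list(curve = curve, fit = fit, band = band)
}
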