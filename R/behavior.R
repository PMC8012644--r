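#' Signal-detection sensitivity and criterion from outcome counts
#'
#' Computes `d' = qnorm(hit rate) - qnorm(FA rate)` and criterion
#' `c = -(qnorm(hit rate) + qnorm(FA rate)) / 2`, where the hit rate is taken
#' within nonmatch trials and the FA rate within match trials. Rates of
#' exactly 0 or 1 are clipped to `1/(2N)` and `1 - 1/(2N)` of their class
#' before the probit transform (the log-linear correction). Percent correct
#' is `(hits + CRs) / completed trials`.
#'
#' @param n_hit,n_miss,n_cr,n_fa Non-negative outcome counts.
#' @return A one-row tibble: `hit_rate`, `fa_rate`, `dprime`, `criterion`,
#'   `pc`, and the class sizes.
#' @export
#' @examples
#' dprime_criterion(84, 16, 84, 16) # d' ~ 2, c ~ 0
dprime_criterion <- function(n_hit, n_miss, n_cr, n_fa) {
  n_sig <- n_hit + n_miss
  n_noise <- n_cr + n_fa
  if (n_sig < 1 || n_noise < 1) {
    stop("undefined-rate error: need at least one nonmatch and one match trial",
         call. = FALSE)
  }
  hit <- clip_rate(n_hit, n_sig)
  fa <- clip_rate(n_fa, n_noise)
  zh <- stats::qnorm(hit)
  zf <- stats::qnorm(fa)
  tibble::tibble(
    hit_rate = hit, fa_rate = fa,
    dprime = zh - zf,
    criterion = -(zh + zf) / 2,
    pc = (n_hit + n_cr) / (n_sig + n_noise),
    n_signal = n_sig, n_noise = n_noise
  )
}

#' Combine per-hemifield sensitivities into overall d'
#'
#' Overall (spatially nonselective) sensitivity is the Euclidean combination
#' `sqrt(d_in^2 + d_out^2)` of the sensitivities for test stimuli inside and
#' outside the recorded receptive fields.
#'
#' @param d_in,d_out Per-hemifield sensitivities.
#' @return `sqrt(d_in^2 + d_out^2)`.
#' @export
#' @examples
#' overall_dprime(3, 4) # 5
overall_dprime <- function(d_in, d_out) {
  sqrt(d_in^2 + d_out^2)
}

#' Behavioral summary of a trial table
#'
#' Per reward condition: hit/FA rates, d', criterion, percent correct, the
#' per-hemifield sensitivities (test stimulus inside vs outside the recorded
#' RFs), and overall d' combining them via [overall_dprime()]. Aborted trials
#' are excluded throughout.
#'
#' @param trials A trial table (as in `v4_session$trials`) or a `v4_session`.
#' @return A tibble with one row per reward condition.
#' @export
behavior_summary <- function(trials) {
  if (inherits(trials, "v4_session")) trials <- trials$trials
  ct <- completed(trials)
  one <- function(df) {
    s <- dprime_criterion(sum(df$outcome == "hit"), sum(df$outcome == "miss"),
                          sum(df$outcome == "CR"), sum(df$outcome == "FA"))
    d_in <- dprime_criterion(
      sum(df$outcome == "hit" & df$test_side == "inRF"),
      sum(df$outcome == "miss" & df$test_side == "inRF"),
      sum(df$outcome == "CR" & df$test_side == "inRF"),
      sum(df$outcome == "FA" & df$test_side == "inRF"))$dprime
    d_out <- dprime_criterion(
      sum(df$outcome == "hit" & df$test_side == "outRF"),
      sum(df$outcome == "miss" & df$test_side == "outRF"),
      sum(df$outcome == "CR" & df$test_side == "outRF"),
      sum(df$outcome == "FA" & df$test_side == "outRF"))$dprime
    dplyr::mutate(s, dprime_inRF = d_in, dprime_outRF = d_out,
                  dprime_overall = overall_dprime(d_in, d_out))
  }
  ct |>
    dplyr::group_by(.data$reward_cond) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Align completed trials to the first correct trial after block transitions
#'
#' Within each block, trials from the first correct response (hit or CR)
#' onward get aligned orders 1, 2, ...; earlier trials in the block get `NA`.
#' Blocks without any correct trial are skipped with a warning.
#'
#' @param trials Trial table or `v4_session`.
#' @return The completed-trial tibble with an added `aligned` column.
#' @export
align_blocks <- function(trials) {
  if (inherits(trials, "v4_session")) trials <- trials$trials
  ct <- completed(trials)
  out <- ct |>
    dplyr::group_by(.data$block) |>
    dplyr::group_modify(function(df, key) {
      first_ok <- which(df$outcome %in% c("hit", "CR"))[1]
      df$aligned <- NA_integer_
      if (is.na(first_ok)) {
        warning("block ", key$block, " has no correct trial; skipped",
                call. = FALSE)
      } else {
        idx <- first_ok:nrow(df)
        df$aligned[idx] <- seq_along(idx)
      }
      df
    }) |>
    dplyr::ungroup()
  out
}

#' Block-aligned trial courses pooled across blocks
#'
#' For a numeric variable: the mean at each aligned trial order, per reward
#' condition, pooled across blocks. For behavioral sensitivity, use
#' [aligned_dprime()], which pools all responses at a given order.
#'
#' @param aligned Output of [align_blocks()].
#' @param var Name of the numeric column to average (string).
#' @return Tibble: `reward_cond`, `aligned`, `mean`, `n`.
#' @export
aligned_course <- function(aligned, var) {
  aligned |>
    dplyr::filter(!is.na(.data$aligned)) |>
    dplyr::group_by(.data$reward_cond, .data$aligned) |>
    dplyr::summarise(mean = mean(.data[[var]], na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")
}

#' Block-aligned behavioral d' course
#'
#' d' at aligned order i is computed from all responses at order i pooled
#' across blocks of the same reward condition.
#'
#' @param aligned Output of [align_blocks()].
#' @param min_n Orders with fewer pooled trials than this are dropped.
#' @param bin_width Width (in aligned trials) of bins pooled before
#'   computing d'; use > 1 when few blocks are available per condition.
#' @return Tibble: `reward_cond`, `aligned` (bin center when `bin_width >
#'   1`), `dprime`, `criterion`, `pc`, `n`.
#' @export
aligned_dprime <- function(aligned, min_n = 4, bin_width = 1) {
  aligned |>
    dplyr::filter(!is.na(.data$aligned)) |>
    dplyr::mutate(aligned = (ceiling(.data$aligned / bin_width) - 0.5) *
                    bin_width + 0.5) |>
    dplyr::group_by(.data$reward_cond, .data$aligned) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < min_n ||
          sum(df$trial_type == "nonmatch") == 0 ||
          sum(df$trial_type == "match") == 0) {
        return(tibble::tibble(dprime = NA_real_, criterion = NA_real_,
                              pc = NA_real_, n = nrow(df)))
      }
      s <- dprime_criterion(sum(df$outcome == "hit"), sum(df$outcome == "miss"),
                            sum(df$outcome == "CR"), sum(df$outcome == "FA"))
      tibble::tibble(dprime = s$dprime, criterion = s$criterion, pc = s$pc,
                     n = nrow(df))
    }) |>
    dplyr::ungroup()
}

#' Fit a single exponential to a block-aligned trial course
#'
#' Nonlinear least squares of `y = A + B * exp(-t / tau)` with `tau`
#' constrained positive. Initialization: `A` from the tail mean, `tau` from a
#' log-linear regression of `log|y - A|` on `t`. A series with no usable
#' dynamic range is returned as a flagged degenerate fit (`B = 0`, `tau` NA)
#' rather than an error.
#'
#' @param y Response per trial order.
#' @param t Trial orders (default `seq_along(y)`); a seconds axis may be
#'   supplied instead to express the constant in time units.
#' @return An object of class `v4_expfit` with elements `A`, `B`, `tau`,
#'   `tau_se`, `tau_ci`, `resid_ss`, `fitted`, `degenerate`, `converged`.
#' @export
#' @examples
#' t <- 1:60
#' f <- fit_exponential(1 + 2 * exp(-t / 5), t)
#' f$tau
fit_exponential <- function(y, t = seq_along(y)) {
  keep <- is.finite(y) & is.finite(t)
  y <- y[keep]; t <- t[keep]
  if (length(y) < 8) stop("fit-failure error: need >= 8 finite points", call. = FALSE)

  n_tail <- max(3, round(length(y) / 4))
  A0 <- mean(utils::tail(y, n_tail))
  B0 <- y[1] - A0
  rng <- diff(range(y))
  if (rng == 0 || abs(B0) < 1e-12 * max(1, abs(A0))) {
    fit <- list(A = mean(y), B = 0, tau = NA_real_, tau_se = NA_real_,
                tau_ci = c(NA_real_, NA_real_),
                resid_ss = sum((y - mean(y))^2),
                fitted = rep(mean(y), length(y)), t = t, y = y,
                degenerate = TRUE, converged = TRUE)
    class(fit) <- "v4_expfit"
    return(fit)
  }
  res0 <- abs(y - A0)
  pos <- res0 > 1e-12 * rng
  tau0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(res0[pos]) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  tau0 <- min(max(tau0, 1e-3), diff(range(t)) * 10)

  try_fit <- function(tau_start) {
    tryCatch(
      minpack.lm::nlsLM(y ~ A + B * exp(-t / tau),
                        start = list(A = A0, B = B0, tau = tau_start),
                        lower = c(-Inf, -Inf, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  fit <- try_fit(tau0)
  if (inherits(fit, "error")) fit <- try_fit(diff(range(t)) / 3)
  if (inherits(fit, "error")) fit <- try_fit(diff(range(t)) / 20)
  if (inherits(fit, "error")) {
    stop("fit-failure error: ", conditionMessage(fit),
         sprintf(" (starting values A=%.3g B=%.3g tau=%.3g)", A0, B0, tau0),
         call. = FALSE)
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  out <- list(A = unname(co["A"]), B = unname(co["B"]),
              tau = unname(co["tau"]), tau_se = se,
              tau_ci = unname(co["tau"]) + c(-1, 1) * 1.96 * se,
              resid_ss = sum(stats::residuals(fit)^2),
              fitted = stats::fitted(fit), t = t, y = y,
              degenerate = FALSE, converged = fit$convInfo$isConv %||% TRUE)
  class(out) <- "v4_expfit"
  out
}

#' @export
print.v4_expfit <- function(x, ...) {
  if (x$degenerate) {
    cat("<v4_expfit> degenerate (constant series), A =", format(x$A), "\n")
  } else {
    cat(sprintf("<v4_expfit> y = %.4g + %.4g * exp(-t / %.4g), tau 95%% CI [%.3g, %.3g]\n",
                x$A, x$B, x$tau, x$tau_ci[1], x$tau_ci[2]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.v4_expfit <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "tau"),
                 estimate = c(x$A, x$B, x$tau),
                 std.error = c(NA_real_, NA_real_, x$tau_se))
}

#' @exportS3Method generics::glance
glance.v4_expfit <- function(x, ...) {
  tibble::tibble(tau = x$tau, tau_low = x$tau_ci[1], tau_high = x$tau_ci[2],
                 resid_ss = x$resid_ss, degenerate = x$degenerate,
                 converged = x$converged, nobs = length(x$y))
}

#' Hysteresis mid-point rewards for the two transition directions
#'
#' For each transition direction, finds the (fractional) aligned trial at
#' which the response trajectory crosses the midpoint of its dynamic range,
#' by linear interpolation, and reports the aligned reward value at that
#' point. A response that tracks reward instantaneously gives identical
#' mid-point rewards in both directions; direction-dependent lags separate
#' them.
#'
#' @param course A tibble with columns `direction` (two levels, e.g.
#'   `"small"`/`"large"` for the entered condition), `aligned`, `response`,
#'   and `reward` (block-aligned means pooled across blocks).
#' @return A tibble per direction: `mid_response`, `crossing_order`
#'   (fractional aligned trial), `mid_reward`, `flagged` (TRUE when the
#'   trajectory crossed the midpoint more than once and the first crossing
#'   was used).
#' @export
hysteresis_curve <- function(course) {
  dirs <- unique(course$direction)
  if (length(dirs) < 2) {
    stop("both transition directions must be present", call. = FALSE)
  }
  mid <- (max(course$response, na.rm = TRUE) +
            min(course$response, na.rm = TRUE)) / 2
  purrr::map_dfr(dirs, function(d) {
    df <- course |>
      dplyr::filter(.data$direction == d, is.finite(.data$response)) |>
      dplyr::arrange(.data$aligned)
    s <- df$response - mid
    cross <- which(s[-1] * s[-length(s)] <= 0 & (s[-1] != s[-length(s)]))
    if (length(cross) == 0) {
      return(tibble::tibble(direction = d, mid_response = mid,
                            crossing_order = NA_real_, mid_reward = NA_real_,
                            flagged = TRUE))
    }
    i <- cross[1]
    frac <- s[i] / (s[i] - s[i + 1])
    ord <- df$aligned[i] + frac * (df$aligned[i + 1] - df$aligned[i])
    rwd <- df$reward[i] + frac * (df$reward[i + 1] - df$reward[i])
    tibble::tibble(direction = d, mid_response = mid, crossing_order = ord,
                   mid_reward = rwd, flagged = length(cross) > 1)
  })
}
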