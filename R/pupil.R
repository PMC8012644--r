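#' Normalize raw pupil traces within a session
#'
#' Each eye is normalized separately by its session extrema over the 0-400 ms
#' window from sample onset: `(raw - min) / (max - min)`, then the two eyes
#' are averaged. Mean pupil area per trial is the average of the normalized
#' binocular trace over 0-400 ms.
#'
#' @param raw A trials x samples matrix of raw pupil areas (device units), or
#'   a named list of such matrices, one per eye.
#' @param time Sample times in ms relative to sample onset (length =
#'   `ncol`).
#' @param norm_window Window (ms) over which the session extrema and per-trial
#'   means are taken.
#' @return A list: `traces` (normalized, eye-averaged), `mean_area` (per
#'   trial), `extrema` (per-eye min/max used).
#' @export
normalize_pupil <- function(raw, time, norm_window = c(0, 400)) {
  if (is.matrix(raw)) raw <- list(eye = raw)
  win <- time >= norm_window[1] & time < norm_window[2]
  if (!any(win)) stop("normalization window contains no samples", call. = FALSE)
  norm_eyes <- lapply(raw, function(m) {
    v <- m[, win, drop = FALSE]
    lo <- min(v); hi <- max(v)
    if (hi <= lo) stop("normalization error: flat trace (max == min)", call. = FALSE)
    (m - lo) / (hi - lo)
  })
  traces <- Reduce(`+`, norm_eyes) / length(norm_eyes)
  extrema <- purrr::map_dfr(names(raw), function(e) {
    v <- raw[[e]][, win, drop = FALSE]
    tibble::tibble(eye = e, pupil_min = min(v), pupil_max = max(v))
  })
  list(traces = traces,
       mean_area = rowMeans(traces[, win, drop = FALSE]),
       extrema = extrema, time = time)
}

# 10 ms boxcar spike rate stepped at 2 ms for one unit, trials x centers
spike_rate_series <- function(spikes, unit_id, n_trials, centers,
                              binwidth = 10) {
  sp <- spikes[spikes$unit == unit_id, ]
  out <- matrix(0, n_trials, length(centers))
  if (nrow(sp) == 0) return(out)
  half <- binwidth / 2
  step <- centers[2] - centers[1]
  for (j in seq_along(centers)) {
    lo <- centers[j] - half; hi <- centers[j] + half
    idx <- sp$time >= lo & sp$time < hi
    if (any(idx)) {
      tab <- table(sp$trial[idx])
      out[as.integer(names(tab)), j] <- as.integer(tab)
    }
  }
  out / (binwidth / 1000)
}

#' Shuffle-corrected pupil-spike cross-correlation
#'
#' Single-trial cross-correlations between the unit's spike-rate series
#' (10 ms sliding bins, 2 ms steps) and the pupil trace (native 500 Hz
#' sampling) as a function of lag, averaged across trials, minus the average
#' over trial-shuffled pairings, separately per reward condition. Negative
#' lags mean pupil leads spikes. Lags where either series has zero variance
#' are returned as `NA` (flagged), never silently zero.
#'
#' @param session A `v4_session` with spike times.
#' @param unit Unit id.
#' @param lags Lags in ms (multiples of the pupil sampling step).
#' @param window Analysis window (ms around sample onset) for the spike-rate
#'   series.
#' @return Tibble: `reward_cond`, `lag`, `r`, `r_shuffled`, `r_corrected`.
#' @export
pupil_spike_xcorr <- function(session, unit,
                              lags = seq(-350, 350, by = 2),
                              window = c(-350, 350)) {
  stopifnot(!is.null(session$spikes))
  ct <- completed_trials(session)
  centers <- seq(window[1], window[2], by = 2)
  S <- spike_rate_series(session$spikes, unit, nrow(ct), centers)
  P <- session$pupil
  ptime <- session$pupil_time

  purrr::map_dfr(unique(ct$reward_cond), function(cond) {
    tr <- which(ct$reward_cond == cond)
    if (length(tr) < 2) return(NULL)
    Sc <- S[tr, , drop = FALSE]
    perm <- c(seq_along(tr)[-1], 1)       # trial-shuffled pairing
    r <- r_sh <- rep(NA_real_, length(lags))
    for (k in seq_along(lags)) {
      tcol <- centers + lags[k]
      ok <- tcol >= min(ptime) & tcol <= max(ptime)
      if (sum(ok) < 10) next
      pj <- match(round(tcol[ok]), round(ptime))
      Pm <- P[tr, pj, drop = FALSE]
      r[k] <- mean_rowwise_cor(Sc[, ok, drop = FALSE], Pm)
      r_sh[k] <- mean_rowwise_cor(Sc[perm, ok, drop = FALSE], Pm)
    }
    tibble::tibble(reward_cond = cond, lag = lags, r = r, r_shuffled = r_sh,
                   r_corrected = r - r_sh)
  })
}

# mean over rows of cor(row of A, row of B); rows with zero variance dropped
mean_rowwise_cor <- function(A, B) {
  Ac <- A - rowMeans(A); Bc <- B - rowMeans(B)
  sa <- rowSums(Ac^2); sb <- rowSums(Bc^2)
  ok <- sa > 0 & sb > 0
  if (!any(ok)) return(NA_real_)
  mean(rowSums(Ac[ok, , drop = FALSE] * Bc[ok, , drop = FALSE]) /
         sqrt(sa[ok] * sb[ok]))
}

#' Spike-triggered average pupil area, shuffle-corrected
#'
#' Pupil traces aligned to individual spikes (0-400 ms from sample onset)
#' and averaged; the shuffled STA realigns each spike to the pupil trace of
#' a different trial and is subtracted.
#'
#' @param session A `v4_session` with spike times.
#' @param unit Unit id.
#' @param sta_window Symmetric window (ms) around each spike.
#' @param spike_window Window of spikes to use (ms from sample onset).
#' @param min_spikes Minimum pooled spikes.
#' @return Tibble: `lag`, `sta`, `sta_shuffled`, `sta_corrected`; attribute
#'   `n_spikes`.
#' @export
sta_pupil <- function(session, unit, sta_window = c(-200, 200),
                      spike_window = c(0, 400), min_spikes = 100) {
  stopifnot(!is.null(session$spikes))
  sp <- session$spikes
  sp <- sp[sp$unit == unit & sp$time >= spike_window[1] &
             sp$time < spike_window[2], ]
  if (nrow(sp) < min_spikes) {
    stop("insufficient-data error: ", nrow(sp), " spikes (< ", min_spikes, ")",
         call. = FALSE)
  }
  ptime <- session$pupil_time
  step <- ptime[2] - ptime[1]
  rel <- seq(sta_window[1], sta_window[2], by = step)
  n_tr <- nrow(session$pupil)

  grab <- function(trial_idx) {
    # rows: spikes; cols: rel lags; NA outside the recorded trace
    tmat <- outer(sp$time, rel, `+`)
    jmat <- round((tmat - ptime[1]) / step) + 1
    ok <- jmat >= 1 & jmat <= length(ptime)
    jmat[!ok] <- 1
    vals <- session$pupil[cbind(rep(trial_idx, ncol(jmat)), as.vector(t(jmat)))]
    m <- matrix(vals, nrow = nrow(sp), byrow = TRUE)
    m[!ok] <- NA
    m
  }
  sta <- colMeans(grab(sp$trial), na.rm = TRUE)
  sh_trial <- (sp$trial %% n_tr) + 1         # deterministic other-trial pairing
  sta_sh <- colMeans(grab(sh_trial), na.rm = TRUE)
  out <- tibble::tibble(lag = rel, sta = sta, sta_shuffled = sta_sh,
                        sta_corrected = sta - sta_sh)
  attr(out, "n_spikes") <- nrow(sp)
  out
}

#' Pupil-area regression on spike counts and attentional intensity
#'
#' Fits `pupil = a * spikes + b * intensity` by ordinary least squares on
#' z-scored variables without an intercept. When `intensity` is `NULL`, the
#' reduced form `pupil = a * spikes` is fit. Model significance is the
#' overall F-test at `p < 0.05`.
#'
#' @param pupil,spikes Numeric vectors (per trial).
#' @param intensity Optional attentional-intensity label per trial (numeric
#'   or two-level factor/character; z-scored like the rest).
#' @return One-row tibble: `a`, `b` (NA in the reduced form), `f_stat`,
#'   `p_value`, `significant`, `n`.
#' @export
regress_pupil <- function(pupil, spikes, intensity = NULL) {
  z <- function(v) {
    if (!is.numeric(v)) v <- as.numeric(factor(v))
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("regression error: constant variable", call. = FALSE)
    }
    (v - mean(v)) / s
  }
  df <- data.frame(p = z(pupil), s = z(spikes))
  if (!is.null(intensity)) {
    df$i <- z(intensity)
    fit <- stats::lm(p ~ 0 + s + i, data = df)
  } else {
    fit <- stats::lm(p ~ 0 + s, data = df)
  }
  if (any(is.na(stats::coef(fit)))) {
    stop("regression error: rank-deficient design", call. = FALSE)
  }
  fs <- summary(fit)$fstatistic
  pval <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  tibble::tibble(a = unname(stats::coef(fit)["s"]),
                 b = if (is.null(intensity)) NA_real_ else
                   unname(stats::coef(fit)["i"]),
                 f_stat = unname(fs[1]), p_value = unname(pval),
                 significant = pval < 0.05, n = nrow(df))
}

#' Greedy pupil matching across reward conditions
#'
#' Nearest-neighbor matching of trials on mean pupil area between the two
#' reward conditions with a caliper (default 0.05 normalized units); each
#' trial is used at most once.
#'
#' @param trials Trial table or `v4_session` (completed trials used).
#' @param caliper Maximum pupil-area difference for a match.
#' @return Tibble of matched pairs: `trial_small`, `trial_large`,
#'   `pupil_small`, `pupil_large`.
#' @export
match_pupil_trials <- function(trials, caliper = 0.05) {
  if (inherits(trials, "v4_session")) trials <- trials$trials
  ct <- completed(trials)
  sm <- ct[ct$reward_cond == "small", c("trial", "pupil_mean")]
  lg <- ct[ct$reward_cond == "large", c("trial", "pupil_mean")]
  lg <- lg[order(lg$pupil_mean), ]
  used <- rep(FALSE, nrow(lg))
  pairs <- purrr::map_dfr(order(sm$pupil_mean), function(i) {
    d <- abs(lg$pupil_mean - sm$pupil_mean[i])
    d[used] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j]) || d[j] > caliper) return(NULL)
    used[j] <<- TRUE
    tibble::tibble(trial_small = sm$trial[i], trial_large = lg$trial[j],
                   pupil_small = sm$pupil_mean[i], pupil_large = lg$pupil_mean[j])
  })
  pairs
}
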