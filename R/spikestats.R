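#' Spike counts in a time window
#'
#' Counts spikes per completed trial and unit in a half-open window
#' `[start, end)` ms relative to sample onset.
#'
#' @param session A `v4_session` with spike times.
#' @param window `c(start, end)` in ms.
#' @return Integer matrix, completed trials x units.
#' @export
window_counts <- function(session, window) {
  stopifnot(!is.null(session$spikes))
  sp <- session$spikes
  n_tr <- nrow(completed_trials(session))
  n_un <- nrow(session$units)
  sp <- sp[sp$time >= window[1] & sp$time < window[2], ]
  out <- matrix(0L, n_tr, n_un)
  if (nrow(sp) > 0) {
    tab <- table(factor(sp$trial, levels = seq_len(n_tr)),
                 factor(sp$unit, levels = seq_len(n_un)))
    out <- matrix(as.integer(tab), n_tr, n_un)
  }
  out
}

#' Screen units for stimulus responsiveness
#'
#' One-sided paired comparison (t-test) of the evoked rate (60-260 ms after
#' sample onset) against the baseline rate (-250-0 ms); units whose evoked
#' rate is significantly greater at `p < alpha` are kept.
#'
#' @param session A `v4_session` with spike times.
#' @param alpha Significance level (default 0.01).
#' @param evoked_window,baseline_window Analysis windows, ms.
#' @return Tibble: `unit`, `evoked_rate`, `baseline_rate`, `p_value`, `keep`.
#' @export
screen_responsive <- function(session, alpha = 0.01,
                              evoked_window = c(60, 260),
                              baseline_window = c(-250, 0)) {
  ev <- window_counts(session, evoked_window) / (diff(evoked_window) / 1000)
  bs <- window_counts(session, baseline_window) / (diff(baseline_window) / 1000)
  stopifnot(nrow(ev) >= 10)
  purrr::map_dfr(seq_len(ncol(ev)), function(u) {
    p <- if (stats::sd(ev[, u] - bs[, u]) == 0) 1 else
      stats::t.test(ev[, u], bs[, u], paired = TRUE,
                    alternative = "greater")$p.value
    tibble::tibble(unit = u, evoked_rate = mean(ev[, u]),
                   baseline_rate = mean(bs[, u]), p_value = p,
                   keep = p < alpha)
  })
}

#' Causal half-Gaussian smoothing kernel
#'
#' Gaussian of standard deviation `sigma` (ms) with only the rightward tail
#' (a spike influences later times only), discretized at `binwidth` and
#' normalized to unit mass: `sum(kernel) * binwidth == 1`.
#'
#' @param sigma Kernel SD, ms.
#' @param binwidth Bin width, ms.
#' @return Numeric vector of kernel densities (per ms).
#' @export
half_gaussian_kernel <- function(sigma = 15, binwidth = 2) {
  tt <- seq(0, 5 * sigma, by = binwidth)
  k <- exp(-tt^2 / (2 * sigma^2))
  k / (sum(k) * binwidth)
}

#' Peri-stimulus time histogram
#'
#' Spike trains binned at `binwidth` ms, averaged across trials, converted to
#' spikes/s and smoothed with a causal half-Gaussian kernel
#' ([half_gaussian_kernel()]). With `normalize = TRUE` the rate is divided by
#' its peak within `peak_window` (used for population averages).
#'
#' @param session A `v4_session` with spike times.
#' @param unit Unit id.
#' @param trials Optional completed-trial ids to restrict to.
#' @param window PSTH window, ms.
#' @param binwidth Bin width, ms (default 2).
#' @param sigma Kernel SD, ms (default 15).
#' @param normalize Peak-normalize over `peak_window`.
#' @param peak_window Window for the normalization peak, ms.
#' @return Tibble: `time` (bin centers, ms), `rate` (spikes/s).
#' @export
psth <- function(session, unit, trials = NULL, window = c(-400, 600),
                 binwidth = 2, sigma = 15, normalize = FALSE,
                 peak_window = c(60, 260)) {
  stopifnot(!is.null(session$spikes))
  sp <- session$spikes
  sp <- sp[sp$unit == unit, ]
  n_tr <- if (is.null(trials)) nrow(completed_trials(session)) else length(trials)
  if (!is.null(trials)) sp <- sp[sp$trial %in% trials, ]
  breaks <- seq(window[1], window[2], by = binwidth)
  h <- graphics::hist(sp$time[sp$time >= window[1] & sp$time < window[2]],
                      breaks = breaks, plot = FALSE, right = FALSE)
  rate <- h$counts / n_tr / (binwidth / 1000)
  k <- half_gaussian_kernel(sigma, binwidth) * binwidth
  sm <- stats::filter(c(rate, rep(0, length(k))), k, method = "convolution",
                      sides = 1)
  rate_s <- as.numeric(sm)[seq_along(rate) + 0]
  rate_s[is.na(rate_s)] <- 0
  out <- tibble::tibble(time = h$mids, rate = rate_s)
  if (normalize) {
    pk <- max(out$rate[out$time >= peak_window[1] & out$time < peak_window[2]])
    if (pk > 0) out$rate <- out$rate / pk
  }
  out
}

#' Modulation index
#'
#' `(X_large - X_small) / (X_large + X_small)`, in `[-1, 1]` for
#' non-negative measures.
#'
#' @param x_large,x_small Condition means.
#' @return The index.
#' @export
#' @examples
#' modulation_index(3, 1) # 0.5
modulation_index <- function(x_large, x_small) {
  (x_large - x_small) / (x_large + x_small)
}

#' Neuronal d': z-scored rate difference between reward conditions
#'
#' Spike counts are z-scored over the pooled trials of the unit; the
#' modulation is the difference of mean z-scores, large minus small. A
#' two-sided t-test flags units significantly different from 0.
#'
#' @param counts_large,counts_small Per-trial counts in the two conditions.
#' @return One-row tibble: `dprime`, `p_value`, `significant`, `n_large`,
#'   `n_small`, `undefined`.
#' @export
neuronal_dprime <- function(counts_large, counts_small) {
  pooled <- c(counts_large, counts_small)
  s <- stats::sd(pooled)
  if (!is.finite(s) || s == 0) {
    return(tibble::tibble(dprime = NA_real_, p_value = NA_real_,
                          significant = NA, n_large = length(counts_large),
                          n_small = length(counts_small), undefined = TRUE))
  }
  zl <- (counts_large - mean(pooled)) / s
  zs <- (counts_small - mean(pooled)) / s
  tt <- stats::t.test(zl, zs)
  tibble::tibble(dprime = mean(zl) - mean(zs), p_value = tt$p.value,
                 significant = tt$p.value < 0.05,
                 n_large = length(counts_large), n_small = length(counts_small),
                 undefined = FALSE)
}

#' Per-unit neuronal d' for a session
#'
#' Applies [neuronal_dprime()] to each unit's sample-window counts on correct
#' trials (hits and CRs).
#'
#' @param session A `v4_session`.
#' @param correct_only Restrict to correct trials (default TRUE).
#' @return Tibble with one row per unit.
#' @export
session_neuronal_dprime <- function(session, correct_only = TRUE) {
  ct <- completed_trials(session)
  keep <- if (correct_only) ct$outcome %in% c("hit", "CR") else rep(TRUE, nrow(ct))
  lg <- keep & ct$reward_cond == "large"
  sm <- keep & ct$reward_cond == "small"
  purrr::map_dfr(seq_len(ncol(session$counts_sample)), function(u) {
    dplyr::mutate(neuronal_dprime(session$counts_sample[lg, u],
                                  session$counts_sample[sm, u]),
                  unit = u, .before = 1)
  })
}

#' Mean-matched Fano factor
#'
#' Works on a table of per-(unit, condition, time) spike-count means and
#' variances across trials. The greatest common distribution of means is
#' found by binned-histogram intersection across all condition x time
#' groups; each group is then randomly subsampled (`n_draws` times) to match
#' that common distribution, and the average variance-to-mean ratio of the
#' retained points is reported.
#'
#' @param stats_df Tibble with columns `unit`, `cond`, `time`, `mean`,
#'   `var` (means and variances of spike counts per analysis window).
#' @param bin Histogram bin width for the mean distribution, in count units
#'   (default 0.05 counts = 1 spike/s in a 50 ms window).
#' @param n_draws Random subsamples per group (default 20).
#' @return Tibble: `cond`, `time`, `fano` (mean-matched), `fano_raw`
#'   (unmatched), `n_matched`, `n_points`.
#' @export
mean_matched_fano <- function(stats_df, bin = 0.05, n_draws = 20) {
  stats_df <- dplyr::filter(stats_df, .data$mean > 0)
  if (nrow(stats_df) == 0) stop("matching error: no positive means", call. = FALSE)
  breaks <- seq(0, max(stats_df$mean) + bin, by = bin)
  stats_df$bin_idx <- findInterval(stats_df$mean, breaks,
                                   rightmost.closed = TRUE)
  grp <- dplyr::group_by(stats_df, .data$cond, .data$time)
  hists <- dplyr::summarise(
    grp, hist = list(tabulate(.data$bin_idx, nbins = length(breaks))),
    .groups = "drop")
  common <- Reduce(pmin, hists$hist)
  if (sum(common) == 0) stop("matching error: empty common mean distribution",
                             call. = FALSE)
  dplyr::group_modify(grp, function(df, key) {
    ratios <- df$var / df$mean
    draws <- vapply(seq_len(n_draws), function(d) {
      sel <- unlist(lapply(which(common > 0), function(b) {
        idx <- which(df$bin_idx == b)
        if (length(idx) <= common[b]) idx else sample(idx, common[b])
      }))
      mean(ratios[sel])
    }, numeric(1))
    tibble::tibble(fano = mean(draws), fano_raw = mean(ratios),
                   n_matched = sum(common), n_points = nrow(df))
  }) |>
    dplyr::ungroup()
}

#' Fano-factor time course from spike times
#'
#' Spike counts over sliding windows (default 50 ms stepped by 2 ms) for
#' each unit and reward condition, then [mean_matched_fano()] across the
#' resulting mean/variance table.
#'
#' @param session A `v4_session` with spike times.
#' @param window_ms,step_ms Sliding-window length and step, ms.
#' @param range Time range of window centers, ms.
#' @param correct_only Restrict to correct trials.
#' @param ... Passed to [mean_matched_fano()].
#' @return As [mean_matched_fano()].
#' @export
fano_timecourse <- function(session, window_ms = 50, step_ms = 2,
                            range = c(-100, 350), correct_only = TRUE, ...) {
  ct <- completed_trials(session)
  keep <- if (correct_only) which(ct$outcome %in% c("hit", "CR")) else
    seq_len(nrow(ct))
  centers <- seq(range[1], range[2], by = step_ms)
  sp <- session$spikes
  stats_df <- purrr::map_dfr(seq_len(nrow(session$units)), function(u) {
    S <- spike_rate_series(sp, u, nrow(ct), centers, binwidth = window_ms) *
      (window_ms / 1000)                     # back to counts
    purrr::map_dfr(c("small", "large"), function(cond) {
      tr <- keep[ct$reward_cond[keep] == cond]
      tibble::tibble(unit = u, cond = cond, time = centers,
                     mean = colMeans(S[tr, , drop = FALSE]),
                     var = apply(S[tr, , drop = FALSE], 2, stats::var))
    })
  })
  mean_matched_fano(stats_df, ...)
}

#' Pairwise spike-count noise correlations
#'
#' Pearson correlation of trial-wise spike counts for every pair of columns.
#' Pairs with a zero-variance member are skipped and counted.
#'
#' @param counts Trials x units count matrix.
#' @return Tibble `unit1`, `unit2`, `r`; attribute `n_skipped`.
#' @export
pairwise_noise_corr <- function(counts) {
  v <- apply(counts, 2, stats::var)
  ok <- which(v > 0)
  cm <- stats::cor(counts[, ok, drop = FALSE])
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble::tibble(unit1 = ok[idx[, 1]], unit2 = ok[idx[, 2]],
                        r = cm[idx])
  n_all <- ncol(counts) * (ncol(counts) - 1) / 2
  attr(out, "n_skipped") <- n_all - nrow(out)
  out
}

#' Noise correlations binned by evoked response
#'
#' Per reward condition (correct trials): Pearson correlations of
#' sample-window counts for all simultaneous pairs, binned by the geometric
#' mean of the two units' evoked responses (trial-averaged 60-260 ms rate
#' minus -200-0 ms baseline rate) in 5 Hz intervals; the top bin pools all
#' evoked responses above 25 Hz.
#'
#' @param session A `v4_session` with spike times.
#' @param bin_hz Bin width, Hz.
#' @param top_hz Lower edge of the open top bin, Hz.
#' @return Tibble: `reward_cond`, `unit1`, `unit2`, `r`, `geo_mean`, `bin`.
#' @export
noise_correlations <- function(session, bin_hz = 5, top_hz = 25) {
  ct <- completed_trials(session)
  ev <- window_counts(session, c(60, 260)) / 0.2
  bs <- window_counts(session, c(-200, 0)) / 0.2
  purrr::map_dfr(c("small", "large"), function(cond) {
    tr <- which(ct$reward_cond == cond & ct$outcome %in% c("hit", "CR"))
    evoked <- pmax(colMeans(ev[tr, , drop = FALSE]) -
                     colMeans(bs[tr, , drop = FALSE]), 0)
    pairs <- pairwise_noise_corr(session$counts_sample[tr, , drop = FALSE])
    pairs$geo_mean <- sqrt(evoked[pairs$unit1] * evoked[pairs$unit2])
    pairs$bin <- pmin(floor(pairs$geo_mean / bin_hz), top_hz / bin_hz) *
      bin_hz
    dplyr::mutate(pairs, reward_cond = cond, .before = 1)
  })
}

#' Spike counts conditioned on the previous trial's reward
#'
#' Trials are sorted into nine overlapping bins (width 0.2, overlap 0.1) of
#' the session-normalized reward received on the preceding completed trial,
#' separately for block phase (aligned trials 1-10 after the first correct
#' response following the reward switch vs aligned trials 61-120) and block
#' reward condition. Mean spike counts (per-unit mean-normalized, averaged
#' over units) on the immediately following trial are reported per bin.
#'
#' @param session A `v4_session`.
#' @return Tibble: `phase`, `reward_cond`, `bin` (1-9), `bin_lo`, `bin_hi`,
#'   `mean_count` (NA marks an empty bin), `n_trials`.
#' @export
reward_matched_counts <- function(session) {
  al <- align_blocks(session)
  ct <- completed_trials(session)
  prev_reward <- c(NA, ct$reward_ul[-nrow(ct)]) / max(ct$reward_ul)
  norm_counts <- sweep(session$counts_sample, 2,
                       pmax(colMeans(session$counts_sample), 1e-9), "/")
  mc <- rowMeans(norm_counts)
  df <- tibble::tibble(trial = ct$trial, prev_reward = prev_reward,
                       mean_count = mc) |>
    dplyr::left_join(al[, c("trial", "reward_cond", "aligned")], by = "trial") |>
    dplyr::filter(!is.na(.data$prev_reward), !is.na(.data$aligned)) |>
    dplyr::mutate(phase = dplyr::case_when(
      .data$aligned <= 10 ~ "early",
      .data$aligned >= 61 & .data$aligned <= 120 ~ "late",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$phase))
  bins <- tibble::tibble(bin = 1:9, bin_lo = seq(0, 0.8, by = 0.1),
                         bin_hi = seq(0.2, 1.0, by = 0.1))
  tidyr::crossing(phase = c("early", "late"),
                  reward_cond = c("small", "large"), bins) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_trials = sum(df$phase == .data$phase &
                       df$reward_cond == .data$reward_cond &
                       df$prev_reward >= .data$bin_lo &
                       df$prev_reward <= .data$bin_hi),
      mean_count = if (.data$n_trials > 0) {
        mean(df$mean_count[df$phase == .data$phase &
                             df$reward_cond == .data$reward_cond &
                             df$prev_reward >= .data$bin_lo &
                             df$prev_reward <= .data$bin_hi])
      } else NA_real_) |>
    dplyr::ungroup()
}

#' PCA of per-unit PSTHs across reward conditions
#'
#' Rows are unit x condition PSTHs (0-400 ms); PCA on the mean-removed rows,
#' plus linear regressions of per-unit scores between the two conditions for
#' the first `n_pc` components.
#'
#' @param psth_mat Matrix, rows = unit x condition, columns = time bins.
#' @param units,conds Row labels (unit id and condition per row).
#' @param n_pc Components to report (default 3).
#' @return A list: `explained` (variance fractions), `scores` (tibble),
#'   `loadings`, `slopes` (per-PC regression slope between conditions),
#'   `degenerate` flag.
#' @export
pca_psth <- function(psth_mat, units, conds, n_pc = 3) {
  if (nrow(psth_mat) < n_pc) stop("fewer rows than requested components",
                                  call. = FALSE)
  total_var <- sum(apply(psth_mat, 2, stats::var))
  degenerate <- total_var < 1e-12
  pc <- stats::prcomp(psth_mat, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / max(sum(pc$sdev^2), 1e-300)
  sc <- tibble::as_tibble(pc$x[, seq_len(min(n_pc, ncol(pc$x))), drop = FALSE])
  sc$unit <- units
  sc$cond <- conds
  slopes <- vapply(seq_len(min(n_pc, ncol(pc$x))), function(j) {
    wide <- tidyr::pivot_wider(sc[, c("unit", "cond", paste0("PC", j))],
                               names_from = "cond",
                               values_from = paste0("PC", j))
    cols <- setdiff(names(wide), "unit")
    if (degenerate || stats::sd(wide[[cols[1]]]) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(wide[[cols[2]]] ~ wide[[cols[1]]]))[2])
  }, numeric(1))
  list(explained = expl, scores = sc, loadings = pc$rotation,
       slopes = slopes, degenerate = degenerate)
}
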