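#' Ground-truth configuration for a synthetic session
#'
#' Builds the configuration object that drives [generate_session()]. Every
#' parameter that the analysis pipeline can recover is stated here explicitly,
#' so parameter-recovery tests can compare estimates against known truth.
#'
#' The defaults describe one session of a blocked reward-size manipulation of
#' attentional intensity: alternating small/large-reward blocks of 120
#' completed trials, an equal-hemifield signal-detection observer whose
#' sensitivity relaxes toward the block asymptote with direction-dependent
#' exponential trial constants, a pupil-linked arousal state with its own
#' (faster-rising, slower-decaying) dynamics, and per-neuron spike counts
#' drawn from a negative-binomial GLM with a log link.
#'
#' @param n_blocks Number of reward blocks (alternating small, large, ...).
#' @param trials_per_block Completed trials per block.
#' @param n_neurons Number of simultaneously recorded units.
#' @param dprime_small,dprime_large Behavioral d' asymptotes per reward
#'   condition (identical in both hemifields: the manipulation is spatially
#'   nonselective by construction).
#' @param criterion Signal-detection criterion c of the observer.
#' @param tau_dprime_rise,tau_dprime_decay Trial constants of the exponential
#'   approach of d' to its asymptote after a small-to-large (rise) or
#'   large-to-small (decay) transition, in trials.
#' @param tau_pupil_rise,tau_pupil_decay Same for the pupil arousal state.
#' @param tau_rate_rise,tau_rate_decay Same for the multiplicative intensity
#'   gain on spike rates.
#' @param reward_mean_small,reward_mean_large Mean reward volume per
#'   condition, microliters.
#' @param reward_cv Coefficient of variation of the within-block gamma reward
#'   distribution.
#' @param reward_hit_factor,reward_cr_factor Multipliers on the condition
#'   mean for hit vs correct-rejection rewards (hits and CRs are paid from
#'   distinct distributions, which keeps criterion near zero and makes reward
#'   history identifiable).
#' @param p_abort_small,p_abort_large Per-trial probability that a trial is
#'   aborted (fixation break) before completion; aborted trials carry no
#'   behavioral or spike payload and do not count toward the 120 completed
#'   trials of a block.
#' @param pupil_small,pupil_large Normalized pupil arousal level per
#'   condition (asymptotes of the block dynamics).
#' @param pupil_evoked Amplitude of the stimulus-evoked pupil component.
#' @param pupil_noise_sd Trial-to-trial SD of the pupil state.
#' @param baseline_rate Baseline firing rate, spikes/s, shared across units.
#' @param intercept_mean,intercept_sd Per-neuron NB-GLM intercept
#'   distribution (log expected count in the 200 ms sample window).
#' @param beta_ori_mean,beta_ori_sd Per-neuron sample-orientation coefficient
#'   distribution (log-rate units for the 0/1 orientation indicator).
#' @param beta_pupil_mean,beta_pupil_sd Per-neuron pupil coefficient
#'   distribution (log-rate units per normalized pupil unit); this is the
#'   pathway through which attentional intensity reaches spike counts.
#' @param beta_reward_scale Amplitude of the 10-lag reward-history kernel
#'   (exponentially decaying over lags); zero by default, matching the weak
#'   reward-history coding the model family is designed to detect.
#' @param beta_saccade_mean,beta_saccade_sd Saccade-indicator coefficient
#'   distribution (test-1 window models).
#' @param beta_dori_mean,beta_dori_sd Orientation-change (delta-ori)
#'   coefficient distribution (test-1 window models).
#' @param tuning_sd SD of the per-neuron log-rate tuning values over the four
#'   test-1 orientations.
#' @param theta_shape,theta_rate Gamma distribution of the per-neuron NB
#'   shape parameter theta (one theta per neuron, shared across trials).
#' @param intensity_coupling `"uniform"` draws pupil coefficients
#'   independently of receptive-field position (spatially nonselective
#'   intensity gain); `"overlap"` makes them proportional to RF-stimulus
#'   overlap (a spatially selective alternative used to probe the analysis).
#' @param gabor_center_inRF,gabor_sigma Gabor sample-stimulus center (degrees
#'   azimuth/elevation) and isotropic envelope SD in the recorded hemifield.
#' @param rf_scatter_sd SD of RF centers around the stimulus center, degrees.
#' @param rf_sigma_mean,rf_sigma_sd Per-neuron RF size (1 SD), degrees.
#' @param sample_oris The two possible sample orientations, degrees.
#' @param delta_ori Orientation change on nonmatch trials, degrees.
#' @param pupil_hz Pupil sampling rate, Hz.
#' @param trace_window Pupil/spike trace window relative to sample onset, ms.
#'
#' @return A list with class `"v4_config"`.
#' @export
#' @examples
#' cfg <- session_config(n_blocks = 2, n_neurons = 4)
#' cfg$dprime_large
session_config <- function(n_blocks = 4,
                           trials_per_block = 120,
                           n_neurons = 40,
                           dprime_small = 2.03,
                           dprime_large = 3.48,
                           criterion = 0,
                           tau_dprime_rise = 12.2,
                           tau_dprime_decay = 1,
                           tau_pupil_rise = 4,
                           tau_pupil_decay = 9,
                           tau_rate_rise = 2,
                           tau_rate_decay = 9,
                           reward_mean_small = 131,
                           reward_mean_large = 522,
                           reward_cv = 0.25,
                           reward_hit_factor = 1.15,
                           reward_cr_factor = 0.85,
                           p_abort_small = 0.10,
                           p_abort_large = 0.05,
                           pupil_small = 0.40,
                           pupil_large = 0.62,
                           pupil_evoked = 0.15,
                           pupil_noise_sd = 0.04,
                           baseline_rate = 8,
                           intercept_mean = log(4.5),
                           intercept_sd = 0.25,
                           beta_ori_mean = 0.30,
                           beta_ori_sd = 0.12,
                           beta_pupil_mean = 0.80,
                           beta_pupil_sd = 0.25,
                           beta_reward_scale = 0,
                           beta_saccade_mean = 0.05,
                           beta_saccade_sd = 0.10,
                           beta_dori_mean = 0.00,
                           beta_dori_sd = 0.30,
                           tuning_sd = 0.30,
                           theta_shape = 8,
                           theta_rate = 1.6,
                           intensity_coupling = c("uniform", "overlap"),
                           gabor_center_inRF = c(4, -2),
                           gabor_sigma = 0.5,
                           rf_scatter_sd = 1.2,
                           rf_sigma_mean = 1.1,
                           rf_sigma_sd = 0.15,
                           sample_oris = c(45, 135),
                           delta_ori = 20,
                           pupil_hz = 500,
                           trace_window = c(-400, 600)) {
  intensity_coupling <- match.arg(intensity_coupling)
  cfg <- as.list(environment())
  class(cfg) <- "v4_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "v4_config"))
  pos <- c("tau_dprime_rise", "tau_dprime_decay", "tau_pupil_rise",
           "tau_pupil_decay", "tau_rate_rise", "tau_rate_decay",
           "reward_mean_small", "reward_mean_large", "theta_shape",
           "theta_rate", "gabor_sigma", "rf_sigma_mean", "trials_per_block")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || any(cfg[[p]] <= 0)) {
      stop("configuration error: `", p, "` must be positive", call. = FALSE)
    }
  }
  if (cfg$n_blocks < 2) stop("configuration error: need >= 2 blocks", call. = FALSE)
  if (cfg$n_neurons < 1) stop("configuration error: need >= 1 neuron", call. = FALSE)
  if (cfg$dprime_small < 0 || cfg$dprime_large < 0) {
    stop("configuration error: d' asymptotes must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.v4_config <- function(x, ...) {
  cat("<v4_config> synthetic session ground truth\n")
  cat(sprintf("  %d blocks x %d trials, %d neurons\n",
              x$n_blocks, x$trials_per_block, x$n_neurons))
  cat(sprintf("  d' small/large: %.2f/%.2f  (tau rise %.1f, decay %.1f)\n",
              x$dprime_small, x$dprime_large,
              x$tau_dprime_rise, x$tau_dprime_decay))
  cat(sprintf("  reward means small/large: %.0f/%.0f ul\n",
              x$reward_mean_small, x$reward_mean_large))
  invisible(x)
}
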