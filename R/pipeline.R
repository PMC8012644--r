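#' Write a session to a directory of plain-text files
#'
#' `trials.csv`, `counts_sample.csv`, `counts_test1.csv`, `units.csv`,
#' `pupil.csv` (normalized binocular-average traces), `pupil_time.csv`,
#' `spikes.csv` (if present), and `truth.json`.
#'
#' @param session A `v4_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$counts_sample, file.path(dir, "counts_sample.csv"),
                   row.names = FALSE)
  utils::write.csv(session$counts_test1, file.path(dir, "counts_test1.csv"),
                   row.names = FALSE)
  utils::write.csv(session$units, file.path(dir, "units.csv"),
                   row.names = FALSE)
  utils::write.csv(session$pupil, file.path(dir, "pupil.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time = session$pupil_time),
                   file.path(dir, "pupil_time.csv"), row.names = FALSE)
  if (!is.null(session$spikes)) {
    utils::write.csv(session$spikes, file.path(dir, "spikes.csv"),
                     row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- session$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(list(seed = session$seed, truth = truth),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' Restores the tables and matrices; ground truth comes back as plain lists
#' (numeric vectors/matrices), sufficient to rerun every analysis stage.
#'
#' @param dir Directory written by [write_session()].
#' @return A `v4_session`.
#' @export
read_session <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE)
  trials <- tibble::as_tibble(rd("trials.csv"))
  out <- list(
    trials = trials,
    counts_sample = as.matrix(rd("counts_sample.csv")),
    counts_test1 = as.matrix(rd("counts_test1.csv")),
    units = tibble::as_tibble(rd("units.csv")),
    pupil = as.matrix(rd("pupil.csv")),
    pupil_time = rd("pupil_time.csv")$time,
    spikes = if (file.exists(file.path(dir, "spikes.csv")))
      tibble::as_tibble(rd("spikes.csv")) else NULL,
    truth = NULL, seed = NA_integer_
  )
  if (file.exists(file.path(dir, "truth.json")) &&
      requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
    out$truth <- tr$truth
    out$truth$config <- structure(as.list(tr$truth$config),
                                  class = "v4_config")
    out$seed <- tr$seed
  }
  structure(out, class = "v4_session")
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Orchestrates generate, behavior, pupil, spikestats, rf, glm, and decode
#' stages in dependency order, with every random step seeded from one master
#' seed. Disabled stages are skipped and noted in the manifest; stages
#' downstream of a disabled dependency are skipped too.
#'
#' @param config A [session_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param stages Character vector of stages to run.
#' @param out_dir Optional directory: session and stage tables are written
#'   there as CSV/JSON.
#' @param glm_models Encoding models to fit in the glm stage.
#' @return A list with class `v4_report`: per-stage results plus `manifest`
#'   (tibble of stage, status, rows, seed).
#' @export
run_pipeline <- function(config = session_config(), seed = 1,
                         stages = c("behavior", "pupil", "spikestats", "rf",
                                    "glm", "decode"),
                         out_dir = NULL,
                         glm_models = c("complete", "dori", "saccade")) {
  res <- list()
  manifest <- list()
  note <- function(stage, status, rows, sd = NA_integer_) {
    manifest[[length(manifest) + 1]] <<-
      tibble::tibble(stage = stage, status = status, rows = rows, seed = sd)
  }

  session <- generate_session(config, seed = seed)
  res$session <- session
  note("generate", "ok", nrow(session$trials), seed)

  if ("behavior" %in% stages) {
    al <- align_blocks(session)
    bw <- if (config$n_blocks >= 20) 1 else 5   # pool orders when few blocks
    course_d <- aligned_dprime(al, bin_width = bw)
    course_p <- aligned_course(al, "pupil_mean")
    course_r <- aligned_course(al, "reward_ul")
    expfits <- course_d |>
      dplyr::filter(!is.na(.data$dprime)) |>
      dplyr::group_by(.data$reward_cond) |>
      dplyr::group_modify(~ glance(fit_exponential(.x$dprime, .x$aligned))) |>
      dplyr::ungroup()
    hys <- tryCatch({
      course_rb <- course_r |>
        dplyr::mutate(aligned = (ceiling(.data$aligned / bw) - 0.5) * bw + 0.5) |>
        dplyr::group_by(.data$reward_cond, .data$aligned) |>
        dplyr::summarise(reward = mean(.data$mean), .groups = "drop")
      course <- dplyr::inner_join(
        dplyr::select(course_d, "reward_cond", "aligned",
                      response = "dprime"),
        course_rb,
        by = c("reward_cond", "aligned")) |>
        dplyr::rename(direction = "reward_cond")
      hysteresis_curve(course)
    }, error = function(e) NULL)
    res$behavior <- list(summary = behavior_summary(session),
                         aligned_dprime = course_d,
                         aligned_pupil = course_p,
                         exp_fits = expfits, hysteresis = hys)
    note("behavior", "ok", nrow(course_d))
  } else note("behavior", "skipped", 0L)

  if ("pupil" %in% stages) {
    al <- align_blocks(session)
    post <- al$trial[!is.na(al$aligned)]
    ct <- completed_trials(session)
    idx <- ct$trial %in% post
    intensity <- as.integer(ct$reward_cond[idx] == "large")
    pupil_reg <- purrr::map_dfr(seq_len(ncol(session$counts_sample)),
      function(u) {
        dplyr::mutate(regress_pupil(ct$pupil_mean[idx],
                                    session$counts_sample[idx, u], intensity),
                      unit = u, .before = 1)
      })
    res$pupil <- list(regression = pupil_reg,
                      matched = match_pupil_trials(session))
    note("pupil", "ok", nrow(pupil_reg))
  } else note("pupil", "skipped", 0L)

  if ("spikestats" %in% stages && !is.null(session$spikes)) {
    screen <- screen_responsive(session)
    nd <- session_neuronal_dprime(session)
    # coarse mean-histogram bin: matching needs occupancy at this unit count
    fano <- tryCatch(
      fano_timecourse(session, range = c(100, 260), step_ms = 40, bin = 0.25),
      error = function(e) NULL)
    nc <- noise_correlations(session)
    rmc <- reward_matched_counts(session)
    res$spikestats <- list(screen = screen, neuronal_dprime = nd,
                           fano = fano, noise_corr = nc,
                           reward_matched = rmc)
    note("spikestats", "ok", nrow(nd))
  } else note("spikestats", "skipped", 0L)

  if ("rf" %in% stages && "spikestats" %in% stages) {
    nd <- res$spikestats$neuronal_dprime
    units <- dplyr::left_join(session$units, nd[, c("unit", "dprime")],
                              by = "unit")
    ovm <- tryCatch(overlap_vs_modulation(units), error = function(e) NULL)
    res$rf <- list(units = units, overlap_vs_modulation = ovm)
    note("rf", "ok", nrow(units))
  } else note("rf", "skipped", 0L)

  glmsets <- list()
  if ("glm" %in% stages) {
    for (m in glm_models) glmsets[[m]] <- fit_session_glms(session, m)
    res$glm <- glmsets
    note("glm", "ok", sum(vapply(glmsets, function(g) nrow(g$summary),
                                 numeric(1))))
  } else note("glm", "skipped", 0L)

  if ("decode" %in% stages && "glm" %in% stages) {
    dec <- list()
    if (!is.null(glmsets$dori)) {
      dec$dori <- tryCatch(decode_pairs(glmsets$dori, seed = seed + 1),
                           error = function(e) NULL)
    }
    if (!is.null(glmsets$saccade)) {
      dec$saccade <- tryCatch(decode_pairs(glmsets$saccade, seed = seed + 2),
                              error = function(e) NULL)
      dec$choice <- tryCatch(
        decode_choice(session, glmsets$saccade, seed = seed + 3),
        error = function(e) NULL)
    }
    res$decode <- dec
    note("decode", "ok", length(dec), seed + 1)
  } else note("decode", "skipped", 0L)

  res$manifest <- dplyr::bind_rows(manifest)
  class(res) <- "v4_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_session(session, file.path(out_dir, "session"))
    wr <- function(df, f) if (!is.null(df))
      utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
    wr(res$behavior$summary, "behavior.csv")
    wr(res$behavior$exp_fits, "exp_fits.csv")
    wr(res$pupil$regression, "pupil_metrics.csv")
    wr(res$spikestats$neuronal_dprime, "neuronal_dprime.csv")
    wr(res$spikestats$noise_corr, "noise_correlations.csv")
    wr(res$spikestats$fano, "fano.csv")
    wr(res$rf$units, "rf.csv")
    if (!is.null(res$glm)) {
      for (m in names(res$glm)) wr(res$glm[[m]]$summary,
                                   paste0("glm_", m, ".csv"))
    }
    if (!is.null(res$decode)) {
      wr(purrr::map_dfr(res$decode, tidy), "decode.csv")
    }
    wr(res$manifest, "manifest.csv")
  }
  res
}

#' @export
print.v4_report <- function(x, ...) {
  cat("<v4_report> pipeline run\n")
  print(x$manifest)
  if (!is.null(x$decode)) {
    for (d in x$decode) if (!is.null(d))
      cat(sprintf("  decode %s: %.3f\n", d$variable, d$accuracy))
  }
  invisible(x)
}
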