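#' Bivariate-Gaussian receptive-field model
#'
#' @param x,y Center, degrees of visual angle (azimuth, elevation).
#' @param sx,sy Standard deviations, degrees.
#' @param rho Correlation, `|rho| < 1`.
#' @param amp,base Optional response amplitude and baseline from a fit.
#' @return An object of class `v4_rf`.
#' @export
rf_model <- function(x, y, sx, sy, rho = 0, amp = NA_real_, base = NA_real_) {
  if (sx <= 0 || sy <= 0 || abs(rho) >= 1) {
    stop("fit error: covariance not positive-definite", call. = FALSE)
  }
  structure(list(x = x, y = y, sx = sx, sy = sy, rho = rho,
                 amp = amp, base = base),
            class = "v4_rf")
}

#' @export
print.v4_rf <- function(x, ...) {
  cat(sprintf("<v4_rf> center (%.2f, %.2f) deg, sigma (%.2f, %.2f), rho %.2f\n",
              x$x, x$y, x$sx, x$sy, x$rho))
  invisible(x)
}

# bivariate normal density on grids gx, gy (vectors) -> matrix [gx x gy]
bvn_grid <- function(rf, gx, gy) {
  dx <- outer(gx - rf$x, rep(1, length(gy)))
  dy <- outer(rep(1, length(gx)), gy - rf$y)
  q <- (dx / rf$sx)^2 - 2 * rf$rho * (dx / rf$sx) * (dy / rf$sy) +
    (dy / rf$sy)^2
  exp(-q / (2 * (1 - rf$rho^2))) /
    (2 * pi * rf$sx * rf$sy * sqrt(1 - rf$rho^2))
}

#' Overlap between two bivariate-Gaussian densities
#'
#' Percent overlap between the receptive-field density and a stimulus
#' density, both normalized to unit mass. The default metric is the overlap
#' coefficient `100 * integral of min(f, g)`, evaluated on a grid covering
#' +/- `n_sigma` SD of both densities at resolution `min(sigma) /
#' res_factor`; `method = "bhattacharyya"` uses `100 * integral of
#' sqrt(f * g)` instead.
#'
#' @param rf,stimulus `v4_rf` objects (build the stimulus from the Gabor
#'   center and envelope SD).
#' @param method `"min"` (overlap coefficient, default) or
#'   `"bhattacharyya"`.
#' @param n_sigma Grid extent in SDs.
#' @param res_factor Grid resolution divisor.
#' @return Overlap in percent, `[0, 100]`.
#' @export
#' @examples
#' g <- rf_model(0, 0, 1, 1)
#' density_overlap(g, g) # 100
density_overlap <- function(rf, stimulus, method = c("min", "bhattacharyya"),
                            n_sigma = 4, res_factor = 20) {
  method <- match.arg(method)
  res <- min(rf$sx, rf$sy, stimulus$sx, stimulus$sy) / res_factor
  x_lo <- min(rf$x - n_sigma * rf$sx, stimulus$x - n_sigma * stimulus$sx)
  x_hi <- max(rf$x + n_sigma * rf$sx, stimulus$x + n_sigma * stimulus$sx)
  y_lo <- min(rf$y - n_sigma * rf$sy, stimulus$y - n_sigma * stimulus$sy)
  y_hi <- max(rf$y + n_sigma * rf$sy, stimulus$y + n_sigma * stimulus$sy)
  gx <- seq(x_lo, x_hi, by = res)
  gy <- seq(y_lo, y_hi, by = res)
  f <- bvn_grid(rf, gx, gy)
  g <- bvn_grid(stimulus, gx, gy)
  v <- if (method == "min") pmin(f, g) else sqrt(f * g)
  min(100 * sum(v) * res^2, 100)
}

#' Fit a bivariate Gaussian to a receptive-field response map
#'
#' Least-squares fit of `baseline + amplitude * bivariate Gaussian` to
#' responses on a probe grid. Initialization by response-weighted moments. A
#' flat map is returned as a flagged degenerate fit.
#'
#' @param map Data frame with columns `x`, `y` (probe positions, degrees)
#'   and `resp` (response).
#' @return A `v4_rf` with `amp`, `base`, and attributes `resid_ss` and
#'   `degenerate`.
#' @export
fit_rf_gaussian <- function(map) {
  stopifnot(all(c("x", "y", "resp") %in% names(map)), nrow(map) >= 9)
  r0 <- map$resp - min(map$resp)
  if (sum(r0) <= 0 || stats::sd(map$resp) == 0) {
    out <- rf_model(mean(map$x), mean(map$y), stats::sd(map$x) + 1e-6,
                    stats::sd(map$y) + 1e-6, 0, amp = 0, base = mean(map$resp))
    attr(out, "degenerate") <- TRUE
    attr(out, "resid_ss") <- sum((map$resp - mean(map$resp))^2)
    return(out)
  }
  w <- r0 / sum(r0)
  cx0 <- sum(w * map$x); cy0 <- sum(w * map$y)
  sx0 <- max(sqrt(sum(w * (map$x - cx0)^2)), 1e-2)
  sy0 <- max(sqrt(sum(w * (map$y - cy0)^2)), 1e-2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ base + amp * exp(-(((x - cx) / sx)^2 -
                                  2 * rho * ((x - cx) / sx) * ((y - cy) / sy) +
                                  ((y - cy) / sy)^2) / (2 * (1 - rho^2))),
      data = map,
      start = list(base = min(map$resp), amp = max(r0), cx = cx0, cy = cy0,
                   sx = sx0, sy = sy0, rho = 0),
      lower = c(-Inf, 0, -Inf, -Inf, 1e-3, 1e-3, -0.99),
      upper = c(Inf, Inf, Inf, Inf, Inf, Inf, 0.99),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("fit error: ", conditionMessage(e), call. = FALSE))
  co <- as.list(stats::coef(fit))
  out <- rf_model(co$cx, co$cy, co$sx, co$sy, co$rho,
                  amp = co$amp, base = co$base)
  attr(out, "degenerate") <- FALSE
  attr(out, "resid_ss") <- sum(stats::residuals(fit)^2)
  out
}

#' Relate RF-stimulus overlap to attentional modulation
#'
#' Spearman correlation between per-unit modulation (neuronal d') and
#' RF-Gabor overlap, plus group means over four equal overlap intervals with
#' a one-way ANOVA. A spatially nonselective intensity signal predicts no
#' relation.
#'
#' @param units Tibble with columns `overlap` (percent) and `dprime`.
#' @return A list: `rho`, `p_value` (Spearman, two-sided), `groups` (tibble
#'   of interval means), `anova_p`, `flagged` (TRUE when the correlation is
#'   undefined, e.g. a single overlap value).
#' @export
overlap_vs_modulation <- function(units) {
  units <- dplyr::filter(units, is.finite(.data$overlap), is.finite(.data$dprime))
  stopifnot(nrow(units) >= 20)
  if (stats::sd(units$overlap) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, groups = NULL,
                anova_p = NA_real_, flagged = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(units$overlap, units$dprime, method = "spearman"))
  brk <- seq(min(units$overlap), max(units$overlap), length.out = 5)
  units$grp <- cut(units$overlap, breaks = brk, include.lowest = TRUE)
  groups <- units |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(mean_dprime = mean(.data$dprime), n = dplyr::n(),
                     .groups = "drop")
  anova_p <- if (dplyr::n_distinct(units$grp) > 1) {
    summary(stats::aov(dprime ~ grp, data = units))[[1]][["Pr(>F)"]][1]
  } else NA_real_
  list(rho = unname(ct$estimate), p_value = ct$p.value, groups = groups,
       anova_p = anova_p, flagged = FALSE)
}
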