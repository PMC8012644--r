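# internal helpers shared across modules

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# discrete-time exponential relaxation toward a per-step target with
# direction-dependent time constants (units: steps)
exp_relax <- function(target, tau_rise, tau_decay, start) {
  n <- length(target)
  out <- numeric(n)
  s <- start
  for (t in seq_len(n)) {
    tau <- if (target[t] >= s) tau_rise else tau_decay
    s <- target[t] + (s - target[t]) * exp(-1 / tau)
    out[t] <- s
  }
  out
}

# proportion clipped away from 0/1 before probit transform:
# 0 -> 1/(2N), 1 -> 1 - 1/(2N)
clip_rate <- function(k, n) {
  stopifnot(all(n >= 1))
  r <- k / n
  r[r <= 0] <- 1 / (2 * n[r <= 0])
  r[r >= 1] <- 1 - 1 / (2 * n[r >= 1])
  r
}

completed <- function(trials) {
  dplyr::filter(trials, .data$outcome != "aborted")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
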