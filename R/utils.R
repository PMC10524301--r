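#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed for a named random sub-stream. Keeps every
# modality on its own stream so adding one generator never shifts another's
# draws. Result is always a valid 32-bit seed.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 48271 + h * 69621) %% 2147483562)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Calcium impulse-response kernel
#'
#' Difference-of-exponentials rise/decay kernel approximating a slow calcium
#' indicator. Normalised so the continuous-time peak equals 1.
#'
#' @param t numeric vector of times (s) relative to onset; negative times
#'   return 0.
#' @param tau_rise,tau_decay rise and decay time constants (s);
#'   `tau_decay > tau_rise > 0`.
#' @return numeric vector, same length as `t`.
#' @export
calcium_kernel <- function(t, tau_rise = 0.1, tau_decay = 0.8) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k[t < 0] <- 0
  tstar <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  k / (exp(-tstar / tau_decay) - exp(-tstar / tau_rise))
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

# mean-preserving AR(1) smoother used for hemodynamic artifacts
smooth_ar1 <- function(n, tau, dt) {
  rho <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  for (i in seq_len(n - 1L)) x[i + 1L] <- rho * x[i] + innov[i + 1L]
  x
}
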