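#' Canonical hemodynamic response function
#'
#' Evaluates the canonical double-gamma HRF (difference of two gamma
#' densities: response peak around 5 s, undershoot around 15 s) on a regular
#' grid of one sample per TR over its 32-s support, and rescales it so that
#' its maximum sampled value is exactly 1. With peak height 1, a trial whose
#' true amplitude is `beta` produces an isolated BOLD response whose peak
#' equals `beta`, so amplitudes and scan noise share a common unit.
#'
#' @param tr Sampling interval (repetition time) in seconds; must be > 0.
#' @param response_delay,undershoot_delay Shape parameters (seconds to the
#'   mode, roughly) of the positive and undershoot gamma components.
#' @param response_dispersion,undershoot_dispersion Scale parameters of the
#'   two gamma components.
#' @param undershoot_ratio The undershoot is divided by this factor.
#' @param support Temporal support of the kernel in seconds.
#' @return An object of class `hrf_kernel`: a list with elements `tr`,
#'   `time` (sample times, `0, tr, ..., support`), `values` (peak-normalized
#'   amplitudes) and the parameter set.
#' @examples
#' h <- canonical_hrf(1)
#' length(h$values)  # 33 samples covering 0..32 s
#' max(h$values)     # exactly 1
#' @export
canonical_hrf <- function(tr,
                          response_delay = 6,
                          undershoot_delay = 16,
                          response_dispersion = 1,
                          undershoot_dispersion = 1,
                          undershoot_ratio = 6,
                          support = 32) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("'tr' must be a single positive number (seconds)", call. = FALSE)
  time <- seq(0, support, by = tr)
  pars <- list(response_delay = response_delay,
               undershoot_delay = undershoot_delay,
               response_dispersion = response_dispersion,
               undershoot_dispersion = undershoot_dispersion,
               undershoot_ratio = undershoot_ratio,
               support = support)
  raw <- hrf_shape(time, pars)
  values <- raw / max(raw)
  structure(list(tr = tr, time = time, values = values, parameters = pars),
            class = "hrf_kernel")
}

# Unnormalized double-gamma shape at arbitrary (possibly off-grid) times.
# Zero outside [0, support].
hrf_shape <- function(t, pars) {
  out <- numeric(length(t))
  inside <- t >= 0 & t <= pars$support
  ti <- t[inside]
  out[inside] <-
    stats::dgamma(ti, shape = pars$response_delay / pars$response_dispersion,
                  scale = pars$response_dispersion) -
    stats::dgamma(ti, shape = pars$undershoot_delay / pars$undershoot_dispersion,
                  scale = pars$undershoot_dispersion) / pars$undershoot_ratio
  out
}

# Peak-normalized kernel evaluated at arbitrary lags (seconds). Uses the
# same scale factor as the TR-grid samples so grid-aligned onsets reproduce
# the stored kernel exactly.
hrf_at <- function(hrf, lags) {
  raw <- hrf_shape(lags, hrf$parameters)
  peak <- max(hrf_shape(hrf$time, hrf$parameters))
  raw / peak
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat("Canonical HRF kernel: TR =", x$tr, "s,", length(x$values),
      "samples over 0-", x$parameters$support, "s, peak = 1 at t =",
      x$time[which.max(x$values)], "s\n")
  invisible(x)
}
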