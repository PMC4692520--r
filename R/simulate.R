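#' Trial amplitude specification
#'
#' Population mean and trial-to-trial standard deviation of the true evoked
#' amplitude, per trial type (and optionally per voxel). Amplitudes are in
#' peak-BOLD units (the HRF has peak height 1). The defaults follow the
#' reference simulation conditions: mean 3 for type 1, mean 5 for type 2.
#'
#' @param means Numeric vector of per-type population means, or a
#'   `n_types x n_voxels` matrix of per-type, per-voxel means (used for
#'   two-voxel pattern simulations where the types have opposite patterns).
#' @param trial_sd Trial-to-trial SD; a single value shared by all types or
#'   one value per type. Amplitudes are Gaussian and may go negative at
#'   large SDs; they are deliberately not clipped.
#' @return A list of class `amplitude_spec`.
#' @export
amplitude_spec <- function(means = 3, trial_sd = 0) {
  if (!is.matrix(means)) means <- matrix(means, ncol = 1)
  n_types <- nrow(means)
  if (length(trial_sd) == 1L) trial_sd <- rep(trial_sd, n_types)
  if (length(trial_sd) != n_types)
    stop("'trial_sd' must have length 1 or n_types", call. = FALSE)
  if (any(trial_sd < 0)) stop("'trial_sd' must be >= 0", call. = FALSE)
  structure(list(means = means, trial_sd = trial_sd, n_types = n_types),
            class = "amplitude_spec")
}

#' Coherence specification for multi-voxel simulations
#'
#' Whether the trial-variability and scan-noise samples are shared
#' (coherent) or drawn independently (incoherent) across voxels. The two
#' flags are independent, giving the 2 x 2 factorial of the classification
#' analysis.
#'
#' @param trial_coherent,noise_coherent Logical flags.
#' @export
coherence_spec <- function(trial_coherent = FALSE, noise_coherent = FALSE) {
  structure(list(trial_coherent = isTRUE(trial_coherent),
                 noise_coherent = isTRUE(noise_coherent)),
            class = "coherence_spec")
}

#' Draw true per-trial amplitudes
#'
#' For trial `j` of type `k` and voxel `v`, the amplitude is
#' `mean[k, v] + trial_sd[k] * z`, with the standard-normal deviate `z`
#' shared across voxels under coherent trial variability and drawn
#' independently per voxel otherwise.
#'
#' @param schedule An [event_schedule()].
#' @param amp_spec An [amplitude_spec()].
#' @param n_voxels Number of voxels.
#' @param coherence A [coherence_spec()]; only `trial_coherent` is used.
#' @param seed Optional integer seed (amplitude sub-stream).
#' @return A `n_trials x n_voxels` matrix of true amplitudes.
#' @export
draw_trial_betas <- function(schedule, amp_spec, n_voxels = 1L,
                             coherence = coherence_spec(), seed = NULL) {
  if (amp_spec$n_types < schedule$n_types)
    stop("amplitude spec covers fewer types than the schedule", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- schedule$n_trials
  means <- amp_spec$means
  if (ncol(means) == 1L && n_voxels > 1L)
    means <- means[, rep(1L, n_voxels), drop = FALSE]
  if (ncol(means) != n_voxels)
    stop("per-voxel means must have n_voxels columns", call. = FALSE)
  z <- if (coherence$trial_coherent)
    matrix(stats::rnorm(m), m, n_voxels) else
    matrix(stats::rnorm(m * n_voxels), m, n_voxels)
  mu <- means[schedule$labels, , drop = FALSE]
  sd <- amp_spec$trial_sd[schedule$labels]
  mu + sd * z
}

#' Synthesize BOLD timeseries
#'
#' Each voxel's signal is the superposition of amplitude-scaled HRF
#' responses at the trial onsets, sampled on the scan grid, plus
#' independent zero-mean Gaussian scan noise per TR. Under coherent noise
#' the same noise sample is added to every voxel.
#'
#' @param schedule An [event_schedule()].
#' @param betas `n_trials x n_voxels` true amplitudes
#'   (see [draw_trial_betas()]).
#' @param hrf An [canonical_hrf()] kernel.
#' @param scan_sd Scan-noise SD (single value applied to all voxels).
#' @param coherence A [coherence_spec()]; only `noise_coherent` is used.
#' @param seed Optional integer seed (noise sub-stream).
#' @param tr Repetition time; defaults to the kernel's.
#' @param trial_cols Optional precomputed trial-regressor matrix (cache).
#' @return An object of class `simulated_session`: list with `y`
#'   (scans x voxels), `betas`, `schedule`, `hrf`, `scan_sd`, `tr`.
#' @export
synthesize_bold <- function(schedule, betas, hrf, scan_sd = 0,
                            coherence = coherence_spec(), seed = NULL,
                            tr = hrf$tr, trial_cols = NULL) {
  if (!is.matrix(betas)) betas <- matrix(betas, ncol = 1)
  if (nrow(betas) != schedule$n_trials)
    stop("'betas' must have one row per trial in the schedule", call. = FALSE)
  if (scan_sd < 0) stop("'scan_sd' must be >= 0", call. = FALSE)
  if (is.null(trial_cols)) trial_cols <- trial_columns(schedule, hrf, tr)
  signal <- trial_cols %*% betas
  n_scans <- nrow(signal)
  n_voxels <- ncol(signal)
  if (scan_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- if (coherence$noise_coherent)
      matrix(stats::rnorm(n_scans, sd = scan_sd), n_scans, n_voxels) else
      matrix(stats::rnorm(n_scans * n_voxels, sd = scan_sd), n_scans, n_voxels)
    y <- signal + noise
  } else y <- signal
  structure(list(y = y, betas = betas, schedule = schedule, hrf = hrf,
                 scan_sd = scan_sd, tr = tr, coherence = coherence),
            class = "simulated_session")
}

#' Simulate a full session in one call
#'
#' Convenience wrapper drawing amplitudes and noise from separate,
#' independently seeded sub-streams, so the same amplitude sample can be
#' reused across noise draws.
#'
#' @inheritParams draw_trial_betas
#' @inheritParams synthesize_bold
#' @param amp_seed,noise_seed Seeds for the two sub-streams.
#' @export
simulate_session <- function(schedule, amp_spec, hrf, scan_sd = 0,
                             n_voxels = 1L, coherence = coherence_spec(),
                             amp_seed = NULL, noise_seed = NULL,
                             tr = hrf$tr, trial_cols = NULL) {
  betas <- draw_trial_betas(schedule, amp_spec, n_voxels, coherence,
                            seed = amp_seed)
  synthesize_bold(schedule, betas, hrf, scan_sd, coherence,
                  seed = noise_seed, tr = tr, trial_cols = trial_cols)
}

#' Amplitude signal-to-noise ratio
#'
#' Ratio of the population-mean amplitude to the scan-noise SD; with mean 3
#' the scan-noise grid 0.5, 0.8, 1.6, 3 corresponds to SNRs of 6, 3.8, 1.9
#' and 1 (to one decimal).
#'
#' @param mean_amplitude Population mean evoked amplitude.
#' @param scan_sd Scan-noise SD (vectorized).
#' @export
amplitude_snr <- function(mean_amplitude = 3, scan_sd) {
  if (any(scan_sd <= 0)) stop("'scan_sd' must be > 0", call. = FALSE)
  mean_amplitude / scan_sd
}

#' Export a simulated session to plain-text files
#'
#' Writes the timeseries as a numeric CSV (scans x voxels) and the event
#' schedule as a BIDS-style TSV, for use by external GLM tools.
#'
#' @param session A `simulated_session`.
#' @param timeseries_path,events_path Output paths.
#' @export
write_session <- function(session, timeseries_path, events_path) {
  utils::write.table(session$y, timeseries_path, sep = ",",
                     row.names = FALSE,
                     col.names = paste0("voxel", seq_len(ncol(session$y))),
                     quote = FALSE)
  write_events(session$schedule, events_path)
  invisible(timeseries_path)
}

#' @export
print.simulated_session <- function(x, ...) {
  cat("Simulated session:", nrow(x$y), "scans x", ncol(x$y), "voxel(s),",
      x$schedule$n_trials, "trials, scan SD", x$scan_sd, "\n")
  invisible(x)
}
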