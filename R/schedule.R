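#' Construct an event schedule
#'
#' An event schedule holds the ordered trial onsets (in seconds) and their
#' trial-type labels for one scanning session.
#'
#' @param onsets Strictly increasing onset times in seconds, all within
#'   `[0, session_duration)`.
#' @param labels Integer trial-type labels in `1..n_types`, one per onset.
#' @param session_duration Session length in seconds.
#' @param soa Stimulus onset asynchrony in seconds, for fixed-SOA designs;
#'   `NA` for irregular onsets.
#' @param n_types Number of trial types; defaults to `max(labels)`.
#' @return An object of class `event_schedule` with fields `onsets`,
#'   `labels`, `soa`, `session_duration`, `n_trials`, `n_types`.
#' @export
event_schedule <- function(onsets, labels, session_duration,
                           soa = NA_real_, n_types = max(labels)) {
  onsets <- as.numeric(onsets)
  labels <- as.integer(labels)
  if (length(onsets) == 0L)
    stop("empty schedule: at least one onset is required", call. = FALSE)
  if (length(labels) != length(onsets))
    stop("'labels' and 'onsets' must have equal length", call. = FALSE)
  if (any(diff(onsets) <= 0))
    stop("'onsets' must be strictly increasing", call. = FALSE)
  if (any(onsets < 0) || any(onsets >= session_duration))
    stop("all onsets must lie in [0, session_duration)", call. = FALSE)
  if (any(labels < 1L) || any(labels > n_types))
    stop("'labels' must be integers in 1..n_types", call. = FALSE)
  structure(list(onsets = onsets, labels = labels, soa = soa,
                 session_duration = session_duration,
                 n_trials = length(onsets), n_types = as.integer(n_types)),
            class = "event_schedule")
}

#' Generate a fixed-SOA schedule of randomly intermixed trial types
#'
#' Places onsets at `0, soa, 2*soa, ...` up to (not including) the session
#' end, and draws trial-type labels independently with the given
#' probabilities. With the default single type every trial is type 1.
#'
#' @param soa Stimulus onset asynchrony in seconds; must be at least `tr`
#'   (designs with sub-scan spacing are unidentifiable).
#' @param session_duration Session length in seconds (must exceed `soa`).
#' @param n_types Number of trial types.
#' @param type_probs Sampling probabilities per type; must sum to 1.
#' @param seed Optional integer seed for the label draw.
#' @param tr Repetition time in seconds, used only to validate `soa`.
#' @return An `event_schedule` with one trial per multiple of `soa` in
#'   `[0, session_duration)`.
#' @examples
#' s <- generate_schedule(soa = 24, session_duration = 2700)
#' head(s$onsets)   # 0 24 48 ...
#' s$n_trials       # 112
#' @export
generate_schedule <- function(soa, session_duration, n_types = 1L,
                              type_probs = rep(1 / n_types, n_types),
                              seed = NULL, tr = 1) {
  if (soa < tr)
    stop("'soa' must be >= 'tr': sub-scan trial spacing is unidentifiable",
         call. = FALSE)
  if (session_duration <= soa)
    stop("'session_duration' must exceed 'soa'", call. = FALSE)
  if (abs(sum(type_probs) - 1) > 1e-8 || length(type_probs) != n_types)
    stop("'type_probs' must have length n_types and sum to 1", call. = FALSE)
  m <- ceiling(session_duration / soa)  # all multiples of soa in [0, dur)
  onsets <- soa * (seq_len(m) - 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- if (n_types == 1L) rep(1L, m) else
    sample.int(n_types, m, replace = TRUE, prob = type_probs)
  event_schedule(onsets, labels, session_duration, soa = soa,
                 n_types = n_types)
}

#' Balanced label helper
#'
#' Returns a schedule whose labels contain exactly `n_per_type` trials of
#' each type in random order — the layout used for classification
#' pattern-set simulations (e.g. 30 trials per type per session).
#'
#' @inheritParams generate_schedule
#' @param n_per_type Trials of each type.
#' @param shuffle Randomly permute the labels (default) or keep types in
#'   blocks.
#' @export
balanced_schedule <- function(soa, n_types = 2L, n_per_type = 30L,
                              seed = NULL, tr = 1, shuffle = TRUE) {
  m <- n_types * n_per_type
  # pad the session so the last trial's full response is recorded
  session_duration <- m * soa + 32
  if (!is.null(seed)) set.seed(seed)
  labels <- rep(seq_len(n_types), each = n_per_type)
  if (shuffle) labels <- sample(labels)
  event_schedule(soa * (seq_len(m) - 1), labels, session_duration,
                 soa = soa, n_types = n_types)
}

#' Which trials are fully modeled after transient trimming?
#'
#' When session-edge transients are discarded, only scans in
#' `[trim, session_duration - trim)` are kept and a trial is fully modeled
#' only if its complete HRF support fits the retained window.
#'
#' @param schedule An `event_schedule`.
#' @param trim Seconds discarded at each session edge (0 = no trimming).
#' @param support HRF support in seconds.
#' @return Logical vector, one entry per trial.
#' @export
fully_modeled <- function(schedule, trim = 32, support = 32) {
  if (trim <= 0) return(rep(TRUE, schedule$n_trials))
  lo <- trim
  hi <- schedule$session_duration - trim
  schedule$onsets >= lo & (schedule$onsets + support) <= hi
}

#' Read / write BIDS-style event tables
#'
#' Tab-separated files with columns `onset`, `duration`, `trial_type`
#' (durations are 0 for delta events). `trial_type` values are mapped to
#' integer labels in order of first appearance unless already integer.
#'
#' @param path File path.
#' @param session_duration Session length in seconds; defaults to the last
#'   onset plus 32 s.
#' @return `read_events`: an `event_schedule`. `write_events`: `path`,
#'   invisibly.
#' @export
read_events <- function(path, session_duration = NULL) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "trial_type")
  if (!all(need %in% names(tab)))
    stop("event table must have columns 'onset' and 'trial_type'",
         call. = FALSE)
  types <- tab$trial_type
  labels <- if (is.numeric(types)) as.integer(types)
            else as.integer(factor(types, levels = unique(types)))
  if (is.null(session_duration))
    session_duration <- max(tab$onset) + 32
  soa <- if (nrow(tab) > 1 && length(unique(round(diff(tab$onset), 9))) == 1L)
    diff(tab$onset)[1] else NA_real_
  event_schedule(tab$onset, labels, session_duration, soa = soa,
                 n_types = max(labels))
}

#' @rdname read_events
#' @param schedule An `event_schedule`.
#' @export
write_events <- function(schedule, path) {
  tab <- data.frame(onset = schedule$onsets,
                    duration = 0,
                    trial_type = schedule$labels)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.event_schedule <- function(x, ...) {
  cat("Event schedule:", x$n_trials, "trials of", x$n_types, "type(s),",
      "SOA", if (is.na(x$soa)) "irregular" else paste0(x$soa, " s,"),
      "session", x$session_duration, "s\n")
  invisible(x)
}
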