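#' Simulate a multi-session trial pattern set
#'
#' Simulates independent scanning sessions (two by default) sharing the
#' same amplitude specification, estimates single-trial amplitudes per
#' voxel, and collects the trials x voxels pattern matrix and labels per
#' session — the input to cross-session classification. Each session uses a
#' balanced schedule (`n_per_type` trials of each type, randomly ordered)
#' padded so every trial's full response is recorded.
#'
#' @param soa Stimulus onset asynchrony in seconds.
#' @param amp_spec An [amplitude_spec()]; for the reference two-voxel
#'   configuration use type means `rbind(c(5, 3), c(3, 5))` (the two types
#'   have opposite patterns across the two voxels).
#' @param scan_sd Scan-noise SD.
#' @param coherence A [coherence_spec()] controlling whether trial
#'   variability and scan noise are shared across voxels.
#' @param model Estimator for the single-trial patterns: `"lsa"`,
#'   `"lssn"` (LSS-2 for two types; its use of labels for the non-target
#'   regressors is unbiased because training and test folds are separate
#'   sessions), `"lss1"` (for single-session use), or ridge-LSA via
#'   `lambda`.
#' @param n_voxels Number of voxels (2 in the reference analysis).
#' @param n_per_type Trials per type per session.
#' @param n_sessions Number of independently simulated sessions.
#' @param lambda Optional ridge penalty (LSA only).
#' @param tr Repetition time in seconds.
#' @param seed Integer seed; session s uses derived sub-seeds.
#' @return An object of class `trial_pattern_set`: list of sessions, each
#'   with `patterns` (trials x voxels) and `labels`.
#' @export
simulate_pattern_set <- function(soa, amp_spec, scan_sd,
                                 coherence = coherence_spec(),
                                 model = c("lsa", "lssn", "lss1"),
                                 n_voxels = 2L, n_per_type = 30L,
                                 n_sessions = 2L, lambda = NULL, tr = 1,
                                 seed = 1L) {
  model <- match.arg(model)
  hrf <- canonical_hrf(tr)
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sch <- balanced_schedule(soa, n_types = amp_spec$n_types,
                             n_per_type = n_per_type, tr = tr,
                             seed = cell_seed(seed, "labels", s))
    ses <- simulate_session(sch, amp_spec, hrf, scan_sd,
                            n_voxels = n_voxels, coherence = coherence,
                            amp_seed = cell_seed(seed, "amp", s),
                            noise_seed = cell_seed(seed, "noise", s),
                            tr = tr)
    fit <- estimate_trials(ses, model = model, lambda = lambda)
    sessions[[s]] <- list(patterns = coef(fit), labels = fit$labels)
  }
  structure(list(sessions = sessions, model = model, soa = soa,
                 scan_sd = scan_sd, coherence = coherence),
            class = "trial_pattern_set")
}

#' @export
print.trial_pattern_set <- function(x, ...) {
  cat("Trial pattern set:", length(x$sessions), "sessions of",
      nrow(x$sessions[[1]]$patterns), "trials x",
      ncol(x$sessions[[1]]$patterns), "voxels (", toupper(x$model),
      "estimates )\n")
  invisible(x)
}

#' Cross-session classification performance (CP)
#'
#' Two-fold cross-validated accuracy of a linear support-vector classifier
#' on single-trial voxel patterns: train on one session, test on the other,
#' swap, and average the two fold accuracies. The SVM uses a linear kernel
#' with soft-margin constant `cost` and no feature scaling (the voxels
#' share units). Chance level for two balanced classes is 0.5.
#'
#' @param patterns A [simulate_pattern_set()] result, or any list with a
#'   `sessions` field of `list(patterns, labels)` entries (at least two
#'   sessions, equal voxel counts).
#' @param cost SVM soft-margin constant.
#' @param permute_labels Permute the training labels (for building a
#'   permutation null); requires `seed`.
#' @param seed Optional seed for the permutation.
#' @return Mean accuracy in `[0, 1]`.
#' @export
classification_performance <- function(patterns, cost = 1,
                                       permute_labels = FALSE, seed = NULL) {
  sess <- patterns$sessions
  if (length(sess) < 2L)
    stop("classification requires at least two sessions", call. = FALSE)
  nv <- vapply(sess, function(s) ncol(s$patterns), integer(1))
  if (length(unique(nv)) != 1L)
    stop("sessions must share the voxel count", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  folds <- utils::combn(length(sess), 2L)
  accs <- numeric(0)
  for (f in seq_len(ncol(folds))) {
    pair <- folds[, f]
    for (swap in 1:2) {
      tr_i <- pair[swap]; te_i <- pair[3L - swap]
      xtr <- sess[[tr_i]]$patterns
      ytr <- sess[[tr_i]]$labels
      if (permute_labels) ytr <- sample(ytr)
      if (length(unique(ytr)) < 2L)
        stop("training fold contains a single class", call. = FALSE)
      fitsvm <- e1071::svm(xtr, factor(ytr), kernel = "linear",
                           cost = cost, scale = FALSE)
      pred <- stats::predict(fitsvm, sess[[te_i]]$patterns)
      accs <- c(accs,
                mean(as.character(pred) ==
                     as.character(sess[[te_i]]$labels)))
    }
  }
  mean(accs)
}

#' Export a pattern set as CSV
#'
#' Long-format CSV with columns `session`, `trial`, `label` and one column
#' per voxel estimate.
#'
#' @param patterns A `trial_pattern_set`.
#' @param path Output path.
#' @export
write_pattern_set <- function(patterns, path) {
  rows <- lapply(seq_along(patterns$sessions), function(s) {
    p <- patterns$sessions[[s]]
    data.frame(session = s, trial = seq_len(nrow(p$patterns)),
               label = p$labels, p$patterns, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
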