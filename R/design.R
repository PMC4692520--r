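#' Nuisance configuration for design construction
#'
#' @param trim_transients Discard the first and last `trim` seconds of the
#'   session, model only trials whose complete HRF fits the retained
#'   window, and add a single covariate of no interest summing the
#'   regressors of all boundary-crossing ("partial") trials.
#' @param highpass Append a Discrete Cosine Transform high-pass set
#'   capturing frequencies up to `1/hp_cutoff` Hz.
#' @param trim Seconds discarded at each edge (the HRF support).
#' @param hp_cutoff High-pass cutoff period in seconds (SPM default 128).
#' @return A list of class `nuisance_config`.
#' @export
nuisance_config <- function(trim_transients = FALSE, highpass = FALSE,
                            trim = 32, hp_cutoff = 128) {
  structure(list(trim_transients = isTRUE(trim_transients),
                 highpass = isTRUE(highpass),
                 trim = trim, hp_cutoff = hp_cutoff),
            class = "nuisance_config")
}

#' Discrete cosine transform high-pass basis
#'
#' Cosine regressors of order `1 .. floor(2 * n_scans * tr / cutoff)` on the
#' scan grid (the order-0 constant is excluded; a constant column is always
#' present in the design). Columns are mutually orthogonal.
#'
#' @param n_scans Number of scans (> 1).
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cutoff period in seconds; `Inf` gives 0 columns.
#' @return A `n_scans` x `k` matrix (`k` possibly 0).
#' @examples
#' ncol(dct_basis(2700, 1))  # 42 regressors at the 128-s default
#' @export
dct_basis <- function(n_scans, tr = 1, cutoff = 128) {
  if (n_scans <= 1) stop("'n_scans' must exceed 1", call. = FALSE)
  k <- if (is.infinite(cutoff)) 0L else floor(2 * n_scans * tr / cutoff)
  if (k <= 0) return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  n <- n_scans
  idx <- 0:(n - 1)
  cols <- vapply(seq_len(k), function(ord)
    sqrt(2 / n) * cos(pi * (2 * idx + 1) * ord / (2 * n)), numeric(n))
  colnames(cols) <- paste0("dct", seq_len(k))
  cols
}

# scans x n_trials matrix of unit-amplitude HRF regressors, one column per
# trial, on the full (untrimmed) scan grid. Onsets aligned to the grid
# reproduce the sampled kernel exactly; off-grid onsets sample the
# continuous double-gamma at scan times.
trial_columns <- function(schedule, hrf, tr = hrf$tr) {
  n_scans <- floor(schedule$session_duration / tr)
  times <- tr * (seq_len(n_scans) - 1)
  m <- schedule$n_trials
  out <- matrix(0, n_scans, m)
  support <- hrf$parameters$support
  on_grid <- abs(schedule$onsets / tr - round(schedule$onsets / tr)) < 1e-9
  for (j in seq_len(m)) {
    o <- schedule$onsets[j]
    if (on_grid[j]) {
      i0 <- round(o / tr) + 1L
      len <- min(length(hrf$values), n_scans - i0 + 1L)
      if (len > 0)
        out[i0:(i0 + len - 1L), j] <- hrf$values[seq_len(len)]
    } else {
      lag <- times - o
      sel <- lag >= 0 & lag <= support
      out[sel, j] <- hrf_at(hrf, lag[sel])
    }
  }
  colnames(out) <- paste0("trial", seq_len(m))
  out
}

#' Build a GLM design matrix
#'
#' Constructs the design matrix for one of the four single-trial GLM
#' families:
#' \describe{
#'   \item{`"lsu"` (Least Squares Unitary)}{one regressor per trial type.}
#'   \item{`"lsa"` (Least Squares All)}{one regressor per individual trial.}
#'   \item{`"lss1"` (Least Squares Separate)}{one regressor for the target
#'     trial plus a single regressor aggregating all non-target trials.}
#'   \item{`"lssn"`}{as `lss1` but with one aggregate non-target regressor
#'     per trial type (LSS-2 for two types).}
#' }
#' Nuisance columns follow the task columns: the optional partial-trial
#' covariate, the optional DCT high-pass set, and always a final constant.
#'
#' @param schedule An [event_schedule()].
#' @param hrf An [canonical_hrf()] kernel.
#' @param model One of `"lsu"`, `"lsa"`, `"lss1"`, `"lssn"`.
#' @param target_trial Trial index (1-based) of the target trial; required
#'   for the LSS models, which fit one GLM per target.
#' @param nuisance A [nuisance_config()].
#' @param tr Repetition time; defaults to the kernel's.
#' @param trial_cols Optional precomputed [trial_columns] matrix (internal
#'   cache used by the sweep driver; must match `schedule` and `hrf`).
#' @return An object of class `fmri_design`: list with `X` (retained scans
#'   x columns), `roles` (per-column role strings), `penalize` (logical,
#'   `TRUE` for task columns — the columns a ridge penalty acts on),
#'   `retained` (scan indices kept), `modeled` (logical per trial),
#'   `model`, `target_trial`, `tr`.
#' @export
build_design <- function(schedule, hrf, model = c("lsu", "lsa", "lss1", "lssn"),
                         target_trial = NULL,
                         nuisance = nuisance_config(), tr = hrf$tr,
                         trial_cols = NULL) {
  model <- match.arg(model)
  if (model %in% c("lss1", "lssn")) {
    if (is.null(target_trial))
      stop("LSS designs require 'target_trial'", call. = FALSE)
    if (target_trial < 1 || target_trial > schedule$n_trials)
      stop("'target_trial' out of range", call. = FALSE)
  }
  if (is.null(trial_cols)) trial_cols <- trial_columns(schedule, hrf, tr)
  n_scans <- nrow(trial_cols)
  modeled <- fully_modeled(schedule,
                           trim = if (nuisance$trim_transients) nuisance$trim else 0,
                           support = hrf$parameters$support)
  retained <- if (nuisance$trim_transients) {
    times <- tr * (seq_len(n_scans) - 1)
    which(times >= nuisance$trim &
          times < schedule$session_duration - nuisance$trim)
  } else seq_len(n_scans)
  Tm <- trial_cols[retained, , drop = FALSE]
  midx <- which(modeled)
  if (length(midx) == 0L)
    stop("no fully modeled trials remain after trimming", call. = FALSE)

  labels <- schedule$labels
  task <- switch(model,
    lsu = {
      X <- vapply(seq_len(schedule$n_types), function(k) {
        sel <- midx[labels[midx] == k]
        if (length(sel) == 0) numeric(nrow(Tm))
        else rowSums(Tm[, sel, drop = FALSE])
      }, numeric(nrow(Tm)))
      colnames(X) <- paste0("condition", seq_len(schedule$n_types))
      list(X = X, roles = paste0("condition(", seq_len(schedule$n_types), ")"))
    },
    lsa = {
      X <- Tm[, midx, drop = FALSE]
      list(X = X, roles = paste0("trial(", midx, ")"))
    },
    lss1 = {
      if (!modeled[target_trial])
        stop("target trial ", target_trial,
             " is not fully modeled under the current trimming", call. = FALSE)
      others <- setdiff(midx, target_trial)
      X <- cbind(target = Tm[, target_trial],
                 nontarget = if (length(others))
                   rowSums(Tm[, others, drop = FALSE]) else NULL)
      list(X = X,
           roles = c(paste0("trial(", target_trial, ")"),
                     if (length(others)) "nontarget_aggregate")[seq_len(ncol(X))])
    },
    lssn = {
      if (!modeled[target_trial])
        stop("target trial ", target_trial,
             " is not fully modeled under the current trimming", call. = FALSE)
      others <- setdiff(midx, target_trial)
      agg <- lapply(seq_len(schedule$n_types), function(k) {
        sel <- others[labels[others] == k]
        if (length(sel)) rowSums(Tm[, sel, drop = FALSE]) else NULL
      })
      keep <- !vapply(agg, is.null, logical(1))
      X <- cbind(Tm[, target_trial],
                 do.call(cbind, agg[keep]))
      colnames(X) <- c("target", paste0("nontarget", which(keep)))
      list(X = X,
           roles = c(paste0("trial(", target_trial, ")"),
                     paste0("nontarget_aggregate(", which(keep), ")")))
    })

  X <- task$X
  roles <- task$roles
  penalize <- rep(TRUE, ncol(X))

  if (nuisance$trim_transients && any(!modeled)) {
    partial <- rowSums(trial_cols[retained, !modeled, drop = FALSE])
    if (sum(partial^2) > 0) {
      X <- cbind(X, partial_trial = partial)
      roles <- c(roles, "partial_trial")
      penalize <- c(penalize, FALSE)
    }
  }
  if (nuisance$highpass) {
    D <- dct_basis(length(retained), tr, nuisance$hp_cutoff)
    if (ncol(D) > 0) {
      X <- cbind(X, D)
      roles <- c(roles, paste0("dct(", seq_len(ncol(D)), ")"))
      penalize <- c(penalize, rep(FALSE, ncol(D)))
    }
  }
  X <- cbind(X, constant = 1)
  roles <- c(roles, "constant")
  penalize <- c(penalize, FALSE)

  structure(list(X = X, roles = roles, penalize = penalize,
                 retained = retained, modeled = modeled, model = model,
                 target_trial = target_trial, tr = tr,
                 n_scans = n_scans),
            class = "fmri_design")
}

#' @export
print.fmri_design <- function(x, ...) {
  cat("fMRI design (", toupper(x$model), "): ", nrow(x$X), " scans x ",
      ncol(x$X), " columns; ", sum(x$modeled), "/", length(x$modeled),
      " trials fully modeled\n", sep = "")
  invisible(x)
}
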