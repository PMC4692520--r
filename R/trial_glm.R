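#' Fit a single-trial GLM to BOLD timeseries
#'
#' The central fitting function. Given a voxel timeseries (or a scans x
#' voxels matrix) and an event schedule, estimates evoked amplitudes under
#' one of four GLM families:
#' \describe{
#'   \item{LSU}{one regressor per trial type; returns per-condition
#'     estimates. Trial-to-trial variability is relegated to the residual.}
#'   \item{LSA}{one regressor per trial in a single GLM; returns per-trial
#'     estimates (the "beta series"). Optionally ridge-regularized via
#'     `lambda`.}
#'   \item{LSS-1 / LSS-N}{one GLM per target trial, with the non-target
#'     trials collapsed into a single aggregate regressor (LSS-1) or one
#'     aggregate per trial type (LSS-N); only each fit's target coefficient
#'     is kept.}
#' }
#' All designs include a final constant; transient trimming and DCT
#' high-pass regressors are controlled by `nuisance` and applied
#' identically to the design and the data. Only fully modeled trials (those
#' whose complete HRF fits the retained window) receive estimates.
#'
#' @param y Numeric vector or scans x voxels matrix covering the full
#'   session grid (trimming is applied internally).
#' @param schedule An [event_schedule()], or the path of a BIDS-style
#'   events TSV.
#' @param model `"lsu"`, `"lsa"`, `"lss1"` or `"lssn"`.
#' @param hrf HRF kernel; defaults to the canonical HRF at `tr`.
#' @param tr Repetition time in seconds.
#' @param nuisance A [nuisance_config()].
#' @param lambda Optional ridge penalty; only valid with `model = "lsa"`.
#' @param trial_cols,design_cache Internal caches used by the sweep driver.
#' @return An object of class `trial_glm` with methods `print`, `summary`,
#'   `coef`, `fitted`, `residuals` and `plot`. `coef()` returns the
#'   per-trial (LSA/LSS) or per-condition (LSU) estimate matrix, one column
#'   per voxel.
#' @examples
#' hrf <- canonical_hrf(1)
#' sch <- generate_schedule(soa = 8, session_duration = 240)
#' ses <- simulate_session(sch, amplitude_spec(3, 1), hrf, scan_sd = 0.5,
#'                         amp_seed = 1, noise_seed = 2)
#' fit <- trial_glm(ses$y, sch, model = "lsa")
#' head(coef(fit))
#' @export
trial_glm <- function(y, schedule, model = c("lsu", "lsa", "lss1", "lssn"),
                      hrf = canonical_hrf(tr), tr = 1,
                      nuisance = nuisance_config(), lambda = NULL,
                      trial_cols = NULL, design_cache = NULL) {
  model <- match.arg(model)
  if (is.character(schedule))  # the timeseries defines the session grid
    schedule <- read_events(schedule,
                            session_duration = nrow(as.matrix(y)) * tr)
  if (!is.null(lambda) && model != "lsa")
    stop("'lambda' (ridge) is only supported for the LSA model",
         call. = FALSE)
  y <- as.matrix(y)
  if (is.null(trial_cols)) trial_cols <- trial_columns(schedule, hrf, tr)
  if (nrow(y) != nrow(trial_cols))
    stop("'y' has ", nrow(y), " scans but the session grid has ",
         nrow(trial_cols), call. = FALSE)

  if (model %in% c("lsu", "lsa")) {
    design <- if (!is.null(design_cache)) design_cache else
      build_design(schedule, hrf, model, nuisance = nuisance, tr = tr,
                   trial_cols = trial_cols)
    yr <- y[design$retained, , drop = FALSE]
    coefs <- if (!is.null(lambda) && lambda > 0)
      fit_ridge(design, yr, lambda) else
      fit_ols(design$X, yr, qr_cache = design$qr)
    coefs <- as.matrix(coefs)
    is_task <- design$penalize
    est <- coefs[is_task, , drop = FALSE]
    fitted_vals <- design$X %*% coefs
    resid <- yr - fitted_vals
    trial_index <- if (model == "lsa") which(design$modeled) else NULL
    rownames(est) <- if (model == "lsa") paste0("trial", trial_index)
                     else paste0("condition", seq_len(schedule$n_types))
    out <- list(model = model, estimates = est, trial_index = trial_index,
                coefficients = coefs, design = design,
                fitted = fitted_vals, residuals = resid)
  } else {
    modeled <- fully_modeled(
      schedule, trim = if (nuisance$trim_transients) nuisance$trim else 0,
      support = hrf$parameters$support)
    targets <- which(modeled)
    if (length(targets) == 0L)
      stop("LSS: every trial is boundary-partial under the current trimming",
           call. = FALSE)
    est <- matrix(NA_real_, length(targets), ncol(y))
    for (i in seq_along(targets)) {
      d <- build_design(schedule, hrf, model, target_trial = targets[i],
                        nuisance = nuisance, tr = tr,
                        trial_cols = trial_cols)
      b <- as.matrix(fit_ols(d$X, y[d$retained, , drop = FALSE]))
      est[i, ] <- b[1L, ]  # target column is first
    }
    rownames(est) <- paste0("trial", targets)
    out <- list(model = model, estimates = est, trial_index = targets,
                coefficients = NULL, design = NULL,
                fitted = NULL, residuals = NULL)
  }
  colnames(out$estimates) <- paste0("voxel", seq_len(ncol(y)))
  out$schedule <- schedule
  out$lambda <- if (is.null(lambda)) 0 else lambda
  out$nuisance <- nuisance
  out$tr <- tr
  out$labels <- if (!is.null(out$trial_index))
    schedule$labels[out$trial_index] else seq_len(schedule$n_types)
  out$call <- match.call()
  class(out) <- "trial_glm"
  out
}

#' Estimate trial amplitudes from a simulated session
#'
#' Thin wrapper applying [trial_glm()] to a `simulated_session`, returning
#' the fit plus the matched true amplitudes of the modeled trials.
#'
#' @param session A [synthesize_bold()] / [simulate_session()] result.
#' @inheritParams trial_glm
#' @return A `trial_glm` object with an extra `truth` field: the true
#'   `betas` rows for the modeled trials (all trials for LSU).
#' @export
estimate_trials <- function(session, model = c("lsu", "lsa", "lss1", "lssn"),
                            nuisance = nuisance_config(), lambda = NULL,
                            hrf = session$hrf, trial_cols = NULL,
                            design_cache = NULL) {
  model <- match.arg(model)
  fit <- trial_glm(session$y, session$schedule, model = model, hrf = hrf,
                   tr = session$tr, nuisance = nuisance, lambda = lambda,
                   trial_cols = trial_cols, design_cache = design_cache)
  fit$truth <- if (!is.null(fit$trial_index))
    session$betas[fit$trial_index, , drop = FALSE] else session$betas
  fit$truth_labels <- if (!is.null(fit$trial_index))
    session$schedule$labels[fit$trial_index] else session$schedule$labels
  fit
}

#' @export
coef.trial_glm <- function(object, ...) object$estimates

#' @export
fitted.trial_glm <- function(object, ...) {
  if (is.null(object$fitted))
    stop("fitted values are only stored for single-fit models (LSU/LSA)",
         call. = FALSE)
  object$fitted
}

#' @export
residuals.trial_glm <- function(object, ...) {
  if (is.null(object$residuals))
    stop("residuals are only stored for single-fit models (LSU/LSA); ",
         "LSS fits one GLM per trial", call. = FALSE)
  object$residuals
}

#' @export
print.trial_glm <- function(x, ...) {
  kind <- switch(x$model, lsu = "LSU (one regressor per condition)",
                 lsa = "LSA (one regressor per trial)",
                 lss1 = "LSS-1 (separate GLM per target trial)",
                 lssn = "LSS-N (separate GLM per target, typed non-targets)")
  cat("Single-trial GLM fit:", kind, "\n")
  if (x$lambda > 0) cat("  ridge penalty lambda =", x$lambda, "\n")
  cat(" ", nrow(x$estimates),
      if (x$model == "lsu") "condition estimate(s) x" else "trial estimates x",
      ncol(x$estimates), "voxel(s)\n")
  invisible(x)
}

#' @export
summary.trial_glm <- function(object, ...) {
  est <- object$estimates
  by_type <- if (object$model == "lsu") est else
    apply(est, 2, function(v) tapply(v, object$labels, mean))
  by_type <- matrix(by_type, ncol = ncol(est),
                    dimnames = list(paste0("type", sort(unique(object$labels))),
                                    colnames(est)))
  res_sd <- if (!is.null(object$residuals))
    apply(object$residuals, 2, stats::sd) else NULL
  out <- list(model = object$model, lambda = object$lambda,
              n_estimates = nrow(est), n_voxels = ncol(est),
              type_means = by_type, residual_sd = res_sd)
  class(out) <- "summary.trial_glm"
  out
}

#' @export
print.summary.trial_glm <- function(x, ...) {
  cat("Model:", toupper(sub("ss", "SS-", x$model)), "-", x$n_estimates,
      "estimates x", x$n_voxels, "voxel(s)\n")
  cat("Mean estimate per trial type:\n")
  print(round(x$type_means, 4))
  if (!is.null(x$residual_sd))
    cat("Residual SD per voxel:", round(x$residual_sd, 4), "\n")
  invisible(x)
}

#' Plot a beta series
#'
#' Per-trial amplitude estimates against trial index, one panel line per
#' voxel; for LSU fits, condition estimates are drawn as horizontal lines.
#'
#' @param x A `trial_glm` fit.
#' @param voxel Voxel column to plot.
#' @param truth Optional vector of true amplitudes to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trial_glm <- function(x, voxel = 1L, truth = NULL, ...) {
  est <- x$estimates[, voxel]
  if (x$model == "lsu") {
    graphics::plot(seq_along(est), est, pch = 19,
                   xlab = "condition", ylab = "estimated amplitude", ...)
  } else {
    graphics::plot(x$trial_index, est, type = "b", pch = 19,
                   xlab = "trial", ylab = "estimated amplitude", ...)
    if (!is.null(truth))
      graphics::lines(x$trial_index, truth, col = "darkgreen", lty = 2)
  }
  invisible(x)
}

#' Export a beta series as CSV
#'
#' Long-format CSV with columns `trial_index`, `onset`, `trial_type`,
#' `voxel`, `estimate` (for LSU, `trial_index`/`onset` are `NA` and rows
#' are per condition).
#'
#' @param fit A `trial_glm`.
#' @param path Output path.
#' @export
write_beta_series <- function(fit, path) {
  est <- fit$estimates
  nv <- ncol(est)
  if (fit$model == "lsu") {
    tab <- data.frame(trial_index = NA_integer_, onset = NA_real_,
                      trial_type = rep(seq_len(nrow(est)), nv),
                      voxel = rep(seq_len(nv), each = nrow(est)),
                      estimate = as.vector(est))
  } else {
    tab <- data.frame(trial_index = rep(fit$trial_index, nv),
                      onset = rep(fit$schedule$onsets[fit$trial_index], nv),
                      trial_type = rep(fit$labels, nv),
                      voxel = rep(seq_len(nv), each = nrow(est)),
                      estimate = as.vector(est))
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
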