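#' Deterministic cell/replicate seed
#'
#' Stable 31-bit seed derived from arbitrary coordinate values by a
#' base-31 polynomial rolling hash of their `|`-joined string
#' representation, reduced modulo `2^31 - 1`. Used to give every
#' (cell, replicate, sub-stream) combination an independently reproducible
#' RNG seed, so cells can be recomputed in any order (or in parallel)
#' with identical results.
#'
#' @param ... Coordinate values (coerced to character).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
cell_seed <- function(...) {
  s <- paste(unlist(list(...)), collapse = "|")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Sweep configuration
#'
#' Bundles every knob of a simulation sweep. The defaults reproduce the
#' reference simulation conditions: TR 1 s, 45-min sessions, SOA grid
#' 2-24 s in 1-s steps, trial-SD grid \{0, 0.5, 0.8, 1.6, 3\}, scan-SD
#' grid \{0.5, 0.8, 1.6, 3\}, type means 3 and 5, 10,000 replicates.
#'
#' @param tr Repetition time (s).
#' @param session_duration Session length (s).
#' @param soas SOA grid (s).
#' @param trial_sds Trial-to-trial amplitude SD grid.
#' @param scan_sds Scan-noise SD grid.
#' @param means Population mean amplitude per trial type.
#' @param n_types Number of trial types (1 = single type vs baseline,
#'   2 = randomly intermixed pair; the metric contrast follows: single for
#'   one type, difference of the two type means for two).
#' @param models Model grid: subset of `"lsu"`, `"lsa"`, `"lss1"`,
#'   `"lssn"`, `"ridge"` (ridge-regularized LSA with penalty `lambda`).
#' @param metrics Metric grid: subset of `"ppm"`, `"psm"`, `"psc"`.
#' @param n_replicates Replicates per cell (>= 2).
#' @param seed Master seed; every replicate seed is derived from it via
#'   [cell_seed()].
#' @param trim_transients,highpass,hp_cutoff Nuisance handling, see
#'   [nuisance_config()].
#' @param lambda Ridge penalty for `models = "ridge"`.
#' @param verbose Log per-cell progress to stderr.
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(tr = 1, session_duration = 2700, soas = 2:24,
                         trial_sds = c(0, 0.5, 0.8, 1.6, 3),
                         scan_sds = c(0.5, 0.8, 1.6, 3),
                         means = c(3, 5), n_types = 1L,
                         models = "lsu", metrics = "ppm",
                         n_replicates = 10000L, seed = 1L,
                         trim_transients = FALSE, highpass = FALSE,
                         hp_cutoff = 128, lambda = 5, verbose = FALSE) {
  if (!length(soas) || !length(trial_sds) || !length(scan_sds) ||
      !length(models) || !length(metrics))
    stop("all sweep grids must be non-empty", call. = FALSE)
  if (n_replicates < 2L)
    stop("'n_replicates' must be >= 2", call. = FALSE)
  if (n_types > length(means))
    stop("'means' must supply one mean per trial type", call. = FALSE)
  models <- match.arg(models, c("lsu", "lsa", "lss1", "lssn", "ridge"),
                      several.ok = TRUE)
  metrics <- match.arg(metrics, c("ppm", "psm", "psc"), several.ok = TRUE)
  structure(list(tr = tr, session_duration = session_duration, soas = soas,
                 trial_sds = trial_sds, scan_sds = scan_sds,
                 means = means[seq_len(n_types)], n_types = as.integer(n_types),
                 models = models, metrics = metrics,
                 n_replicates = as.integer(n_replicates), seed = seed,
                 trim_transients = trim_transients, highpass = highpass,
                 hp_cutoff = hp_cutoff, lambda = lambda, verbose = verbose),
            class = "sweep_config")
}

#' Named sweep profiles
#'
#' `"reference"` is the full simulation profile (45-min sessions, 10,000
#' replicates); `"desk"` is a scaled-down profile for interactive use and
#' continuous testing (15-min sessions, 500 replicates), which preserves
#' the qualitative structure of the efficiency surfaces at a fraction of
#' the cost.
#'
#' @param profile Profile name.
#' @param ... Overrides passed on to [sweep_config()].
#' @export
sweep_profile <- function(profile = c("desk", "reference"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    reference = list(session_duration = 2700, n_replicates = 10000L),
    desk = list(session_duration = 900, n_replicates = 500L))
  do.call(sweep_config, utils::modifyList(base, list(...)))
}

#' Read / write sweep configurations as YAML
#'
#' @param path File path.
#' @export
read_sweep_config <- function(path) {
  do.call(sweep_config, yaml::read_yaml(path))
}

#' @rdname read_sweep_config
#' @param config A `sweep_config`.
#' @export
write_sweep_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Precomputed per-cell context shared by all replicates: trial regressors,
# trimming, nuisance columns and (when the design does not depend on the
# random label sequence) the design factorization.
cell_context <- function(config, soa, model) {
  hrf <- canonical_hrf(config$tr)
  template <- generate_schedule(soa, config$session_duration,
                                n_types = config$n_types,
                                seed = 0L, tr = config$tr)
  tc <- trial_columns(template, hrf, config$tr)
  nuis <- nuisance_config(config$trim_transients, config$highpass,
                          hp_cutoff = config$hp_cutoff)
  fit_model <- if (model == "ridge") "lsa" else model
  label_free <- fit_model == "lsa" || config$n_types == 1L
  design <- NULL
  if (label_free && fit_model %in% c("lsu", "lsa")) {
    design <- build_design(template, hrf, fit_model, nuisance = nuis,
                           tr = config$tr, trial_cols = tc)
    if (model == "ridge") {
      A <- crossprod(design$X)
      diag(A) <- diag(A) + config$lambda * as.numeric(design$penalize)
      design$chol <- chol(A)
    } else {
      design$qr <- qr(design$X)
    }
  }
  modeled <- fully_modeled(template,
                           trim = if (nuis$trim_transients) nuis$trim else 0,
                           support = hrf$parameters$support)
  retained <- if (!is.null(design)) design$retained else {
    if (nuis$trim_transients) {
      times <- config$tr * (seq_len(nrow(tc)) - 1)
      which(times >= nuis$trim &
            times < config$session_duration - nuis$trim)
    } else seq_len(nrow(tc))
  }
  # fixed nuisance block: optional partial-trial covariate, DCT set, constant
  nuisX <- NULL
  if (nuis$trim_transients && any(!modeled)) {
    partial <- rowSums(tc[retained, !modeled, drop = FALSE])
    if (sum(partial^2) > 0) nuisX <- cbind(partial_trial = partial)
  }
  if (nuis$highpass) {
    D <- dct_basis(length(retained), config$tr, nuis$hp_cutoff)
    if (ncol(D) > 0) nuisX <- cbind(nuisX, D)
  }
  nuisX <- cbind(nuisX, constant = rep(1, length(retained)))
  list(hrf = hrf, template = template, trial_cols = tc, nuisance = nuis,
       fit_model = fit_model, design = design, modeled = modeled,
       midx = which(modeled), retained = retained, nuisX = nuisX,
       Tm = tc[retained, , drop = FALSE])
}

# One replicate of simulate + fit for a cell; returns the per-trial (or
# per-condition) estimates plus truth and labels of the modeled trials.
cell_replicate <- function(ctx, config, trial_sd, scan_sd, model, rep_i,
                           soa) {
  n_types <- config$n_types
  m <- ctx$template$n_trials
  tag <- function(stream) cell_seed(config$seed, model, soa, trial_sd,
                                    scan_sd, rep_i, stream)
  labels <- if (n_types == 1L) rep(1L, m) else {
    set.seed(tag("labels"))
    sample.int(n_types, m, replace = TRUE)
  }
  sched <- ctx$template
  sched$labels <- labels
  spec <- amplitude_spec(config$means, trial_sd)
  betas <- draw_trial_betas(sched, spec, seed = tag("amp"))
  session <- synthesize_bold(sched, betas, ctx$hrf, scan_sd,
                             seed = tag("noise"), tr = config$tr,
                             trial_cols = ctx$trial_cols)
  yr <- session$y[ctx$retained, 1L]
  midx <- ctx$midx
  fm <- ctx$fit_model

  est <- if (!is.null(ctx$design)) {
    coefs <- if (model == "ridge")
      backsolve(ctx$design$chol,
                forwardsolve(t(ctx$design$chol), crossprod(ctx$design$X, yr)))
    else qr.coef(ctx$design$qr, yr)
    coefs[seq_len(if (fm == "lsu") n_types else length(midx))]
  } else if (fm == "lsu") {
    Xt <- vapply(seq_len(n_types), function(k) {
      sel <- midx[labels[midx] == k]
      if (length(sel)) rowSums(ctx$Tm[, sel, drop = FALSE])
      else numeric(nrow(ctx$Tm))
    }, numeric(nrow(ctx$Tm)))
    fit_ols(cbind(Xt, ctx$nuisX), yr)[seq_len(n_types)]
  } else {
    # LSS: one GLM per target; aggregate columns by subtraction from
    # precomputed per-type sums
    sums <- lapply(seq_len(n_types), function(k) {
      sel <- midx[labels[midx] == k]
      if (length(sel)) rowSums(ctx$Tm[, sel, drop = FALSE])
      else numeric(nrow(ctx$Tm))
    })
    total <- Reduce(`+`, sums)
    vapply(midx, function(j) {
      tcol <- ctx$Tm[, j]
      agg <- if (fm == "lss1") {
        a <- total - tcol
        if (sum(a^2) > 0) cbind(a) else NULL
      } else {
        cols <- lapply(seq_len(n_types), function(k) {
          a <- sums[[k]] - if (labels[j] == k) tcol else 0
          if (sum(a^2) > 0) a else NULL
        })
        keep <- !vapply(cols, is.null, logical(1))
        if (any(keep)) do.call(cbind, cols[keep]) else NULL
      }
      fit_ols(cbind(tcol, agg, ctx$nuisX), yr)[1L]
    }, numeric(1))
  }
  list(estimates = unname(est),
       truth = betas[midx, 1L],
       labels = labels[midx])
}

#' Run one sweep cell
#'
#' Simulates `n_replicates` sessions at the given (SOA, trial SD, scan SD)
#' coordinates, fits the requested model to each, and computes the
#' requested efficiency metrics over the replicate ensemble. Fully
#' deterministic given the configuration's master seed: each replicate's
#' label, amplitude and noise draws use independent seeds derived by
#' [cell_seed()], so any cell can be recomputed in isolation.
#'
#' @param config A [sweep_config()].
#' @param soa,trial_sd,scan_sd Cell coordinates.
#' @param model Model kind for this cell (defaults to the first in the
#'   config).
#' @param metrics Metrics to compute (defaults to the config's).
#' @param keep_ensemble Also return the [replicate_ensemble()].
#' @return List with `values` (named metric values), `se` (approximate
#'   Monte-Carlo standard errors), `n_replicates`, and optionally
#'   `ensemble`.
#' @export
run_cell <- function(config, soa, trial_sd, scan_sd,
                     model = config$models[1], metrics = config$metrics,
                     keep_ensemble = FALSE) {
  ctx <- cell_context(config, soa, model)
  reps <- lapply(seq_len(config$n_replicates), function(i)
    cell_replicate(ctx, config, trial_sd, scan_sd, model, i, soa))
  ens <- replicate_ensemble(reps, ctx$fit_model,
                            meta = list(soa = soa, trial_sd = trial_sd,
                                        scan_sd = scan_sd, model = model))
  contrast <- if (config$n_types >= 2L) "difference" else "single"
  n <- config$n_replicates
  values <- se <- stats::setNames(numeric(length(metrics)), metrics)
  for (mt in metrics) {
    v <- switch(mt,
                ppm = ppm(ens, contrast),
                psm = psm(ens, contrast),
                psc = psc(ens))
    values[mt] <- v
    se[mt] <- if (mt == "psc") {
      cors <- vapply(ens$replicates, function(r)
        stats::cor(r$estimates, r$truth), numeric(1))
      stats::sd(cors) / sqrt(n)
    } else v / sqrt(2 * (n - 1))  # delta-method SE of 1/sd
  }
  out <- list(values = values, se = se, n_replicates = n,
              cell = list(soa = soa, trial_sd = trial_sd,
                          scan_sd = scan_sd, model = model))
  if (keep_ensemble) out$ensemble <- ens
  out
}

#' Run a full sweep
#'
#' Loops [run_cell()] over the model x SOA x trial-SD x scan-SD grid and
#' returns one row per (metric, model, soa, trial_sd, scan_sd). Metrics
#' requested together share each cell's replicate ensemble. A cell whose
#' estimator fails is flagged (`ok = FALSE`, `value = NA`) and the sweep
#' continues; with `checkpoint` the table is written after every cell and
#' completed cells are skipped on rerun.
#'
#' @param config A [sweep_config()].
#' @param checkpoint Optional CSV path for resumable execution.
#' @return An [efficiency_grid()] data frame with columns `metric`,
#'   `model`, `soa`, `trial_sd`, `scan_sd`, `value`, `se`, `n`, `ok`.
#' @export
run_sweep <- function(config, checkpoint = NULL) {
  cells <- expand.grid(model = config$models, soa = config$soas,
                       trial_sd = config$trial_sds,
                       scan_sd = config$scan_sds,
                       stringsAsFactors = FALSE)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint, stringsAsFactors = FALSE)
    if (config$verbose)
      message("resuming: ", nrow(done), " rows already computed")
  }
  rows <- if (is.null(done)) list() else list(done)
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    if (!is.null(done) &&
        any(done$model == cl$model & done$soa == cl$soa &
            done$trial_sd == cl$trial_sd & done$scan_sd == cl$scan_sd))
      next
    res <- tryCatch(
      run_cell(config, cl$soa, cl$trial_sd, cl$scan_sd, model = cl$model),
      error = function(e) e)
    row <- if (inherits(res, "error")) {
      warning("cell (", cl$model, ", soa=", cl$soa, ", trial_sd=",
              cl$trial_sd, ", scan_sd=", cl$scan_sd, ") failed: ",
              conditionMessage(res), call. = FALSE)
      data.frame(metric = config$metrics, model = cl$model, soa = cl$soa,
                 trial_sd = cl$trial_sd, scan_sd = cl$scan_sd,
                 value = NA_real_, se = NA_real_,
                 n = config$n_replicates, ok = FALSE)
    } else {
      data.frame(metric = names(res$values), model = cl$model,
                 soa = cl$soa, trial_sd = cl$trial_sd,
                 scan_sd = cl$scan_sd, value = unname(res$values),
                 se = unname(res$se), n = res$n_replicates, ok = TRUE)
    }
    rows[[length(rows) + 1L]] <- row
    if (config$verbose)
      message(sprintf("[%d/%d] %s soa=%g trial_sd=%g scan_sd=%g: %s",
                      i, nrow(cells), cl$model, cl$soa, cl$trial_sd,
                      cl$scan_sd,
                      paste(row$metric, signif(row$value, 4),
                            collapse = ", ")))
    if (!is.null(checkpoint))
      utils::write.csv(do.call(rbind, rows), checkpoint, row.names = FALSE)
  }
  efficiency_grid(do.call(rbind, rows))
}

#' SOA maximizing a metric, with flatness diagnostic
#'
#' Finds the SOA with the largest metric value in one (metric, model,
#' trial_sd, scan_sd) slice of a sweep table. Ties are broken towards the
#' longer SOA. The `flat` field lists every SOA whose value lies within
#' one Monte-Carlo standard error of the maximum — when that set is wide,
#' the optimum should be read as a region, not a point.
#'
#' @param grid An [efficiency_grid()] (output of [run_sweep()]).
#' @param metric,model,trial_sd,scan_sd Slice coordinates (defaults take
#'   the slice as-is if unique).
#' @return List with `soa`, `value`, `flat` (SOAs within 1 SE of the max).
#' @export
argmax_soa <- function(grid, metric = NULL, model = NULL, trial_sd = NULL,
                       scan_sd = NULL) {
  df <- as.data.frame(grid)
  if (!is.null(metric)) df <- df[df$metric == metric, ]
  if (!is.null(model)) df <- df[df$model == model, ]
  if (!is.null(trial_sd)) df <- df[df$trial_sd == trial_sd, ]
  if (!is.null(scan_sd)) df <- df[df$scan_sd == scan_sd, ]
  if (nrow(df) == 0) stop("empty slice", call. = FALSE)
  if (anyDuplicated(df$soa))
    stop("slice is not unique per SOA; specify metric/model/trial_sd/scan_sd",
         call. = FALSE)
  df <- df[order(df$soa), ]
  best <- max(df$value)
  soa <- max(df$soa[df$value == best])  # ties -> longer SOA
  flat <- if ("se" %in% names(df) && all(is.finite(df$se))) {
    se_at <- df$se[df$soa == soa][1]
    df$soa[df$value >= best - se_at]
  } else soa
  list(soa = soa, value = best, flat = flat)
}

#' Local maxima of a metric-versus-SOA curve
#'
#' SOAs whose value is at least as large as both neighbors (endpoints
#' count as maxima if they beat their single neighbor). Used to locate the
#' secondary short-SOA efficiency peak produced by session-edge
#' transients.
#'
#' @inheritParams argmax_soa
#' @return Increasing vector of locally maximal SOAs.
#' @export
soa_local_maxima <- function(grid, metric = NULL, model = NULL,
                             trial_sd = NULL, scan_sd = NULL) {
  df <- as.data.frame(grid)
  if (!is.null(metric)) df <- df[df$metric == metric, ]
  if (!is.null(model)) df <- df[df$model == model, ]
  if (!is.null(trial_sd)) df <- df[df$trial_sd == trial_sd, ]
  if (!is.null(scan_sd)) df <- df[df$scan_sd == scan_sd, ]
  df <- df[order(df$soa), ]
  v <- df$value
  n <- length(v)
  if (n == 0) stop("empty slice", call. = FALSE)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  df$soa[v >= left & v >= right]
}

#' Mean classification performance for one design cell
#'
#' Replicates the full pipeline — simulate two sessions, estimate
#' single-trial patterns, cross-validated SVM — and averages CP across
#' replicates. Seeded like [run_cell()].
#'
#' @inheritParams simulate_pattern_set
#' @param n_replicates Number of simulate/classify replicates.
#' @param seed Master seed.
#' @return List with `cp` (mean accuracy), `se`, `per_replicate`.
#' @export
run_cp_cell <- function(soa, amp_spec, scan_sd,
                        coherence = coherence_spec(), model = "lsa",
                        n_per_type = 30L, lambda = NULL, tr = 1,
                        n_replicates = 20L, seed = 1L) {
  cps <- vapply(seq_len(n_replicates), function(i) {
    ps <- simulate_pattern_set(soa, amp_spec, scan_sd, coherence,
                               model = model, n_per_type = n_per_type,
                               lambda = lambda, tr = tr,
                               seed = cell_seed(seed, "cp", model, soa,
                                                scan_sd, i))
    classification_performance(ps)
  }, numeric(1))
  list(cp = mean(cps), se = stats::sd(cps) / sqrt(n_replicates),
       per_replicate = cps)
}
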