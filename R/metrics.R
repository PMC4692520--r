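#' Replicate ensemble
#'
#' Container for the true and estimated amplitudes across simulation
#' replicates — the input to all efficiency metrics. Each replicate holds
#' the (single-voxel) estimates, the matching true per-trial amplitudes and
#' the trial-type labels of the modeled trials.
#'
#' @param replicates List with one element per replicate, each a list with
#'   fields `estimates` (per-trial vector, or per-condition vector for
#'   LSU), `truth` (per-trial true amplitudes of the modeled trials) and
#'   `labels` (trial-type per modeled trial).
#' @param model The fitted model kind (`"lsu"`, `"lsa"`, `"lss1"`,
#'   `"lssn"`).
#' @param meta Named list of cell metadata (soa, trial_sd, scan_sd, ...).
#' @return An object of class `replicate_ensemble`.
#' @export
replicate_ensemble <- function(replicates, model, meta = list()) {
  if (length(replicates) < 2L)
    stop("at least 2 replicates are required for any precision metric",
         call. = FALSE)
  structure(list(replicates = replicates, model = model, meta = meta,
                 n_sims = length(replicates)),
            class = "replicate_ensemble")
}

#' @export
print.replicate_ensemble <- function(x, ...) {
  cat("Replicate ensemble:", x$n_sims, "replicates of a", toupper(x$model),
      "fit\n")
  if (length(x$meta))
    cat("  cell:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

# Per-replicate mean estimate for the requested contrast. For LSU the
# "mean estimate" is the condition coefficient itself; for per-trial models
# it is the mean over each type's fully modeled trials.
replicate_means <- function(rep, model, contrast, use_truth = FALSE) {
  if (model == "lsu") {
    est <- rep$estimates
    if (contrast == "single") {
      e <- est[1L]
      t <- mean(rep$truth[rep$labels == 1L])
    } else {
      e <- est[1L] - est[2L]
      t <- mean(rep$truth[rep$labels == 1L]) -
           mean(rep$truth[rep$labels == 2L])
    }
  } else {
    if (contrast == "single") {
      e <- mean(rep$estimates)
      t <- mean(rep$truth)
    } else {
      e <- mean(rep$estimates[rep$labels == 1L]) -
           mean(rep$estimates[rep$labels == 2L])
      t <- mean(rep$truth[rep$labels == 1L]) -
           mean(rep$truth[rep$labels == 2L])
    }
  }
  if (use_truth) e - t else e
}

#' Precision of the population mean (PPM)
#'
#' Reciprocal of the across-replicate standard deviation (sample SD, N-1
#' denominator) of the per-replicate mean estimate: the mean over trials of
#' the per-trial estimates (LSA/LSS), the condition coefficient itself
#' (LSU), or the difference of the two per-type means for the two-type
#' contrast. The true population mean, being constant across replicates,
#' does not enter. A zero across-replicate SD yields the infinite-precision
#' sentinel `Inf` rather than an error.
#'
#' @param ensemble A [replicate_ensemble()].
#' @param contrast `"single"` (type 1 versus baseline) or `"difference"`
#'   (type 1 minus type 2).
#' @return A single efficiency value (possibly `Inf`).
#' @export
ppm <- function(ensemble, contrast = c("single", "difference")) {
  contrast <- match.arg(contrast)
  vals <- vapply(ensemble$replicates, replicate_means, numeric(1),
                 model = ensemble$model, contrast = contrast,
                 use_truth = FALSE)
  s <- stats::sd(vals)
  if (s == 0) Inf else 1 / s
}

#' Precision of the sample mean (PSM)
#'
#' As [ppm()], but each replicate's mean estimate has that replicate's true
#' sample mean subtracted first (for LSU, the sample mean of the true
#' amplitudes of the modeled trials is subtracted from the condition
#' coefficient). Measures how well the estimator tracks the realized
#' sample, rather than the population, mean.
#'
#' @inheritParams ppm
#' @export
psm <- function(ensemble, contrast = c("single", "difference")) {
  contrast <- match.arg(contrast)
  vals <- vapply(ensemble$replicates, replicate_means, numeric(1),
                 model = ensemble$model, contrast = contrast,
                 use_truth = TRUE)
  s <- stats::sd(vals)
  if (s == 0) Inf else 1 / s
}

#' Precision of the sample correlation (PSC)
#'
#' Mean over replicates of the Pearson correlation, across trials, between
#' estimated and true amplitudes. Requires per-trial estimates (LSA or
#' LSS); undefined at zero trial variability, where the true amplitudes
#' are constant.
#'
#' @inheritParams ppm
#' @export
psc <- function(ensemble) {
  if (ensemble$model == "lsu")
    stop("PSC requires per-trial estimates; the LSU model cannot be used",
         call. = FALSE)
  vals <- vapply(ensemble$replicates, function(rep) {
    if (stats::sd(rep$truth) == 0)
      stop("PSC is undefined when trial variability is zero ",
           "(true amplitudes are constant)", call. = FALSE)
    stats::cor(rep$estimates, rep$truth)
  }, numeric(1))
  mean(vals)
}

#' Efficiency grid container
#'
#' Tidy long-format table of metric values over a (SOA x trial-SD x
#' scan-SD) grid for one or more models.
#'
#' @param df Data frame with columns `metric`, `model`, `soa`, `trial_sd`,
#'   `scan_sd`, `value` (and optionally `se`).
#' @return The data frame with class `efficiency_grid` prepended.
#' @export
efficiency_grid <- function(df) {
  need <- c("metric", "model", "soa", "trial_sd", "scan_sd", "value")
  if (!all(need %in% names(df)))
    stop("grid needs columns ", paste(need, collapse = ", "), call. = FALSE)
  class(df) <- c("efficiency_grid", "data.frame")
  df
}

#' Log10 model-comparison ratio of two efficiency grids
#'
#' Elementwise `log10(A / B)` on matching (soa, trial_sd, scan_sd) cells;
#' positive values mean model A is more efficient.
#'
#' @param grid_a,grid_b `efficiency_grid`s over identical axes.
#' @return An `efficiency_grid` with metric `"log10(<mA>/<mB>)"` and model
#'   `"<modelA>:<modelB>"`.
#' @export
model_ratio <- function(grid_a, grid_b) {
  key <- function(g) paste(g$soa, g$trial_sd, g$scan_sd)
  a <- grid_a[order(key(grid_a)), ]
  b <- grid_b[order(key(grid_b)), ]
  if (nrow(a) != nrow(b) || !identical(key(a), key(b)))
    stop("grids have mismatched axes", call. = FALSE)
  out <- a
  out$model <- paste0(a$model[1], ":", b$model[1])
  out$metric <- paste0("log10(", a$metric[1], "/", b$metric[1], ")")
  out$value <- log10(a$value / b$value)
  out$se <- NULL
  efficiency_grid(out)
}

#' Serialize an efficiency grid as tidy CSV
#'
#' @param grid An `efficiency_grid`.
#' @param path Output path.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' Heatmap panels of an efficiency grid
#'
#' One SOA x scan-noise heatmap panel per trial-variability level, colored
#' on a base-10 log scale (raw scale for classification accuracy, which is
#' bounded in \\[0, 1\\]). Infinite-precision cells are drawn at the color
#' map maximum.
#'
#' @param x An `efficiency_grid`.
#' @param log10_scale Color on log10 of the value (default `TRUE`; use
#'   `FALSE` for accuracies).
#' @param palette Color ramp function.
#' @param ... Ignored.
#' @export
plot.efficiency_grid <- function(x, log10_scale = TRUE,
                                 palette = grDevices::hcl.colors, ...) {
  df <- as.data.frame(x)
  tsds <- sort(unique(df$trial_sd))
  soas <- sort(unique(df$soa))
  ssds <- sort(unique(df$scan_sd))
  vals <- df$value
  if (log10_scale) vals <- log10(vals)
  finite <- vals[is.finite(vals)]
  if (length(finite) == 0) stop("no finite values to plot", call. = FALSE)
  vals[is.infinite(vals) & vals > 0] <- max(finite)
  zlim <- range(finite)
  old <- graphics::par(mfrow = c(1, length(tsds)),
                       mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  cols <- palette(64, "YlOrRd", rev = TRUE)
  for (ts in tsds) {
    sub <- df$trial_sd == ts
    z <- matrix(NA_real_, length(ssds), length(soas))
    z[cbind(match(df$scan_sd[sub], ssds), match(df$soa[sub], soas))] <-
      vals[sub]
    graphics::image(seq_along(ssds), soas, z, col = cols, zlim = zlim,
                    xaxt = "n", xlab = "scan noise SD", ylab = "SOA (s)",
                    main = paste0(df$metric[1], ", trial SD ", ts))
    graphics::axis(1, at = seq_along(ssds), labels = ssds)
  }
  invisible(x)
}
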