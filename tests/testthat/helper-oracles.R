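# Naive reference implementations of the efficiency metrics, written as
# plain loops directly from their definitions and kept independent of the
# metrics module.

naive_ppm <- function(ens, contrast = "single") {
  vals <- sapply(ens$replicates, function(r) {
    if (ens$model == "lsu") {
      if (contrast == "single") r$estimates[1]
      else r$estimates[1] - r$estimates[2]
    } else {
      if (contrast == "single") sum(r$estimates) / length(r$estimates)
      else mean(r$estimates[r$labels == 1]) - mean(r$estimates[r$labels == 2])
    }
  })
  s <- sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1))
  if (s == 0) Inf else 1 / s
}

naive_psm <- function(ens, contrast = "single") {
  vals <- sapply(ens$replicates, function(r) {
    if (ens$model == "lsu") {
      if (contrast == "single") r$estimates[1] - mean(r$truth[r$labels == 1])
      else (r$estimates[1] - r$estimates[2]) -
           (mean(r$truth[r$labels == 1]) - mean(r$truth[r$labels == 2]))
    } else {
      if (contrast == "single") mean(r$estimates - r$truth)
      else (mean(r$estimates[r$labels == 1]) - mean(r$estimates[r$labels == 2])) -
           (mean(r$truth[r$labels == 1]) - mean(r$truth[r$labels == 2]))
    }
  })
  s <- sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1))
  if (s == 0) Inf else 1 / s
}

naive_psc <- function(ens) {
  mean(sapply(ens$replicates, function(r) {
    x <- r$estimates; y <- r$truth
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }))
}

# Synthetic ensemble with per-replicate estimate/truth vectors produced by
# a supplied generator function(i) -> list(estimates, truth, labels).
make_ensemble <- function(n, gen, model = "lsa", meta = list()) {
  replicate_ensemble(lapply(seq_len(n), gen), model = model, meta = meta)
}

# Small simulated session for estimator tests.
quick_session <- function(soa = 8, dur = 240, n_types = 1, means = 3,
                          trial_sd = 0, scan_sd = 0, seed = 1, tr = 1) {
  hrf <- canonical_hrf(tr)
  sch <- generate_schedule(soa, dur, n_types = n_types, seed = seed, tr = tr)
  simulate_session(sch, amplitude_spec(means, trial_sd), hrf, scan_sd,
                   amp_seed = seed + 1000, noise_seed = seed + 2000, tr = tr)
}
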