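test_that("LSA, LSS-1 and LSS-N coincide when trials do not overlap", {
  # SOA beyond the HRF support makes trial regressors orthogonal, so the
  # target projection is identical however non-targets are modeled
  hrf <- canonical_hrf(1)
  sch <- generate_schedule(33, 33 * 10 + 33, n_types = 2, seed = 4)
  ses <- simulate_session(sch, amplitude_spec(c(3, 5), 1.6), hrf, 0.8,
                          amp_seed = 1, noise_seed = 2)
  e_lsa <- coef(estimate_trials(ses, "lsa"))
  e_ls1 <- coef(estimate_trials(ses, "lss1"))
  e_lsn <- coef(estimate_trials(ses, "lssn"))
  expect_lt(max(abs(e_lsa - e_ls1)), 1e-8)
  expect_lt(max(abs(e_lsa - e_lsn)), 1e-8)
})

test_that("noise-free fits are exact", {
  ses <- quick_session(soa = 4, dur = 200, trial_sd = 1.2, scan_sd = 0,
                       seed = 6)
  # LSA recovers every individual amplitude
  f <- estimate_trials(ses, "lsa")
  expect_equal(unname(coef(f)[, 1]), unname(f$truth[, 1]), tolerance = 1e-8)
  expect_lt(sum(residuals(f)^2), 1e-16)
  # LSU with no trial variability recovers the population mean exactly,
  # including under trimming (partial trials share the common amplitude)
  ses0 <- quick_session(soa = 4, dur = 200, trial_sd = 0, scan_sd = 0)
  f0 <- trial_glm(ses0$y, ses0$schedule, "lsu",
                  nuisance = nuisance_config(trim_transients = TRUE))
  expect_equal(unname(coef(f0)[1, 1]), 3, tolerance = 1e-9)
  # LSU leaves unmodeled trial variability in the residual
  fU <- estimate_trials(ses, "lsu")
  expect_gt(sum(residuals(fU)^2), 1)
  expect_equal(as.numeric(residuals(fU)),
               unname(residuals(lm(ses$y[, 1] ~ fU$design$X - 1))),
               tolerance = 1e-8)
})

test_that("LSA trial estimates are unbiased across replicates", {
  hrf <- canonical_hrf(1)
  sch <- generate_schedule(5, 150, n_types = 1)
  tc <- soaopt:::trial_columns(sch, hrf, 1)
  d <- build_design(sch, hrf, "lsa", trial_cols = tc)
  qx <- qr(d$X)
  nrep <- 400
  bias <- matrix(0, sch$n_trials, nrep)
  for (i in seq_len(nrep)) {
    ses <- simulate_session(sch, amplitude_spec(3, 1), hrf, 1,
                            amp_seed = 10000 + i, noise_seed = 20000 + i,
                            trial_cols = tc)
    est <- qr.coef(qx, ses$y[, 1])[seq_len(sch$n_trials)]
    bias[, i] <- est - ses$betas[, 1]
  }
  mean_bias <- rowMeans(bias)
  se <- apply(bias, 1, sd) / sqrt(nrep)
  expect_true(all(abs(mean_bias) < 4 * se + 1e-12))
})

test_that("LSS smooths the beta series more than LSA at short SOA", {
  # when scan noise exceeds trial variability, the shared non-target
  # regressor forces temporal smoothness: higher lag-1 autocorrelation
  hrf <- canonical_hrf(1)
  sch <- generate_schedule(2, 2 * 50 + 32, n_types = 1)
  ac1 <- function(x) cor(x[-1], x[-length(x)])
  diffs <- sapply(1:5, function(i) {
    ses <- simulate_session(sch, amplitude_spec(3, 0.1), hrf, 0.3,
                            amp_seed = i, noise_seed = 100 + i)
    ac1(coef(estimate_trials(ses, "lss1"))[, 1]) -
      ac1(coef(estimate_trials(ses, "lsa"))[, 1])
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.5)
})

test_that("ridge LSA estimates move continuously and towards zero in lambda", {
  ses <- quick_session(soa = 3, dur = 150, trial_sd = 1, scan_sd = 1,
                       seed = 9)
  lams <- c(0, 1, 5, 25, 125)
  ests <- sapply(lams, function(l)
    coef(trial_glm(ses$y, ses$schedule, "lsa", lambda = l))[, 1])
  norms <- sqrt(colSums(ests^2))
  expect_true(all(diff(norms) < 0))
  # small lambda step moves estimates by a small amount (path continuity)
  e_a <- coef(trial_glm(ses$y, ses$schedule, "lsa", lambda = 1))[, 1]
  e_b <- coef(trial_glm(ses$y, ses$schedule, "lsa", lambda = 1.01))[, 1]
  expect_lt(max(abs(e_a - e_b)), 0.05)
  expect_error(trial_glm(ses$y, ses$schedule, "lsu", lambda = 1), "LSA")
})

test_that("external timeseries + events files can be fit directly", {
  ses <- quick_session(soa = 6, dur = 180, trial_sd = 0.5, scan_sd = 0.5,
                       seed = 10)
  ev <- withr::local_tempfile(fileext = ".tsv")
  write_events(ses$schedule, ev)
  fit <- trial_glm(ses$y, ev, model = "lsa")
  expect_equal(coef(fit), coef(trial_glm(ses$y, ses$schedule, "lsa")),
               tolerance = 1e-6)
  out <- withr::local_tempfile(fileext = ".csv")
  write_beta_series(fit, out)
  tab <- read.csv(out)
  expect_named(tab, c("trial_index", "onset", "trial_type", "voxel",
                      "estimate"))
  expect_equal(nrow(tab), nrow(coef(fit)))
})

test_that("methods behave: print, summary, coef dimensions, LSS residuals", {
  ses <- quick_session(soa = 8, dur = 200, trial_sd = 1, scan_sd = 0.5,
                       seed = 11)
  f <- estimate_trials(ses, "lsa")
  expect_output(print(f), "LSA")
  sm <- summary(f)
  expect_output(print(sm), "Mean estimate")
  expect_equal(dim(coef(f)), c(length(f$trial_index), 1))
  fls <- estimate_trials(ses, "lss1")
  expect_error(residuals(fls), "one GLM per trial")
})
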