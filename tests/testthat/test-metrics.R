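test_that("PPM and PSM reduce to forced arithmetic on tiny ensembles", {
  # per-replicate means 2 and 4: sd = sqrt(2), PPM = 1/sqrt(2)
  ens <- make_ensemble(2, function(i)
    list(estimates = rep(c(2, 4)[i], 10), truth = rep(3, 10),
         labels = rep(1L, 10)))
  expect_equal(ppm(ens), 1 / sqrt(2))
  # constant per-replicate means: infinite-precision sentinel, not a crash
  ens3 <- make_ensemble(3, function(i)
    list(estimates = rep(3, 10), truth = rep(3, 10), labels = rep(1L, 10)))
  expect_identical(ppm(ens3), Inf)
  # estimates identical to truth: PSM sentinel
  ensT <- make_ensemble(4, function(i) {
    tr <- rnorm(10, 3); list(estimates = tr, truth = tr,
                             labels = rep(1L, 10))
  })
  expect_identical(psm(ensT), Inf)
})

test_that("PSM is invariant to a constant added to truth and estimates", {
  set.seed(1)
  base <- lapply(1:20, function(i)
    list(estimates = rnorm(15, 3), truth = rnorm(15, 3),
         labels = rep(1L, 15)))
  shifted <- lapply(base, function(r)
    list(estimates = r$estimates + 7, truth = r$truth + 7,
         labels = r$labels))
  e1 <- replicate_ensemble(base, "lsa")
  e2 <- replicate_ensemble(shifted, "lsa")
  expect_equal(psm(e1), psm(e2))
})

test_that("PSC is 1 for exact or affinely related estimates", {
  set.seed(2)
  ens <- make_ensemble(5, function(i) {
    tr <- rnorm(20, 3, 1.6)
    list(estimates = tr, truth = tr, labels = rep(1L, 20))
  })
  expect_equal(psc(ens), 1)
  ens2 <- make_ensemble(5, function(i) {
    tr <- rnorm(20, 3, 1.6)
    list(estimates = 2 * tr + 5, truth = tr, labels = rep(1L, 20))
  })
  expect_equal(psc(ens2), 1)
})

test_that("PSC follows the attenuation law under matched estimation noise", {
  # est = truth + independent noise of equal variance -> cor -> 1/sqrt(2)
  set.seed(3)
  ens <- make_ensemble(400, function(i) {
    tr <- rnorm(200, 3, 1)
    list(estimates = tr + rnorm(200, 0, 1), truth = tr,
         labels = rep(1L, 200))
  })
  expect_equal(psc(ens), 1 / sqrt(2), tolerance = 0.02)
})

test_that("PSC refuses LSU fits and zero trial variability", {
  ens_lsu <- replicate_ensemble(lapply(1:3, function(i)
    list(estimates = 3, truth = rep(3, 10), labels = rep(1L, 10))),
    model = "lsu")
  expect_error(psc(ens_lsu), "LSU")
  ens0 <- make_ensemble(3, function(i)
    list(estimates = rnorm(10), truth = rep(3, 10), labels = rep(1L, 10)))
  expect_error(psc(ens0), "undefined")
})

test_that("metrics equal an independent naive reimplementation", {
  set.seed(4)
  for (model in c("lsa", "lsu")) {
    for (contrast in c("single", "difference")) {
      ens <- make_ensemble(30, function(i) {
        lab <- rep(1:2, 10)
        if (model == "lsu")
          list(estimates = rnorm(2, c(3, 5)), truth = rnorm(20, c(3, 5)[lab]),
               labels = lab)
        else
          list(estimates = rnorm(20, c(3, 5)[lab]),
               truth = rnorm(20, c(3, 5)[lab]), labels = lab)
      }, model = model)
      expect_equal(ppm(ens, contrast), naive_ppm(ens, contrast))
      expect_equal(psm(ens, contrast), naive_psm(ens, contrast))
      if (model == "lsa") expect_equal(psc(ens), naive_psc(ens))
    }
  }
})

test_that("noise-free LSU tracks the sample mean exactly at long SOA", {
  # with orthogonal equal-norm trial regressors the condition coefficient
  # equals the sample mean of the true amplitudes: PSM is infinite while
  # PPM stays finite
  hrf <- canonical_hrf(1)
  sch <- generate_schedule(33, 363, n_types = 1)
  reps <- lapply(1:10, function(i) {
    ses <- simulate_session(sch, amplitude_spec(3, 1.6), hrf, 0,
                            amp_seed = i)
    f <- estimate_trials(ses, "lsu")
    list(estimates = unname(coef(f)[, 1]), truth = unname(f$truth[, 1]),
         labels = f$truth_labels)
  })
  ens <- replicate_ensemble(reps, "lsu")
  expect_gt(psm(ens), 1e6)
  expect_lt(ppm(ens), 10)
})

test_that("std-based metrics are scale equivariant", {
  # multiplying all SDs by c divides PPM and PSM by c exactly when the
  # underlying normal deviates are shared (same sub-stream seeds)
  hrf <- canonical_hrf(1)
  sch <- generate_schedule(6, 240, n_types = 1)
  run <- function(scale) {
    reps <- lapply(1:12, function(i) {
      ses <- simulate_session(sch, amplitude_spec(3, scale * 0.5), hrf,
                              scale * 0.8, amp_seed = 300 + i,
                              noise_seed = 600 + i)
      f <- estimate_trials(ses, "lsa")
      list(estimates = unname(coef(f)[, 1]), truth = unname(f$truth[, 1]),
           labels = f$truth_labels)
    })
    replicate_ensemble(reps, "lsa")
  }
  e1 <- run(1); e3 <- run(3)
  expect_equal(ppm(e3), ppm(e1) / 3, tolerance = 1e-8)
  expect_equal(psm(e3), psm(e1) / 3, tolerance = 1e-8)
})

test_that("LSS-N estimates targets at least as precisely as LSS-1", {
  cfg <- sweep_profile("desk", session_duration = 240, soas = 3,
                       trial_sds = 1.6, scan_sds = 0.8, n_types = 2,
                       metrics = "psc", n_replicates = 150, seed = 5)
  v1 <- run_cell(cfg, 3, 1.6, 0.8, model = "lss1")$values["psc"]
  vN <- run_cell(cfg, 3, 1.6, 0.8, model = "lssn")$values["psc"]
  expect_gte(vN, v1)
})

test_that("model_ratio takes elementwise log10 with axis checking", {
  g <- expand.grid(metric = "ppm", model = "lsa", soa = 2:4,
                   trial_sd = c(0, 3), scan_sd = 0.5,
                   stringsAsFactors = FALSE)
  g$value <- c(1, 2, 3, 4, 5, 6)
  g <- efficiency_grid(g)
  g2 <- g; g2$model <- "lsu"
  expect_equal(model_ratio(g, g2)$value, rep(0, 6))
  g10 <- g2; g10$value <- g$value / 10
  expect_equal(model_ratio(g, g10)$value, rep(1, 6))
  bad <- g2[g2$soa != 2, ]
  expect_error(model_ratio(g, bad), "mismatched")
})

test_that("grids serialize as tidy CSV and render as heatmap panels", {
  g <- expand.grid(metric = "ppm", model = "lsu", soa = 2:6,
                   trial_sd = c(0, 1), scan_sd = c(0.5, 3),
                   stringsAsFactors = FALSE)
  set.seed(6)
  g$value <- exp(rnorm(nrow(g)))
  g <- efficiency_grid(g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid(g, path)
  back <- read.csv(path)
  expect_equal(back$value, g$value)
  png_path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_path)
  expect_silent(plot(g))
  grDevices::dev.off()
  expect_true(file.size(png_path) > 0)
})
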