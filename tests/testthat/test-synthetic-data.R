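# Trace and cohort generators: closed forms, determinism, self-consistency.

single_step_params <- function(flux = 40, ...) {
  proto <- tibble::tibble(step = "ONLY", titrant = "none",
                          concentration = "", duration_s = 600)
  attr(proto, "protocol_id") <- "single"
  trace_sim_params(protocol = proto,
                   true_fluxes = stats::setNames(flux, "ONLY"), ...)
}

test_that("noiseless single-step trace declines at exactly flux*rho/1000 uM/s", {
  tr <- simulate_trace(single_step_params(40, noise_sd = 0,
                                          equilibration_tau = 0))
  slopes <- diff(tr$o2) / diff(tr$time)
  expect_equal(slopes, rep(-0.040, length(slopes)), tolerance = 1e-12)

  # background adds to the consumption rate
  tr_bg <- simulate_trace(single_step_params(40, noise_sd = 0,
                                             equilibration_tau = 0,
                                             background_a = 2))
  expect_equal(unique(round(diff(tr_bg$o2) / diff(tr_bg$time), 12)), -0.042)
})

test_that("traces are continuous at titration events (no concentration jumps)", {
  p <- trace_sim_params(true_fluxes = suit02_truth, noise_sd = 0,
                        equilibration_tau = 20)
  tr <- simulate_trace(p)
  # largest one-sample drop bounded by the largest flux's consumption rate
  max_rate <- max(suit02_truth) * p$mass_density / 1000 * p$sample_interval
  expect_lt(max(abs(diff(tr$o2))), max_rate * 1.01)
})

test_that("identical seeds give bit-identical traces, different seeds differ", {
  p <- trace_sim_params(true_fluxes = suit02_truth, noise_sd = 1.5, seed = 42)
  expect_identical(simulate_trace(p)$o2, simulate_trace(p)$o2)
  p2 <- trace_sim_params(true_fluxes = suit02_truth, noise_sd = 1.5, seed = 43)
  expect_false(identical(simulate_trace(p)$o2, simulate_trace(p2)$o2))
})

test_that("oxygen exhaustion before protocol end names the offending step", {
  p <- trace_sim_params(true_fluxes = suit02_truth, o2_start = 14)
  expect_error(simulate_trace(p), "OXPHOS")
})

test_that("every protocol step needs a true flux", {
  expect_error(
    trace_sim_params(true_fluxes = c(LEAK = 8)),
    "no true flux"
  )
})

test_that("Monte-Carlo mean of the extracted plateau is unbiased at noise_sd = 2", {
  proto <- tibble::tibble(step = "ONLY", titrant = "none",
                          concentration = "", duration_s = 900)
  attr(proto, "protocol_id") <- "single"
  cfg <- flux_extraction_config(skip_after_event = 90, window_length = 600,
                                smoothing_halfwidth = 15, cv_max = 3,
                                slope_tolerance = 1, max_wait = 900)
  est <- vapply(1:50, function(s) {
    p <- trace_sim_params(protocol = proto,
                          true_fluxes = c(ONLY = 40), noise_sd = 2,
                          equilibration_tau = 0, seed = s)
    fs <- compute_flux_series(simulate_trace(p), cfg)
    detect_plateau(fs, 0, Inf, cfg)$flux
  }, numeric(1))
  expect_lt(abs(mean(est) - 40) / 40, 0.01)
})

test_that("liver records collapse to the liver-level draw without drift or noise", {
  p <- cohort_sim_params(n_livers = 3, drift_sd = 0, obs_noise_sd = 0,
                         seed = 5)
  rec <- simulate_liver(p, 1)
  wide <- tidyr::pivot_wider(rec$biomarkers, names_from = "parameter",
                             values_from = "value")
  expect_equal(wide$S_P, rep(rec$truth$S_P, nrow(wide)))
  expect_equal(wide$pl_eff, rep(rec$truth$pl_eff, nrow(wide)))
  # derived quantities are internally consistent
  expect_equal(wide$LEAK, (1 - wide$pl_eff) * wide$S_P)
  expect_equal(wide$Pc, wide$S_P / (1 - wide$cytc_eff))
})

test_that("same seed reproduces a liver record exactly", {
  p <- cohort_sim_params(n_livers = 3, seed = 9)
  expect_identical(simulate_liver(p, 2), simulate_liver(p, 2))
  expect_false(identical(simulate_liver(p, 2)$biomarkers$value,
                         simulate_liver(p, 3)$biomarkers$value))
})

test_that("default cohort median succinate OXPHOS at pre lies in the published IQR", {
  b <- simulate_cohort(cohort_sim_params(seed = 101))
  bm <- cohort_biomarkers(b)
  s_pre <- bm$value[bm$parameter == "S_P" & bm$timepoint == "pre"]
  expect_gt(stats::median(s_pre), 33.57)
  expect_lt(stats::median(s_pre), 52.15)
})

test_that("noiseless cohorts are exactly identifiable: refit recovers the coefficients", {
  p <- cohort_sim_params(n_livers = 60, outcome_noise_sd = 0, seed = 21)
  b <- simulate_cohort(p)
  d <- assemble_design(b$cohort, "lgraft",
                       c("auc_pl", "auc_cytc", "auc_leak"),
                       interactions = list(c("auc_cytc", "auc_leak")))
  f <- fit_and_anova(d, "lgraft",
                     c("auc_pl", "auc_cytc", "auc_leak", "auc_cytc:auc_leak"))
  expect_equal(f$coef_table$b,
               unname(p$outcome_coefs[c("auc_pl", "auc_cytc", "auc_leak",
                                        "auc_cytc:auc_leak")]),
               tolerance = 1e-8)
  expect_equal(unname(stats::coef(f$model)[1]),
               unname(p$outcome_coefs["intercept"]), tolerance = 1e-8)
  # generator and bundle agree on the noiseless linear predictor
  expect_equal(b$cohort$lgraft, b$true_outcome_terms$linpred)
})

test_that("cohort refuses fewer livers than outcome-model terms", {
  expect_error(cohort_sim_params(n_livers = 1), "n_livers")
  p <- cohort_sim_params(n_livers = 3)
  expect_error(simulate_cohort(p), "at least as many livers")
})

test_that("cohort CSV round-trip preserves biomarkers and outcomes", {
  b <- simulate_cohort(cohort_sim_params(n_livers = 5, seed = 3))
  prefix <- file.path(withr::local_tempdir(), "cohort")
  write_cohort_csv(b, prefix)
  back <- read_cohort_csv(prefix)
  expect_equal(back$cohort$lgraft, b$cohort$lgraft, tolerance = 1e-12)
  expect_equal(nrow(back$biomarkers), nrow(cohort_biomarkers(b)))
})
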