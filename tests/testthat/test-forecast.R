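# A deterministic patient: no residual noise, no between-occasion
# variability, constant covariates. Under the self-consistent generative
# model every Bayesian forecast must reproduce the future observations.

noise_free_patient <- function(eta_true = c(0.25, -0.1), n_occasions = 3) {
  spec <- cohort_spec(n_patients = 1, n_occasions = n_occasions,
                      residual_cv = 0, iov2_day = 0, cl_drift_day = 0,
                      omega2 = c(cl = 1e-12, v = 1e-12),
                      cl_shift = 1, titrate = FALSE, seed = 99)
  prior <- default_prior()
  ch <- generate_cohort(spec, prior)
  p <- ch$patients[[1]]
  # replace the near-typical individual with a known offset one and
  # regenerate the observations noise-free
  th <- typical_params(prior, p$cov, 0)
  ind <- individual_pk(th[["cl"]] * exp(eta_true[1]),
                       th[["v"]] * exp(eta_true[2]))
  p$obs$conc <- infusion_concentration(ind, p$doses, p$obs$time)
  list(patient = p, prior = prior, ind = ind)
}

test_that("self-consistent generative model is forecast exactly by two-sample Bayes", {
  # a patient whose true random effects are zero: evidence sits exactly on
  # the population prediction, so the MAP optimum is eta = 0 for every
  # variant and the forecast reproduces the future observations
  fx <- noise_free_patient(eta_true = c(0, 0))
  m <- list(id = "conventional", type = "bayes", spec = flatten_spec("conventional"))
  pairs <- run_forecast(fx$patient, fx$prior, m, "peak+trough", target = 2)
  expect_identical(nrow(pairs), 3L)
  expect_equal(pairs$c_forecast, pairs$c_observed, tolerance = 1e-5)
  expect_true(all(pairs$converged))
  expect_true(all(pairs$lead_time_days > 0))
})

test_that("doubling the dose schedule doubles the forecasts (superposition linearity)", {
  fx <- noise_free_patient(eta_true = c(0, 0))
  p2 <- fx$patient
  p2$doses$amount <- 2 * p2$doses$amount
  p2$obs$conc <- 2 * p2$obs$conc  # linear PK: observations scale with dose
  m <- list(id = "conventional", type = "bayes", spec = flatten_spec("conventional"))
  base <- run_forecast(fx$patient, fx$prior, m, "peak+trough", target = 3)
  doubled <- run_forecast(p2, fx$prior, m, "peak+trough", target = 3)
  expect_equal(doubled$c_forecast, 2 * base$c_forecast, tolerance = 1e-6)
})

test_that("first-order and pure-data Bayes coincide on noise-free steady-state data", {
  fx <- noise_free_patient()
  m_fo <- list(id = "first_order", type = "first_order")
  m_w1 <- list(id = "w1", type = "bayes",
               spec = flatten_spec("weighted", weight = 1))
  pairs_fo <- run_forecast(fx$patient, fx$prior, m_fo, target = 2)
  pairs_w1 <- run_forecast(fx$patient, fx$prior, m_w1, "peak+trough", target = 2)
  expect_equal(pairs_fo$c_forecast, pairs_w1$c_forecast, tolerance = 1e-3)
})

test_that("unavailable sample windows yield no pairs rather than an error", {
  fx <- noise_free_patient()
  p <- fx$patient
  occ <- split_occasions(p$obs, p$doses)
  p$obs <- p$obs[!(occ$occasion == 1 & occ$label == "mid"), ]
  m <- list(id = "conventional", type = "bayes", spec = flatten_spec("conventional"))
  pairs <- run_forecast(p, fx$prior, m, "mid", target = 2)
  expect_identical(nrow(pairs), 0L)
  pairs2 <- run_forecast(p, fx$prior, m, "peak+mid", target = 2)
  expect_identical(nrow(pairs2), 0L)
})

test_that("conventional forecasts sit on the shrinkage path between prior and data fits", {
  fx <- noise_free_patient(eta_true = c(0.5, 0.2))
  p <- fx$patient
  prior <- default_prior()  # realistic omega2, so shrinkage is visible
  occ <- split_occasions(p$obs, p$doses)
  used <- occ[occ$occasion == 1 & occ$label %in% c("peak", "trough"),
              c("time", "conc")]
  fit_conv <- map_estimate(used, p$doses, prior, p$cov, flatten_spec("conventional"))
  fit_prior <- map_estimate(used, p$doses, prior, p$cov,
                            flatten_spec("flattened", flat_coef = 1e8))
  fit_data <- map_estimate(used, p$doses, prior, p$cov,
                           flatten_spec("weighted", weight = 1))
  # the conventional optimum is sandwiched in the objective's own terms:
  # its prior penalty cannot exceed the pure-data fit's (else the data fit
  # would be a better conventional candidate) and its misfit cannot exceed
  # the pure-prior fit's
  expect_lte(fit_conv$prior_penalty, fit_data$prior_penalty + 1e-8)
  expect_lte(fit_conv$data_misfit, fit_prior$data_misfit + 1e-8)
  # and in 1-D (volume fixed) the shrinkage path is exactly monotone
  fit_c1 <- map_estimate(used, p$doses, prior, p$cov,
                         flatten_spec("conventional"), fixed_eta = c(v = 0))
  fit_d1 <- map_estimate(used, p$doses, prior, p$cov,
                         flatten_spec("weighted", weight = 1),
                         fixed_eta = c(v = 0))
  expect_gte(fit_c1$eta[["cl"]], min(0, fit_d1$eta[["cl"]]) - 1e-6)
  expect_lte(fit_c1$eta[["cl"]], max(0, fit_d1$eta[["cl"]]) + 1e-6)
})

test_that("the full design matrix is exercised with consistent pair counts per cell", {
  spec <- cohort_spec(n_patients = 4, seed = 31)
  ch <- generate_cohort(spec)
  prior <- default_prior()
  ms <- method_set(flat_coefs = c(0.125), weighted = weight_fixed(0.8))
  tab <- suppressWarnings(suppressMessages(
    forecast_table(ch$patients, prior, ms)))
  cells <- table(tab$method, tab$samples_used)
  bayes_methods <- c("conventional", "flat_0.125", "weighted")
  # all six selections populated for every Bayesian method, equally
  for (m in bayes_methods)
    expect_true(all(cells[m, default_selections()] ==
                    cells["conventional", "peak"]))
  expect_gt(cells["first_order", "two_post_dose"], 0)
  # every generated occasion samples all three windows, so each cell holds
  # (n_occasions - 1) * 3 pairs per patient
  expect_identical(unname(cells["conventional", "trough"]), 4L * 3L * 3L)
})

test_that("creatinine updates in the lead time shift Bayesian forecasts through the typical values", {
  fx <- noise_free_patient()
  p <- fx$patient
  occ <- split_occasions(p$obs, p$doses)
  t_between <- max(p$obs$time[occ$occasion == 1]) + 1
  p_scr <- p
  p_scr$cov <- patient_covariates(
    p$cov$age_mo, p$cov$wt,
    scr = data.frame(time = c(0, t_between),
                     value = c(p$cov$scr$value[1], p$cov$scr$value[1] * 2)))
  m <- list(id = "conventional", type = "bayes", spec = flatten_spec("conventional"))
  base <- run_forecast(p, fx$prior, m, "peak+trough", target = 2)
  upd <- run_forecast(p_scr, fx$prior, m, "peak+trough", target = 2)
  # doubled creatinine lowers typical clearance at the forecast times, so
  # forecast concentrations rise; the evidence fit (pre-step) is unchanged
  expect_true(all(upd$c_forecast > base$c_forecast))
})
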