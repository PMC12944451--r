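test_that("demographics match their median/IQR targets at large n", {
  spec <- cohort_spec(n_patients = 5000, n_occasions = 1, titrate = FALSE,
                      seed = 314)
  ch <- generate_cohort(spec)
  led <- ch$ledger
  wt <- tapply(led$WT_KG, led$ID, `[`, 1)
  expect_lt(abs(median(wt) - 10) / 10, 0.03)
  q <- quantile(wt, c(0.25, 0.75))
  expect_lt(abs(q[[1]] - 7) / 7, 0.05)
  expect_lt(abs(q[[2]] - 15) / 15, 0.05)
  scr <- tapply(led$SCR_MGDL, led$ID, `[`, 1)
  expect_lt(abs(median(scr) - 0.34) / 0.34, 0.05)
  age <- tapply(led$AGE_MO, led$ID, `[`, 1)
  expect_true(all(age >= 3 & age <= 216))
})

test_that("noise-free generation emits exactly the truth-record concentrations", {
  spec <- cohort_spec(n_patients = 3, residual_cv = 0, seed = 12)
  ch <- generate_cohort(spec)
  obs <- ch$ledger[ch$ledger$EVID == 0, ]
  expect_equal(obs$DV, ch$truth$conc$conc_true, tolerance = 1e-12)
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- cohort_spec(n_patients = 4, seed = 2024)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_spec(n_patients = 4, seed = 2025))
  expect_false(identical(a$ledger, c$ledger))
})

test_that("ledgers satisfy the study inclusion rule by construction", {
  spec <- cohort_spec(n_patients = 6, seed = 77)
  ch <- generate_cohort(spec)
  for (p in ch$patients) {
    occ <- split_occasions(p$obs, p$doses)
    # at least two post-dose samples in one occasion plus a later occasion
    expect_gte(max(occ$occasion), 2)
    expect_gte(sum(occ$occasion == 1), 2)
    # first sample at least 24 h after the first dose
    expect_gte(min(p$obs$time), 24)
    # every occasion carries all three window labels
    for (o in unique(occ$occasion))
      expect_setequal(occ$label[occ$occasion == o], c("peak", "mid", "trough"))
  }
})

test_that("titration follows the proportional AUC rule", {
  expect_equal(titrate_dose(1200, 300, c(400, 600), step = 1e-9), 1200 * 4 / 3,
               tolerance = 1e-6)
  expect_identical(titrate_dose(1200, 500, c(400, 600)), 1200)
  expect_equal(titrate_dose(1200, 800, c(400, 600), step = 1e-9), 1200 * 600 / 800,
               tolerance = 1e-6)
  expect_identical(titrate_dose(1200, 300, c(400, 600), bounds = c(0, 1300)), 1300)

  # closed loop on a noise-free patient converges into the window quickly
  spec <- cohort_spec(n_patients = 1, residual_cv = 0, iov2_day = 0,
                      cl_drift_day = 0, n_occasions = 4, seed = 5)
  ch <- generate_cohort(spec)
  true_cl <- ch$truth$params$cl[1]
  d <- ch$patients[[1]]$doses
  occ <- split_occasions(ch$patients[[1]]$obs, d)
  # daily dose in force at the last occasion
  last_start <- d$start[occ$interval[occ$occasion == 4][1]]
  amt <- d$amount[d$start == last_start]
  auc <- steady_state_auc24(individual_pk(true_cl, 1), amt * 4)
  expect_gte(auc, 400 * 0.95)
  expect_lte(auc, 600 * 1.05)
})

test_that("between-occasion clearance perturbations accumulate with elapsed time", {
  # the walk mechanism itself, at generator level: the spread of the
  # log-clearance increment between consecutive occasions grows with the
  # inter-occasion gap
  spec <- cohort_spec(n_patients = 400, n_occasions = 3, titrate = FALSE,
                      seed = 59)
  ch <- generate_cohort(spec)
  pars <- ch$truth$params
  conc <- ch$truth$conc
  inc <- gap <- numeric(0)
  for (id in unique(pars$patient)) {
    e <- pars$eta_iov[pars$patient == id]
    tt <- tapply(conc$time[conc$patient == id], conc$occasion[conc$patient == id], min)
    inc <- c(inc, diff(e))
    gap <- c(gap, diff(as.numeric(tt)) / 24)
  }
  ct <- suppressWarnings(cor.test(gap, abs(inc - median(inc)),
                                  method = "spearman", exact = FALSE))
  expect_gt(ct$estimate, 0.1)
  expect_lt(ct$p.value, 1e-4)
  # and the drift pushes clearance down on average
  expect_lt(mean(inc), 0)
})

test_that("realized forecast error correlates positively with lead time", {
  spec <- cohort_spec(n_patients = 40, seed = 11)
  ch <- generate_cohort(spec)
  prior <- default_prior()
  ms <- method_set(first_order = FALSE, flat_coefs = numeric(0), weighted = NULL)
  tab <- suppressWarnings(suppressMessages(
    forecast_table(ch$patients, prior, ms,
                   selections = c("trough", "peak+trough"))))
  d <- abs(pair_deviation(tab$c_forecast, tab$c_observed))
  ct <- suppressWarnings(
    cor.test(tab$lead_time_days, d, method = "spearman", exact = FALSE))
  expect_gt(ct$estimate, 0)
})
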