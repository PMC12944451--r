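# Fixtures: flat-covariate prior, short regimen, observations generated from
# known individuals. A dense grid search over eta serves as the independent
# oracle for the optimizer.

map_fixture <- function(eta_true = c(0.3, -0.1), n_obs = 2, cv = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prior <- toy_prior()
  cov <- toy_cov()
  d <- regimen(n = 6, tau = 6, amount = 150)
  ind <- individual_pk(2.5 * exp(eta_true[1]), 6.36 * exp(eta_true[2]),
                       eta = c(cl = eta_true[1], v = eta_true[2]))
  t_obs <- d$start[6] + c(2, 5.5)[seq_len(n_obs)]
  conc <- infusion_concentration(ind, d, t_obs)
  if (cv > 0) conc <- conc * exp(rnorm(n_obs, 0, cv))
  list(prior = prior, cov = cov, doses = d,
       obs = data.frame(time = t_obs, conc = conc), ind = ind)
}

test_that("objective vanishes when the prior prediction matches the data exactly", {
  fx <- map_fixture(eta_true = c(0, 0))
  for (sp in list(flatten_spec("conventional"),
                  flatten_spec("flattened", flat_coef = 0.125),
                  flatten_spec("weighted", weight = 0.7))) {
    expect_equal(map_objective(c(0, 0), fx$obs, fx$doses, fx$prior, fx$cov, sp), 0)
  }
})

test_that("objective algebra ties the three variants together", {
  fx <- map_fixture(eta_true = c(0.4, 0.2), n_obs = 2, cv = 0.2, seed = 31)
  set.seed(8)
  for (rep in 1:25) {
    eta <- rnorm(2, 0, 1)
    conv <- map_objective(eta, fx$obs, fx$doses, fx$prior, fx$cov,
                          flatten_spec("conventional"))
    half <- map_objective(eta, fx$obs, fx$doses, fx$prior, fx$cov,
                          flatten_spec("weighted", weight = 0.5))
    expect_equal(half, 0.5 * conv, tolerance = 1e-12)
    f <- runif(1, 0.005, 2)
    flat <- map_objective(eta, fx$obs, fx$doses, fx$prior, fx$cov,
                          flatten_spec("flattened", flat_coef = f))
    wf <- map_objective(eta, fx$obs, fx$doses, fx$prior, fx$cov,
                        flatten_spec("weighted", weight = 1 / (1 + f)))
    expect_equal(flat, (1 + f) * wf, tolerance = 1e-12)
  }
})

test_that("flatten_spec rejects degenerate weights and coefficients", {
  expect_error(flatten_spec("weighted", weight = 0), "weight")
  expect_error(flatten_spec("weighted", weight = 1.2), "weight")
  expect_error(flatten_spec("flattened", flat_coef = 0), "flat_coef")
  expect_silent(flatten_spec("weighted", weight = 1))
})

test_that("objective errors on missing data or degenerate variances", {
  fx <- map_fixture()
  sp <- flatten_spec("conventional")
  expect_error(map_objective(c(0, 0), fx$obs[0, ], fx$doses, fx$prior, fx$cov, sp),
               "at least one")
  pr0 <- toy_prior(sigma = list(prop_cv = 0, add_sd = 0))
  expect_error(map_objective(c(0, 0), fx$obs, fx$doses, pr0, fx$cov, sp),
               "residual SD")
  prw <- toy_prior(omega2 = c(cl = 0, v = 0.04))
  expect_error(map_objective(c(0, 0), fx$obs, fx$doses, prw, fx$cov, sp),
               "omega2")
})

test_that("MAP estimates agree with a dense 1-D grid search (V fixed)", {
  set.seed(21)
  for (rep in 1:6) {
    fx <- map_fixture(eta_true = c(runif(1, -1, 1), 0), n_obs = 1,
                      cv = 0.2, seed = 100 + rep)
    sp <- flatten_spec("conventional")
    grid <- seq(-4, 4, by = 1e-4)
    # vectorized oracle: single observation, flat prior, closed-form profile
    f_grid <- vapply(grid, function(e)
      map_objective(c(e, 0), fx$obs, fx$doses, fx$prior, fx$cov, sp),
      numeric(1))
    e_grid <- grid[which.min(f_grid)]
    fit <- map_estimate(fx$obs, fx$doses, fx$prior, fx$cov, sp,
                        fixed_eta = c(v = 0))
    expect_true(fit$converged)
    expect_lt(abs(fit$eta[["cl"]] - e_grid), 2e-4)
  }
})

test_that("prior-dominated and data-dominated limits behave as expected", {
  # enormous flattening coefficient: prior dominates, eta -> 0
  fx <- map_fixture(eta_true = c(0.5, 0.2), n_obs = 1)
  fit <- map_estimate(fx$obs, fx$doses, fx$prior, fx$cov,
                      flatten_spec("flattened", flat_coef = 1e6))
  expect_lt(sqrt(sum(fit$eta^2)), 1e-2)

  # pure data weight with two exact observations: recovers the generator
  fx2 <- map_fixture(eta_true = c(0.35, -0.15), n_obs = 2, cv = 0)
  fit2 <- map_estimate(fx2$obs, fx2$doses, fx2$prior, fx2$cov,
                       flatten_spec("weighted", weight = 1))
  expect_equal(fit2$ind$cl, fx2$ind$cl, tolerance = 1e-5)
  expect_equal(fit2$ind$v, fx2$ind$v, tolerance = 1e-5)
})

test_that("fit components reassemble into the reported objective value", {
  fx <- map_fixture(eta_true = c(0.3, 0.1), n_obs = 2, cv = 0.15, seed = 9)
  for (sp in list(flatten_spec("conventional"),
                  flatten_spec("flattened", flat_coef = 0.125),
                  flatten_spec("weighted", weight = 0.8))) {
    fit <- map_estimate(fx$obs, fx$doses, fx$prior, fx$cov, sp)
    expect_equal(fit$objective_value,
                 sp$w_data * fit$data_misfit + sp$w_prior * fit$prior_penalty,
                 tolerance = 1e-10)
    expect_identical(fit$n_obs_used, 2L)
    expect_identical(fit$ind$ke, fit$ind$cl / fit$ind$v)
  }
})

test_that("flattening equivalence: Eq-4 and Eq-6 objectives share their minimizer", {
  fx <- map_fixture(eta_true = c(0.6, -0.3), n_obs = 2, cv = 0.2, seed = 55)
  for (f in c(0.005, 0.125, 0.6)) {
    fit_flat <- map_estimate(fx$obs, fx$doses, fx$prior, fx$cov,
                             flatten_spec("flattened", flat_coef = f))
    fit_w <- map_estimate(fx$obs, fx$doses, fx$prior, fx$cov,
                          flatten_spec("weighted", weight = 1 / (1 + f)))
    expect_equal(unname(fit_flat$eta), unname(fit_w$eta), tolerance = 1e-4)
  }
})

test_that("shrinkage is monotone across the flattening grid on fixed data", {
  fx <- map_fixture(eta_true = c(0.7, 0.2), n_obs = 2, cv = 0.25, seed = 77)
  grid <- c(0.6, 0.3, 0.2, 0.125, 0.02, 0.005)
  fits <- lapply(grid, function(f)
    map_estimate(fx$obs, fx$doses, fx$prior, fx$cov,
                 flatten_spec("flattened", flat_coef = f)))
  dm <- vapply(fits, `[[`, numeric(1), "data_misfit")
  pp <- vapply(fits, `[[`, numeric(1), "prior_penalty")
  # decreasing flat_coef frees the fit: misfit falls, penalty rises
  expect_true(all(diff(dm) <= 1e-8 * (1 + abs(dm[-length(dm)]))))
  expect_true(all(diff(pp) >= -1e-8 * (1 + abs(pp[-length(pp)]))))
})

test_that("theta-space penalty switch reproduces the literal additive form", {
  fx <- map_fixture(eta_true = c(0.2, 0.1))
  pr_th <- toy_prior(penalty_space = "theta")
  eta <- c(0.3, -0.2)
  parts <- map_objective_parts(eta, fx$obs, fx$doses, pr_th, fx$cov,
                               flatten_spec("conventional"))
  th <- c(2.5, 6.36)
  expected <- sum((th - th * exp(eta))^2 / (th^2 * c(0.09, 0.04)))
  expect_equal(parts$prior_penalty, expected, tolerance = 1e-12)
})

test_that("weight selection strategies pick data weights sensibly", {
  # fixed strategy returns its constant and reproduces the conventional argmin
  fx <- map_fixture(eta_true = c(0.4, 0.1), n_obs = 2, cv = 0.2, seed = 13)
  expect_identical(select_weight(weight_fixed(0.5), list(), fx$doses,
                                 fx$prior, fx$cov), 0.5)
  fit_c <- map_estimate(fx$obs, fx$doses, fx$prior, fx$cov,
                        flatten_spec("conventional"))
  fit_w <- map_estimate(fx$obs, fx$doses, fx$prior, fx$cov,
                        flatten_spec("weighted", weight = 0.5))
  expect_equal(unname(fit_c$eta), unname(fit_w$eta), tolerance = 1e-5)

  # retrospective strategy: build two prior occasions from a known individual
  retro_case <- function(eta_true) {
    prior <- toy_prior(); cov <- toy_cov()
    d <- regimen(n = 12, tau = 6, amount = 150)
    ind <- individual_pk(2.5 * exp(eta_true[1]), 6.36 * exp(eta_true[2]))
    occ1_t <- d$start[6] + c(2, 5.5); occ2_t <- d$start[9] + c(2, 5.5)
    history <- list(
      data.frame(time = occ1_t, conc = infusion_concentration(ind, d, occ1_t)),
      data.frame(time = occ2_t, conc = infusion_concentration(ind, d, occ2_t)))
    select_weight(weight_retrospective(), history, d, prior, cov)
  }
  # individual 3 SD from the prior: data-weighted candidates forecast better
  expect_gt(retro_case(c(3 * 0.3, 0)), 0.5)
  # individual matching the prior exactly: no benefit in leaving w = 0.5
  expect_lte(retro_case(c(0, 0)), 0.5)

  # fallback path with insufficient history
  expect_message(
    w <- select_weight(weight_retrospective(), list(), fx$doses, fx$prior, fx$cov),
    "fallback")
  expect_identical(w, 0.5)
})
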