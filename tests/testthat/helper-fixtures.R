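# Shared fixtures: small priors, regimens and independent oracles.

# flat-covariate prior: CL_pop = 2.5 L/h, V_pop = 6.36 L regardless of
# covariates; proportional 20% residual error
toy_prior <- function(omega2 = c(cl = 0.09, v = 0.04),
                      sigma = list(prop_cv = 0.2, add_sd = 0),
                      penalty_space = "eta") {
  pop_prior(cl_expr = "2.5", v_expr = "6.36",
            omega2 = omega2, sigma = sigma,
            penalty_space = penalty_space, name = "toy_flat")
}

toy_cov <- function(age_mo = 24, wt = 10, scr = 0.34) {
  patient_covariates(age_mo = age_mo, wt = wt, scr = scr)
}

# regular q-tau regimen of n doses
regimen <- function(n = 8, tau = 6, amount = 150, duration = 1) {
  dosing_events(start = seq(0, by = tau, length.out = n),
                amount = amount, duration = duration, interval_hint = tau)
}

# Independent ODE oracle: integrates dC/dt = inrate(t)/V - ke*C with deSolve
# on the same dose schedule; bears no code in common with the closed form.
ode_concentration <- function(ind, doses, times) {
  ke <- ind$cl / ind$v
  inrate <- function(t) {
    on <- t > doses$start & t <= doses$start + doses$duration
    sum(doses$amount[on] / doses$duration[on])
  }
  rhs <- function(t, y, p) list(inrate(t) / ind$v - ke * y)
  # force tiny steps across every infusion edge so events are not missed
  edges <- sort(unique(c(0, doses$start, doses$start + doses$duration, times)))
  grid <- sort(unique(c(edges, seq(0, max(times), length.out = 200))))
  grid <- grid[grid <= max(times)]
  out <- deSolve::lsoda(c(C = 0), grid, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  stats::approx(out[, "time"], out[, "C"], xout = times)$y
}

# number of doses after which a regimen is numerically at steady state
# (residual accumulation below ~exp(-40))
n_doses_to_ss <- function(ke, tau) ceiling(40 / (ke * tau)) + 2L

# noise-free steady-state peak/trough style pair generated from the
# superposition profile of a known individual
ss_pair <- function(ind, tau = 6, amount = 150, duration = 1,
                    offsets = c(2, tau - 0.5)) {
  n <- n_doses_to_ss(ind$cl / ind$v, tau)
  d <- regimen(n = n, tau = tau, amount = amount, duration = duration)
  s <- d$start[n]
  t_obs <- s + offsets
  list(doses = d, times = t_obs,
       conc = infusion_concentration(ind, d, t_obs),
       last_dose = d[n, ], tau = tau)
}
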