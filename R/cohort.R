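#' Virtual pediatric ICU cohort specification
#'
#' Describes the generative conditions for a simulated vancomycin TDM cohort:
#' demographics drawn from log-normals matched to published median/IQR
#' summaries of critically ill children (age median 2.0 years, weight median
#' 10 kg, creatinine median 0.34 mg/dL), an empirical 60 mg/kg/day q6h
#' protocol with 1-hour infusions, per-occasion peak/mid/trough sampling,
#' between-subject, between-occasion and residual variability, and
#' AUC-targeted (400-600 mg·h/L) dose titration.
#'
#' Two knobs shape the difficulty of the forecasting problem:
#' `cl_shift` multiplies the cohort's true median clearance relative to the
#' prior's typical value (default 0.8: ICU patients clear 20% below the
#' general-pediatric prior, so the prior is deliberately imperfect), and
#' `iov2_day` is the per-day variance of a Gaussian random walk on
#' log-clearance across occasions, which makes forecast error grow with lead
#' time. A third, `cl_drift_day`, adds a mean log-clearance drift per day to
#' that walk (default -0.02: renal function slowly worsens under critical
#' illness and nephrotoxic co-medication, so concentrations drift upward and
#' forecasts from past occasions under-predict — the accumulation mechanism
#' behind lead-time degradation).
#'
#' @param n_patients cohort size.
#' @param age_median_mo,age_iqr_mo age distribution, months.
#' @param age_bounds_mo truncation of the age draw to the study's inclusion
#'   range (3 months to 18 years).
#' @param wt_median,wt_iqr weight distribution, kg.
#' @param scr_median,scr_iqr serum creatinine distribution, mg/dL.
#' @param mg_per_kg_day empirical starting daily dose.
#' @param interval dosing interval tau, hours.
#' @param infusion_duration hours.
#' @param n_occasions TDM occasions per patient (all three windows sampled at
#'   each, so every sample-selection cell of the design is populated).
#' @param first_occasion_hr range (hours) in which the first TDM occasion
#'   starts; lower bound must be >= 24 (sampling begins at least 24 h after
#'   the first dose).
#' @param gap_days range of the inter-occasion gap, days.
#' @param peak_offset,mid_offset sampling-time ranges, hours post-dose.
#' @param trough_before_next sampling-time range, hours before the next dose.
#' @param omega2,residual_cv,iov2_day variability overrides; `NULL` takes
#'   them from the prior used at generation time.
#' @param cl_shift multiplicative shift of true median clearance vs the prior
#'   typical value.
#' @param cl_drift_day mean drift of log-clearance per day (negative =
#'   declining renal function).
#' @param auc_window AUC24 titration target, mg·h/L.
#' @param dose_round_mg rounding grain for titrated per-dose amounts.
#' @param mg_per_kg_bounds clamp on the titrated daily dose.
#' @param titrate apply the titration rule after each occasion.
#' @param seed integer seed; the generator is fully reproducible under it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 110,
                        age_median_mo = 24, age_iqr_mo = c(7.2, 56.4),
                        age_bounds_mo = c(3, 216),
                        wt_median = 10, wt_iqr = c(7, 15),
                        scr_median = 0.34, scr_iqr = c(0.22, 0.49),
                        mg_per_kg_day = 60, interval = 6,
                        infusion_duration = 1,
                        n_occasions = 4,
                        first_occasion_hr = c(24, 36),
                        gap_days = c(1, 4),
                        peak_offset = c(2.0, 2.2),
                        mid_offset = c(3.5, 4.9),
                        trough_before_next = c(0.5, 0.6),
                        omega2 = NULL, residual_cv = NULL, iov2_day = NULL,
                        cl_shift = 0.8, cl_drift_day = -0.02,
                        auc_window = c(400, 600),
                        dose_round_mg = 1,
                        mg_per_kg_bounds = c(20, 100),
                        titrate = TRUE,
                        seed = NULL) {
  stopifnot(n_patients >= 1, n_occasions >= 1,
            age_median_mo > 0, wt_median > 0, scr_median > 0,
            all(age_iqr_mo > 0), all(wt_iqr > 0), all(scr_iqr > 0),
            mg_per_kg_day > 0, interval > 0, infusion_duration > 0,
            first_occasion_hr[1] >= 24, gap_days[1] > 0,
            auc_window[1] < auc_window[2])
  # the sampling plan must land inside the window it claims to sample
  pk_off <- peak_offset - infusion_duration
  if (pk_off[1] < 1 || pk_off[2] > 2)
    stop("infeasible sampling plan: peak offsets fall outside 1-2 h after infusion end")
  if (!(mid_offset[1] >= infusion_duration + 2 || mid_offset[2] < infusion_duration + 1))
    stop("infeasible sampling plan: mid offsets overlap the peak window")
  if (mid_offset[2] >= interval - 1)
    stop("infeasible sampling plan: mid offsets reach into the trough window")
  if (trough_before_next[1] < 0.5 || trough_before_next[2] >= 1)
    stop("infeasible sampling plan: trough offsets fall outside 0.5-1 h before the next dose")
  if (interval - trough_before_next[1] <= mid_offset[2])
    stop("infeasible sampling plan: trough precedes mid")
  structure(as.list(environment()), class = "cohort_spec")
}

# log-normal matched to a median/IQR summary: log-median is the log mean,
# log-SD from the IQR width divided by 2 * qnorm(0.75) ~= 1.349
lnorm_from_quartiles <- function(median, iqr) {
  sdlog <- (log(iqr[2]) - log(iqr[1])) / (2 * stats::qnorm(0.75))
  c(meanlog = log(median), sdlog = sdlog)
}

#' AUC-targeted proportional dose titration
#'
#' If the estimated steady-state AUC24 sits below the target window, the
#' daily dose is scaled up by `lo/AUC`; above it, down by `hi/AUC`; inside
#' it, unchanged. The result is clamped to `bounds` and rounded to
#' `step` mg.
#'
#' @param daily_dose current total daily dose, mg.
#' @param auc24 estimated steady-state AUC24, mg·h/L.
#' @param window target window `c(lo, hi)`.
#' @param step rounding grain, mg.
#' @param bounds clamp `c(min, max)` on the daily dose, mg.
#' @return new total daily dose, mg.
#' @export
titrate_dose <- function(daily_dose, auc24, window = c(400, 600),
                         step = 1, bounds = c(-Inf, Inf)) {
  stopifnot(daily_dose > 0, auc24 > 0, window[1] < window[2])
  ratio <- if (auc24 < window[1]) window[1] / auc24
           else if (auc24 > window[2]) window[2] / auc24
           else 1
  new_daily <- min(max(daily_dose * ratio, bounds[1]), bounds[2])
  round(new_daily / step) * step
}

#' Generate a virtual TDM cohort
#'
#' Draws a cohort under a [cohort_spec()]: demographics, true individual
#' parameters (log-normal around the — possibly shifted — prior typical
#' values), a q6h dose schedule titrated after each occasion from a
#' Sawchuk-Zaske fit of that occasion's peak and trough, a random walk on
#' log-clearance across occasions, and residual-noise observations at
#' jittered peak/mid/trough times. Every emitted ledger satisfies the study
#' inclusion rule (two post-dose concentrations per occasion plus later
#' occasions) by construction, and the generator is byte-reproducible under
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param prior the [pop_prior()] whose typical-value model anchors the
#'   simulation (also supplies variances not overridden in `spec`).
#' @return list with `ledger` (the NONMEM-style `data.frame`, see
#'   [read_ledger()]), `truth` (list of `params` — per patient and occasion
#'   true clearance, volume and random effects — and `conc` — noise-free
#'   concentrations at every sample time), and `patients` (per-patient
#'   histories ready for [forecast_table()]).
#' @export
generate_cohort <- function(spec = cohort_spec(), prior = default_prior()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(prior, "pop_prior"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  om <- if (is.null(spec$omega2)) prior$omega2 else unlist(spec$omega2)[c("cl", "v")]
  res_cv <- if (is.null(spec$residual_cv)) prior$sigma$prop_cv else spec$residual_cv
  iov2 <- if (is.null(spec$iov2_day)) prior$iov2 else spec$iov2_day
  age_d <- lnorm_from_quartiles(spec$age_median_mo, spec$age_iqr_mo)
  wt_d <- lnorm_from_quartiles(spec$wt_median, spec$wt_iqr)
  scr_d <- lnorm_from_quartiles(spec$scr_median, spec$scr_iqr)
  tau <- spec$interval
  doses_per_day <- 24 / tau

  ledger_rows <- vector("list", spec$n_patients)
  param_rows <- vector("list", spec$n_patients)
  truth_rows <- vector("list", spec$n_patients)

  for (i in seq_len(spec$n_patients)) {
    id <- sprintf("P%03d", i)
    # rejection-truncate draws to the inclusion range and the prior's
    # covariate support (the tails of the matched log-normals are wide)
    draw_in <- function(d, lo, hi) {
      repeat {
        x <- stats::rlnorm(1, d[["meanlog"]], d[["sdlog"]])
        if (x >= lo && x <= hi) return(x)
      }
    }
    sup <- prior$support
    age <- draw_in(age_d, spec$age_bounds_mo[1], spec$age_bounds_mo[2])
    wt <- draw_in(wt_d, sup$wt[1], sup$wt[2])
    scr <- draw_in(scr_d, sup$scr[1], sup$scr[2])
    cov <- patient_covariates(age_mo = age, wt = wt, scr = scr)
    th <- typical_params(prior, cov, 0)
    eta_cl <- log(spec$cl_shift) + stats::rnorm(1, 0, sqrt(om[["cl"]]))
    eta_v <- stats::rnorm(1, 0, sqrt(om[["v"]]))
    cl_base <- th[["cl"]] * exp(eta_cl)
    v_true <- th[["v"]] * exp(eta_v)

    # occasion interval starts, snapped to the dosing grid
    occ_starts <- numeric(spec$n_occasions)
    occ_starts[1] <- tau * ceiling(stats::runif(1, spec$first_occasion_hr[1],
                                                spec$first_occasion_hr[2]) / tau)
    if (spec$n_occasions > 1) {
      for (o in 2:spec$n_occasions) {
        gap <- stats::runif(1, spec$gap_days[1], spec$gap_days[2]) * 24
        occ_starts[o] <- occ_starts[o - 1] + tau * max(1, round(gap / tau))
      }
    }

    # between-occasion random walk on log-clearance
    eta_iov <- numeric(spec$n_occasions)
    prev_t <- 0
    for (o in seq_len(spec$n_occasions)) {
      dt_days <- (occ_starts[o] - prev_t) / 24
      step_sd <- sqrt(iov2 * dt_days)
      # increment mean = configured drift, minus the half-variance correction
      # so E[CL ratio] = exp(cl_drift_day * dt) exactly
      eta_iov[o] <- (if (o == 1) 0 else eta_iov[o - 1]) +
        stats::rnorm(1, spec$cl_drift_day * dt_days - step_sd^2 / 2, step_sd)
      prev_t <- occ_starts[o]
    }

    amt <- round(wt * spec$mg_per_kg_day / doses_per_day)
    dose_times <- seq(0, occ_starts[spec$n_occasions] + tau, by = tau)
    dose_amt <- rep(NA_real_, length(dose_times))
    assigned <- 0L
    obs_t <- obs_dv <- obs_true <- numeric(0)
    obs_occ <- integer(0)

    for (o in seq_len(spec$n_occasions)) {
      upto <- which(dose_times <= occ_starts[o])
      if (length(upto) > assigned) {
        dose_amt[(assigned + 1L):max(upto)] <- amt
        assigned <- max(upto)
      }
      doses_now <- dosing_events(dose_times[seq_len(assigned)],
                                 dose_amt[seq_len(assigned)],
                                 spec$infusion_duration, interval_hint = tau)
      cl_o <- cl_base * exp(eta_iov[o])
      ind_o <- individual_pk(cl = cl_o, v = v_true)
      s <- occ_starts[o]
      times <- c(peak = s + stats::runif(1, spec$peak_offset[1], spec$peak_offset[2]),
                 mid = s + stats::runif(1, spec$mid_offset[1], spec$mid_offset[2]),
                 trough = s + tau - stats::runif(1, spec$trough_before_next[1],
                                                 spec$trough_before_next[2]))
      ctrue <- infusion_concentration(ind_o, doses_now, times)
      dv <- if (res_cv > 0) ctrue * exp(stats::rnorm(3, 0, res_cv)) else ctrue
      obs_t <- c(obs_t, times); obs_dv <- c(obs_dv, dv)
      obs_true <- c(obs_true, ctrue); obs_occ <- c(obs_occ, rep(o, 3))

      if (spec$titrate) {
        iv <- assigned  # dose row covering this occasion
        fit <- tryCatch(suppressWarnings(
          fit_two_point(dv[1], times[["peak"]], dv[3], times[["trough"]],
                        dose = doses_now[iv, ], tau = tau)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          daily <- amt * doses_per_day
          auc <- steady_state_auc24(individual_pk(fit$cl, fit$vd), daily)
          new_daily <- titrate_dose(daily, auc, spec$auc_window,
                                    step = spec$dose_round_mg * doses_per_day,
                                    bounds = wt * spec$mg_per_kg_bounds)
          amt <- round(new_daily / doses_per_day / spec$dose_round_mg) *
            spec$dose_round_mg
        }
      }
    }
    if (assigned < length(dose_times))
      dose_amt[(assigned + 1L):length(dose_times)] <- amt

    led <- rbind(
      data.frame(ID = id, TIME = dose_times, AMT = dose_amt,
                 DUR = spec$infusion_duration, DV = NA_real_, EVID = 1L),
      data.frame(ID = id, TIME = obs_t, AMT = NA_real_, DUR = NA_real_,
                 DV = obs_dv, EVID = 0L))
    led <- led[order(led$TIME, -led$EVID), , drop = FALSE]
    led$AGE_MO <- age; led$WT_KG <- wt; led$SCR_MGDL <- scr
    ledger_rows[[i]] <- led

    param_rows[[i]] <- data.frame(
      patient = id, occasion = seq_len(spec$n_occasions),
      cl = cl_base * exp(eta_iov), v = v_true,
      eta_cl = eta_cl, eta_v = eta_v, eta_iov = eta_iov)
    truth_rows[[i]] <- data.frame(
      patient = id, occasion = obs_occ, time = obs_t,
      label = rep(c("peak", "mid", "trough"), spec$n_occasions),
      conc_true = obs_true)
  }

  ledger <- do.call(rbind, ledger_rows)
  rownames(ledger) <- NULL
  list(ledger = ledger,
       truth = list(params = do.call(rbind, param_rows),
                    conc = do.call(rbind, truth_rows)),
       patients = split_patients(ledger, interval_hint = tau))
}
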