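#' Build the method matrix for a forecasting run
#'
#' Describes which estimation methods to run: the first-order two-point
#' method, conventional MAP, flattened MAP over a coefficient grid, and the
#' weighted-flattened MAP with a data-weight selection strategy. The default
#' flattening grid is `{0.005, 0.02, 0.125, 0.2, 0.3, 0.6}`.
#'
#' @param first_order include the Sawchuk-Zaske two-point method.
#' @param conventional include conventional MAP.
#' @param flat_coefs numeric vector of flattening coefficients (possibly
#'   empty).
#' @param weighted a [weight_fixed()]/[weight_retrospective()] strategy, or
#'   `NULL` to omit the weighted variant.
#' @return named list of method descriptors, consumed by [forecast_table()].
#' @export
method_set <- function(first_order = TRUE, conventional = TRUE,
                       flat_coefs = c(0.005, 0.02, 0.125, 0.2, 0.3, 0.6),
                       weighted = weight_retrospective()) {
  m <- list()
  if (first_order)
    m$first_order <- list(id = "first_order", type = "first_order")
  if (conventional)
    m$conventional <- list(id = "conventional", type = "bayes",
                           spec = flatten_spec("conventional"))
  for (fc in flat_coefs) {
    id <- paste0("flat_", format(fc, scientific = FALSE))
    m[[id]] <- list(id = id, type = "bayes",
                    spec = flatten_spec("flattened", flat_coef = fc))
  }
  if (!is.null(weighted))
    m$weighted <- list(id = "weighted", type = "bayes", strategy = weighted)
  m
}

#' Sample selections examined per Bayesian forecast
#' @return character vector of the six one- and two-sample selections.
#' @export
default_selections <- function() {
  c("peak", "mid", "trough", "peak+mid", "peak+trough", "mid+trough")
}

# pick the evidence observations of an occasion for a selection such as
# "peak" or "peak+trough"; NULL when a required window label is unavailable
select_obs <- function(occ_obs, selection) {
  labels <- strsplit(selection, "+", fixed = TRUE)[[1]]
  rows <- lapply(labels, function(lb) {
    hit <- which(occ_obs$label == lb)
    if (length(hit) == 0) return(NULL)
    occ_obs[hit[1], , drop = FALSE]
  })
  if (any(vapply(rows, is.null, logical(1)))) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}

# dosing interval length covering dose row idx
interval_of <- function(doses, idx) {
  if (idx < nrow(doses)) doses$start[idx + 1] - doses$start[idx]
  else if (is.finite(doses$interval_hint[idx])) doses$interval_hint[idx]
  else stop("cannot determine the dosing interval of the final dose")
}

#' Forecast one TDM occasion from the preceding one
#'
#' The unit step of the study design: fit on selected observations of the
#' preceding occasion, then forecast every observation of the target occasion
#' over the actual dose schedule (dose changes in the lead time are honoured;
#' for Bayesian fits, typical values are re-evaluated with the creatinine in
#' force at each forecast time while the random effects are held fixed).
#'
#' @param patient a per-patient history as produced by [split_patients()] or
#'   [generate_cohort()]: list with `id`, `doses`, `obs`, `cov`.
#' @param prior a [pop_prior()].
#' @param method one descriptor from [method_set()].
#' @param selection a selection string (`"peak"`, `"peak+trough"`, ...);
#'   ignored for the first-order method, which always uses the occasion's two
#'   post-dose levels (first and last, in time order).
#' @param target index of the target occasion (fit uses occasion
#'   `target - 1`).
#' @param occ_obs optional pre-computed [split_occasions()] result for the
#'   patient (computed if missing).
#' @param weight_override for methods carrying a weight-selection strategy:
#'   use this weight instead of running the selector. The weight is a
#'   per-patient, per-occasion decision, so [forecast_table()] selects it
#'   once per target occasion and passes it down to every selection cell.
#' @return a `data.frame` of forecast pairs (possibly zero rows when the
#'   requested samples are unavailable or the fit is infeasible), columns:
#'   patient, method, variant, flat_coef, weight, samples_used,
#'   occasion_prec, occasion_target, target_time, target_label,
#'   lead_time_days, c_forecast, c_observed, converged, age_mo, wt_kg, scr.
#' @export
run_forecast <- function(patient, prior, method, selection = "peak+trough",
                         target, occ_obs = NULL, weight_override = NULL) {
  if (is.null(occ_obs)) occ_obs <- split_occasions(patient$obs, patient$doses)
  prec <- target - 1
  if (prec < 1) stop("target occasion must have a preceding occasion")
  prec_obs <- occ_obs[occ_obs$occasion == prec, , drop = FALSE]
  targ_obs <- occ_obs[occ_obs$occasion == target, , drop = FALSE]
  if (nrow(prec_obs) == 0 || nrow(targ_obs) == 0)
    stop("occasion index out of range for this patient")
  doses <- patient$doses; cov <- patient$cov
  empty <- data.frame()

  variant <- NA_character_; flat_coef <- NA_real_; weight <- NA_real_
  converged <- TRUE; used <- NULL; fc_fun <- NULL

  if (method$type == "first_order") {
    selection <- "two_post_dose"
    if (nrow(prec_obs) < 2) return(empty)
    used <- prec_obs[c(1, nrow(prec_obs)), , drop = FALSE]
    iv <- used$interval[1]
    fit <- tryCatch(
      fit_two_point(used$conc[1], used$time[1], used$conc[2], used$time[2],
                    dose = doses[iv, ], tau = interval_of(doses, iv)),
      error = function(e) {
        message("first-order fit skipped for patient ", patient$id,
                " occasion ", prec, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) return(empty)
    variant <- "first_order"
    fc_fun <- function(times) forecast_first_order(fit, doses, times)
  } else {
    used <- select_obs(prec_obs, selection)
    if (is.null(used)) return(empty)
    if (!is.null(method$strategy)) {
      if (is.null(weight_override)) {
        history <- lapply(seq_len(prec), function(o)
          occ_obs[occ_obs$occasion == o, c("time", "conc"), drop = FALSE])
        weight <- select_weight(method$strategy, history, doses, prior, cov)
      } else {
        weight <- weight_override
      }
      spec <- flatten_spec("weighted", weight = weight)
    } else {
      spec <- method$spec
    }
    variant <- spec$variant
    flat_coef <- spec$flat_coef
    if (spec$variant == "weighted") weight <- spec$weight
    fit <- map_estimate(used[, c("time", "conc")], doses, prior, cov, spec)
    converged <- fit$converged
    fc_fun <- function(times) forecast_bayes(fit, doses, prior, cov, times)
  }

  lead_days <- (min(targ_obs$time) - max(used$time)) / 24
  data.frame(
    patient = patient$id, method = method$id, variant = variant,
    flat_coef = flat_coef, weight = weight, samples_used = selection,
    occasion_prec = prec, occasion_target = target,
    target_time = targ_obs$time, target_label = targ_obs$label,
    lead_time_days = lead_days,
    c_forecast = fc_fun(targ_obs$time), c_observed = targ_obs$conc,
    converged = converged,
    age_mo = cov$age_mo, wt_kg = cov$wt,
    scr = scr_at(cov, min(targ_obs$time)),
    row.names = NULL)
}

#' Run the full forecasting design over a cohort
#'
#' For every patient, every pair of consecutive TDM occasions, and every
#' method-by-selection cell, fits on the preceding occasion and forecasts the
#' target occasion. Cells whose required sample windows are unavailable yield
#' no rows, mirroring observational availability.
#'
#' @param patients a named list of patient histories ([split_patients()] /
#'   [generate_cohort()]`$patients`).
#' @param prior a [pop_prior()].
#' @param methods a [method_set()].
#' @param selections selections to run for Bayesian methods.
#' @param progress print a dot per patient.
#' @return the tidy forecast-pair table (one row per [run_forecast()] pair).
#' @export
forecast_table <- function(patients, prior, methods = method_set(),
                           selections = default_selections(),
                           progress = FALSE) {
  out <- vector("list", length(patients))
  for (pi in seq_along(patients)) {
    patient <- patients[[pi]]
    occ_obs <- split_occasions(patient$obs, patient$doses)
    n_occ <- if (nrow(occ_obs)) max(occ_obs$occasion) else 0
    if (n_occ < 2) next
    rows <- list()
    for (target in 2:n_occ) {
      for (method in methods) {
        sels <- if (method$type == "first_order") "two_post_dose" else selections
        w_occ <- NULL
        if (!is.null(method$strategy)) {
          history <- lapply(seq_len(target - 1), function(o)
            occ_obs[occ_obs$occasion == o, c("time", "conc"), drop = FALSE])
          w_occ <- select_weight(method$strategy, history, patient$doses,
                                 prior, patient$cov)
        }
        for (sel in sels) {
          rows[[length(rows) + 1]] <-
            run_forecast(patient, prior, method, sel, target,
                         occ_obs = occ_obs, weight_override = w_occ)
        }
      }
    }
    out[[pi]] <- do.call(rbind, rows)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame() else res
}
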