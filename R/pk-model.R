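#' Dosing schedule constructor
#'
#' A dosing schedule is a plain `data.frame` with one row per intermittent
#' intravenous infusion: `start` (hours since first dose), `amount` (mg),
#' `duration` (infusion duration, hours) and `interval_hint` (planned dosing
#' interval tau, hours; used to delimit the final interval when no later dose
#' exists).
#'
#' @param start,amount,duration,interval_hint numeric vectors (recycled).
#' @return a validated, time-sorted `data.frame`.
#' @export
dosing_events <- function(start, amount, duration = 1, interval_hint = NA_real_) {
  if (length(start) == 0)
    return(data.frame(start = numeric(0), amount = numeric(0),
                      duration = numeric(0), interval_hint = numeric(0)))
  d <- data.frame(start = as.numeric(start), amount = as.numeric(amount),
                  duration = as.numeric(duration),
                  interval_hint = as.numeric(interval_hint))
  if (nrow(d) == 0) return(d)
  if (any(!is.finite(d$start)) || any(d$start < 0))
    stop("dose start times must be finite and >= 0")
  if (any(d$amount <= 0)) stop("dose amounts must be positive")
  if (any(d$duration <= 0)) stop("infusion durations must be positive")
  d[order(d$start), , drop = FALSE]
}

#' Individual PK parameter set
#'
#' One-compartment parameters for a single patient (possibly a single
#' occasion): clearance `cl` (L/h), volume `v` (L), and the log-scale random
#' effects `eta` that generated them from the population typical values. The
#' elimination rate constant `ke = cl / v` is derived, never stored
#' independently.
#'
#' @param cl clearance, L/h.
#' @param v volume of distribution, L.
#' @param eta optional named numeric `c(cl =, v =)` random effects.
#' @return object of class `individual_pk` with elements `cl`, `v`, `ke`, `eta`.
#' @export
individual_pk <- function(cl, v, eta = c(cl = NA_real_, v = NA_real_)) {
  stopifnot(is.finite(cl), cl > 0, is.finite(v), v > 0)
  structure(list(cl = as.numeric(cl), v = as.numeric(v),
                 ke = as.numeric(cl) / as.numeric(v),
                 eta = eta),
            class = "individual_pk")
}

#' @export
print.individual_pk <- function(x, ...) {
  cat(sprintf("<individual_pk> CL = %.4g L/h, V = %.4g L, ke = %.4g 1/h\n",
              x$cl, x$v, x$ke))
  invisible(x)
}

#' One-compartment intermittent-infusion concentration
#'
#' Closed-form superposition over all infusions. Each dose with zero-order
#' rate `R = amount/duration`, start `s` and duration `T` contributes
#' \deqn{0 \quad (t \le s)}
#' \deqn{(R/CL)(1 - e^{-k_e (t-s)}) \quad (s < t \le s+T)}
#' \deqn{(R/CL)(1 - e^{-k_e T}) e^{-k_e (t-s-T)} \quad (t > s+T)}
#' and the total concentration is the sum; the model is linear in dose
#' amounts.
#'
#' @param ind an [individual_pk()] (or any list with `cl` and `v`).
#' @param doses a [dosing_events()] frame (may be empty).
#' @param t hours since first dose; vectorised.
#' @return concentrations, mg/L (same length as `t`).
#' @export
infusion_concentration <- function(ind, doses, t) {
  cl <- ind$cl; ke <- ind$cl / ind$v
  if (is.null(doses) || nrow(doses) == 0) return(numeric(length(t)))
  # time-since-start matrix: rows = times, cols = doses
  dt <- outer(t, doses$start, `-`)
  Tm <- matrix(doses$duration, nrow = length(t), ncol = nrow(doses), byrow = TRUE)
  R <- matrix(doses$amount / doses$duration, nrow = length(t),
              ncol = nrow(doses), byrow = TRUE)
  during <- dt > 0 & dt <= Tm
  after <- dt > Tm
  contrib <- matrix(0, nrow = length(t), ncol = nrow(doses))
  if (any(during))
    contrib[during] <- (R[during] / cl) * (1 - exp(-ke * dt[during]))
  if (any(after))
    contrib[after] <- (R[after] / cl) * (1 - exp(-ke * Tm[after])) *
      exp(-ke * (dt[after] - Tm[after]))
  rowSums(contrib)
}

#' Steady-state daily exposure
#'
#' At steady state the 24-hour area under the concentration-time curve of any
#' linear-elimination regimen equals the daily dose divided by clearance.
#'
#' @param ind an [individual_pk()].
#' @param daily_dose total daily dose, mg.
#' @return AUC24, mg·h/L.
#' @export
steady_state_auc24 <- function(ind, daily_dose) {
  if (!is.numeric(daily_dose) || daily_dose <= 0)
    stop("daily_dose must be positive")
  daily_dose / ind$cl
}

#' Classify a sample time as peak, mid or trough
#'
#' Window conventions of AUC-guided vancomycin monitoring: a sample drawn
#' 1-2 h after the end of the covering infusion is a peak; one drawn 0.5-1 h
#' before the next dose is a trough; anything else in the interval is a mid.
#' Windows are half-open (`[1, 2)` hours after infusion end; `[0.5, 1)` hours
#' before the next dose start) and peak takes precedence over trough when a
#' short interval makes them overlap. When no later dose exists, the next
#' dose start is projected from the covering dose's `interval_hint`.
#'
#' @param sample_time hours since first dose (scalar).
#' @param doses a [dosing_events()] frame.
#' @return one of `"peak"`, `"mid"`, `"trough"`.
#' @export
classify_sample <- function(sample_time, doses) {
  stopifnot(nrow(doses) >= 1)
  idx <- findInterval(sample_time, doses$start)
  if (idx == 0) stop("sample precedes the first dose")
  s <- doses$start[idx]
  end <- s + doses$duration[idx]
  next_start <- if (idx < nrow(doses)) {
    doses$start[idx + 1]
  } else if (is.finite(doses$interval_hint[idx])) {
    s + doses$interval_hint[idx]
  } else NA_real_
  off_peak <- sample_time - end
  if (is.finite(off_peak) && off_peak >= 1 && off_peak < 2) return("peak")
  if (is.finite(next_start)) {
    before_next <- next_start - sample_time
    if (before_next >= 0.5 && before_next < 1) return("trough")
  }
  "mid"
}
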