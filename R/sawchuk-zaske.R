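#' Sawchuk-Zaske two-point first-order fit
#'
#' Estimates the elimination rate constant and volume of distribution from
#' two post-infusion concentrations of the same dosing interval, assuming
#' steady state. The elimination rate is the log-linear slope
#' `ke = ln(c1/c2) / (t2 - t1)`; the end-of-infusion maximum is found by
#' back-extrapolation `cmax = c1 * exp(ke * (t1 - t_end))`; steady-state
#' clearance follows from the intermittent-infusion maximum
#' \deqn{CL = \frac{D (1 - e^{-k_e T})}{T\, C_{max} (1 - e^{-k_e \tau})}}
#' with `T` the infusion duration and `tau` the dosing interval, and
#' `Vd = CL / ke`.
#'
#' @param c1,t1 first (earlier, higher) concentration in mg/L and its time in
#'   hours since first dose.
#' @param c2,t2 second concentration and time; requires `t1 < t2` and
#'   `c1 > c2 > 0`, both samples after the end of the covering infusion.
#' @param dose the covering dose, one row of a [dosing_events()] frame.
#' @param tau dosing interval in hours.
#' @param back_extrapolate back-extrapolate the peak to the end of infusion
#'   (default) or use `c1` as the peak directly.
#' @return object of class `two_point_fit`: `ke` (1/h), `cmax_end_infusion`
#'   (mg/L), `vd` (L), `cl` (L/h, `= ke * vd`), `source_times`, and
#'   `steady_state_ok` (`FALSE` flags fits where the elapsed time since the
#'   first dose is under five estimated half-lives; a warning is issued).
#' @export
fit_two_point <- function(c1, t1, c2, t2, dose, tau, back_extrapolate = TRUE) {
  stopifnot(is.finite(c1), is.finite(c2), is.finite(t1), is.finite(t2))
  if (t1 >= t2) stop("samples must be in increasing time order (t1 < t2)")
  if (c2 <= 0) stop("concentrations must be positive")
  if (c1 <= c2) stop("non-decaying pair: c1 must exceed c2")
  t_end <- dose$start + dose$duration
  if (t1 <= t_end || t2 <= t_end)
    stop("both samples must fall after the end of the infusion")
  if (!is.finite(tau) || tau <= 0) stop("tau must be a positive interval")
  ke <- log(c1 / c2) / (t2 - t1)
  cmax <- if (back_extrapolate) c1 * exp(ke * (t1 - t_end)) else c1
  Tinf <- dose$duration
  cl <- dose$amount * (1 - exp(-ke * Tinf)) /
    (Tinf * cmax * (1 - exp(-ke * tau)))
  vd <- cl / ke
  half_life <- log(2) / ke
  ss_ok <- t1 >= 5 * half_life
  if (!ss_ok)
    warning(sprintf(
      "two-point fit at t=%.1f h, under 5 estimated half-lives (%.1f h); steady-state assumption doubtful",
      t1, 5 * half_life))
  structure(list(ke = ke, cmax_end_infusion = cmax, vd = vd, cl = cl,
                 source_times = c(t1, t2), steady_state_ok = ss_ok),
            class = "two_point_fit")
}

#' @export
print.two_point_fit <- function(x, ...) {
  cat(sprintf(
    "<two_point_fit> ke = %.4g 1/h, Cmax(end-inf) = %.4g mg/L, Vd = %.4g L, CL = %.4g L/h\n",
    x$ke, x$cmax_end_infusion, x$vd, x$cl))
  invisible(x)
}

#' Forecast concentrations from a two-point fit
#'
#' Evaluates the full one-compartment superposition with the fitted `(cl, vd)`
#' over the actual future dose schedule, so mid-course dose changes are
#' honoured rather than assuming the fitted interval repeats.
#'
#' @param fit a [fit_two_point()] result.
#' @param doses the complete [dosing_events()] schedule (past and future).
#' @param times hours since first dose at which to forecast.
#' @return forecast concentrations, mg/L.
#' @export
forecast_first_order <- function(fit, doses, times) {
  stopifnot(inherits(fit, "two_point_fit"))
  if (is.null(doses) || nrow(doses) == 0)
    stop("an empty future schedule cannot be forecast")
  ind <- individual_pk(cl = fit$cl, v = fit$vd)
  infusion_concentration(ind, doses, times)
}
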