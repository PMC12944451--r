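#' Population pharmacokinetic prior
#'
#' A `pop_prior` bundles everything MAP estimation and cohort simulation need
#' to know about the population: typical-value expressions for clearance and
#' volume as functions of patient covariates, between-subject variances on the
#' log scale, a residual-error model, and (for simulation only) a
#' between-occasion variance.
#'
#' Typical-value expressions are R expressions over the covariate symbols
#' `age_mo` (months), `age_days`, `wt` (kg) and `scr` (mg/dL). They are
#' evaluated at the covariate values in force at a given clock time, so a
#' step change in serum creatinine propagates into the typical clearance.
#'
#' @param cl_expr,v_expr character; R expressions for the typical clearance
#'   (L/h) and volume of distribution (L).
#' @param omega2 named numeric, `c(cl =, v =)`: between-subject variances of
#'   the log-normal random effects (eta).
#' @param sigma list with `prop_cv` (proportional residual CV, unitless) and
#'   `add_sd` (additive residual SD, mg/L). The residual SD for an
#'   observation with model prediction `f` is `sqrt((prop_cv*f)^2 + add_sd^2)`.
#' @param iov2 between-occasion variance of log-clearance, expressed per day
#'   of elapsed time (a random-walk rate); used only by the cohort simulator.
#' @param support named list of `c(min, max)` covariate ranges over which the
#'   typical-value model is trusted; evaluation outside them errors, naming
#'   the covariate. Defaults cover the pediatric range (age 0.5-240 months,
#'   weight 1-150 kg, creatinine 0.05-10 mg/dL).
#' @param penalty_space `"eta"` (default) puts the MAP prior penalty on the
#'   log-scale random effects, `sum(eta^2/omega2)`; `"theta"` reproduces the
#'   literal additive form `sum((theta_pop - theta_ind)^2 / (theta_pop^2 *
#'   omega2))`, i.e. omega read as a CV on the natural scale.
#' @param name label carried through outputs.
#' @return an object of class `pop_prior`.
#' @seealso [typical_params()], [read_prior()], [default_prior()]
#' @export
pop_prior <- function(cl_expr, v_expr,
                      omega2 = c(cl = 0.09, v = 0.04),
                      sigma = list(prop_cv = 0.2, add_sd = 0),
                      iov2 = 0.02,
                      support = list(age_mo = c(0.5, 240), wt = c(1, 150),
                                     scr = c(0.05, 10)),
                      penalty_space = c("eta", "theta"),
                      name = "custom") {
  penalty_space <- match.arg(penalty_space)
  stopifnot(is.character(cl_expr), is.character(v_expr))
  omega2 <- unlist(omega2)[c("cl", "v")]
  if (anyNA(omega2) || any(omega2 < 0))
    stop("omega2 must supply non-negative 'cl' and 'v' variances")
  sigma <- as.list(sigma)
  sigma$prop_cv <- if (is.null(sigma$prop_cv)) 0 else sigma$prop_cv
  sigma$add_sd <- if (is.null(sigma$add_sd)) 0 else sigma$add_sd
  if (sigma$prop_cv < 0 || sigma$add_sd < 0)
    stop("residual-error components must be non-negative")
  structure(
    list(name = name,
         cl_expr = cl_expr, v_expr = v_expr,
         cl_fun = parse(text = cl_expr)[[1]],
         v_fun = parse(text = v_expr)[[1]],
         omega2 = omega2, sigma = sigma, iov2 = iov2,
         support = support, penalty_space = penalty_space),
    class = "pop_prior")
}

#' @export
print.pop_prior <- function(x, ...) {
  cat("<pop_prior> ", x$name, "\n",
      "  CL (L/h): ", x$cl_expr, "\n",
      "  V  (L):   ", x$v_expr, "\n",
      "  omega2:   cl=", x$omega2[["cl"]], " v=", x$omega2[["v"]], "\n",
      "  sigma:    prop_cv=", x$sigma$prop_cv, " add_sd=", x$sigma$add_sd, "\n",
      "  penalty:  ", x$penalty_space, "-space\n", sep = "")
  invisible(x)
}

#' Default pediatric vancomycin prior
#'
#' Typical-value structure of the one-compartment pediatric vancomycin
#' population model of Le et al. (2014): allometric weight on clearance with
#' serum-creatinine and age terms, volume proportional to weight. The
#' between-subject variances and the residual-error magnitude shipped here
#' are representative pediatric values chosen for this package, not estimates
#' transcribed from that analysis; both are plainly configurable.
#'
#' @return a [pop_prior()].
#' @export
default_prior <- function() {
  pop_prior(
    cl_expr = "0.248 * wt^0.75 * (0.48/scr)^0.361 * (log(age_days)/7.8)^0.995",
    v_expr = "0.636 * wt",
    omega2 = c(cl = 0.09, v = 0.04),
    sigma = list(prop_cv = 0.2, add_sd = 0),
    iov2 = 0.02,
    penalty_space = "eta",
    name = "le2014_pediatric")
}

#' Read / write a prior configuration
#'
#' The on-disk format is a small YAML file mirroring the [pop_prior()]
#' arguments. See `system.file("extdata", "prior_pediatric_default.yaml",
#' package = "vancoforecast")` for the shipped default.
#'
#' @param path file path.
#' @return `read_prior` a [pop_prior()]; `write_prior` the path, invisibly.
#' @export
read_prior <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (fld in c("cl_expr", "v_expr"))
    if (is.null(cfg[[fld]])) stop("prior config is missing field '", fld, "'")
  pop_prior(cl_expr = cfg$cl_expr, v_expr = cfg$v_expr,
            omega2 = if (!is.null(cfg$omega2)) unlist(cfg$omega2) else c(cl = 0.09, v = 0.04),
            sigma = if (!is.null(cfg$sigma)) cfg$sigma else list(prop_cv = 0.2, add_sd = 0),
            iov2 = if (!is.null(cfg$iov2)) cfg$iov2 else 0,
            support = if (!is.null(cfg$support)) lapply(cfg$support, unlist)
                      else list(age_mo = c(0.5, 240), wt = c(1, 150),
                                scr = c(0.05, 10)),
            penalty_space = if (!is.null(cfg$penalty_space)) cfg$penalty_space else "eta",
            name = if (!is.null(cfg$name)) cfg$name else "config")
}

#' @rdname read_prior
#' @param prior a [pop_prior()].
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "pop_prior"))
  yaml::write_yaml(
    list(name = prior$name, cl_expr = prior$cl_expr, v_expr = prior$v_expr,
         omega2 = as.list(prior$omega2), sigma = prior$sigma,
         iov2 = prior$iov2, penalty_space = prior$penalty_space),
    path)
  invisible(path)
}

#' Patient covariates with a piecewise-constant creatinine series
#'
#' Serum creatinine may change during therapy; it is stored as a
#' right-continuous step series defined from time 0. Age and weight are
#' treated as constant over the (short) TDM horizon.
#'
#' @param age_mo age in months.
#' @param wt total body weight, kg.
#' @param scr either a single mg/dL value or a `data.frame(time, value)` step
#'   series (hours since first dose; must start at time 0).
#' @return object of class `patient_covariates`.
#' @export
patient_covariates <- function(age_mo, wt, scr) {
  stopifnot(age_mo > 0, wt > 0)
  if (is.data.frame(scr)) {
    stopifnot(all(c("time", "value") %in% names(scr)))
    scr <- scr[order(scr$time), , drop = FALSE]
    if (scr$time[1] > 0) stop("scr series must be defined from time 0")
    if (any(scr$value <= 0)) stop("scr must be positive")
  } else {
    stopifnot(length(scr) == 1L, scr > 0)
    scr <- data.frame(time = 0, value = as.numeric(scr))
  }
  structure(list(age_mo = as.numeric(age_mo), wt = as.numeric(wt), scr = scr),
            class = "patient_covariates")
}

#' Serum creatinine in force at a clock time
#' @param cov a [patient_covariates()].
#' @param t hours since first dose (vectorised).
#' @return mg/dL values.
#' @export
scr_at <- function(cov, t) {
  stopifnot(inherits(cov, "patient_covariates"))
  idx <- findInterval(t, cov$scr$time)
  if (any(idx == 0)) stop("scr series does not cover requested time")
  cov$scr$value[idx]
}

#' Typical PK parameters at a clock time
#'
#' Evaluates the prior's covariate model at the covariate values in force at
#' time `t` (relevant when creatinine changes mid-course). Pure function of
#' its arguments.
#'
#' @param prior a [pop_prior()].
#' @param cov a [patient_covariates()].
#' @param t hours since first dose (scalar).
#' @return named numeric `c(cl =, v =)` in L/h and L.
#' @export
typical_params <- function(prior, cov, t = 0) {
  stopifnot(inherits(prior, "pop_prior"), inherits(cov, "patient_covariates"))
  scr <- scr_at(cov, t)
  vals <- list(age_mo = cov$age_mo, wt = cov$wt, scr = scr)
  for (nm in names(vals)) {
    rng <- prior$support[[nm]]
    if (is.null(rng)) next
    if (!is.finite(vals[[nm]]) || vals[[nm]] < rng[1] || vals[[nm]] > rng[2])
      stop("covariate out of support: ", nm, " = ", vals[[nm]],
           " outside [", rng[1], ", ", rng[2], "]")
  }
  env <- list(age_mo = cov$age_mo, age_days = cov$age_mo * 30.4375,
              wt = cov$wt, scr = scr)
  cl <- eval(prior$cl_fun, env, baseenv())
  v <- eval(prior$v_fun, env, baseenv())
  if (!is.finite(cl) || cl <= 0)
    stop("covariate out of support: typical clearance is not positive ",
         "(age_mo=", cov$age_mo, ", wt=", cov$wt, ", scr=", scr, ")")
  if (!is.finite(v) || v <= 0)
    stop("covariate out of support: typical volume is not positive")
  c(cl = cl, v = v)
}

#' Residual standard deviation for a model prediction
#'
#' Combined proportional + additive residual model:
#' `sqrt((prop_cv * f)^2 + add_sd^2)`.
#'
#' @param prior a [pop_prior()].
#' @param f model-predicted concentration(s), mg/L.
#' @return SD(s), mg/L. Errors if the SD is zero for any prediction (a zero
#'   residual variance makes the estimation objective undefined).
#' @export
residual_sd <- function(prior, f) {
  s <- sqrt((prior$sigma$prop_cv * f)^2 + prior$sigma$add_sd^2)
  if (any(s <= 0))
    stop("residual SD is zero for some prediction; check the sigma model")
  s
}

#' Bedside Schwartz estimated GFR
#'
#' Convenience helper: `eGFR = 0.413 * height / Scr` (mL/min/1.73 m^2).
#' Not used by the estimation machinery.
#'
#' @param height_cm height in cm.
#' @param scr serum creatinine, mg/dL.
#' @export
schwartz_egfr <- function(height_cm, scr) {
  stopifnot(all(height_cm > 0), all(scr > 0))
  0.413 * height_cm / scr
}
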