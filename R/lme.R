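#' Mixed-effects factor analysis of forecasting performance
#'
#' Which factors drive forecast accuracy and precision? Each forecast pair
#' contributes one outcome value: its signed symmetric relative deviation (%)
#' for the accuracy ("rbias") analysis, or its absolute deviation (%) for the
#' precision ("rrmse") analysis. Linear mixed-effects models with a random
#' intercept per patient are fitted by maximum likelihood (lme4): first one
#' model per candidate variable (univariable screen), then a multivariable
#' model containing every variable with a screening p-value below
#' `screen_p`. Estimates carry Wald 95% confidence intervals and
#' normal-approximation p-values.
#'
#' Candidate variables: estimation method (reference: conventional MAP),
#' sample selection collapsed to one-sample window vs two concentrations
#' (reference: two concentrations), forecast lead time (days), age (months),
#' weight (kg) and serum creatinine.
#'
#' @param pairs a [forecast_table()] result.
#' @param outcome `"rbias"` (signed deviation) or `"rrmse"` (absolute
#'   deviation).
#' @param screen_p univariable significance cut-off for entry into the
#'   multivariable model.
#' @param conf confidence level for the Wald intervals.
#' @return `data.frame` with columns `variable`, `term`, `estimate`, `ci_lo`,
#'   `ci_hi`, `p_value`, `model` (`"univariable"`/`"multivariable"`),
#'   `singular` (fit flagged as singular). Reference levels contribute no
#'   row.
#' @export
lme_factor_analysis <- function(pairs, outcome = c("rbias", "rrmse"),
                                screen_p = 0.05, conf = 0.95) {
  outcome <- match.arg(outcome)
  stopifnot(nrow(pairs) > 0)
  dev <- pair_deviation(pairs$c_forecast, pairs$c_observed)
  dat <- data.frame(
    y = if (outcome == "rbias") dev else abs(dev),
    patient = factor(pairs$patient),
    lead_time_days = pairs$lead_time_days,
    age_mo = pairs$age_mo, wt_kg = pairs$wt_kg, scr = pairs$scr)
  # one-sample window vs two concentrations (the reference)
  two <- grepl("+", pairs$samples_used, fixed = TRUE) |
    pairs$samples_used == "two_post_dose"
  sample_group <- ifelse(two, "two", pairs$samples_used)
  dat$sample_group <- factor(sample_group,
                             levels = c("two", setdiff(unique(sample_group), "two")))
  meth <- as.character(pairs$method)
  dat$method <- factor(meth, levels = c(intersect("conventional", meth),
                                        setdiff(unique(meth), "conventional")))

  candidates <- c("age_mo", "wt_kg", "scr", "lead_time_days",
                  "sample_group", "method")
  usable <- vapply(candidates, function(v) length(unique(dat[[v]])) > 1,
                   logical(1))
  candidates <- candidates[usable]

  uni <- do.call(rbind, lapply(candidates, function(v)
    fit_lme_rows(stats::reformulate(c(v, "(1 | patient)"), response = "y"),
                 dat, "univariable", v, conf)))
  keep <- vapply(split(uni, uni$variable),
                 function(d) any(d$p_value < screen_p), logical(1))
  survivors <- names(keep)[keep]
  multi <- NULL
  if (length(survivors)) {
    multi <- fit_lme_rows(
      stats::reformulate(c(survivors, "(1 | patient)"), response = "y"),
      dat, "multivariable", survivors, conf)
  }
  out <- rbind(uni, multi)
  rownames(out) <- NULL
  out
}

# fit one lmer model (ML) and return Wald rows for the fixed effects
fit_lme_rows <- function(formula, dat, model_label, variables, conf) {
  fit <- tryCatch(
    suppressMessages(lme4::lmer(formula, data = dat, REML = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(data.frame(variable = variables[1], term = "(fit failed)",
                      estimate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      p_value = NA_real_, model = model_label,
                      singular = TRUE))
  }
  singular <- lme4::isSingular(fit)
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  terms <- rownames(co)
  # map each coefficient back to the candidate variable that produced it
  var_of <- vapply(terms, function(tm) {
    hit <- variables[startsWith(tm, variables)]
    if (length(hit)) hit[which.max(nchar(hit))] else tm
  }, character(1))
  data.frame(variable = var_of, term = terms,
             estimate = co[, "Estimate"],
             ci_lo = co[, "Estimate"] - z * co[, "Std. Error"],
             ci_hi = co[, "Estimate"] + z * co[, "Std. Error"],
             p_value = 2 * stats::pnorm(-abs(co[, "t value"])),
             model = model_label, singular = singular)
}
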