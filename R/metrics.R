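#' Symmetric relative forecasting metrics
#'
#' Accuracy and precision of forecast/observed concentration pairs are
#' summarised with the symmetric relative deviation
#' \deqn{d_i = \frac{C_{forecast}(i) - C_{observed}(i)}
#'                  {(C_{forecast}(i) + C_{observed}(i))/2} \times 100\,(\%)}
#' `rbias` is the mean of `d_i` and `rrmse` the root of the mean of `d_i^2`.
#' The symmetric denominator bounds both: `rbias` in (-200, 200) and `rrmse`
#' in [0, 200).
#'
#' @param c_forecast,c_observed strictly positive concentration vectors of
#'   equal length (mg/L).
#' @return percentage value.
#' @export
rbias <- function(c_forecast, c_observed) {
  mean(pair_deviation(c_forecast, c_observed))
}

#' @rdname rbias
#' @export
rrmse <- function(c_forecast, c_observed) {
  sqrt(mean(pair_deviation(c_forecast, c_observed)^2))
}

#' @rdname rbias
#' @return `pair_deviation`: the per-pair signed deviations `d_i` (%).
#' @export
pair_deviation <- function(c_forecast, c_observed) {
  if (length(c_forecast) == 0) stop("no forecast pairs supplied")
  if (length(c_forecast) != length(c_observed))
    stop("forecast and observed vectors differ in length")
  if (any(!is.finite(c_forecast)) || any(!is.finite(c_observed)) ||
      any(c_forecast <= 0) || any(c_observed <= 0))
    stop("concentrations must be finite and strictly positive")
  200 * (c_forecast - c_observed) / (c_forecast + c_observed)
}

#' Cluster (patient-level) bootstrap confidence interval
#'
#' Non-parametric bootstrap resampling whole patients with replacement, so
#' the repeated measures within a patient stay together; percentile
#' 2.5/97.5% bounds of the metric across replicates.
#'
#' @param c_forecast,c_observed paired concentrations.
#' @param patient patient id per pair (cluster variable).
#' @param metric `"rbias"` or `"rrmse"`.
#' @param n_boot number of resamples (the study convention is 1000).
#' @param seed integer seed for reproducibility (optional).
#' @param conf confidence level.
#' @return named numeric `c(lo =, hi =)`. With a single patient the interval
#'   degenerates to a point and a warning is issued.
#' @export
bootstrap_ci <- function(c_forecast, c_observed, patient,
                         metric = c("rbias", "rrmse"),
                         n_boot = 1000, seed = NULL, conf = 0.95) {
  metric <- match.arg(metric)
  stopifnot(n_boot >= 1, length(patient) == length(c_forecast))
  dev <- pair_deviation(c_forecast, c_observed)
  # per-patient sufficient statistics: both metrics are functions of the
  # cluster sums of d, d^2 and the cluster sizes
  s1 <- tapply(dev, patient, sum)
  s2 <- tapply(dev^2, patient, sum)
  nn <- tapply(dev, patient, length)
  k <- length(s1)
  if (k == 1) warning("single patient: bootstrap CI is degenerate")
  if (!is.null(seed)) set.seed(seed)
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(k, k, replace = TRUE)
    n_tot <- sum(nn[idx])
    stat[b] <- if (metric == "rbias") sum(s1[idx]) / n_tot
               else sqrt(sum(s2[idx]) / n_tot)
  }
  alpha <- (1 - conf) / 2
  # type 6 follows the (R+1) order-statistic convention of standard
  # bootstrap implementations; its slightly wider tails at finite R are
  # better calibrated than the default interpolation
  q <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE, type = 6)
  c(lo = q[1], hi = q[2])
}

#' Stratified metric summary of a forecast-pair table
#'
#' Computes rBias and rRMSE with cluster-bootstrap confidence intervals for
#' each stratum of a forecast table (by default each method-by-selection
#' cell).
#'
#' @param pairs a [forecast_table()] result.
#' @param by stratifying columns.
#' @param n_boot,seed,conf passed to [bootstrap_ci()].
#' @return `data.frame` with one row per stratum: the `by` columns, `n`,
#'   `n_patients`, `rbias`, `rbias_lo`, `rbias_hi`, `rrmse`, `rrmse_lo`,
#'   `rrmse_hi`.
#' @export
evaluate_forecasts <- function(pairs, by = c("method", "samples_used"),
                               n_boot = 1000, seed = NULL, conf = 0.95) {
  stopifnot(nrow(pairs) > 0, all(by %in% names(pairs)))
  key <- interaction(pairs[by], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(pairs)), key)
  rows <- lapply(groups, function(ii) {
    g <- pairs[ii, , drop = FALSE]
    ci_b <- bootstrap_ci(g$c_forecast, g$c_observed, g$patient, "rbias",
                         n_boot = n_boot, seed = seed, conf = conf)
    ci_r <- bootstrap_ci(g$c_forecast, g$c_observed, g$patient, "rrmse",
                         n_boot = n_boot, seed = seed, conf = conf)
    cbind(g[1, by, drop = FALSE],
          data.frame(n = nrow(g), n_patients = length(unique(g$patient)),
                     rbias = rbias(g$c_forecast, g$c_observed),
                     rbias_lo = ci_b[["lo"]], rbias_hi = ci_b[["hi"]],
                     rrmse = rrmse(g$c_forecast, g$c_observed),
                     rrmse_lo = ci_r[["lo"]], rrmse_hi = ci_r[["hi"]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
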