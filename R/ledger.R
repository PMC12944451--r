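#' Read and validate a TDM ledger
#'
#' The interchange format is a NONMEM-style longitudinal CSV with columns
#' `ID`, `TIME` (hours since the patient's first dose), `AMT` (mg, dose rows),
#' `DUR` (infusion duration, h), `DV` (observed concentration mg/L,
#' observation rows), `EVID` (1 = dose, 0 = observation), and the covariates
#' `AGE_MO`, `WT_KG`, `SCR_MGDL`. `DV` is blank on dose rows and `AMT` on
#' observation rows.
#'
#' Validation: required columns present, `TIME` non-decreasing within `ID`,
#' positive doses and concentrations. A missing or blank `DUR` defaults to a
#' 1-hour infusion with a warning. Problems are reported with row numbers.
#'
#' @param path CSV file path.
#' @return the validated ledger `data.frame`.
#' @export
read_ledger <- function(path) {
  led <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ledger(led)
}

#' @rdname read_ledger
#' @param ledger a ledger `data.frame` already in memory.
#' @export
validate_ledger <- function(ledger) {
  required <- c("ID", "TIME", "AMT", "DV", "EVID", "AGE_MO", "WT_KG", "SCR_MGDL")
  missing_cols <- setdiff(required, names(ledger))
  if (length(missing_cols))
    stop("ledger is missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!"DUR" %in% names(ledger)) {
    warning("ledger has no DUR column; assuming 1-hour infusions")
    ledger$DUR <- NA_real_
  }
  dose <- ledger$EVID == 1
  if (any(dose & (is.na(ledger$DUR) | ledger$DUR <= 0))) {
    n_fix <- sum(dose & (is.na(ledger$DUR) | ledger$DUR <= 0))
    warning(n_fix, " dose row(s) without a valid DUR; defaulting to 1 h")
    ledger$DUR[dose & (is.na(ledger$DUR) | ledger$DUR <= 0)] <- 1
  }
  bad <- unlist(lapply(split(seq_len(nrow(ledger)), ledger$ID), function(rows) {
    tt <- ledger$TIME[rows]
    rows[c(FALSE, diff(tt) < 0)]
  }))
  if (length(bad))
    stop("TIME is not non-decreasing within ID at row(s): ",
         paste(sort(bad), collapse = ", "))
  if (any(dose & (is.na(ledger$AMT) | ledger$AMT <= 0)))
    stop("dose rows must carry a positive AMT; offending row(s): ",
         paste(which(dose & (is.na(ledger$AMT) | ledger$AMT <= 0)), collapse = ", "))
  obs <- ledger$EVID == 0
  if (any(obs & (is.na(ledger$DV) | ledger$DV <= 0)))
    stop("observation rows must carry a positive DV; offending row(s): ",
         paste(which(obs & (is.na(ledger$DV) | ledger$DV <= 0)), collapse = ", "))
  ledger
}

#' @rdname read_ledger
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Split a ledger into per-patient histories
#'
#' @param ledger a validated ledger `data.frame`.
#' @param interval_hint planned dosing interval used to delimit the last
#'   interval when it cannot be inferred; `NULL` infers it from the median
#'   inter-dose gap.
#' @return named list (one element per `ID`) of lists with `doses`
#'   (a [dosing_events()] frame), `obs` (`data.frame(time, conc)`), and `cov`
#'   (a [patient_covariates()]; `SCR_MGDL` values along the rows become the
#'   creatinine step series).
#' @export
split_patients <- function(ledger, interval_hint = NULL) {
  lapply(split(ledger, ledger$ID), function(df) {
    df <- df[order(df$TIME), , drop = FALSE]
    d <- df[df$EVID == 1, , drop = FALSE]
    o <- df[df$EVID == 0, , drop = FALSE]
    hint <- interval_hint
    if (is.null(hint))
      hint <- if (nrow(d) >= 2) stats::median(diff(d$TIME)) else NA_real_
    doses <- dosing_events(d$TIME, d$AMT, d$DUR, interval_hint = hint)
    scr <- unique(data.frame(time = df$TIME, value = df$SCR_MGDL))
    scr <- scr[!duplicated(scr$time), , drop = FALSE]
    if (nrow(scr) == 0 || scr$time[1] > 0)
      scr <- rbind(data.frame(time = 0, value = df$SCR_MGDL[1]), scr)
    keep <- c(TRUE, diff(scr$value) != 0)  # collapse runs of equal values
    cov <- patient_covariates(age_mo = df$AGE_MO[1], wt = df$WT_KG[1],
                              scr = scr[keep, , drop = FALSE])
    list(id = df$ID[1], doses = doses,
         obs = data.frame(time = o$TIME, conc = o$DV), cov = cov)
  })
}

#' Group observations into TDM occasions
#'
#' A TDM occasion is a dosing interval in which at least one concentration
#' was sampled. Observations are assigned to the half-open interval
#' `[dose start, next dose start)` that covers them (the final interval is
#' closed off by the dose's `interval_hint`); occasions are indexed
#' chronologically `1, 2, ...`.
#'
#' @param obs `data.frame(time, conc)`, time-sorted.
#' @param doses a [dosing_events()] frame.
#' @return `obs` with added columns `occasion` (chronological index),
#'   `interval` (covering dose row index) and `label`
#'   (peak/mid/trough via [classify_sample()]). Zero-row input gives a
#'   zero-row result.
#' @export
split_occasions <- function(obs, doses) {
  out <- cbind(obs[0, , drop = FALSE],
               occasion = integer(0), interval = integer(0),
               label = character(0))
  if (is.null(obs) || nrow(obs) == 0) return(out)
  stopifnot(nrow(doses) >= 1)
  idx <- findInterval(obs$time, doses$start)
  if (any(idx == 0))
    stop("observation(s) before the first dose are not covered by any interval")
  last_end <- doses$start[nrow(doses)] +
    if (is.finite(doses$interval_hint[nrow(doses)]))
      doses$interval_hint[nrow(doses)] else Inf
  if (any(idx == nrow(doses) & obs$time >= last_end))
    stop("observation(s) beyond the end of the final dosing interval")
  occ <- match(idx, sort(unique(idx)))
  obs$occasion <- occ
  obs$interval <- idx
  obs$label <- vapply(obs$time, classify_sample, character(1), doses = doses)
  obs
}
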