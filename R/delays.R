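# Reporting-delay construction: whole-day delays, the 1/7/30-day binary
# indicators, the log transform, and district-level summaries.

#' Reporting delay in whole days
#'
#' Calendar-day difference between report and occurrence date. Negative
#' differences signal recording errors and are returned as NA with a
#' message giving the count; callers drop the flagged rows.
#'
#' @param occurrence_date,report_date Date vectors (recycled to equal length).
#' @return Integer vector of delays; NA where report precedes occurrence.
#' @export
compute_delay <- function(occurrence_date, report_date) {
  occ <- as.Date(occurrence_date); rep <- as.Date(report_date)
  d <- as.integer(rep - occ)
  bad <- !is.na(d) & d < 0
  if (any(bad)) {
    message(sum(bad), " record(s) with report date before occurrence date flagged invalid")
    d[bad] <- NA_integer_
  }
  d
}

#' Binary delay indicators at the 1/7/30-day thresholds
#'
#' d_day = 1 iff delay <= 1 day, d_week = 1 iff <= 7, d_month = 1 iff <= 30;
#' the indicators are nested (d_day <= d_week <= d_month).
#'
#' @param delay_days Nonnegative integer vector.
#' @return data.frame with columns d_day, d_week, d_month (0/1).
#' @export
binarize_delay <- function(delay_days) {
  stopifnot(all(is.na(delay_days) | delay_days >= 0))
  data.frame(d_day   = as.integer(delay_days <= 1),
             d_week  = as.integer(delay_days <= 7),
             d_month = as.integer(delay_days <= 30))
}

#' Log-transformed delay
#'
#' Same-day reports (delay 0) are legitimate and common, so the transform
#' is log(1 + delay), which is 0 exactly at delay 0 and strictly increasing.
#'
#' @param delay_days Nonnegative numeric vector.
#' @return log(1 + delay_days).
#' @export
log_delay <- function(delay_days) {
  if (any(delay_days < 0, na.rm = TRUE)) stop("negative delay")
  log1p(delay_days)
}

#' Filter event records
#'
#' Keeps records matching all supplied criteria: an offence class, a
#' premises class and/or a closed report-date window. NULL criteria pass
#' everything.
#'
#' @param events data.frame of event records.
#' @param offence Offence class value to keep (matched against
#'   `events$offence`), or NULL.
#' @param premises Premises class to keep (against `events$premises`), or NULL.
#' @param report_window Length-2 Date vector (inclusive), or NULL.
#' @return The retained rows; a message logs counts in/out and a warning is
#'   raised when nothing survives.
#' @export
filter_events <- function(events, offence = NULL, premises = NULL,
                          report_window = NULL) {
  keep <- rep(TRUE, nrow(events))
  if (!is.null(offence))  keep <- keep & events$offence == offence
  if (!is.null(premises)) keep <- keep & events$premises == premises
  if (!is.null(report_window)) {
    w <- as.Date(report_window)
    rd <- as.Date(events$report_date)
    keep <- keep & rd >= w[1] & rd <= w[2]
  }
  keep[is.na(keep)] <- FALSE
  message("filter_events: ", sum(keep), " of ", nrow(events), " records retained")
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("filter_events: no records match the criteria")
  out
}

#' District-level delay summaries
#'
#' Per district: event count n_j, the proportions of events reported within
#' one day/week/month, and the median delay. Districts without events are
#' returned with NA summaries and `defined = FALSE`, and are excluded from
#' areal tests downstream.
#'
#' @param events data.frame with columns district_id, delay_days (and the
#'   indicator columns from [binarize_delay()], computed if absent).
#' @param districts data.frame with a column `id` listing all districts.
#' @return data.frame: id, n, p_day, p_week, p_month, median_delay, defined.
#' @export
area_summaries <- function(events, districts) {
  unknown <- setdiff(unique(events$district_id), districts$id)
  if (length(unknown)) {
    stop("events reference unknown district id(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(c("d_day", "d_week", "d_month") %in% names(events))) {
    events <- cbind(events, binarize_delay(events$delay_days))
  }
  grp <- factor(events$district_id, levels = districts$id)
  n <- as.integer(table(grp))
  agg <- function(x, f) {
    v <- tapply(x, grp, f)
    as.numeric(v)
  }
  out <- data.frame(
    id = districts$id,
    n = n,
    p_day = agg(events$d_day, mean),
    p_week = agg(events$d_week, mean),
    p_month = agg(events$d_month, mean),
    median_delay = agg(events$delay_days, stats::median)
  )
  out$defined <- out$n > 0
  out
}
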