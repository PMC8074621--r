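# Holiday calendar and temporal feature flags for occurrence dates.
#
# Federal holidays, Christian movable feasts (via the Gauss computus) and
# popular celebrations are computed; Muslim, Jewish and Hindu holidays
# follow lunar calendars, so their Gregorian dates are bundled as a static
# table (inst/extdata/lunar_holidays.csv, approximate dates for 2012-2019,
# user-overridable via `lunar_table`).

nth_weekday <- function(year, month, wday, n) {
  # wday: 0 = Sunday ... 6 = Saturday; n > 0 from start, n = -1 last
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  days <- seq(first, by = "day",
              to = seq(first, by = "month", length.out = 2)[2] - 1)
  hits <- days[as.POSIXlt(days)$wday == wday]
  if (n == -1) hits[length(hits)] else hits[n]
}

easter_sunday <- function(year) {
  # anonymous Gregorian computus
  a <- year %% 19; b <- year %/% 100; c <- year %% 100
  d <- b %/% 4; e <- b %% 4; f <- (b + 8) %/% 25
  g <- (b - f + 1) %/% 3; h <- (19 * a + b - d - g + 15) %% 30
  i <- c %/% 4; k <- c %% 4
  l <- (32 + 2 * e + 2 * i - h - k) %% 7
  m <- (a + 11 * h + 22 * l) %/% 451
  month <- (h + l - 7 * m + 114) %/% 31
  day <- ((h + l - 7 * m + 114) %% 31) + 1
  as.Date(sprintf("%d-%02d-%02d", year, month, day))
}

#' Build the holiday calendar
#'
#' One row per calendar day in `years`, with binary columns `federal`,
#' `christian`, `muslim`, `jewish`, `hindu`, `celebration`. Lunar-calendar
#' holidays are read from a bundled table of approximate Gregorian dates;
#' pass your own `lunar_table` (columns `date`, `group`) to override or
#' extend coverage.
#'
#' @param years Integer vector of years to cover.
#' @param lunar_table Optional data.frame with columns `date`, `group`
#'   (group in muslim/jewish/hindu); defaults to the bundled table.
#' @return data.frame with column `date` and the six binary flags; the
#'   covered years are recorded in `attr(, "years")`.
#' @export
build_holiday_calendar <- function(years, lunar_table = NULL) {
  stopifnot(length(years) >= 1, all(years == floor(years)))
  years <- sort(unique(as.integer(years)))
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  cal <- data.frame(date = dates, federal = 0L, christian = 0L, muslim = 0L,
                    jewish = 0L, hindu = 0L, celebration = 0L)
  mark <- function(cal, d, col) {
    cal[[col]][cal$date %in% d] <- 1L
    cal
  }
  for (y in years) {
    fed <- c(as.Date(sprintf("%d-01-01", y)),          # New Year's Day
             nth_weekday(y, 1, 1, 3),                  # MLK Day
             nth_weekday(y, 2, 1, 3),                  # Washington's Birthday
             nth_weekday(y, 5, 1, -1),                 # Memorial Day
             as.Date(sprintf("%d-07-04", y)),          # Independence Day
             nth_weekday(y, 9, 1, 1),                  # Labor Day
             nth_weekday(y, 10, 1, 2),                 # Columbus Day
             as.Date(sprintf("%d-11-11", y)),          # Veterans Day
             nth_weekday(y, 11, 4, 4),                 # Thanksgiving
             as.Date(sprintf("%d-12-25", y)))          # Christmas
    easter <- easter_sunday(y)
    chr <- c(as.Date(sprintf("%d-12-25", y)),          # Christmas
             as.Date(sprintf("%d-01-06", y)),          # Epiphany
             easter, easter - 2,                       # Easter, Good Friday
             easter - 46, easter - 7)                  # Ash Wednesday, Palm Sunday
    cel <- c(as.Date(sprintf("%d-02-14", y)),          # Valentine's Day
             as.Date(sprintf("%d-03-17", y)),          # St Patrick's Day
             as.Date(sprintf("%d-05-05", y)),          # Cinco de Mayo
             nth_weekday(y, 5, 0, 2),                  # Mother's Day
             nth_weekday(y, 6, 0, 3),                  # Father's Day
             as.Date(sprintf("%d-10-31", y)),          # Halloween
             nth_weekday(y, 11, 4, 4),                 # Thanksgiving
             as.Date(sprintf("%d-12-31", y)))          # New Year's Eve
    cal <- mark(cal, fed, "federal")
    cal <- mark(cal, chr, "christian")
    cal <- mark(cal, cel, "celebration")
  }
  if (is.null(lunar_table)) {
    path <- system.file("extdata", "lunar_holidays.csv", package = "reportlag")
    lunar_table <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  lunar_table$date <- as.Date(lunar_table$date)
  for (grp in c("muslim", "jewish", "hindu")) {
    cal <- mark(cal, lunar_table$date[lunar_table$group == grp], grp)
  }
  attr(cal, "years") <- years
  cal
}

#' Temporal feature flags for occurrence dates
#'
#' Seasons use the meteorological convention (Dec-Feb winter, Mar-May
#' spring, Jun-Aug summer, Sep-Nov fall), so exactly one season flag is set
#' per date; weekend = Saturday or Sunday.
#'
#' @param dates Date vector.
#' @param calendar Calendar from [build_holiday_calendar()]; must cover all
#'   years present in `dates`.
#' @return data.frame with columns winter, spring, summer, fall, weekend,
#'   federal, christian, muslim, jewish, hindu, celebration (all 0/1).
#' @export
temporal_features <- function(dates, calendar) {
  dates <- as.Date(dates)
  yrs <- unique(as.POSIXlt(dates)$year + 1900L)
  missing_yrs <- setdiff(yrs, attr(calendar, "years"))
  if (length(missing_yrs)) {
    stop("calendar does not cover year(s) ", paste(missing_yrs, collapse = ", "),
         "; rebuild it with build_holiday_calendar() over those years")
  }
  lt <- as.POSIXlt(dates)
  mon <- lt$mon + 1L
  out <- data.frame(
    winter = as.integer(mon %in% c(12L, 1L, 2L)),
    spring = as.integer(mon %in% 3:5),
    summer = as.integer(mon %in% 6:8),
    fall   = as.integer(mon %in% 9:11),
    weekend = as.integer(lt$wday %in% c(0L, 6L))
  )
  idx <- match(dates, calendar$date)
  for (col in c("federal", "christian", "muslim", "jewish", "hindu", "celebration")) {
    out[[col]] <- calendar[[col]][idx]
  }
  out
}
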