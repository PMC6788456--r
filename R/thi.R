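#' Temperature-humidity index from temperature and relative humidity
#'
#' Computes the THI used to quantify heat load on lactating cows:
#' \deqn{THI = (1.8\,temp + 32) - (0.55 - 0.55\,rh)(1.8\,temp - 26)}
#' with `temp` in degrees Celsius and `rh` a proportion in \[0, 1\].
#' Percent-scale humidity (values above 1) is rejected rather than silently
#' rescaled, because it would corrupt every downstream heat-load covariate;
#' divide by 100 on ingest (see [readHourlyWeather()]'s `rhPercent`).
#'
#' @param temp air temperature, degrees C (vectorised).
#' @param rh relative humidity as a proportion in \[0, 1\] (vectorised).
#' @return numeric vector of THI values (dimensionless).
#' @examples
#' hourlyTHI(30, 1.0)   # 86: at rh = 1 the humidity adjustment vanishes
#' hourlyTHI(25, 0.50)  # 71.775
#' @export
hourlyTHI <- function(temp, rh) {
  if (!all(is.finite(temp))) stop("temp must be finite")
  bad <- !is.finite(rh) | rh < 0 | rh > 1
  if (any(bad))
    stop("rh must be a proportion in [0,1]; offending value(s): ",
         paste(utils::head(rh[bad], 5), collapse = ", "),
         " (divide by 100 if humidity is on the percent scale)")
  (1.8 * temp + 32) - (0.55 - 0.55 * rh) * (1.8 * temp - 26)
}

#' Daily mean THI from hourly weather
#'
#' Averages hourly THI within each calendar day. Days with no data are absent
#' from the output; available hours are averaged without diurnal weighting,
#' and per-day hour coverage is reported so gaps are visible.
#'
#' @param hourly data.frame with columns `timestamp` (POSIXct or ISO-8601
#'   character), `temp` (deg C) and `rh` (proportion).
#' @return data.frame with columns `date` (Date), `thi` (daily mean) and
#'   `n_hours` (hours contributing).
#' @export
dailyMeanTHI <- function(hourly) {
  if (nrow(hourly) == 0L)
    return(data.frame(date = as.Date(character()), thi = numeric(),
                      n_hours = integer()))
  ts <- hourly$timestamp
  if (!inherits(ts, "POSIXt")) ts <- as.POSIXct(ts, tz = "UTC")
  day <- as.Date(ts, tz = "UTC")
  thi <- hourlyTHI(hourly$temp, hourly$rh)
  agg <- tapply(thi, day, mean)
  cnt <- tapply(thi, day, length)
  data.frame(date = as.Date(names(agg)), thi = as.numeric(agg),
             n_hours = as.integer(cnt), row.names = NULL)
}

#' THI assigned to a test day
#'
#' The heat load acting on a test-day record is taken as the mean of the
#' daily THI of the three calendar days immediately preceding the test day
#' (days t-3, t-2, t-1; the test day itself is excluded), reflecting the
#' lagged effect of heat on milk synthesis.
#'
#' @param daily data.frame as returned by [dailyMeanTHI()] (columns `date`,
#'   `thi`).
#' @param testDate Date (or coercible), the test day; vectorised.
#' @return numeric vector of assigned THI values, one per test date.
#' @examples
#' d <- data.frame(date = as.Date("2015-06-01") + 0:9, thi = 70:79)
#' assignTestDayTHI(d, as.Date("2015-06-05"))  # mean of days 2,3,4
#' @export
assignTestDayTHI <- function(daily, testDate) {
  testDate <- as.Date(testDate)
  lut <- stats::setNames(daily$thi, as.character(daily$date))
  vapply(testDate, function(td) {
    need <- td - 3:1
    v <- lut[as.character(need)]
    if (anyNA(v))
      stop("daily THI missing for date(s): ",
           paste(need[is.na(v)], collapse = ", "),
           " (required for test day ", td, ")")
    mean(v)
  }, numeric(1))
}

#' Broken-stick heat-load covariate f(THI)
#'
#' The reaction-norm covariate: zero at or below the comfort threshold and
#' rising one-for-one with THI above it,
#' \eqn{f(THI) = \max(0, THI - THI_{thr})}. The default threshold 68 marks
#' the onset of heat stress for lactating Holsteins.
#'
#' @param thi THI value(s).
#' @param thr threshold THI (default 68).
#' @return numeric vector of heat loads, all `>= 0`.
#' @examples
#' heatLoad(c(60, 68, 78))  # 0, 0, 10
#' @export
heatLoad <- function(thi, thr = 68) {
  if (!all(is.finite(thi))) stop("thi must be finite")
  pmax(0, thi - thr)
}

#' Read hourly weather from delimited text
#'
#' Expects columns `timestamp` (ISO-8601), `temp` (deg C) and `rh`. Humidity
#' is validated as a proportion; set `rhPercent = TRUE` when the source
#' records percent (divided by 100 on ingest).
#'
#' @param path file path.
#' @param rhPercent logical; humidity recorded as percent?
#' @param sep field separator (default tab).
#' @return data.frame with `timestamp` (POSIXct, UTC), `temp`, `rh`.
#' @export
readHourlyWeather <- function(path, rhPercent = FALSE, sep = "\t") {
  w <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("timestamp", "temp", "rh")
  if (!all(need %in% names(w)))
    stop("weather file must have columns: ", paste(need, collapse = ", "))
  w$timestamp <- as.POSIXct(w$timestamp, tz = "UTC")
  if (rhPercent) w$rh <- w$rh / 100
  if (any(w$rh < 0 | w$rh > 1, na.rm = TRUE))
    stop("rh outside [0,1] after ingest; use rhPercent = TRUE for percent data")
  if (is.unsorted(w$timestamp, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  w[, need]
}

#' Write a daily THI series as delimited text
#'
#' @param daily data.frame from [dailyMeanTHI()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDailyTHI <- function(daily, path) {
  utils::write.table(daily, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
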