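#' Read a daily weather table
#'
#' Expects a CSV with header `date,mean_temp,precip`: ISO-8601 dates, daily
#' mean temperature in degrees C and daily precipitation sum in mm. Rows are
#' sorted by date; duplicate dates and negative precipitation are rejected.
#' Gaps in the record are allowed (downstream functions flag excessive
#' missingness).
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `date` (Date), `mean_temp`, `precip`.
#' @export
read_daily_weather <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("date", "mean_temp", "precip")
  if (!all(req %in% names(d)))
    stop("weather CSV must have columns: ", paste(req, collapse = ", "))
  d$date <- as.Date(d$date)
  as_daily_weather(d[req])
}

#' Validate and normalise a daily weather data.frame
#'
#' @param records data.frame with columns `date`, `mean_temp`, `precip`.
#' @return the sorted, validated data.frame.
#' @export
as_daily_weather <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("date", "mean_temp", "precip") %in% names(records)))
  records <- records[order(records$date), , drop = FALSE]
  if (anyDuplicated(records$date))
    stop("duplicate dates in weather record")
  if (any(records$precip < 0, na.rm = TRUE))
    stop("negative precipitation in weather record")
  rownames(records) <- NULL
  records
}

winter_window <- function(winter_label) {
  c(start = as.Date(sprintf("%d-11-01", winter_label - 1)),
    end   = as.Date(sprintf("%d-04-30", winter_label)))
}

#' Rain-on-snow (ROS) index for one winter
#'
#' Sums precipitation recorded on days with mean temperature at or above
#' `temp_threshold` (default 1 degrees C, inclusive) over the winter window
#' 1 November--30 April, adds 1 and takes the natural log. The winter is
#' labelled by the calendar year in which it ends (the 1995/96 winter is
#' winter 1996). The result is a dimensionless icing/winter-harshness proxy
#' on a natural-log scale, >= 0 by construction.
#'
#' Missing days inside the window are skipped; if more than
#' `missing_tolerance` of the window is absent a warning is issued and the
#' computation proceeds over the available days. An empty window is an error.
#'
#' @param records daily weather data.frame (see [as_daily_weather()]).
#' @param winter_label integer year labelling the winter by its end.
#' @param temp_threshold warm-day temperature threshold in degrees C.
#' @param missing_tolerance maximal tolerated fraction of missing window days.
#' @return scalar log-scale ROS value.
#' @examples
#' w <- data.frame(date = seq(as.Date("1995-11-01"), as.Date("1996-04-30"), 1),
#'                 mean_temp = -10, precip = 0)
#' w$mean_temp[50] <- 2; w$precip[50] <- 10
#' compute_ros(w, 1996)  # log(11)
#' @export
compute_ros <- function(records, winter_label, temp_threshold = 1,
                        missing_tolerance = 0.1) {
  records <- as_daily_weather(records)
  win <- winter_window(winter_label)
  all_days <- seq(win[["start"]], win[["end"]], by = "day")
  sel <- records$date >= win[["start"]] & records$date <= win[["end"]]
  d <- records[sel & !is.na(records$mean_temp) & !is.na(records$precip), ]
  if (nrow(d) == 0L)
    stop("no winter data for winter ", winter_label)
  miss <- 1 - nrow(d) / length(all_days)
  if (miss > missing_tolerance)
    warning(sprintf("winter %d: %.0f%% of window days missing; ROS computed over available days",
                    winter_label, 100 * miss))
  warm <- d$mean_temp >= temp_threshold
  log1p(sum(d$precip[warm]))
}

trailing_mean <- function(x, k) {
  out <- rep(NA_real_, length(x))
  cs <- cumsum(ifelse(is.na(x), 0, x))
  nn <- cumsum(!is.na(x))
  for (i in seq_along(x)) {
    lo <- max(1L, i - k + 1L)
    n_avail <- nn[i] - if (lo > 1L) nn[lo - 1L] else 0
    if (n_avail > 0)
      out[i] <- (cs[i] - if (lo > 1L) cs[lo - 1L] else 0) / n_avail
  }
  out
}

#' Winter length for one winter
#'
#' Winter onset is the first autumn day (searched from `onset_search`,
#' default 1 September) on which the 10-day trailing running mean of daily
#' mean temperature is below 0 degrees C and remains below 0 for at least 10
#' consecutive days; winter end is the first day after the core winter
#' period (searched from `end_search`, default 1 May) on which the running
#' mean is above 0 and remains so for at least 10 consecutive days. The
#' returned length is `end - onset` in days.
#'
#' The running mean is trailing: the mean of the day itself and the 9
#' preceding days, computed over available (non-missing) days. "Remains" is
#' evaluated on the running-mean series itself: the candidate day and the 9
#' following days must all satisfy the sign condition.
#'
#' @param records daily weather data.frame covering at least 1 September of
#'   `winter_label - 1` through 31 July of `winter_label`.
#' @param winter_label integer year labelling the winter by its end.
#' @param run_window running-mean window length in days.
#' @param sustain required run of qualifying running-mean days.
#' @param onset_search,end_search month-day strings ("MM-DD") where the onset
#'   and end searches begin.
#' @return scalar winter length in days.
#' @export
compute_winter_length <- function(records, winter_label, run_window = 10,
                                  sustain = 10,
                                  onset_search = "09-01",
                                  end_search = "05-01") {
  records <- as_daily_weather(records)
  d0 <- as.Date(sprintf("%d-%s", winter_label - 1, onset_search))
  d_end_search <- as.Date(sprintf("%d-%s", winter_label, end_search))
  d1 <- as.Date(sprintf("%d-07-31", winter_label))
  # grid from 9 days before the search start so the trailing mean is full
  grid <- seq(d0 - (run_window - 1), max(d1, max(records$date)), by = "day")
  temp <- records$mean_temp[match(grid, records$date)]
  rm10 <- trailing_mean(temp, run_window)

  sustained <- function(cond, from_idx) {
    cond[is.na(cond)] <- FALSE
    idx <- which(cond)
    idx <- idx[idx >= from_idx]
    for (i in idx) {
      if (i + sustain - 1L > length(cond)) break
      if (all(cond[i:(i + sustain - 1L)])) return(i)
    }
    NA_integer_
  }

  i_on <- sustained(rm10 < 0, which(grid == d0))
  if (is.na(i_on)) stop("winter boundaries undetected (no onset) for winter ",
                        winter_label)
  i_off <- sustained(rm10 > 0, which(grid == d_end_search))
  if (is.na(i_off)) stop("winter boundaries undetected (no end) for winter ",
                         winter_label)
  as.numeric(grid[i_off] - grid[i_on])
}

#' Per-winter environmental covariates from a daily weather record
#'
#' Applies [compute_ros()] and [compute_winter_length()] to every winter in
#' `from:to` (winters labelled by their ending year).
#'
#' @param records daily weather data.frame.
#' @param from,to first and last winter label.
#' @param ... passed on to the per-winter functions.
#' @return data.frame with columns `winter`, `ros`, `winter_length`.
#' @export
winter_covariates <- function(records, from, to, ...) {
  records <- as_daily_weather(records)
  winters <- from:to
  data.frame(
    winter = winters,
    ros = vapply(winters, function(w) compute_ros(records, w, ...), 0),
    winter_length = vapply(winters, function(w)
      compute_winter_length(records, w), 0)
  )
}

#' Mean and standard deviation of winter length over a period
#'
#' @param covariates data.frame with columns `winter` and `winter_length`
#'   (see [winter_covariates()]).
#' @param period integer vector of winter labels to include (default: all).
#' @return named numeric vector `c(mean = , sd = )` in days; the sd uses the
#'   sample (n - 1) denominator.
#' @export
summarize_winter_length <- function(covariates, period = NULL) {
  x <- covariates
  if (!is.null(period)) x <- x[x$winter %in% period, ]
  if (nrow(x) < 2L) stop("need at least 2 winters to summarise winter length")
  c(mean = mean(x$winter_length), sd = stats::sd(x$winter_length))
}
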