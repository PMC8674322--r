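#' Median-filter smoothing with missing-value passthrough
#'
#' Replaces each observed point by the median of its centered window of
#' `kernel` points. Edges are handled by nearest-value padding (the first/last
#' value is repeated), so output length equals input length. Missing entries
#' are skipped when computing a window's median and stay missing in the
#' output. A kernel of 3 is the smallest that removes isolated one-minute
#' outliers.
#'
#' @param series numeric vector, `NA` allowed.
#' @param kernel odd positive integer window size.
#' @return smoothed numeric vector of the same length.
#' @examples
#' medianSmooth(c(0, 100, 0))   # the spike is removed: 0 0 0
#' @export
medianSmooth <- function(series, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("'kernel' must be an odd positive integer")
  n <- length(series)
  if (n == 0L || kernel == 1L) return(series)
  h <- (kernel - 1L) %/% 2L
  # fast path: ternary median without missing values
  if (kernel == 3L && !anyNA(series)) {
    a <- c(series[1], series[-n]); b <- series; c_ <- c(series[-1], series[n])
    return(pmax(pmin(a, b), pmin(pmax(a, b), c_)))
  }
  xp <- c(rep(series[1], h), series, rep(series[n], h))
  out <- series
  for (i in which(!is.na(series))) {
    w <- xp[i:(i + kernel - 1L)]
    out[i] <- stats::median(w[!is.na(w)])
  }
  out
}

#' Merge duplicate sensors into one per-minute series
#'
#' When more than one sensor monitors the same site/location/variable, the
#' minute-level values are averaged over the sensors that reported; a minute
#' is missing only when every sensor is missing. The output covers the full
#' minute grid from the earliest to the latest timestamp in the group.
#'
#' @param records data.frame with columns `timestamp` (POSIXct), `sensor`,
#'   `value`, and constant `site`, `location`, `variable` columns (mixed
#'   groups are rejected).
#' @return data.frame with `timestamp` and `value` on a uniform minute grid.
#' @export
mergeDuplicateSensors <- function(records) {
  need <- c("timestamp", "site", "location", "variable", "sensor", "value")
  if (!all(need %in% colnames(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  for (col in c("site", "location", "variable"))
    if (length(unique(records[[col]])) > 1L)
      stop("records mix multiple values of '", col,
           "'; merge operates within one site/location/variable group")
  if (nrow(records) == 0L)
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      value = numeric()))
  grid <- seq(min(records$timestamp), max(records$timestamp), by = "1 min")
  sensors <- unique(records$sensor)
  vals <- matrix(NA_real_, length(grid), length(sensors))
  for (k in seq_along(sensors)) {
    r <- records[records$sensor == sensors[k], ]
    if (anyDuplicated(r$timestamp))
      stop("duplicate timestamps within sensor '", sensors[k], "'")
    vals[match(as.numeric(r$timestamp), as.numeric(grid)), k] <- r$value
  }
  m <- rowMeans(vals, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  data.frame(timestamp = grid, value = m)
}

#' Truncate long gaps, interpolate short ones
#'
#' Runs of consecutive missing values shorter than `max_gap` are filled by
#' linear interpolation between the flanking observed values (bidirectional:
#' both neighbors are required, so boundary gaps are never extrapolated).
#' Runs of `max_gap` or more are left missing — those intervals are reported
#' and will make their day windows fail the completeness rule downstream.
#'
#' @param series numeric vector on a uniform minute grid, `NA` allowed.
#' @param max_gap gap length (minutes) at or above which a run is truncated
#'   rather than interpolated (default 60: sub-hour gaps are filled).
#' @return list with `values` (the filled series) and `removed`, a data.frame
#'   of untouched intervals (`start`, `end` indices and `length`).
#' @export
fillGaps <- function(series, max_gap = 60L) {
  n <- length(series)
  removed <- data.frame(start = integer(), end = integer(), length = integer())
  if (n == 0L || !anyNA(series))
    return(list(values = series, removed = removed))
  r <- rle(is.na(series))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- series
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]; len <- e - s + 1L
    boundary <- s == 1L || e == n
    if (!boundary && len < max_gap) {
      x0 <- series[s - 1L]; x1 <- series[e + 1L]
      out[s:e] <- x0 + (x1 - x0) * seq_len(len) / (len + 1L)
    } else {
      removed <- rbind(removed,
                       data.frame(start = s, end = e, length = len))
    }
  }
  list(values = out, removed = removed)
}

#' Min-max rescaling per group
#'
#' Maps values to `[0, 1]` with the group-wide minimum and maximum taken over
#' *all* days and sites within each group (so between-day amplitude
#' differences survive scaling). The realized `(min, max)` pairs are returned
#' for inversion.
#'
#' @param data data.frame with a numeric `value` column (`NA` allowed and
#'   ignored for range computation).
#' @param per character vector of grouping column names (default
#'   `c("variable", "location")`).
#' @return list with `data` (values rescaled in place) and `ranges`
#'   (one row per group: grouping columns, `min`, `max`).
#' @export
rescaleMinmax <- function(data, per = c("variable", "location")) {
  if (!"value" %in% colnames(data)) stop("'data' must have a 'value' column")
  if (!all(per %in% colnames(data)))
    stop("grouping columns missing: ", paste(setdiff(per, colnames(data)), collapse = ", "))
  key <- if (length(per)) do.call(paste, c(data[per], sep = "|")) else rep("all", nrow(data))
  ranges <- NULL
  for (g in unique(key)) {
    idx <- key == g
    v <- data$value[idx]
    lo <- suppressWarnings(min(v, na.rm = TRUE))
    hi <- suppressWarnings(max(v, na.rm = TRUE))
    if (!is.finite(lo) || !is.finite(hi) || hi == lo)
      stop("constant or empty group '", g, "': min-max scaling undefined")
    data$value[idx] <- (v - lo) / (hi - lo)
    ranges <- rbind(ranges, data.frame(group = g, min = lo, max = hi))
  }
  list(data = data, ranges = ranges)
}

#' Cut a minute stream into complete day windows
#'
#' Non-overlapping 1440-minute windows anchored at `window_start` (20:00 by
#' default, matching evening questionnaire time). Windows with fewer than 1440
#' timestamps or any remaining missing value are dropped. The window's date is
#' the calendar date of its start, and its season follows the meteorological
#' convention of [seasonOf()].
#'
#' @param stream data.frame with `timestamp` (POSIXct, uniform minute grid)
#'   and `value` (`NA` allowed).
#' @param window_start clock time `"HH:MM"`.
#' @return list with `values` (1440 x n matrix, possibly 0 columns) and
#'   `info` (data.frame: `date`, `season`).
#' @export
windowDays <- function(stream, window_start = "20:00") {
  day_len <- 1440L
  empty <- list(values = matrix(numeric(0), day_len, 0),
                info = data.frame(date = as.Date(character()), season = character()))
  if (nrow(stream) == 0L) return(empty)
  ws <- .clock_minutes(window_start)
  tt <- stream$timestamp
  clock <- as.integer(format(tt, "%H")) * 60L + as.integer(format(tt, "%M"))
  first <- which(clock == ws)[1]
  if (is.na(first)) return(empty)
  cols <- list(); dates <- as.Date(character())
  s <- first
  while (s + day_len - 1L <= nrow(stream)) {
    v <- stream$value[s:(s + day_len - 1L)]
    if (!anyNA(v)) {
      cols[[length(cols) + 1L]] <- v
      dates <- c(dates, as.Date(format(tt[s], "%Y-%m-%d")))
    }
    s <- s + day_len
  }
  if (!length(cols)) return(empty)
  list(values = do.call(cbind, cols),
       info = data.frame(date = dates, season = seasonOf(dates)))
}

#' Attach daily outcomes to day observations
#'
#' Left join on `site` + window-start `date`: matched days get the binary
#' outcome, unmatched days keep `NA` (they are excluded from outcome overlays
#' but retained for clustering). Duplicate outcome rows per site-date are
#' rejected.
#'
#' @param info data.frame of day metadata with `site` and `date` columns.
#' @param outcomes data.frame with `site`, `date`, `outcome` (or `NULL`).
#' @return `info` with an `outcome` column.
#' @export
matchOutcomes <- function(info, outcomes = NULL) {
  if (is.null(outcomes)) { info$outcome <- NA_integer_; return(info) }
  need <- c("site", "date", "outcome")
  if (!all(need %in% colnames(outcomes)))
    stop("outcomes must have columns: ", paste(need, collapse = ", "))
  key_out <- paste(outcomes$site, as.Date(outcomes$date))
  if (anyDuplicated(key_out))
    stop("duplicate outcome rows for site-date: ",
         paste(unique(key_out[duplicated(key_out)]), collapse = ", "))
  info$outcome <- outcomes$outcome[match(paste(info$site, as.Date(info$date)),
                                         key_out)]
  info
}

#' Full preprocessing chain: raw records to complete daily observations
#'
#' Applies the cleaning stages in fixed order — median smoothing per sensor
#' stream, duplicate-sensor averaging, truncation of gaps of an hour or more
#' plus linear interpolation of shorter ones, min-max scaling of pollutant
#' values to `[0, 1]` (group-wide per variable and location), windowing into
#' complete 1440-minute days anchored at 20:00, and outcome matching.
#' Temperature is left in native units unless `scale_temperature = TRUE`.
#'
#' @param records long-format data.frame (`timestamp`, `site`, `location`,
#'   `variable`, `sensor`, `value`).
#' @param outcomes optional data.frame (`site`, `date`, `outcome`).
#' @param kernel median-filter window (odd, default 3).
#' @param max_gap gap-truncation threshold in minutes (default 60).
#' @param window_start day-window anchor clock time (default `"20:00"`).
#' @param scale_temperature also min-max scale temperature (default `FALSE`;
#'   only pollutant values are scaled).
#' @return An [ExposureDays] object; `metadata()` holds `removed` (truncated
#'   gap intervals per stream) and `ranges` (min-max scaling parameters).
#' @export
preprocessExposures <- function(records, outcomes = NULL, kernel = 3L,
                                max_gap = 60L, window_start = "20:00",
                                scale_temperature = FALSE) {
  need <- c("timestamp", "site", "location", "variable", "sensor", "value")
  if (!all(need %in% colnames(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))

  # 1) median smoothing per sensor stream
  skey <- paste(records$site, records$location, records$variable, records$sensor)
  records <- records[order(skey, records$timestamp), ]
  skey <- sort(skey)
  records$value <- unlist(lapply(split(records$value, skey),
                                 medianSmooth, kernel = kernel),
                          use.names = FALSE)

  # 2) duplicate-sensor averaging + 3) gap truncation/interpolation, per group
  gkey <- paste(records$site, records$location, records$variable, sep = "|")
  streams <- list(); removed <- NULL
  for (g in unique(gkey)) {
    sub <- records[gkey == g, ]
    merged <- mergeDuplicateSensors(sub)
    fg <- fillGaps(merged$value, max_gap = max_gap)
    merged$value <- fg$values
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    merged$site <- parts[1]; merged$location <- parts[2]; merged$variable <- parts[3]
    streams[[g]] <- merged
    if (nrow(fg$removed)) {
      fg$removed$stream <- g
      removed <- rbind(removed, fg$removed)
    }
  }
  long <- do.call(rbind, streams)

  # 4) min-max scaling of pollutant values (and optionally temperature)
  scale_rows <- long$variable == "pm" |
    (scale_temperature & long$variable == "temperature")
  ranges <- NULL
  if (any(scale_rows)) {
    sc <- rescaleMinmax(long[scale_rows, ], per = c("variable", "location"))
    long$value[scale_rows] <- sc$data$value
    ranges <- sc$ranges
  }

  # 5) windowing into complete days + 6) outcome matching
  vals <- NULL; info <- NULL
  gkey2 <- paste(long$site, long$location, long$variable, sep = "|")
  for (g in unique(gkey2)) {
    sub <- long[gkey2 == g, c("timestamp", "value")]
    wd <- windowDays(sub, window_start = window_start)
    if (!ncol(wd$values)) next
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    wd$info$site <- parts[1]; wd$info$location <- parts[2]
    wd$info$variable <- parts[3]
    vals <- cbind(vals, wd$values)
    info <- rbind(info, wd$info)
  }
  if (is.null(vals)) {
    vals <- matrix(numeric(0), 1440, 0)
    info <- data.frame(site = character(), date = as.Date(character()),
                       variable = character(), location = character(),
                       season = character())
  }
  info <- matchOutcomes(info, outcomes)
  ExposureDays(vals, info,
               metadata = list(removed = removed, ranges = ranges,
                               window_start = window_start))
}
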