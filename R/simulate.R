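#' Season of a calendar date
#'
#' Meteorological seasons by month: Dec-Feb winter, Mar-May spring, Jun-Aug
#' summer, Sep-Nov fall.
#'
#' @param date a `Date` vector.
#' @return character vector of season labels.
#' @export
seasonOf <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "fall", "fall", "fall", "winter")[m]
}

#' Default seasonal model for outdoor temperature
#'
#' Baseline (night-time level, deg C) and diurnal amplitude per meteorological
#' season, loosely matching a mid-latitude continental climate: cold flat
#' winters, warm summers with pronounced noon peaks.
#'
#' @return named list of `list(baseline=, amplitude=)` per season.
#' @export
defaultSeasonModel <- function() {
  list(winter = list(baseline = 0,  amplitude = 6),
       spring = list(baseline = 10, amplitude = 8),
       summer = list(baseline = 20, amplitude = 10),
       fall   = list(baseline = 10, amplitude = 8))
}

.sim_fields <- c("n_sites", "n_days", "day_length", "variables", "season_model",
                 "warp_magnitude", "noise_sd", "spike_rate",
                 "spike_time_jitter_sd", "missing_gap_rate",
                 "outcome_logit_coefs", "start_date", "window_start", "seed")

#' Build a simulation configuration
#'
#' Describes a synthetic panel of households carrying indoor/outdoor
#' temperature and PM2.5 sensors at minute resolution. Defaults emulate the
#' motivating study design: 7 sites, four variables, 1440-minute days windowed
#' at 20:00, duplicated indoor sensors, random monotone time warps of up to 30
#' minutes, occasional data gaps, and a daily binary outcome (inhaler use)
#' driven logistically by indoor-PM spike count and day-level variability.
#'
#' @param n_sites positive integer number of sites (households).
#' @param n_days nonnegative integer days per site (0 gives empty output).
#' @param day_length positive integer samples per day window (>= 2). The
#'   diurnal cycle always spans the window, so 1440 is a minute-resolution
#'   day and smaller values give coarser test-scale days.
#' @param variables subset of `outdoor_temperature`, `indoor_temperature`,
#'   `outdoor_pm`, `indoor_pm`.
#' @param season_model per-season baseline/amplitude for outdoor temperature,
#'   see [defaultSeasonModel()].
#' @param warp_magnitude nonnegative maximum timestamp displacement (samples;
#'   minutes when `day_length = 1440`) of the random monotone warp applied to
#'   every day.
#' @param noise_sd nonnegative additive Gaussian sensor noise SD (native
#'   units).
#' @param spike_rate expected number of PM spikes per day (Poisson).
#' @param spike_time_jitter_sd SD (minutes) of the jitter on spike clock times
#'   around the morning/evening cooking anchors.
#' @param missing_gap_rate expected missing-data gaps per sensor-day; gap
#'   lengths are a mixture of short (< 1 h, interpolatable) and long (>= 1 h,
#'   truncating) runs.
#' @param outcome_logit_coefs `c(intercept, spike-count coef, daily-SD coef)`
#'   of the logistic outcome model on standardized indoor-PM day features.
#' @param start_date first calendar date.
#' @param window_start clock time `"HH:MM"` at which day windows start.
#' @param seed integer; identical configs produce byte-identical output.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(n_sites = 7L, n_days = 30L, day_length = 1440L,
                      variables = c("outdoor_temperature", "indoor_temperature",
                                    "outdoor_pm", "indoor_pm"),
                      season_model = defaultSeasonModel(),
                      warp_magnitude = 30, noise_sd = 0.5, spike_rate = 2,
                      spike_time_jitter_sd = 30, missing_gap_rate = 0.2,
                      outcome_logit_coefs = c(-0.5, 0.8, 0.5),
                      start_date = as.Date("2017-04-01"),
                      window_start = "20:00", seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), n_days = as.integer(n_days),
              day_length = as.integer(day_length),
              variables = as.character(variables), season_model = season_model,
              warp_magnitude = as.numeric(warp_magnitude),
              noise_sd = as.numeric(noise_sd), spike_rate = as.numeric(spike_rate),
              spike_time_jitter_sd = as.numeric(spike_time_jitter_sd),
              missing_gap_rate = as.numeric(missing_gap_rate),
              outcome_logit_coefs = as.numeric(outcome_logit_coefs),
              start_date = as.Date(start_date),
              window_start = as.character(window_start), seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) if (!ok) stop("invalid SimConfig field '",
                                                field, "': ", why)
  chk(cfg$n_sites >= 1L, "n_sites", "must be a positive integer")
  chk(cfg$n_days >= 0L, "n_days", "must be nonnegative")
  chk(cfg$day_length >= 2L, "day_length", "must be >= 2")
  ok_vars <- c("outdoor_temperature", "indoor_temperature", "outdoor_pm", "indoor_pm")
  chk(length(cfg$variables) >= 1L && all(cfg$variables %in% ok_vars),
      "variables", paste("must be a subset of", paste(ok_vars, collapse = ", ")))
  chk(cfg$warp_magnitude >= 0, "warp_magnitude", "must be >= 0")
  chk(cfg$warp_magnitude < cfg$day_length / 2, "warp_magnitude",
      "must be < day_length/2 (degenerate warp)")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(cfg$spike_rate >= 0, "spike_rate", "must be >= 0")
  chk(cfg$spike_time_jitter_sd >= 0, "spike_time_jitter_sd", "must be >= 0")
  chk(cfg$missing_gap_rate >= 0, "missing_gap_rate", "must be >= 0")
  chk(length(cfg$outcome_logit_coefs) == 3L, "outcome_logit_coefs",
      "must have length 3 (intercept, spike-count, daily-SD)")
  chk(all(names(cfg$season_model) %in% c("winter", "spring", "summer", "fall")) &&
        length(cfg$season_model) >= 1L, "season_model",
      "must be named by season with baseline/amplitude entries")
  invisible(cfg)
}

#' Apply a random monotone time warp to a series
#'
#' Resamples the series through a strictly increasing, endpoint-fixed
#' piecewise-linear time map with 4 interior knots whose displacements are
#' drawn uniformly from `[-warp_magnitude, warp_magnitude]`. The maximum
#' displacement of any timestamp is bounded by `warp_magnitude`, and output
#' length equals input length. This is the timing variability (shifted peaks,
#' earlier/later dinners) that warping-based matching is designed to absorb.
#'
#' @param series gap-free numeric vector.
#' @param warp_magnitude nonnegative maximum timestamp displacement (samples);
#'   must be `< length(series)/2`.
#' @param seed optional integer; `NULL` draws from the current RNG stream.
#' @param time_map optional explicit source-time vector `f` of the same length
#'   as `series` (strictly increasing, `f[1] = 0`, `f[T] = T - 1`, 0-based):
#'   output `t` takes the interpolated value of the input at time `f[t]`.
#'   Overrides the random map.
#' @return The warped series, with the realized source-time map attached as
#'   attribute `"time_map"`.
#' @export
applyWarp <- function(series, warp_magnitude, seed = NULL, time_map = NULL) {
  .check_series(series, "series")
  n <- length(series)
  tgrid <- seq.int(0, n - 1)
  if (!is.null(time_map)) {
    if (length(time_map) != n || any(diff(time_map) <= 0) ||
        abs(time_map[1]) > 1e-9 || abs(time_map[n] - (n - 1)) > 1e-9)
      stop("'time_map' must be strictly increasing with fixed endpoints 0 and T-1")
    out <- stats::approx(tgrid, series, xout = time_map)$y
    attr(out, "time_map") <- time_map
    return(out)
  }
  if (warp_magnitude < 0) stop("'warp_magnitude' must be >= 0")
  if (warp_magnitude >= n / 2)
    stop("'warp_magnitude' must be < length(series)/2 (degenerate warp)")
  if (warp_magnitude == 0) {
    attr(series, "time_map") <- tgrid
    return(series)
  }
  draw_map <- function() {
    knots <- seq(0, n - 1, length.out = 6)  # endpoints + 4 interior knots
    for (k in seq_len(200)) {
      g <- knots + c(0, stats::runif(4, -warp_magnitude, warp_magnitude), 0)
      if (all(diff(g) > 0)) break
    }
    if (any(diff(g) <= 0))
      stop("could not draw a strictly increasing time map; lower 'warp_magnitude'")
    stats::approx(knots, g, xout = tgrid)$y
  }
  f <- if (is.null(seed)) draw_map() else withr::with_seed(seed, draw_map())
  out <- stats::approx(tgrid, series, xout = f)$y
  attr(out, "time_map") <- f
  out
}

# Smooth diurnal temperature prototype: baseline at night, half-sine solar
# gain between sunrise (06:00) and sunset (18:00), peaking at noon. `t` runs
# over the day window which starts at `window_start` clock minutes.
.temperature_prototype <- function(day_length, baseline, amplitude,
                                   window_start_min) {
  u <- ((window_start_min / 1440 + seq.int(0, day_length - 1) / day_length) %% 1)
  s <- sin(pi * (u - 0.25) / 0.5)          # positive between 06:00 and 18:00
  baseline + amplitude * pmax(s, 0)
}

# PM prototype: low baseline plus Gaussian-shaped spikes (SD 20 min in clock
# time) centred at jittered morning/evening anchors. Returns the series and
# the spike clock times (minutes of day).
.pm_prototype <- function(day_length, baseline, n_spikes, amp_range,
                          jitter_sd, window_start_min) {
  minute_of_day <- (window_start_min + seq.int(0, day_length - 1) *
                      (1440 / day_length)) %% 1440
  vals <- rep(baseline, day_length)
  times <- numeric(0)
  if (n_spikes > 0) {
    anchors <- sample(c(450, 1110), n_spikes, replace = TRUE)  # 07:30, 18:30
    times <- (anchors + stats::rnorm(n_spikes, 0, jitter_sd)) %% 1440
    amps <- stats::runif(n_spikes, amp_range[1], amp_range[2])
    for (k in seq_len(n_spikes)) {
      d <- abs(minute_of_day - times[k])
      d <- pmin(d, 1440 - d)               # circular clock distance
      vals <- vals + amps[k] * exp(-d^2 / (2 * 20^2))
    }
  }
  list(values = vals, spike_times = times)
}

.clock_minutes <- function(hhmm) {
  p <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}

#' Generate a synthetic exposure dataset with ground truth
#'
#' Produces minute-level long-format sensor records (one or two sensors per
#' microenvironment), plus a ground-truth table recording, per site-day and
#' variable, the prototype used, its season, the realized warp, spike times
#' and the daily outcome. Temperature days are smooth noon-peaked curves whose
#' baseline and amplitude follow the seasonal model; PM days are a low
#' baseline with Poisson-count combustion-like spikes at jittered clock times.
#' Each prototype day is passed through [applyWarp()], gets additive Gaussian
#' sensor noise per sensor, and may lose data to randomly placed gaps (a
#' mixture of sub-hour and multi-hour runs). Daily outcomes are Bernoulli with
#' a logistic model on the standardized indoor-PM spike count and daily SD.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `records` (data.frame: `timestamp`, `site`,
#'   `location`, `variable`, `sensor`, `value`), `truth` (one row per
#'   site-day-variable) and `outcomes` (site, date, outcome).
#' @export
simulateExposure <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .validate_sim_config(config)
  withr::with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  empty_records <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                              site = character(), location = character(),
                              variable = character(), sensor = character(),
                              value = numeric())
  empty_truth <- data.frame(site = character(), date = as.Date(character()),
                            variable = character(), location = character(),
                            prototype = character(), season = character(),
                            warp_max_disp = numeric(), n_spikes = integer(),
                            spike_times = character(), outcome = integer())
  empty_out <- data.frame(site = character(), date = as.Date(character()),
                          outcome = integer())
  if (cfg$n_days == 0L)
    return(list(records = empty_records, truth = empty_truth,
                outcomes = empty_out))

  ws_min <- .clock_minutes(cfg$window_start)
  sites <- sprintf("site%d", seq_len(cfg$n_sites))
  # mild site-level heterogeneity, drawn once
  site_temp_offset <- stats::rnorm(cfg$n_sites, 0, 1)
  site_pm_scale <- stats::runif(cfg$n_sites, 0.8, 1.2)

  rec_list <- list(); truth_list <- list()
  feat <- list()  # per site-day indoor-PM features for the outcome model

  for (si in seq_along(sites)) {
    for (d in seq_len(cfg$n_days)) {
      date <- cfg$start_date + (d - 1L)
      start_time <- as.POSIXct(paste(date, cfg$window_start), tz = "UTC")
      times <- start_time + 60 * seq.int(0, cfg$day_length - 1)
      season <- seasonOf(date)
      sm <- cfg$season_model[[season]]
      if (is.null(sm)) sm <- list(baseline = 10, amplitude = 8)

      day_spikes <- NA_integer_; day_sd <- NA_real_
      for (v in cfg$variables) {
        location <- if (startsWith(v, "indoor")) "indoor" else "outdoor"
        varname <- if (endsWith(v, "temperature")) "temperature" else "pm"
        n_spk <- 0L; spk_times <- numeric(0)
        if (varname == "temperature") {
          if (location == "outdoor") {
            proto <- .temperature_prototype(cfg$day_length,
                                            sm$baseline + site_temp_offset[si],
                                            sm$amplitude, ws_min)
            pname <- paste0(season, "_outdoor_temperature")
          } else {
            proto <- .temperature_prototype(cfg$day_length,
                                            19 + 0.1 * sm$baseline, 1.5, ws_min)
            pname <- paste0(season, "_indoor_temperature")
          }
        } else {
          n_spk <- stats::rpois(1, cfg$spike_rate)
          amp_range <- if (location == "indoor") c(20, 80) else c(5, 20)
          base <- (if (location == "indoor") 5 else 8) * site_pm_scale[si]
          pm <- .pm_prototype(cfg$day_length, base, n_spk, amp_range,
                              cfg$spike_time_jitter_sd, ws_min)
          proto <- pm$values; spk_times <- pm$spike_times
          pname <- paste0(location, "_pm")
        }
        warped <- applyWarp(proto, cfg$warp_magnitude)
        fmap <- attr(warped, "time_map")
        warped <- as.numeric(warped)
        if (v == "indoor_pm") { day_spikes <- n_spk; day_sd <- stats::sd(warped) }

        sensors <- if (location == "indoor") c("A", "B") else "A"
        for (sn in sensors) {
          vals <- warped + stats::rnorm(cfg$day_length, 0, cfg$noise_sd)
          # insert missing gaps: mixture of short (< 1 h) and long (>= 1 h)
          n_gaps <- stats::rpois(1, cfg$missing_gap_rate)
          for (g in seq_len(n_gaps)) {
            len <- if (stats::runif(1) < 0.3)
              as.integer(stats::runif(1, 61, 180)) else
              as.integer(stats::runif(1, 5, 45))
            len <- min(len, cfg$day_length)
            st <- sample.int(cfg$day_length - len + 1L, 1)
            vals[st:(st + len - 1L)] <- NA_real_
          }
          rec_list[[length(rec_list) + 1L]] <- data.frame(
            timestamp = times, site = sites[si], location = location,
            variable = varname, sensor = sn, value = vals)
        }
        truth_list[[length(truth_list) + 1L]] <- data.frame(
          site = sites[si], date = date, variable = varname,
          location = location, prototype = pname, season = season,
          warp_max_disp = max(abs(fmap - seq.int(0, cfg$day_length - 1))),
          n_spikes = n_spk,
          spike_times = paste(round(spk_times, 1), collapse = ";"),
          outcome = NA_integer_)
      }
      feat[[length(feat) + 1L]] <- data.frame(site = sites[si], date = date,
                                              n_spikes = day_spikes,
                                              day_sd = day_sd)
    }
  }

  records <- do.call(rbind, rec_list)
  truth <- do.call(rbind, truth_list)
  fe <- do.call(rbind, feat)

  # logistic outcome on standardized day features (zeros when degenerate)
  zs <- function(x) {
    x[is.na(x)] <- 0
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  co <- cfg$outcome_logit_coefs
  p <- stats::plogis(co[1] + co[2] * zs(fe$n_spikes) + co[3] * zs(fe$day_sd))
  fe$outcome <- stats::rbinom(nrow(fe), 1, p)
  outcomes <- fe[, c("site", "date", "outcome")]

  key <- paste(truth$site, truth$date)
  truth$outcome <- outcomes$outcome[match(key, paste(outcomes$site, outcomes$date))]
  rownames(records) <- NULL; rownames(truth) <- NULL; rownames(outcomes) <- NULL
  list(records = records, truth = truth, outcomes = outcomes)
}

#' Warped-prototype benchmark datasets
#'
#' Small, fully synthetic datasets used to study how training rules cope with
#' timing variability, at a reduced series length for tractability.
#'
#' `simulatePrototypeDays()` draws `n` day-series from `k` seasonal outdoor
#' temperature prototypes (winter/spring/summer shapes from
#' [defaultSeasonModel()]), each randomly warped and noised — smooth, broad
#' diurnal shapes whose warps are small relative to feature width.
#'
#' `simulateImpulseDays()` draws `n` copies of a single Gaussian-bump
#' prototype (peak 1, baseline 0) whose position is displaced by a random
#' monotone warp — the sharp-feature regime where timestamp-aligned averaging
#' flattens the peak.
#'
#' @param n number of day-series.
#' @param len series length (samples per day).
#' @param k number of prototypes (up to 3: winter, summer, spring).
#' @param warp_magnitude maximum timestamp displacement, in samples.
#' @param noise_sd additive Gaussian noise SD.
#' @param bump_sd impulse width (samples) for the impulse dataset.
#' @param seed integer seed.
#' @return list with `values` (`len x n` matrix), `prototypes` (`len x k`
#'   matrix or `len x 1`), and `labels` (prototype index per column).
#' @export
simulatePrototypeDays <- function(n = 200, len = 144, k = 3,
                                  warp_magnitude = 6, noise_sd = 0.5,
                                  seed = 1L) {
  stopifnot(k >= 1, k <= 3, n >= 1, len >= 8)
  sm <- defaultSeasonModel()
  seasons <- c("winter", "summer", "spring")[seq_len(k)]
  ws_min <- 1200  # windows anchored at 20:00, as in the full-scale generator
  protos <- vapply(seasons, function(s)
    .temperature_prototype(len, sm[[s]]$baseline, sm[[s]]$amplitude, ws_min),
    numeric(len))
  withr::with_seed(seed, {
    labels <- sample(rep_len(seq_len(k), n))
    vals <- vapply(labels, function(l) {
      as.numeric(applyWarp(protos[, l], warp_magnitude)) +
        stats::rnorm(len, 0, noise_sd)
    }, numeric(len))
  })
  list(values = vals, prototypes = protos, labels = labels)
}

#' @rdname simulatePrototypeDays
#' @export
simulateImpulseDays <- function(n = 60, len = 144, warp_magnitude = 30,
                                bump_sd = 6, noise_sd = 0.01, seed = 1L) {
  stopifnot(n >= 1, len >= 8, warp_magnitude < len / 2)
  t0 <- seq_len(len) - 1
  proto <- exp(-(t0 - len %/% 2)^2 / (2 * bump_sd^2))  # peak exactly 1, on-grid
  withr::with_seed(seed, {
    vals <- vapply(seq_len(n), function(i) {
      as.numeric(applyWarp(proto, warp_magnitude)) +
        stats::rnorm(len, 0, noise_sd)
    }, numeric(len))
  })
  list(values = vals, prototypes = matrix(proto, ncol = 1),
       labels = rep(1L, n))
}
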