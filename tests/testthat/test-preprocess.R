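test_that("median smoothing removes isolated spikes and keeps edges sane", {
  expect_equal(medianSmooth(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  expect_equal(medianSmooth(c(0, 100, 0)), c(0, 0, 0))
  expect_equal(medianSmooth(c(1, 9, 1, 1)), c(1, 1, 1, 1))
  expect_error(medianSmooth(1:5, kernel = 2), "odd")
  expect_equal(medianSmooth(numeric(0)), numeric(0))
  # missing stays missing; windows skip missing entries
  x <- c(1, NA, 9, 1, 1)
  s <- medianSmooth(x)
  expect_true(is.na(s[2]))
  expect_equal(s[3], median(c(9, 1)))   # window (NA, 9, 1) skips the NA
  expect_equal(medianSmooth(c(2, 4, 6, 8, 10), kernel = 5),
               c(2, 4, 6, 8, 10))       # nearest-value padding at both edges
})

test_that("duplicate sensors are averaged per minute, missing only when all miss", {
  t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  rec <- function(sensor, vals) data.frame(
    timestamp = t0 + 60 * (seq_along(vals) - 1), site = "s", location = "indoor",
    variable = "pm", sensor = sensor, value = vals)
  one <- mergeDuplicateSensors(rec("A", c(1, 2, 3)))
  expect_equal(one$value, c(1, 2, 3))
  two <- mergeDuplicateSensors(rbind(rec("A", c(10, NA, NA)),
                                     rec("B", c(20, 7, NA))))
  expect_equal(two$value, c(15, 7, NA))
  bad <- rbind(rec("A", 1:3), rec("B", 1:3))
  bad$variable[4] <- "temperature"
  expect_error(mergeDuplicateSensors(bad), "variable")
})

test_that("gap filling interpolates short runs and truncates long or boundary ones", {
  clean <- fillGaps(c(1, 2, 3))
  expect_equal(clean$values, c(1, 2, 3))
  expect_equal(nrow(clean$removed), 0)
  # linear interpolation between flanking values
  f <- fillGaps(c(0, NA, NA, 3))
  expect_equal(f$values, c(0, 1, 2, 3))
  # a 61-minute run is left missing and reported
  x <- c(rnorm(100), rep(NA, 61), rnorm(100))
  g <- fillGaps(x, max_gap = 60)
  expect_true(all(is.na(g$values[101:161])))
  expect_equal(g$removed, data.frame(start = 101L, end = 161L, length = 61L))
  # exactly 60 minutes is assigned to truncation, 59 to interpolation
  x60 <- c(0, rep(NA, 60), 1); x59 <- c(0, rep(NA, 59), 1)
  expect_true(all(is.na(fillGaps(x60)$values[2:61])))
  expect_false(anyNA(fillGaps(x59)$values))
  # boundary gaps are never extrapolated
  b <- fillGaps(c(NA, NA, 5, 6))
  expect_true(all(is.na(b$values[1:2])))
  expect_equal(b$removed$length, 2L)
})

test_that("min-max scaling uses group-wide ranges and rejects constant groups", {
  d <- data.frame(variable = "pm", location = "indoor", value = c(10, 20, 30))
  r <- rescaleMinmax(d)
  expect_equal(r$data$value, c(0, 0.5, 1))
  expect_equal(r$ranges$min, 10); expect_equal(r$ranges$max, 30)
  d01 <- data.frame(variable = "pm", location = "o", value = c(0, 0.25, 1))
  expect_equal(rescaleMinmax(d01)$data$value, c(0, 0.25, 1))
  dc <- data.frame(variable = "pm", location = "indoor", value = rep(4, 5))
  expect_error(rescaleMinmax(dc), "pm\\|indoor")
})

test_that("day windowing keeps only complete 1440-minute windows with seasons", {
  t0 <- as.POSIXct("2017-06-01 20:00:00", tz = "UTC")
  mk <- function(n, vals) data.frame(timestamp = t0 + 60 * (seq_len(n) - 1),
                                     value = vals)
  expect_equal(ncol(windowDays(mk(720, rnorm(720)))$values), 0)  # 12 h only
  wd <- windowDays(mk(3 * 1440, rnorm(3 * 1440)))
  expect_equal(ncol(wd$values), 3)
  expect_equal(nrow(wd$values), 1440)
  expect_equal(wd$info$season, rep("summer", 3))
  expect_equal(wd$info$date, as.Date("2017-06-01") + 0:2)
  # a day containing an unfilled gap is dropped
  v <- rnorm(3 * 1440); v[2000] <- NA
  expect_equal(ncol(windowDays(mk(3 * 1440, v))$values), 2)
})

test_that("outcome matching joins on site and date and rejects duplicates", {
  info <- data.frame(site = "s1", date = as.Date("2020-01-01") + 0:4)
  out <- data.frame(site = "s1", date = as.Date("2020-01-01") + 0:2,
                    outcome = c(1L, 0L, 1L))
  m <- matchOutcomes(info, out)
  expect_equal(sum(!is.na(m$outcome)), 3)
  expect_equal(m$outcome[1:3], c(1L, 0L, 1L))
  expect_true(all(is.na(matchOutcomes(info, NULL)$outcome)))
  expect_error(matchOutcomes(info, rbind(out, out[1, ])), "duplicate")
})

test_that("the full chain yields complete scaled days from a messy toy stream", {
  days <- preprocessExposures(toy_stream())
  # day 2 has a 61-minute truncated gap, so 2 of 3 days survive
  expect_equal(ncol(days), 2)
  expect_equal(nrow(days), 1440)
  v <- daySeries(days)
  expect_true(all(is.finite(v)))
  expect_true(all(v >= 0 & v <= 1))       # pollutant min-max scaled
  expect_equal(dayInfo(days)$date, as.Date(c("2017-06-01", "2017-06-03")))
  expect_equal(S4Vectors::metadata(days)$removed$length, 61L)
})

test_that("simulated full days round-trip the chain with outcomes attached", {
  cfg <- simConfig(n_sites = 1, n_days = 2, day_length = 1440,
                   missing_gap_rate = 0, seed = 5)
  sim <- simulateExposure(cfg)
  days <- preprocessExposures(sim$records, outcomes = sim$outcomes)
  info <- dayInfo(days)
  expect_equal(ncol(days), 2 * 4)         # 2 days x 4 variable streams
  expect_true(all(is.finite(daySeries(days))))
  expect_true(all(!is.na(info$outcome)))
  expect_true(all(daySeries(days)[, info$variable == "pm"] >= 0))
  expect_true(all(daySeries(days)[, info$variable == "pm"] <= 1))
  # temperature stays in native units by default
  expect_gt(max(daySeries(days)[, info$variable == "temperature"]), 1.5)
})
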