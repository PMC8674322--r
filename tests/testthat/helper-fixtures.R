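# Shared in-code fixtures for the test suite.

# A three-day toy sensor stream for one site: duplicated indoor PM sensors,
# one 30-minute gap (interpolatable) on day 1, one 61-minute gap (truncating)
# on day 2, day 3 clean. Days are anchored at 20:00 UTC.
toy_stream <- function() {
  start <- as.POSIXct("2017-06-01 20:00:00", tz = "UTC")
  times <- start + 60 * seq.int(0, 3 * 1440 - 1)
  n <- length(times)
  base <- 10 + 5 * sin(2 * pi * seq_len(n) / 1440)
  a <- base; b <- base + 2          # two indoor sensors, constant offset
  gap30 <- 200:229                  # day 1: 30-minute gap in sensor A only...
  a[gap30] <- NA; b[gap30] <- NA    # ...in both, so the merged minute is missing
  gap61 <- (1440 + 700):(1440 + 760)  # day 2: 61 minutes missing in both
  a[gap61] <- NA; b[gap61] <- NA
  rbind(
    data.frame(timestamp = times, site = "s1", location = "indoor",
               variable = "pm", sensor = "A", value = a),
    data.frame(timestamp = times, site = "s1", location = "indoor",
               variable = "pm", sensor = "B", value = b))
}

# Random short series pair for DTW property tests.
random_pair <- function(max_len = 7L) {
  list(a = round(stats::runif(sample.int(max_len, 1), -2, 2), 3),
       b = round(stats::runif(sample.int(max_len, 1), -2, 2), 3))
}
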