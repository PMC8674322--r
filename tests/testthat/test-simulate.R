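test_that("invalid configurations are rejected with the field named", {
  expect_error(simConfig(n_sites = 0), "n_sites")
  expect_error(simConfig(noise_sd = -1), "noise_sd")
  expect_error(simConfig(day_length = 1), "day_length")
  expect_error(simConfig(day_length = 100, warp_magnitude = 50), "warp_magnitude")
  expect_error(simConfig(variables = "co2"), "variables")
  expect_error(simConfig(outcome_logit_coefs = 1), "outcome_logit_coefs")
})

test_that("zero days yield empty records and ground truth", {
  sim <- simulateExposure(simConfig(n_days = 0))
  expect_equal(nrow(sim$records), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nrow(sim$outcomes), 0)
  expect_named(sim$records, c("timestamp", "site", "location", "variable",
                              "sensor", "value"))
})

test_that("identical configs with the same seed reproduce byte-identical output", {
  cfg <- simConfig(n_sites = 2, n_days = 2, day_length = 300,
                   missing_gap_rate = 0.5, seed = 7)
  expect_identical(simulateExposure(cfg), simulateExposure(cfg))
  cfg2 <- simConfig(n_sites = 2, n_days = 2, day_length = 300,
                    missing_gap_rate = 0.5, seed = 8)
  expect_false(identical(simulateExposure(cfg)$records,
                         simulateExposure(cfg2)$records))
})

test_that("ground truth has one record per day-variable and binary outcomes", {
  cfg <- simConfig(n_sites = 2, n_days = 3, day_length = 240, seed = 3)
  sim <- simulateExposure(cfg)
  expect_equal(nrow(sim$truth), 2 * 3 * 4)
  expect_false(anyDuplicated(sim$truth[, c("site", "date", "variable",
                                           "location")]) > 0)
  expect_true(all(sim$outcomes$outcome %in% c(0L, 1L)))
  expect_equal(nrow(sim$outcomes), 2 * 3)
  # season labels partition days
  expect_true(all(sim$truth$season %in% c("winter", "spring", "summer", "fall")))
})

test_that("summer temperature days sit above winter days and peak near noon", {
  mk <- function(start) simConfig(n_sites = 1, n_days = 6, day_length = 288,
                                  variables = "outdoor_temperature",
                                  warp_magnitude = 5, noise_sd = 0.02,
                                  missing_gap_rate = 0, start_date = start,
                                  seed = 21)
  summer <- simulateExposure(mk(as.Date("2017-07-01")))
  winter <- simulateExposure(mk(as.Date("2017-01-05")))
  expect_gt(mean(summer$records$value), mean(winter$records$value))
  expect_true(all(summer$truth$season == "summer"))
  expect_true(all(winter$truth$season == "winter"))
  # pre-warp prototype peaks at noon: with a 20:00 window start and 5-minute
  # sampling (288/day), noon falls 16 h in, index 193; warp can move it by
  # warp_magnitude samples at most
  day1 <- summer$records$value[1:288]
  expect_lte(abs(which.max(day1) - 193), 5 + 2)
})

test_that("applyWarp is the identity at magnitude zero and respects its bounds", {
  x <- sin(seq(0, 2 * pi, length.out = 200))
  expect_equal(as.numeric(applyWarp(x, 0)), x)
  w <- applyWarp(x, 25, seed = 5)
  f <- attr(w, "time_map")
  expect_true(all(diff(f) > 0))
  expect_equal(f[1], 0)
  expect_equal(f[200], 199)
  expect_lte(max(abs(f - 0:199)), 25)
  expect_length(w, length(x))
  expect_error(applyWarp(x, 100), "degenerate")
  expect_error(applyWarp(x, -1), ">= 0")
})

test_that("an explicit time map displaces an impulse by the stated amount", {
  n <- 200L
  x <- numeric(n); x[120] <- 1
  # map with f(t) = t - 30 in the interior: output argmax moves +30
  f <- c(0, pmax(pmin(seq_len(n - 2) - 30, n - 2), 1e-6), n - 1)
  f <- cummax(f) + seq(0, 1e-6, length.out = n)   # strictly increasing
  f[1] <- 0; f[n] <- n - 1
  w <- applyWarp(x, 0, time_map = f)
  expect_equal(which.max(w), 150)
  expect_error(applyWarp(x, 0, time_map = rev(f)), "strictly increasing")
})

test_that("warping moves series much further element-wise than under DTW", {
  proto <- simulatePrototypeDays(n = 1, len = 288, k = 1, warp_magnitude = 0,
                                 noise_sd = 0, seed = 1)$prototypes[, 1]
  withr::with_seed(13, {
    for (i in 1:5) {
      w <- as.numeric(applyWarp(proto, 15))
      d_dtw <- dtwDistance(proto, w, return_path = FALSE)@distance
      d_el <- dtwDistance(proto, w, band = 0, return_path = FALSE)@distance
      expect_lt(d_dtw, 0.2 * d_el)
    }
  })
})

test_that("prototype and impulse benchmark datasets are deterministic and shaped", {
  d <- simulatePrototypeDays(n = 30, len = 96, k = 3, seed = 4)
  expect_equal(dim(d$values), c(96, 30))
  expect_equal(sort(unique(d$labels)), 1:3)
  expect_identical(d, simulatePrototypeDays(n = 30, len = 96, k = 3, seed = 4))
  im <- simulateImpulseDays(n = 10, len = 144, seed = 2)
  expect_equal(max(im$prototypes), 1)
  expect_equal(dim(im$values), c(144, 10))
})
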