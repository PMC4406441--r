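test_that("dF/F of a constant trace is identically zero", {
  rec <- make_recording(rep(100, 5000))
  dff <- compute_dff(rec, "A")
  expect_true(all(abs(dff$dff) < 1e-12))
})

test_that("dF/F of a plateau over baseline matches the definition", {
  tr <- rep(100, 20000)
  tr[5001:5400] <- 150  # 400 ms plateau, well under the 10% percentile span
  dff <- compute_dff(make_recording(tr), "A")
  expect_equal(max(dff$dff), 0.5, tolerance = 1e-6)
  expect_lt(abs(dff$dff[1000]), 1e-6)
})

test_that("dF/F peak tracks the simulator ground truth", {
  cfg <- sim_config(seed = 21, noise_sigma = 0)
  prot <- stim_protocol(onset_ms = 20000, duration_ms = 5, compartment = "A")
  sim <- simulate_culture(cfg, prot, 40000)
  dff <- compute_dff(sim$recording, "A")
  f <- sim$activity$bursts$recruited_fraction[1]
  # full burst: peak dF/F should land within 10% of ca_amplitude * f
  expect_equal(max(dff$dff, na.rm = TRUE), cfg$ca_amplitude * f,
               tolerance = 0.1)
})

test_that("an all-masked trace is an error", {
  rec <- make_recording(rep(100, 100), mask_A = rep(TRUE, 100))
  expect_error(compute_dff(rec, "A"), "unmasked")
})

test_that("burst detection returns nothing on a flat trace", {
  expect_equal(nrow(detect_bursts(numeric(5000), threshold_dff = 0.1)), 0)
})

test_that("burst detection recovers two separated transients exactly", {
  x <- transient_template(12000, 2000) + transient_template(12000, 7000)
  ev <- detect_bursts(x, threshold_dff = 0.1)
  expect_equal(nrow(ev), 2)
  expect_lt(max(abs(ev$onset_ms - c(2000, 7000))), 5)
  expect_true(all(ev$peak_dff > 0.9))
  expect_true(all(ev$onset_ms <= ev$peak_ms))
})

test_that("a transient split by a short mask still counts once", {
  x <- transient_template(8000, 2000)
  x[2050:2100] <- NA  # 50 ms saturation gap through the transient
  ev <- detect_bursts(x, threshold_dff = 0.1)
  expect_equal(nrow(ev), 1)
})

test_that("gaps longer than the bridge limit split events", {
  x <- transient_template(8000, 2000)
  x[2010:3100] <- NA  # 1.09 s gap, beyond the 1024 ms bridge
  # the decay tail re-emerges above threshold after the gap
  expect_gt(x[3102], 0.1)
  ev <- detect_bursts(x, threshold_dff = 0.1)
  expect_equal(nrow(ev), 2)
})

test_that("simulated recordings give exact burst-count recovery", {
  cfg <- sim_config(seed = 31)  # noise well below half the transient
  sim <- simulate_culture(cfg, stim_protocol(), 300000)
  dff <- compute_dff(sim$recording, "A")
  ev <- detect_bursts(dff)
  gt <- sim$activity$bursts
  gt <- gt[gt$compartment == "A", ]
  expect_equal(nrow(ev), nrow(gt))
  expect_lt(max(abs(ev$onset_ms - gt$ignition_time_ms)), 10)
})

test_that("bursting rate is count over duration", {
  ev <- data.frame(onset_ms = seq_len(12))
  expect_equal(bursting_rate(ev, 2), 6)
  expect_equal(bursting_rate(ev[0, , drop = FALSE], 5), 0)
  expect_error(bursting_rate(ev, 0), "> 0")
})

test_that("bursting rate recovers a Poisson event rate", {
  set.seed(99)
  r <- 6  # bursts/min
  counts <- stats::rpois(20, r * 10)
  rates <- counts / 10
  se <- sqrt(r / 10) / sqrt(20)
  expect_lt(abs(mean(rates) - r), 3 * se)
})

test_that("detection is invariant under joint amplitude/threshold rescaling", {
  x <- 0.3 * (transient_template(12000, 2000) +
                transient_template(12000, 7000))
  for (scale in c(0.5, 1, 4)) {
    ev <- detect_bursts(scale * x, threshold_dff = scale * 0.05)
    expect_equal(nrow(ev), 2)
  }
})

test_that("rate normalization follows the per-culture reference rule", {
  r <- data.frame(culture = "c1", condition = c("1x", "2x", "4x"),
                  rate = c(6.0, 6.3, 5.8))
  out <- normalize_rates(r, "1x")
  expect_equal(out$normalized_rate, c(1, 1.05, 5.8 / 6), tolerance = 1e-12)
  # all-equal rates normalize to 1
  req <- data.frame(culture = "c2", condition = c("1x", "2x"), rate = 3)
  expect_equal(normalize_rates(req, "1x")$normalized_rate, c(1, 1))
})

test_that("rate normalization is invariant under per-culture rescaling", {
  r <- data.frame(culture = rep(c("a", "b"), each = 3),
                  condition = rep(c("1x", "2x", "4x"), 2),
                  rate = c(4, 5, 3, 8, 10, 6))  # b = 2 * a
  out <- normalize_rates(r, "1x")
  expect_equal(out$normalized_rate[1:3], out$normalized_rate[4:6])
})

test_that("zero-reference cultures are reported and excluded", {
  r <- data.frame(culture = c("a", "a", "b", "b"),
                  condition = rep(c("1x", "2x"), 2),
                  rate = c(0, 2, 4, 5))
  expect_warning(out <- normalize_rates(r, "1x"), "zero reference")
  expect_false("a" %in% out$culture)
})

test_that("binning averages chunks and propagates full-mask bins", {
  ramp <- 0:999
  b <- bin_trace(ramp, 50)
  expect_equal(b$value, seq(24.5, 974.5, by = 50))
  expect_equal(bin_trace(ramp, 1)$value, ramp)  # identity at one sample
  expect_equal(unique(bin_trace(rep(7, 300), 50)$value), 7)
  x <- c(rep(1, 50), rep(NA, 50), rep(3, 50))
  bb <- bin_trace(x, 50)
  expect_equal(bb$value, c(1, NA, 3))
  expect_error(bin_trace(ramp, 50.7), "multiple")
})
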