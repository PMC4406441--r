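test_that("cross-correlation identities: self, shift, sign inversion", {
  t <- seq(0, 6, by = 0.001)
  x <- exp(-((t - 2)^2) / 0.02) + 0.5 * exp(-((t - 4)^2) / 0.05)
  ccf <- normalized_xcorr(x, x, max_lag_ms = 20)
  expect_equal(ccf$coefficient[ccf$lag_ms == 0], 1)
  expect_equal(ccf$lag_ms[which.max(ccf$coefficient)], 0)

  y <- c(rep(0, 3), x[seq_len(length(x) - 3)])  # x delayed by 3 samples
  ccf2 <- normalized_xcorr(x, y, max_lag_ms = 20)
  expect_equal(ccf2$lag_ms[which.max(ccf2$coefficient)], 3)

  ccf3 <- normalized_xcorr(x, -x, max_lag_ms = 20)
  expect_equal(ccf3$coefficient[ccf3$lag_ms == 0], -1)
  expect_true(all(ccf3$coefficient >= -1 & ccf3$coefficient <= 1,
                  na.rm = TRUE))
})

test_that("cross-correlation equals the brute-force loop, masks included", {
  set.seed(6)
  x <- as.numeric(stats::filter(rnorm(300), 0.9, method = "recursive"))
  y <- c(rep(NA, 5), x[seq_len(295)]) + rnorm(300, 0, 0.1)
  x[sample(300, 20)] <- NA
  got <- normalized_xcorr(x, y, max_lag_ms = 12)
  want <- oracle_xcorr(x, y, 12)
  expect_equal(got$coefficient, want$coefficient, tolerance = 1e-12)
})

test_that("cross-correlation is symmetric under argument exchange", {
  set.seed(8)
  x <- as.numeric(stats::filter(rnorm(400), 0.8, method = "recursive"))
  y <- as.numeric(stats::filter(rnorm(400), 0.8, method = "recursive"))
  x[sample(400, 15)] <- NA
  fwd <- normalized_xcorr(x, y, max_lag_ms = 10)
  rev_ <- normalized_xcorr(y, x, max_lag_ms = 10)
  expect_equal(fwd$coefficient, rev(rev_$coefficient), tolerance = 1e-12)
})

test_that("lags with insufficient unmasked overlap are undefined", {
  x <- c(rnorm(15), rep(NA, 200))
  y <- c(rep(NA, 200), rnorm(15))
  ccf <- normalized_xcorr(x, y, max_lag_ms = 5)
  expect_true(all(is.na(ccf$coefficient)))
})

test_that("transmission delay recovers constructed shifts at sub-sample accuracy", {
  tmpl <- transient_template(2000, 300)
  for (d in 1:10) {
    shifted <- c(rep(0, d), tmpl[seq_len(length(tmpl) - d)])
    est <- transmission_delay(tmpl, shifted, max_lag_ms = 30)
    expect_lt(abs(est$delay_ms - d), 0.5)
  }
  # identical traces: zero delay
  expect_lt(abs(transmission_delay(tmpl, tmpl, max_lag_ms = 30)$delay_ms),
            0.25)
})

test_that("delay recovery tolerates 20% noise after 30-trial averaging", {
  set.seed(17)
  tmpl <- transient_template(2000, 300)
  for (d in c(1, 4, 7, 10)) {
    shifted <- c(rep(0, d), tmpl[seq_len(length(tmpl) - d)])
    mx <- t(replicate(30, tmpl + rnorm(2000, 0, 0.2)))
    my <- t(replicate(30, shifted + rnorm(2000, 0, 0.2)))
    est <- transmission_delay(colMeans(mx), colMeans(my), max_lag_ms = 30)
    expect_lt(abs(est$delay_ms - d), 1)
  }
})

test_that("an undefined or non-evoked receiving side yields no delay", {
  x <- transient_template(600, 100)
  y <- rep(NA_real_, 600)
  est <- transmission_delay(x, y, max_lag_ms = 20)
  expect_true(is.na(est$delay_ms))
})

test_that("device classification implements the published decision rules", {
  # reverse absent -> unidirectional
  u <- classify_device(3, NA, 1, 0)
  expect_equal(u$classification, "unidirectional")
  expect_true(is.na(u$relative_delay_increase))
  # 3 vs 3.1 ms: 3.3% difference, below the 10% symmetric tolerance
  s <- classify_device(3, 3.1, 1, 1)
  expect_equal(s$classification, "symmetric")
  # 4 vs 8 ms: +100%, inside the observed 23-211% asymmetry band
  a <- classify_device(4, 8, 1, 1)
  expect_equal(a$classification, "bidirectional_asymmetric")
  expect_equal(a$relative_delay_increase, 1)
  # chance-level reverse success counts as non-transmitting
  c2 <- classify_device(3, 5, 1, 0.1)
  expect_equal(c2$classification, "unidirectional")
  expect_error(classify_device(3, 4, NULL, NULL), "both directions")
})

test_that("paired delay test matches the textbook formula and edge cases", {
  idn <- paired_delay_test(c(3, 4, 5), c(3, 4, 5))
  expect_equal(idn$statistic, 0)
  expect_equal(idn$p_value, 1)
  const <- paired_delay_test(c(3, 4, 5), c(4, 5, 6))
  expect_true(const$degenerate)
  expect_error(paired_delay_test(3, 4), "at least 2")

  set.seed(23)
  fwd <- runif(10, 2, 5)
  rev_ <- fwd * runif(10, 1.23, 3.11)
  got <- paired_delay_test(fwd, rev_)
  d <- rev_ - fwd
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 9)
  expect_equal(got$p_value,
               2 * stats::pt(abs(t_hand), 9, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("end-to-end estimation classifies a straight device as symmetric-grade", {
  prot <- alternating_protocol(n_per_side = 8, interval_s = 6)
  rec <- simulate_experiment(sim_config(seed = 61), prot,
                             protocol_duration(prot))$recording
  rep_ <- estimate_connectivity(rec)
  expect_gte(rep_$success_forward, 0.7)
  expect_gte(rep_$success_reverse, 0.7)
  expect_lt(rep_$delay_forward_ms, 5)
  expect_lt(rep_$delay_reverse_ms, 5)
  expect_true(all(rep_$ccf_forward$coefficient <= 1, na.rm = TRUE))
})

test_that("batch analysis writes a report per manifest row", {
  dir <- withr::local_tempdir()
  prot <- alternating_protocol(n_per_side = 6, interval_s = 6)
  for (i in 1:2) {
    rec <- simulate_experiment(sim_config(n_neurons = 800, seed = 70 + i),
                               prot, protocol_duration(prot))$recording
    write_recording(rec, file.path(dir, sprintf("dev%d.csv", i)))
  }
  manifest <- data.frame(device = c("dev1", "dev2"),
                         recording = file.path(dir, c("dev1.csv", "dev2.csv")))
  res <- run_connectivity_batch(manifest, out_dir = file.path(dir, "out"))
  expect_equal(nrow(res$devices), 2)
  expect_true(all(nzchar(res$devices$classification)))
  expect_true(all(file.exists(
    file.path(dir, "out", c("dev1_report.json", "dev2_report.json")))))
  expect_equal(res$paired_test$n, 2)
})
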