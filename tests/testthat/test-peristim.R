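test_that("peristimulus mean and SD equal a direct two-pass computation", {
  set.seed(4)
  n <- 4000
  x <- as.numeric(transient_template(n, 500)) + rnorm(n, 0, 0.02)
  x[c(600:620, 1500)] <- NA
  prot <- stim_protocol(onset_ms = c(500, 1500, 2500), duration_ms = 5,
                        compartment = "A")
  dff <- structure(list(dff = x, time_ms = seq_len(n) - 1,
                        mask = is.na(x), sampling_rate = 1000),
                   class = "dff_trace")
  ps <- extract_peristimulus(dff, prot, window_pre_ms = 200,
                             window_post_ms = 400)
  expect_equal(ps$n_stimuli, 3)
  # oracle: explicit per-column loops over unmasked entries
  for (j in seq_along(ps$lag_ms)) {
    col <- ps$matrix[, j]
    col <- col[!is.na(col)]
    if (length(col)) {
      expect_equal(ps$mean[j], sum(col) / length(col))
      if (length(col) > 1) {
        expect_equal(ps$sd[j],
                     sqrt(sum((col - mean(col))^2) / (length(col) - 1)))
      }
    } else {
      expect_true(is.na(ps$mean[j]))
    }
  }
})

test_that("identical responses give a zero SD trace", {
  tmpl <- transient_template(1200, 600)
  x <- rep(tmpl, 30)
  onsets <- 600 + 1200 * (0:29)
  prot <- stim_protocol(onset_ms = onsets, duration_ms = 5,
                        compartment = "A")
  dff <- structure(list(dff = x, time_ms = seq_along(x) - 1,
                        mask = rep(FALSE, length(x)), sampling_rate = 1000),
                   class = "dff_trace")
  ps <- extract_peristimulus(dff, prot, window_pre_ms = 100,
                             window_post_ms = 400)
  expect_equal(ps$n_stimuli, 30)
  expect_true(all(ps$sd < 1e-12))
})

test_that("compartment filtering selects exactly the alternating events", {
  prot <- alternating_protocol(n_per_side = 15, interval_s = 2)
  x <- numeric(protocol_duration(prot))
  dff <- structure(list(dff = x, time_ms = seq_along(x) - 1,
                        mask = rep(FALSE, length(x)), sampling_rate = 1000),
                   class = "dff_trace")
  psA <- extract_peristimulus(dff, prot, stim_compartment = "A",
                              window_pre_ms = 100, window_post_ms = 100)
  expect_equal(psA$n_stimuli, 15)
  expect_equal(psA$onsets_ms,
               prot$onset_ms[prot$compartment == "A"])
})

test_that("events whose window exceeds the recording are skipped with a warning", {
  prot <- stim_protocol(onset_ms = c(300, 1900), duration_ms = 5,
                        compartment = "A")
  dff <- structure(list(dff = numeric(2000), time_ms = 0:1999,
                        mask = rep(FALSE, 2000), sampling_rate = 1000),
                   class = "dff_trace")
  expect_warning(
    ps <- extract_peristimulus(dff, prot, window_pre_ms = 200,
                               window_post_ms = 400),
    "skipped")
  expect_equal(ps$n_stimuli, 1)
})

test_that("evoked scoring flags supra-threshold responses and only those", {
  n_win <- 701
  lag <- seq(-200, 500)
  flat <- matrix(0, 10, n_win)
  make_set <- function(m) {
    structure(list(matrix = m, lag_ms = lag,
                   mean = colMeans(m), sd = apply(m, 2, sd),
                   n_stimuli = nrow(m), window_pre_ms = 200,
                   window_post_ms = 500, sampling_rate = 1000),
              class = "peristimulus_set")
  }
  expect_equal(score_evoked(make_set(flat))$success_rate, 0)
  hit <- flat; hit[, lag >= 10 & lag <= 60] <- 0.9
  expect_equal(score_evoked(make_set(hit))$success_rate, 1)
  mixed <- flat; mixed[1:4, lag >= 10 & lag <= 60] <- 0.9
  expect_equal(score_evoked(make_set(mixed))$success_rate, 0.4)
  expect_error(score_evoked(make_set(flat), latency_window_ms = 900),
               "exceeds")
})

test_that("success rate is monotone non-increasing in the threshold", {
  set.seed(12)
  lag <- seq(-200, 500)
  m <- matrix(rnorm(30 * length(lag), 0, 0.05), 30)
  m[, lag >= 20 & lag <= 80] <- m[, lag >= 20 & lag <= 80] +
    rep(runif(30, 0.05, 0.6), times = sum(lag >= 20 & lag <= 80))
  s <- structure(list(matrix = m, lag_ms = lag, mean = colMeans(m),
                      sd = apply(m, 2, sd), n_stimuli = 30,
                      window_pre_ms = 200, window_post_ms = 500,
                      sampling_rate = 1000),
                 class = "peristimulus_set")
  rates <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(th) {
    score_evoked(s, amplitude_threshold = th)$success_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("identical responses at all durations give a flat curve", {
  durs <- c(1, 4, 16)
  onsets <- seq(3000, by = 3000, length.out = 9)
  prot <- stim_protocol(onset_ms = onsets,
                        duration_ms = rep(durs, 3), compartment = "A")
  x <- numeric(30000)
  for (o in onsets) {
    idx <- o + seq_len(1500)
    x[idx] <- pmax(x[idx], transient_template(1500, 20))
  }
  dff <- structure(list(dff = x, time_ms = seq_along(x) - 1,
                        mask = rep(FALSE, length(x)), sampling_rate = 1000),
                   class = "dff_trace")
  cv <- response_amplitude_curve(dff, prot, "A")
  expect_equal(cv$duration_ms, durs)
  expect_lt(max(cv$mean_amplitude) / min(cv$mean_amplitude), 1.001)
})
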