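test_that("a disconnected device never relays bursts across compartments", {
  cfg <- test_config(n_axons_forward = 0, n_axons_reverse = 0)
  prot <- stim_protocol(onset_ms = c(5000, 15000), duration_ms = 5,
                        compartment = "A")
  sim <- simulate_experiment(cfg, prot, 30000, render = FALSE)
  b <- sim$activity$bursts
  expect_false(any(b$origin == "synaptic_from_other_compartment"))
  expect_false(any(b$compartment == "B" & b$origin == "direct_photo"))
})

test_that("ground-truth recruitment is graded under CNQX, all-or-none without", {
  prot <- stim_protocol(onset_ms = c(5000, 15000), duration_ms = c(1, 1024),
                        compartment = "A")
  cfg10 <- test_config(cnqx_concentration = 10, spontaneous_burst_rate = 0)
  b10 <- simulate_experiment(cfg10, prot, 25000, render = FALSE)$activity$bursts
  b10 <- b10[b10$origin == "direct_photo", ]
  expect_equal(nrow(b10), 2)
  # saturating CNQX: only the directly photo-activated fraction responds
  expect_lt(b10$recruited_fraction[1], 0.15)  # 1 ms pulse
  expect_gt(b10$recruited_fraction[2], 0.4)   # 1024 ms pulse
  expect_gt(b10$recruited_fraction[2], 2 * b10$recruited_fraction[1])

  cfg0 <- test_config(cnqx_concentration = 0, spontaneous_burst_rate = 0)
  b0 <- simulate_experiment(cfg0, prot, 25000, render = FALSE)$activity$bursts
  b0 <- b0[b0$origin == "direct_photo", ]
  # full percolation: recruited fraction independent of stimulus duration
  expect_equal(b0$recruited_fraction[1], b0$recruited_fraction[2],
               tolerance = 0.02)
  expect_gt(min(b0$recruited_fraction), 0.95)
})

test_that("evoked stimulation overrides the spontaneous refractory period", {
  # a pulse 1 s after a forced spontaneous burst still ignites
  cfg <- test_config(spontaneous_burst_rate = 0)
  prot <- stim_protocol(onset_ms = c(2000, 3000), duration_ms = 5,
                        compartment = "A")
  b <- simulate_experiment(cfg, prot, 10000, render = FALSE)$activity$bursts
  expect_equal(sum(b$origin == "direct_photo" & b$compartment == "A"), 2)
})

test_that("spontaneous ignitions respect the post-burst dead time", {
  cfg <- test_config(spontaneous_burst_rate = 30,  # dense proposals
                     n_axons_forward = 0, n_axons_reverse = 0)
  sim <- simulate_experiment(cfg, stim_protocol(), 120000, render = FALSE)
  b <- sim$activity$bursts
  for (cp in c("A", "B")) {
    sp <- b[b$compartment == cp, ]
    expect_gt(nrow(sp), 1)
    expect_gte(min(diff(sp$ignition_time_ms)), 2999)
  }
})

test_that("protocols extending beyond the simulation are rejected", {
  cfg <- test_config()
  prot <- stim_protocol(onset_ms = 9000, duration_ms = 2000,
                        compartment = "A")
  expect_error(simulate_experiment(cfg, prot, 10000), "beyond")
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- sim_config(n_neurons = 400, seed = 77)
  prot <- alternating_protocol(n_per_side = 2, interval_s = 5)
  r1 <- simulate_experiment(cfg, prot, protocol_duration(prot))$recording
  r2 <- simulate_experiment(cfg, prot, protocol_duration(prot))$recording
  expect_identical(r1$trace_A, r2$trace_A)
  expect_identical(r1$trace_B, r2$trace_B)
  expect_identical(r1$mask_A, r2$mask_A)
  r3 <- simulate_experiment(sim_config(n_neurons = 400, seed = 78), prot,
                            protocol_duration(prot))$recording
  expect_false(identical(r1$trace_A, r3$trace_A))
})

test_that("coupling parameters do not perturb spontaneous event streams", {
  # Saturating CNQX keeps every burst below the propagation threshold, so
  # no relays fire and the accepted spontaneous times expose the proposal
  # stream directly; changing the axon counts must leave them untouched.
  times <- lapply(c(0, 7, 100), function(n_ax) {
    cfg <- sim_config(n_neurons = 400, seed = 55, cnqx_concentration = 10,
                      n_axons_forward = n_ax, n_axons_reverse = n_ax)
    b <- simulate_experiment(cfg, stim_protocol(), 120000,
                             render = FALSE)$activity$bursts
    b$ignition_time_ms[b$origin == "spontaneous" & b$compartment == "A"]
  })
  expect_identical(times[[1]], times[[2]])
  expect_identical(times[[1]], times[[3]])
  expect_gt(length(times[[1]]), 0)
})

test_that("relayed bursts carry the percolation delay of the receiving side", {
  cfg <- sim_config(seed = 13, spontaneous_burst_rate = 0)
  prot <- stim_protocol(onset_ms = 5000, duration_ms = 5, compartment = "A")
  b <- simulate_experiment(cfg, prot, 12000, render = FALSE)$activity$bursts
  relay <- b[b$origin == "synaptic_from_other_compartment", ]
  src <- b[b$origin == "direct_photo", ]
  expect_equal(nrow(relay), 1)
  expect_equal(relay$compartment, "B")
  expect_equal(relay$ignition_time_ms,
               src$ignition_time_ms + src$ignition_delay_steps)
})
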