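#' Packaged example scenarios
#'
#' Deterministic, code-generated scenarios covering the canonical
#' experimental designs: the imaging-intensity series (1x/2x/4x at 549 nm),
#' the stimulus-duration series with and without saturating CNQX, a
#' one-sided-transduction device, straight-channel versus axon-diode
#' devices, and a diode under 5 uM (under-saturating) CNQX. Durations are
#' kept short so the whole set regenerates in seconds; every scenario is a
#' complete (config, protocol, duration) triple ready for
#' [simulate_experiment()].
#'
#' @param seed Base seed; each scenario derives its own sub-seed from it.
#' @param n_neurons Compartment size used for the examples.
#' @return Named list of scenarios, each a list with `config`, `protocol`,
#'   `duration_ms` and a one-line `description`.
#' @export
fixture_scenarios <- function(seed = 20160101, n_neurons = 1000) {
  sc <- list()
  add <- function(name, config, protocol, duration_ms, description) {
    sc[[name]] <<- list(config = config, protocol = protocol,
                        duration_ms = duration_ms,
                        description = description)
  }
  k <- 0L
  next_seed <- function() { k <<- k + 1L; sub_seed(seed, 10L * k) }

  for (int in c(1, 2, 4)) {
    prot <- stim_protocol(onset_ms = 0, duration_ms = 120000,
                          compartment = "A", role = "imaging_549",
                          intensity = int)
    add(sprintf("intensity_%dx", int),
        sim_config(n_neurons = n_neurons, n_axons_forward = 0,
                   n_axons_reverse = 0, seed = next_seed()),
        prot, 120000,
        sprintf("spontaneous activity under %dx 549 nm imaging light", int))
  }
  durs <- 2^(0:10)
  for (cnqx in c(0, 10)) {
    add(if (cnqx == 0) "duration_series" else "duration_series_cnqx10",
        sim_config(n_neurons = n_neurons, cnqx_concentration = cnqx,
                   n_axons_forward = 0, n_axons_reverse = 0,
                   seed = next_seed()),
        duration_series_protocol(durations_ms = durs),
        protocol_duration(duration_series_protocol(durations_ms = durs)),
        sprintf("1-1024 ms stimulus series at %g uM CNQX", cnqx))
  }
  add("one_sided",
      sim_config(n_neurons = n_neurons, transduced_fraction = c(0.7, 0),
                 seed = next_seed()),
      alternating_protocol(n_per_side = 10, interval_s = 6),
      protocol_duration(alternating_protocol(n_per_side = 10, interval_s = 6)),
      "only compartment A transduced; alternating stimulation")
  add("straight",
      sim_config(n_neurons = n_neurons, seed = next_seed()),
      alternating_protocol(n_per_side = 10, interval_s = 6),
      protocol_duration(alternating_protocol(n_per_side = 10, interval_s = 6)),
      "symmetric straight-channel device")
  for (cnqx in c(0, 5)) {
    add(if (cnqx == 0) "diode" else "diode_cnqx5",
        diode_config(n_neurons = n_neurons, cnqx_concentration = cnqx,
                     seed = next_seed()),
        alternating_protocol(n_per_side = 10, interval_s = 6),
        protocol_duration(alternating_protocol(n_per_side = 10,
                                               interval_s = 6)),
        sprintf("axon-diode device at %g uM CNQX", cnqx))
  }
  sc
}

#' Regenerate the packaged example set on disk
#'
#' Simulates every [fixture_scenarios()] scenario and writes the recording
#' (CSV + sidecar), the ground truth (JSON) and the config/protocol for
#' each. Fully deterministic: same seed, byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed.
#' @param n_neurons Compartment size.
#' @return Invisibly, the vector of scenario names written.
#' @export
write_fixtures <- function(out_dir, seed = 20160101, n_neurons = 1000) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sc <- fixture_scenarios(seed = seed, n_neurons = n_neurons)
  for (nm in names(sc)) {
    s <- sc[[nm]]
    sim <- simulate_experiment(s$config, s$protocol, s$duration_ms)
    base <- file.path(out_dir, nm)
    write_recording(sim$recording, paste0(base, "_recording.csv"))
    write_ground_truth(sim$activity, paste0(base, "_ground_truth.json"))
    write_sim_config(s$config, paste0(base, "_config.json"))
    write_stim_protocol(s$protocol, paste0(base, "_protocol.json"))
  }
  invisible(names(sc))
}
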