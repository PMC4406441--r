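#' Simulate a two-compartment optogenetic calcium-imaging experiment
#'
#' Runs the full synthetic experiment: spontaneous network bursts as a
#' Poisson process with a post-burst dead time (applied to spontaneous, not
#' evoked, ignitions — light pulses are strong enough to override the
#' natural refractory period), direct photo-activation of ChR2-transduced
#' neurons by each 470 nm pulse, quorum-percolation recruitment on a fixed
#' per-compartment random graph, and burst relay into the opposite
#' compartment through the inter-compartment axon bundle. A burst that
#' recruits at least `propagation_threshold` of its compartment seeds the
#' other side with as many active inputs as there are afferent axons; the
#' transmission delay is the number of 1 ms synaptic integration steps the
#' receiving population needs to percolate, so fewer afferent axons mean a
#' longer delay.
#'
#' @param config A [sim_config()].
#' @param protocol A [stim_protocol()]; may be empty for spontaneous-only
#'   recordings.
#' @param duration_ms Total simulated time (ms); must cover the protocol.
#' @param refractory_ms Dead time after any burst during which spontaneous
#'   (but never evoked) ignitions are suppressed. Default 3000 ms.
#' @param render If `TRUE` (default) also render the line-scan recording.
#' @return A list with elements `activity` (a `population_activity`: per-ms
#'   active fraction per compartment plus the ground-truth burst table) and
#'   `recording` (a `linescan_recording`, or `NULL` if `render = FALSE`).
#' @examples
#' cfg <- sim_config(n_neurons = 400, seed = 7)
#' sim <- simulate_experiment(cfg, stim_protocol(), duration_ms = 30000)
#' sim$activity$bursts
#' @export
simulate_experiment <- function(config, protocol = stim_protocol(),
                                duration_ms, refractory_ms = 3000,
                                render = TRUE) {
  validate_sim_config(config)
  validate_stim_protocol(protocol)
  duration_ms <- as.integer(round(duration_ms))
  if (duration_ms <= 0) stop("'duration_ms' must be positive", call. = FALSE)
  if (nrow(protocol) &&
      max(protocol$onset_ms + protocol$duration_ms) > duration_ms) {
    stop("protocol extends beyond the simulated duration", call. = FALSE)
  }

  # Independent sub-streams so coupling parameters or protocol edits never
  # perturb the spontaneous event times of either compartment.
  graphs <- list()
  for (i in 1:2) {
    set.seed(sub_seed(config$seed, i))
    graphs[[c("A", "B")[i]]] <- make_quorum_graph(config$n_neurons,
                                                  config$mean_in_degree)
  }
  spont <- list()
  rate_per_ms <- config$spontaneous_burst_rate / 60000
  for (i in 1:2) {
    set.seed(sub_seed(config$seed, 2L + i))
    n_cand <- stats::rpois(1L, rate_per_ms * duration_ms)
    spont[[c("A", "B")[i]]] <- sort(stats::runif(n_cand, 0, duration_ms))
  }
  set.seed(sub_seed(config$seed, 5L))  # dynamics stream

  eff <- config$synaptic_efficacy * cnqx_multiplier(config$cnqx_concentration)

  # pending ignition events: time, compartment, seed count, origin, plateau.
  # Directly photo-activated neurons stay driven for the whole pulse (the
  # ChR2 photocurrent persists while the light is on), so the activity
  # plateau of a light-seeded ignition extends to the pulse duration.
  ev_time <- numeric(0); ev_comp <- character(0)
  ev_seed <- integer(0); ev_origin <- character(0); ev_plateau <- numeric(0)
  push <- function(time, comp, seed, origin,
                   plateau = config$burst_duration_ms) {
    ev_time <<- c(ev_time, time); ev_comp <<- c(ev_comp, comp)
    ev_seed <<- c(ev_seed, as.integer(seed)); ev_origin <<- c(ev_origin, origin)
    ev_plateau <<- c(ev_plateau, plateau)
  }
  for (cp in c("A", "B")) {
    for (t in spont[[cp]]) push(t, cp, config$spontaneous_seed, "spontaneous")
  }
  light <- protocol[protocol$role %in% c("stimulation_470", "imaging_549"), ,
                    drop = FALSE]
  if (nrow(light)) {
    for (i in seq_len(nrow(light))) {
      n_direct <- photo_activate(light[i, ], config)
      if (n_direct > 0) {
        push(light$onset_ms[i], light$compartment[i], n_direct, "direct_photo",
             plateau = max(config$burst_duration_ms, light$duration_ms[i]))
      }
    }
  }

  act <- list(A = numeric(duration_ms), B = numeric(duration_ms))
  busy_until <- c(A = -Inf, B = -Inf)
  refr_until <- c(A = -Inf, B = -Inf)
  bursts <- list()
  origin_rank <- c(direct_photo = 1, synaptic_from_other_compartment = 2,
                   spontaneous = 3)

  while (length(ev_time)) {
    i <- order(ev_time, origin_rank[ev_origin])[1L]
    t <- ev_time[i]; cp <- ev_comp[i]
    seed_n <- ev_seed[i]; origin <- ev_origin[i]; plateau <- ev_plateau[i]
    ev_time <- ev_time[-i]; ev_comp <- ev_comp[-i]
    ev_seed <- ev_seed[-i]; ev_origin <- ev_origin[-i]
    ev_plateau <- ev_plateau[-i]
    if (t >= duration_ms) next
    if (origin == "spontaneous" && t < max(busy_until[cp], refr_until[cp])) next
    if (origin == "synaptic_from_other_compartment" && t < busy_until[cp]) next

    seed_n <- min(seed_n, config$n_neurons)
    seed_idx <- sample.int(config$n_neurons, seed_n)
    perc <- quorum_percolate(graphs[[cp]], seed_idx,
                             config$quorum_threshold, eff)
    f <- perc$recruited_fraction
    d <- perc$ignition_delay_steps
    if (f <= 0) next
    act[[cp]] <- add_burst_waveform(act[[cp]], t, d, f, plateau)
    busy_until[cp] <- t + d + plateau
    refr_until[cp] <- t + d + refractory_ms
    bursts[[length(bursts) + 1L]] <- data.frame(
      compartment = cp, ignition_time_ms = t, recruited_fraction = f,
      ignition_delay_steps = d, origin = origin, stringsAsFactors = FALSE)

    if (f >= config$propagation_threshold) {
      other <- if (cp == "A") "B" else "A"
      n_axons <- if (cp == "A") config$n_axons_forward else config$n_axons_reverse
      if (n_axons > 0) {
        push(t + d, other, n_axons, "synaptic_from_other_compartment")
      }
    }
  }

  bursts <- if (length(bursts)) do.call(rbind, bursts) else data.frame(
    compartment = character(0), ignition_time_ms = numeric(0),
    recruited_fraction = numeric(0), ignition_delay_steps = integer(0),
    origin = character(0), stringsAsFactors = FALSE)
  bursts <- bursts[order(bursts$ignition_time_ms), , drop = FALSE]
  rownames(bursts) <- NULL

  activity <- structure(
    list(time_ms = seq_len(duration_ms) - 1L, fraction = act,
         bursts = bursts, duration_ms = duration_ms),
    class = "population_activity")

  recording <- if (render) render_line_scan(activity, config, protocol) else NULL
  list(activity = activity, recording = recording)
}

# Burst waveform on the 1 ms activity grid: linear rise over the ignition
# delay, plateau at the recruited fraction, then silence (the calcium
# kernel supplies the slow fluorescence decay).
add_burst_waveform <- function(act, t_ms, delay_steps, fraction,
                               burst_duration_ms) {
  n <- length(act)
  start <- floor(t_ms) + 1L  # 1-based index of the ignition millisecond
  if (delay_steps > 0) {
    idx <- start + seq_len(delay_steps) - 1L
    keep <- idx >= 1L & idx <= n
    act[idx[keep]] <- pmax(act[idx[keep]],
                           fraction * seq_len(delay_steps)[keep] / delay_steps)
  }
  p0 <- start + delay_steps
  idx <- p0 + seq_len(max(1L, round(burst_duration_ms))) - 1L
  idx <- idx[idx >= 1L & idx <= n]
  act[idx] <- pmax(act[idx], fraction)
  act
}

# Derived sub-stream seed, kept inside 32-bit integer range.
sub_seed <- function(base, k) {
  as.integer((as.numeric(base) * 101 + k) %% 2147483629)
}

#' Simulate an isolated (single-population) culture
#'
#' A plain culture in a well — the preparation used for the
#' imaging-intensity and stimulus-duration experiments, and the preparation
#' whose spontaneous bursting rate (5.9 ± 2.2 bursts/min) the simulator's
#' defaults are calibrated to — is a single population with no coupled
#' neighbour. This wrapper zeroes the inter-compartment axon counts and
#' runs [simulate_experiment()]; read the culture's trace from compartment
#' A. (In a connected device each compartment also receives its
#' neighbour's relayed bursts, so its observed rate exceeds the isolated
#' rate.)
#'
#' @inheritParams simulate_experiment
#' @return As [simulate_experiment()].
#' @export
simulate_culture <- function(config, protocol = stim_protocol(), duration_ms,
                             ...) {
  config$n_axons_forward <- 0L
  config$n_axons_reverse <- 0L
  simulate_experiment(config, protocol, duration_ms, ...)
}

#' @export
print.population_activity <- function(x, ...) {
  cat(sprintf("<population_activity> %g s, %d ground-truth burst(s)\n",
              x$duration_ms / 1000, nrow(x$bursts)))
  if (nrow(x$bursts)) print(utils::head(x$bursts, 10))
  invisible(x)
}
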