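#' Simulation configuration for a two-compartment optogenetic culture
#'
#' Collects every biological, optical and acquisition parameter of the
#' synthetic experiment. Defaults describe a healthy DIV 13-15 hippocampal
#' culture in a two-well microfluidic device: ~70% of excitatory neurons
#' transduced with ChR2 (inhibitory neurons never express the CaMKIIa-driven
#' construct), spontaneous network bursts every 5-10 s, and a confocal
#' line scan at 8 kHz integrated over 8 cycles for a 1 kHz effective
#' sampling rate.
#'
#' @param n_neurons Neurons per compartment. The physical seeding density
#'   (~5000 neurons/mm^2 on a 2 mm well, i.e. ~15,700 plated) is scaled to a
#'   default of 2000 simulated neurons; quorum-percolation behaviour is
#'   governed by fractions and in-degree, not absolute count.
#' @param inhibitory_fraction Fraction of neurons that are inhibitory
#'   (GABAergic), in `[0, 1]`. Cultures typically carry 10-20%; default 0.15.
#' @param transduced_fraction Fraction of *excitatory* neurons expressing
#'   ChR2. Scalar, or length-2 vector giving compartments A and B separately
#'   (one-sided transduction devices). Inhibitory neurons are never
#'   transduced. Default 0.70.
#' @param quorum_threshold Number of simultaneously active presynaptic
#'   inputs (at unit efficacy) required to recruit a neuron into a burst.
#' @param mean_in_degree Expected within-compartment synaptic in-degree;
#'   in-degrees are Poisson distributed (directed Erdos-Renyi graph).
#' @param synaptic_efficacy Dimensionless weight applied to each active
#'   input before comparison with `quorum_threshold`.
#' @param cnqx_concentration CNQX concentration in uM. Mapped linearly to a
#'   synaptic efficacy multiplier `max(0, 1 - c/10)`: 10 uM (the lowest
#'   saturating concentration) blocks transmission completely, 5 uM halves it.
#' @param n_axons_forward,n_axons_reverse Inter-compartment axons per
#'   direction (forward = A to B). A symmetric straight-channel device has
#'   equal counts; an axon-diode device keeps ~3% of them in the reverse
#'   direction (see [diode_config()]).
#' @param photoactivation_rate Per-neuron activation rate constant (1/ms)
#'   under 470 nm light: a transduced neuron fires during a pulse of
#'   duration d with probability `1 - exp(-rate * d * intensity)`.
#' @param crosstalk_549_activation Per-neuron activation probability per
#'   unit 549 nm imaging intensity (spectral crosstalk). Default 0: Calcium
#'   Orange excitation light does not open ChR2.
#' @param spontaneous_burst_rate Rate (bursts/minute) of the Poisson process
#'   proposing spontaneous ignitions. With the 3 s post-burst dead time that
#'   applies to spontaneous (never evoked) ignitions, the emitted rate is
#'   `r/(1 + r * 3s)`; the default 8.4/min therefore emits ~5.9 bursts/min.
#' @param spontaneous_seed Neurons recruited by the initiating event of a
#'   spontaneous burst before percolation takes over.
#' @param propagation_threshold Minimum recruited fraction for a burst to be
#'   relayed through the inter-compartment axon bundle.
#' @param burst_duration_ms Plateau duration of collective activity during a
#'   network burst, before neurons fall silent again.
#' @param disinhibition_gain Multiplier on the calcium response amplitude
#'   when inhibitory neurons are silenced by saturating CNQX (their only
#'   excitation path is AMPAergic). Interpolated by CNQX efficacy between 1
#'   (drug-free) and this value (saturating).
#' @param ca_rise_tau,ca_decay_tau Calcium-indicator kernel time constants
#'   (ms). The indicator's kinetics are not published; defaults 10/500 ms
#'   make single bursts resolvable at 1 kHz.
#' @param ca_amplitude Peak dF/F of a fully recruited burst.
#' @param ca_saturation Half-saturation constant of the indicator response,
#'   in units of the normalized calcium drive (1 = the drive of a canonical
#'   fully recruited burst). Bulk-loaded dye is nearly saturated by a full
#'   network burst, so sustained full-population activity cannot push the
#'   fluorescence much higher, while sub-saturation responses (partial
#'   recruitment under CNQX) still grow with drive. Large values make the
#'   read-out effectively linear.
#' @param baseline_F Baseline fluorescence (arbitrary units).
#' @param noise_sigma SD of additive Gaussian noise per scan line, same
#'   units as `baseline_F`.
#' @param line_rate Line-scan frequency, Hz.
#' @param cycles_per_sample Scan lines integrated per stored sample; the
#'   effective sampling rate is exactly `line_rate / cycles_per_sample`.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [diode_config()], [simulate_experiment()], [cnqx_multiplier()]
#' @examples
#' cfg <- sim_config(seed = 42)
#' cfg$line_rate / cfg$cycles_per_sample  # 1000 Hz effective sampling
#' @export
sim_config <- function(n_neurons = 2000,
                       inhibitory_fraction = 0.15,
                       transduced_fraction = 0.70,
                       quorum_threshold = 2,
                       mean_in_degree = 100,
                       synaptic_efficacy = 1,
                       cnqx_concentration = 0,
                       n_axons_forward = 100,
                       n_axons_reverse = 100,
                       photoactivation_rate = 0.1,
                       crosstalk_549_activation = 0,
                       spontaneous_burst_rate = 8.4,
                       spontaneous_seed = 50,
                       propagation_threshold = 0.5,
                       burst_duration_ms = 100,
                       disinhibition_gain = 2,
                       ca_rise_tau = 10,
                       ca_decay_tau = 500,
                       ca_amplitude = 0.8,
                       ca_saturation = 0.15,
                       baseline_F = 100,
                       noise_sigma = 2,
                       line_rate = 8000,
                       cycles_per_sample = 8,
                       seed = 1L) {
  cfg <- list(
    n_neurons = n_neurons,
    inhibitory_fraction = inhibitory_fraction,
    transduced_fraction = transduced_fraction,
    quorum_threshold = quorum_threshold,
    mean_in_degree = mean_in_degree,
    synaptic_efficacy = synaptic_efficacy,
    cnqx_concentration = cnqx_concentration,
    n_axons_forward = n_axons_forward,
    n_axons_reverse = n_axons_reverse,
    photoactivation_rate = photoactivation_rate,
    crosstalk_549_activation = crosstalk_549_activation,
    spontaneous_burst_rate = spontaneous_burst_rate,
    spontaneous_seed = spontaneous_seed,
    propagation_threshold = propagation_threshold,
    burst_duration_ms = burst_duration_ms,
    disinhibition_gain = disinhibition_gain,
    ca_rise_tau = ca_rise_tau,
    ca_decay_tau = ca_decay_tau,
    ca_amplitude = ca_amplitude,
    ca_saturation = ca_saturation,
    baseline_F = baseline_F,
    noise_sigma = noise_sigma,
    line_rate = line_rate,
    cycles_per_sample = cycles_per_sample,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Axon-diode variant of a simulation configuration
#'
#' Same defaults as [sim_config()] but with the reverse axon count reduced
#' to the ~3% of the forward count that escapes the narrowing micro-channel
#' geometry.
#'
#' @param ... Passed on to [sim_config()].
#' @param reverse_fraction Fraction of forward axons growing in the reverse
#'   direction (default 0.03).
#' @return A `sim_config`.
#' @export
diode_config <- function(..., reverse_fraction = 0.03) {
  cfg <- sim_config(...)
  cfg$n_axons_reverse <- max(0L, round(reverse_fraction * cfg$n_axons_forward))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_frac <- function(x, nm, max_len = 1L) {
    if (!is.numeric(x) || length(x) < 1L || length(x) > max_len ||
        anyNA(x) || any(x < 0) || any(x > 1)) {
      stop(sprintf("'%s' must be in [0, 1]", nm), call. = FALSE)
    }
  }
  chk_nonneg <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
      stop(sprintf("'%s' must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  chk_frac(cfg$inhibitory_fraction, "inhibitory_fraction")
  chk_frac(cfg$transduced_fraction, "transduced_fraction", max_len = 2L)
  chk_frac(cfg$propagation_threshold, "propagation_threshold")
  for (nm in c("n_neurons", "quorum_threshold", "mean_in_degree",
               "synaptic_efficacy", "cnqx_concentration", "n_axons_forward",
               "n_axons_reverse", "photoactivation_rate",
               "crosstalk_549_activation", "spontaneous_burst_rate",
               "spontaneous_seed", "burst_duration_ms", "ca_rise_tau",
               "ca_decay_tau", "ca_amplitude", "baseline_F", "noise_sigma",
               "line_rate")) {
    chk_nonneg(cfg[[nm]], nm)
  }
  if (cfg$ca_saturation <= 0) {
    stop("'ca_saturation' must be > 0", call. = FALSE)
  }
  if (cfg$disinhibition_gain < 1) {
    stop("'disinhibition_gain' must be >= 1", call. = FALSE)
  }
  if (cfg$cycles_per_sample < 1 ||
      cfg$cycles_per_sample != round(cfg$cycles_per_sample)) {
    stop("'cycles_per_sample' must be an integer >= 1", call. = FALSE)
  }
  if (cfg$line_rate <= 0) stop("'line_rate' must be positive", call. = FALSE)
  if (cfg$ca_rise_tau >= cfg$ca_decay_tau) {
    stop("'ca_rise_tau' must be smaller than 'ca_decay_tau'", call. = FALSE)
  }
  cfg
}

#' Effective sampling rate of the line-scan acquisition
#'
#' The photometric signal is integrated over `cycles_per_sample` consecutive
#' scan lines per stored data point, so the stored rate is exactly
#' `line_rate / cycles_per_sample` (8 kHz over 8 cycles gives 1 kHz).
#'
#' @param config A [sim_config()].
#' @return Sampling rate in Hz.
#' @export
effective_sampling_rate <- function(config) {
  config$line_rate / config$cycles_per_sample
}

#' CNQX efficacy multiplier
#'
#' Maps a CNQX concentration to a multiplier on synaptic efficacy,
#' `max(0, 1 - concentration / saturating)`: the lowest saturating
#' concentration (10 uM) abolishes AMPAergic transmission, an
#' under-saturating 5 uM halves it, 0 leaves it intact.
#'
#' @param concentration_uM CNQX concentration, uM.
#' @param saturating_uM Concentration at which transmission is fully
#'   blocked (default 10).
#' @return Multiplier in `[0, 1]`.
#' @export
cnqx_multiplier <- function(concentration_uM, saturating_uM = 10) {
  if (any(concentration_uM < 0)) stop("CNQX concentration must be >= 0")
  pmax(0, 1 - concentration_uM / saturating_uM)
}

# Per-compartment transduced fraction ("A" or "B"); scalar configs apply to
# both compartments.
transduced_fraction_of <- function(config, compartment) {
  tf <- config$transduced_fraction
  if (length(tf) == 1L) return(tf)
  tf[[match(compartment, c("A", "B"))]]
}

# Partition neuron indices 1..N into inhibitory / excitatory and mark the
# transduced subset. Inhibitory neurons are never transduced (the CaMKIIa
# promoter driving ChR2 is inactive in GABAergic neurons).
assign_populations <- function(config, compartment = "A") {
  n <- config$n_neurons
  n_inhib <- round(n * config$inhibitory_fraction)
  n_excit <- n - n_inhib
  tf <- transduced_fraction_of(config, compartment)
  n_transduced <- round(n_excit * tf)
  list(
    excitatory = seq_len(n_excit),
    inhibitory = if (n_inhib > 0) seq.int(n_excit + 1L, n) else integer(0),
    transduced = seq_len(n_transduced),
    n_transduced = n_transduced
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d neurons/compartment (%.0f%% inhibitory, %s transduced)\n",
              x$n_neurons, 100 * x$inhibitory_fraction,
              paste0(round(100 * x$transduced_fraction), "%",
                     collapse = "/")))
  cat(sprintf("  quorum threshold %g, mean in-degree %g, efficacy %g, CNQX %g uM (x%.2f)\n",
              x$quorum_threshold, x$mean_in_degree, x$synaptic_efficacy,
              x$cnqx_concentration, cnqx_multiplier(x$cnqx_concentration)))
  cat(sprintf("  axons forward/reverse: %d/%d\n",
              x$n_axons_forward, x$n_axons_reverse))
  cat(sprintf("  acquisition: %g Hz lines x %d cycles -> %g Hz; seed %d\n",
              x$line_rate, x$cycles_per_sample, effective_sampling_rate(x),
              x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as JSON
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}

# Stable short provenance hash of an object's canonical JSON form.
# Polynomial string hash mod 2^31 - 1 (exact in double arithmetic).
config_hash <- function(x) {
  if (inherits(x, "sim_config")) x <- unclass(x)
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  b <- utf8ToInt(as.character(s))
  h <- 0
  m <- 2147483647
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% m
  sprintf("%08x", as.integer(h))
}
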