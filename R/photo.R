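#' Direct photo-activation of transduced neurons
#'
#' During a 470 nm pulse each ChR2-expressing neuron of the target
#' compartment fires with probability `1 - exp(-rate * duration * intensity)`,
#' so the number of directly activated neurons is binomial in the transduced
#' count; the light-recruited seed therefore grows with stimulus duration
#' even though synaptic percolation usually hides this dependence. Only
#' excitatory neurons can be transduced. A 549 nm imaging event activates
#' through the spectral-crosstalk probability instead, which is zero by
#' default (Calcium Orange excitation does not open ChR2).
#'
#' @param pulse One-row subset of a [stim_protocol()] (an event).
#' @param config A [sim_config()].
#' @return Integer count of directly activated neurons (a random draw).
#' @examples
#' set.seed(1)
#' cfg <- sim_config(photoactivation_rate = 0.1)
#' p <- stim_protocol(onset_ms = 0, duration_ms = 16, compartment = "A")
#' photo_activate(p[1, ], cfg)
#' @export
photo_activate <- function(pulse, config) {
  if (nrow(as.data.frame(pulse)) != 1L) {
    stop("'pulse' must be a single stimulation event", call. = FALSE)
  }
  pop <- assign_populations(config, pulse$compartment)
  n_eligible <- pop$n_transduced
  if (pulse$role == "stimulation_470") {
    p <- 1 - exp(-config$photoactivation_rate * pulse$duration_ms *
                   pulse$intensity)
  } else if (pulse$role == "imaging_549") {
    p <- min(1, config$crosstalk_549_activation * pulse$intensity)
  } else {
    stop("unknown stimulation role: ", pulse$role, call. = FALSE)
  }
  stats::rbinom(1L, n_eligible, p)
}
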