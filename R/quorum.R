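#' Quorum-percolation burst ignition
#'
#' Network bursts in dense cultures behave like a percolation process: a
#' neuron joins the burst once enough of its presynaptic inputs are already
#' active, and a sufficiently large seed recruits the whole population.
#' These functions implement the canonical discrete-threshold formulation on
#' a directed random graph with Poisson in-degrees, updated synchronously
#' until a fixed point.
#'
#' A neuron activates when
#' `#active_inputs * synaptic_efficacy * cnqx_multiplier >= quorum_threshold`;
#' active neurons stay active for the duration of the ignition. Under
#' saturating CNQX the multiplier is 0 and nothing beyond the seed is ever
#' recruited.
#'
#' @name quorum
NULL

#' Build a random synaptic graph for one compartment
#'
#' Directed Erdos-Renyi-type graph: each neuron independently draws
#' `Poisson(mean_in_degree)` presynaptic partners uniformly (with
#' replacement; multi-edges count as parallel synapses).
#'
#' @param n_neurons Number of neurons.
#' @param mean_in_degree Expected in-degree.
#' @return A `quorum_graph`: list with integer vectors `pre` and `post`
#'   (one entry per synapse) and `n_neurons`.
#' @export
make_quorum_graph <- function(n_neurons, mean_in_degree) {
  stopifnot(n_neurons >= 1, mean_in_degree >= 0)
  k <- stats::rpois(n_neurons, mean_in_degree)
  post <- rep.int(seq_len(n_neurons), k)
  pre <- sample.int(n_neurons, length(post), replace = TRUE)
  structure(list(pre = pre, post = post, n_neurons = as.integer(n_neurons)),
            class = "quorum_graph")
}

#' Deterministic quorum percolation on an explicit graph
#'
#' Synchronous threshold iteration: at each step every inactive neuron
#' counts its active presynaptic inputs (multi-edges counted with
#' multiplicity) and activates when the weighted count reaches the
#' threshold. Iterates to the fixed point.
#'
#' @param graph A [make_quorum_graph()] object, or any list with `pre`,
#'   `post`, `n_neurons`.
#' @param seed_neurons Integer indices of the initially active neurons.
#' @param quorum_threshold Inputs needed at unit weight.
#' @param efficacy Weight per active input (synaptic efficacy times the
#'   CNQX multiplier). Zero disables recruitment entirely.
#' @return List: `active` (logical per neuron), `recruited_fraction`,
#'   `ignition_delay_steps` (synchronous steps to reach 95% of the final
#'   recruited count; 0 if the seed already is the fixed point),
#'   `fraction_by_step` (fraction active after each step, step 0 = seed).
#' @export
quorum_percolate <- function(graph, seed_neurons, quorum_threshold,
                             efficacy = 1) {
  n <- graph$n_neurons
  if (any(seed_neurons < 1L) || any(seed_neurons > n)) {
    stop("seed neuron indices out of range", call. = FALSE)
  }
  active <- logical(n)
  active[seed_neurons] <- TRUE
  frac <- mean(active)
  # effective integer threshold on the raw input count
  thr <- if (efficacy <= 0) Inf else quorum_threshold / efficacy
  if (is.finite(thr) && length(graph$pre)) {
    repeat {
      cnt <- tabulate(graph$post[active[graph$pre]], nbins = n)
      newly <- !active & cnt >= thr
      if (!any(newly)) break
      active <- active | newly
      frac <- c(frac, mean(active))
    }
  }
  final <- frac[length(frac)]
  delay <- if (final == 0) 0L else {
    # first step at which >= 95% of the final recruited count is active
    as.integer(which(frac >= 0.95 * final)[1L] - 1L)
  }
  list(active = active, recruited_fraction = final,
       ignition_delay_steps = delay, fraction_by_step = frac)
}

#' Ignite a burst from a random seed
#'
#' Draws a fresh random graph from the configuration, activates
#' `n_seed_active` uniformly chosen neurons, and percolates. One synchronous
#' update corresponds to one synaptic integration step of 1 ms, matching
#' the 1 kHz read-out granularity.
#'
#' @param n_seed_active Number of initially active neurons.
#' @param config A [sim_config()]; uses `n_neurons`, `mean_in_degree`,
#'   `quorum_threshold`, `synaptic_efficacy`, `cnqx_concentration`.
#' @param graph Optional pre-built [make_quorum_graph()] to reuse across
#'   ignitions of the same compartment.
#' @return As [quorum_percolate()].
#' @examples
#' set.seed(1)
#' cfg <- sim_config(n_neurons = 500)
#' ignite_quorum(25, cfg)$recruited_fraction
#' @export
ignite_quorum <- function(n_seed_active, config, graph = NULL) {
  if (n_seed_active < 0) stop("'n_seed_active' must be >= 0", call. = FALSE)
  n <- config$n_neurons
  if (n_seed_active > n) {
    stop("'n_seed_active' exceeds the compartment size", call. = FALSE)
  }
  if (is.null(graph)) graph <- make_quorum_graph(n, config$mean_in_degree)
  seed <- if (n_seed_active > 0) sample.int(n, n_seed_active) else integer(0)
  eff <- config$synaptic_efficacy * cnqx_multiplier(config$cnqx_concentration)
  quorum_percolate(graph, seed, config$quorum_threshold, eff)
}
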