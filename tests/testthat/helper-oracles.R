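# Independent oracles and small constructors shared across tests.

# Brute-force quorum percolation: literal synchronous iteration over an
# explicit adjacency matrix, written independently of the package's
# edge-list implementation.
oracle_quorum <- function(adj, seed_idx, threshold, efficacy = 1) {
  n <- nrow(adj)
  active <- logical(n)
  active[seed_idx] <- TRUE
  if (efficacy > 0) {
    repeat {
      inputs <- as.vector(t(adj) %*% active)  # adj[i, j]: synapse i -> j
      newly <- !active & (inputs * efficacy >= threshold)
      if (!any(newly)) break
      active <- active | newly
    }
  }
  active
}

# Convert an adjacency matrix (entry = synapse count from row to column)
# into the package's edge-list graph.
graph_from_adj <- function(adj) {
  idx <- which(adj > 0, arr.ind = TRUE)
  pre <- rep(idx[, 1], adj[idx])
  post <- rep(idx[, 2], adj[idx])
  structure(list(pre = as.integer(pre), post = as.integer(post),
                 n_neurons = nrow(adj)),
            class = "quorum_graph")
}

# Naive normalized cross-correlation, an explicit double loop.
oracle_xcorr <- function(x, y, max_lag, min_overlap = 10) {
  out <- data.frame(lag = -max_lag:max_lag, coefficient = NA_real_)
  n <- length(x)
  for (r in seq_len(nrow(out))) {
    l <- out$lag[r]
    xs <- c(); ys <- c()
    for (t in seq_len(n)) {
      if (t + l >= 1 && t + l <= n &&
          !is.na(x[t]) && !is.na(y[t + l])) {
        xs <- c(xs, x[t]); ys <- c(ys, y[t + l])
      }
    }
    if (length(xs) >= min_overlap && stats::sd(xs) > 0 && stats::sd(ys) > 0) {
      out$coefficient[r] <- stats::cor(xs, ys)
    }
  }
  out
}

# Hand-built recording for trace-processing tests.
make_recording <- function(trace_A, trace_B = trace_A,
                           mask_A = rep(FALSE, length(trace_A)),
                           mask_B = mask_A,
                           sampling_rate = 1000,
                           protocol = stim_protocol()) {
  trace_A[mask_A] <- NA_real_
  trace_B[mask_B] <- NA_real_
  structure(
    list(sampling_rate = sampling_rate,
         time_ms = (seq_along(trace_A) - 1) * 1000 / sampling_rate,
         trace_A = trace_A, trace_B = trace_B,
         mask_A = mask_A, mask_B = mask_B,
         protocol = protocol,
         provenance = list(source = "imported")),
    class = "linescan_recording")
}

# A calcium-transient-shaped template at 1 kHz: n_ms samples, transient
# starting at onset_ms, unit peak.
transient_template <- function(n_ms, onset_ms, rise = 10, decay = 500) {
  t <- seq_len(n_ms) - 1 - onset_ms
  v <- ifelse(t < 0, 0, exp(-t / decay) - exp(-t / rise))
  v / max(v)
}

# Small fast configuration for simulation-backed tests.
test_config <- function(...) {
  sim_config(n_neurons = 600, seed = 1234, ...)
}
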