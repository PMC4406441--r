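#' Convert a fluorescence trace to dF/F
#'
#' Baseline F0 is a rolling low percentile of the unmasked samples (10th
#' percentile over 10 s windows by default): with bursts occupying well
#' under half of the recording, a low percentile tracks the quiescent
#' fluorescence while ignoring transients. The percentile is evaluated on
#' consecutive windows and linearly interpolated between window centres.
#' Masked samples stay `NA`.
#'
#' @param recording A `linescan_recording`.
#' @param compartment `"A"` or `"B"`.
#' @param percentile Baseline percentile in (0, 1); default 0.10.
#' @param window_s Baseline window length in seconds; default 10.
#' @return A `dff_trace`: list with `dff`, `time_ms`, `mask`,
#'   `sampling_rate`, `f0`.
#' @export
compute_dff <- function(recording, compartment = "A", percentile = 0.10,
                        window_s = 10) {
  validate_linescan_recording(recording)
  f <- recording[[paste0("trace_", compartment)]]
  mask <- recording[[paste0("mask_", compartment)]]
  if (all(mask) || all(is.na(f))) {
    stop("trace has no unmasked samples", call. = FALSE)
  }
  n <- length(f)
  win <- max(1L, round(window_s * recording$sampling_rate))
  starts <- seq.int(1L, n, by = win)
  centres <- pmin(starts + (win - 1) / 2, n)
  q <- vapply(starts, function(s) {
    chunk <- f[s:min(s + win - 1L, n)]
    chunk <- chunk[!is.na(chunk)]
    if (length(chunk)) stats::quantile(chunk, percentile, names = FALSE)
    else NA_real_
  }, numeric(1))
  ok <- !is.na(q)
  if (!any(ok)) stop("trace has no unmasked samples", call. = FALSE)
  f0 <- if (sum(ok) == 1L) rep(q[ok], n) else {
    stats::approx(centres[ok], q[ok], xout = seq_len(n), rule = 2)$y
  }
  if (any(f0 <= 0)) stop("non-positive baseline; dF/F undefined", call. = FALSE)
  structure(list(dff = (f - f0) / f0, time_ms = recording$time_ms,
                 mask = mask, sampling_rate = recording$sampling_rate,
                 f0 = f0),
            class = "dff_trace")
}

#' Detect network bursts in a dF/F trace
#'
#' Events are upward threshold crossings: the onset is the crossing sample,
#' the peak the maximum before the trace falls back below threshold, the
#' duration the supra-threshold time. Events separated by less than
#' `min_separation_ms` are merged (one burst, one calcium transient).
#' Masked gaps up to `bridge_max_ms` (the longest stimulus, 1024 ms, by
#' default) are bridged by linear interpolation before detection so a
#' transient split by a stimulation-saturation gap still counts once;
#' longer gaps split events.
#'
#' @param dff A `dff_trace` (or plain numeric vector at `sampling_rate`).
#' @param threshold_dff Detection threshold in dF/F units. Default
#'   `5 * mad(dff)`: five times the median absolute deviation of the trace,
#'   a robust noise-floor estimate since bursts are sparse in time.
#' @param min_separation_ms Merge window (default 500 ms, well below the
#'   5-10 s physiological inter-burst interval, above the transient width).
#' @param bridge_max_ms Longest masked gap bridged by interpolation.
#' @param sampling_rate Used when `dff` is a bare numeric vector.
#' @return A data.frame of burst events: `onset_ms`, `peak_ms`, `peak_dff`,
#'   `duration_ms`.
#' @export
detect_bursts <- function(dff, threshold_dff = NULL, min_separation_ms = 500,
                          bridge_max_ms = 1024, sampling_rate = 1000) {
  if (inherits(dff, "dff_trace")) {
    x <- dff$dff; t0 <- dff$time_ms; sr <- dff$sampling_rate
  } else {
    x <- as.numeric(dff); sr <- sampling_rate
    t0 <- (seq_along(x) - 1) * 1000 / sr
  }
  dt <- 1000 / sr
  maxgap <- max(0L, floor(bridge_max_ms / dt))
  if (anyNA(x) && maxgap > 0) {
    x <- zoo::na.approx(x, na.rm = FALSE, maxgap = maxgap)
  }
  if (is.null(threshold_dff)) {
    threshold_dff <- 5 * stats::mad(x, na.rm = TRUE)
  }
  if (threshold_dff <= 0) stop("'threshold_dff' must be > 0", call. = FALSE)

  above <- !is.na(x) & x > threshold_dff
  if (!any(above)) {
    return(data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      peak_dff = numeric(0), duration_ms = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_i <- starts[r$values]
  off_i <- ends[r$values]

  # merge runs whose gap is below the separation window
  if (length(on_i) > 1L) {
    gap_ms <- (on_i[-1L] - off_i[-length(off_i)]) * dt
    grp <- cumsum(c(1L, as.integer(gap_ms >= min_separation_ms)))
    on_i <- tapply(on_i, grp, min)
    off_i <- tapply(off_i, grp, max)
  }
  ev <- lapply(seq_along(on_i), function(k) {
    seg <- x[on_i[k]:off_i[k]]
    pk <- which.max(seg)
    data.frame(onset_ms = t0[on_i[k]],
               peak_ms = t0[on_i[k] + pk - 1L],
               peak_dff = seg[pk],
               duration_ms = (off_i[k] - on_i[k] + 1L) * dt)
  })
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Bursting rate
#'
#' @param events Burst-event data.frame from [detect_bursts()] (or anything
#'   with one row per burst).
#' @param duration_min Recording duration in minutes.
#' @return Bursts per minute.
#' @export
bursting_rate <- function(events, duration_min) {
  if (duration_min <= 0) stop("'duration_min' must be > 0", call. = FALSE)
  nrow(as.data.frame(events)) / duration_min
}

#' Normalize bursting rates by a per-culture reference condition
#'
#' Removes inter-culture variability in baseline activity by dividing each
#' culture's rates by its own rate at the reference condition (e.g. the 1x
#' imaging-intensity recording), so the reference condition maps to 1 for
#' every culture.
#'
#' @param rates A data.frame with columns `culture`, `condition`, `rate`.
#' @param reference_condition The condition used as the denominator.
#' @return A `rate_table`: the input with a `normalized_rate` column;
#'   cultures whose reference rate is zero are dropped with a warning.
#' @examples
#' r <- data.frame(culture = "c1", condition = c("1x", "2x", "4x"),
#'                 rate = c(6.0, 6.3, 5.8))
#' normalize_rates(r, "1x")
#' @export
normalize_rates <- function(rates, reference_condition) {
  rates <- as.data.frame(rates)
  need <- c("culture", "condition", "rate")
  if (!all(need %in% names(rates))) {
    stop("'rates' needs columns culture, condition, rate", call. = FALSE)
  }
  refs <- rates[rates$condition == reference_condition, , drop = FALSE]
  if (!all(unique(rates$culture) %in% refs$culture)) {
    stop("every culture needs a measurement at the reference condition",
         call. = FALSE)
  }
  ref_rate <- stats::setNames(refs$rate, refs$culture)
  bad <- names(ref_rate)[ref_rate <= 0]
  if (length(bad)) {
    warning("dropping culture(s) with zero reference rate: ",
            paste(bad, collapse = ", "))
    rates <- rates[!rates$culture %in% bad, , drop = FALSE]
    ref_rate <- ref_rate[!names(ref_rate) %in% bad]
  }
  rates$normalized_rate <- rates$rate / ref_rate[as.character(rates$culture)]
  rownames(rates) <- NULL
  class(rates) <- c("rate_table", "data.frame")
  rates
}

#' Bin a trace by averaging fixed-width chunks
#'
#' Mean of the unmasked samples in each `bin_ms` chunk (used to de-noise
#' stimulus-duration response curves with 50 ms bins); a bin with no
#' unmasked sample is `NA`.
#'
#' @param trace Numeric vector (may contain `NA` for masked samples) or a
#'   `dff_trace`.
#' @param bin_ms Bin width; must be a multiple of the sample interval.
#' @param sampling_rate Hz, for bare numeric input.
#' @return List with `time_ms` (bin starts) and `value` (bin means).
#' @export
bin_trace <- function(trace, bin_ms, sampling_rate = 1000) {
  if (inherits(trace, "dff_trace")) {
    x <- trace$dff; sr <- trace$sampling_rate; t0 <- trace$time_ms[1]
  } else {
    x <- as.numeric(trace); sr <- sampling_rate; t0 <- 0
  }
  dt <- 1000 / sr
  k <- bin_ms / dt
  if (abs(k - round(k)) > 1e-9) {
    stop("'bin_ms' must be a multiple of the sample interval", call. = FALSE)
  }
  k <- as.integer(round(k))
  n_bins <- length(x) %/% k
  m <- matrix(x[seq_len(n_bins * k)], nrow = k)
  v <- colMeans(m, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  list(time_ms = t0 + (seq_len(n_bins) - 1) * bin_ms, value = v)
}
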