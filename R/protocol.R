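#' Stimulation protocols
#'
#' A `stim_protocol` is an ordered table of timed light pulses. Each event
#' targets one compartment ("A" or "B") with one of two roles:
#' `"stimulation_470"` (blue light opening ChR2 in transduced neurons) or
#' `"imaging_549"` (Calcium Orange excitation light, which by design does
#' not activate ChR2). Intensity is relative to the 1x reference level used
#' during standard imaging.
#'
#' @param onset_ms,duration_ms Event timing in ms; windows are half-open
#'   `[onset, onset + duration)`.
#' @param compartment `"A"` or `"B"`.
#' @param role `"stimulation_470"` or `"imaging_549"`.
#' @param intensity Relative intensity (1 = baseline).
#' @return A `stim_protocol`: a data.frame with columns `onset_ms`,
#'   `duration_ms`, `compartment`, `role`, `intensity`, sorted by onset.
#' @examples
#' stim_protocol(onset_ms = c(5000, 15000), duration_ms = 5,
#'               compartment = c("A", "B"))
#' @export
stim_protocol <- function(onset_ms = numeric(0), duration_ms = numeric(0),
                          compartment = character(0),
                          role = "stimulation_470", intensity = 1) {
  n <- length(onset_ms)
  if (n == 0L) {
    duration_ms <- numeric(0); compartment <- character(0)
    role <- character(0); intensity <- numeric(0)
  }
  p <- data.frame(
    onset_ms = as.numeric(onset_ms),
    duration_ms = as.numeric(duration_ms),
    compartment = as.character(compartment),
    role = as.character(role),
    intensity = as.numeric(intensity),
    stringsAsFactors = FALSE
  )
  p <- p[order(p$onset_ms), , drop = FALSE]
  rownames(p) <- NULL
  class(p) <- c("stim_protocol", "data.frame")
  validate_stim_protocol(p)
}

validate_stim_protocol <- function(p) {
  stopifnot(is.data.frame(p))
  need <- c("onset_ms", "duration_ms", "compartment", "role", "intensity")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop("protocol is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(p) == 0L) return(p)
  if (any(p$duration_ms <= 0)) stop("event durations must be > 0", call. = FALSE)
  if (is.unsorted(p$onset_ms)) stop("events must be sorted by onset", call. = FALSE)
  if (!all(p$compartment %in% c("A", "B"))) {
    stop("compartment must be 'A' or 'B'", call. = FALSE)
  }
  if (!all(p$role %in% c("stimulation_470", "imaging_549"))) {
    stop("unknown stimulation role", call. = FALSE)
  }
  # no two 470 nm pulses may overlap on the same compartment
  for (cp in c("A", "B")) {
    e <- p[p$role == "stimulation_470" & p$compartment == cp, , drop = FALSE]
    if (nrow(e) > 1L) {
      ends <- e$onset_ms + e$duration_ms
      if (any(e$onset_ms[-1L] < ends[-nrow(e)])) {
        stop("overlapping 470 nm pulses on compartment ", cp, call. = FALSE)
      }
    }
  }
  p
}

#' Alternating two-sided stimulation protocol
#'
#' The standard connectivity protocol: short 470 nm pulses delivered in
#' alternation to the two compartments, one pulse every `interval_s` seconds
#' (0.1 Hz overall by default), `n_per_side` pulses per side.
#'
#' @param n_per_side Pulses per compartment (default 30).
#' @param interval_s Seconds between consecutive pulses (default 10,
#'   i.e. 0.1 Hz; each side is revisited every `2 * interval_s`).
#' @param pulse_ms Pulse duration in ms (default 5).
#' @param start_s Time of the first pulse, s.
#' @param intensity Relative intensity.
#' @param first Compartment stimulated first.
#' @return A [stim_protocol()].
#' @export
alternating_protocol <- function(n_per_side = 30, interval_s = 10,
                                 pulse_ms = 5, start_s = 5, intensity = 1,
                                 first = "A") {
  n <- 2L * n_per_side
  onsets <- (start_s + interval_s * (seq_len(n) - 1L)) * 1000
  sides <- rep(if (first == "A") c("A", "B") else c("B", "A"),
               length.out = n)
  stim_protocol(onset_ms = onsets, duration_ms = pulse_ms,
                compartment = sides, role = "stimulation_470",
                intensity = intensity)
}

#' Stimulus-duration series protocol
#'
#' One pulse per duration, spaced `interval_s` seconds apart (5 s by
#' default: slow enough to avoid short-term plasticity, fast enough that a
#' spontaneous burst rarely precedes a pulse). The classic series doubles
#' from 1 to 1024 ms.
#'
#' @param durations_ms Pulse durations in ms.
#' @param repetitions Repetitions of the whole series.
#' @param interval_s Seconds between pulse onsets.
#' @param start_s Time of the first pulse, s.
#' @param compartment Stimulated compartment.
#' @param intensity Relative intensity.
#' @return A [stim_protocol()].
#' @export
duration_series_protocol <- function(durations_ms = 2^(0:10),
                                     repetitions = 1, interval_s = 5,
                                     start_s = 5, compartment = "A",
                                     intensity = 1) {
  durs <- rep(durations_ms, times = repetitions)
  onsets <- (start_s + interval_s * (seq_along(durs) - 1L)) * 1000
  stim_protocol(onset_ms = onsets, duration_ms = durs,
                compartment = compartment, role = "stimulation_470",
                intensity = intensity)
}

#' Duration (ms) needed to contain a protocol plus a post-stimulus margin
#' @param protocol A [stim_protocol()].
#' @param margin_s Seconds appended after the last event.
#' @return Duration in ms.
#' @export
protocol_duration <- function(protocol, margin_s = 5) {
  if (nrow(protocol) == 0L) return(margin_s * 1000)
  max(protocol$onset_ms + protocol$duration_ms) + margin_s * 1000
}

#' @rdname write_sim_config
#' @param protocol A [stim_protocol()].
#' @export
write_stim_protocol <- function(protocol, path) {
  validate_stim_protocol(protocol)
  jsonlite::write_json(list(events = as.data.frame(unclass(protocol))),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_stim_protocol <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- raw$events
  if (is.null(ev) || length(ev) == 0L) return(stim_protocol())
  do.call(stim_protocol, as.list(ev[c("onset_ms", "duration_ms",
                                      "compartment", "role", "intensity")]))
}
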