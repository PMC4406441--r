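#' Read and write line-scan recordings
#'
#' Recordings are stored as delimited text plus a JSON sidecar, diff-able
#' and trivially readable from any language. The CSV has the documented
#' header `time_ms,F_A,mask_A,F_B,mask_B`; masked fluorescence samples are
#' written as empty fields and mask columns as 0/1. The sidecar
#' (`<path>.json`) carries the sampling rate, the stimulation protocol and
#' the provenance record (simulation config hash and seed, or "imported").
#' Round-tripping reproduces every unmasked value exactly (full `%.17g`
#' precision) and the mask bit-exactly.
#'
#' @param recording A `linescan_recording`.
#' @param path CSV file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `linescan_recording`.
#' @export
write_recording <- function(recording, path) {
  validate_linescan_recording(recording)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c("time_ms,F_A,mask_A,F_B,mask_B",
             paste(fmt(recording$time_ms),
                   fmt(recording$trace_A), as.integer(recording$mask_A),
                   fmt(recording$trace_B), as.integer(recording$mask_B),
                   sep = ","))
  writeLines(lines, path)
  sidecar <- list(
    sampling_rate = recording$sampling_rate,
    n_samples = length(recording$time_ms),
    protocol = as.data.frame(unclass(recording$protocol)),
    provenance = recording$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar JSON: ", sidecar_path, call. = FALSE)
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  need <- c("time_ms", "F_A", "mask_A", "F_B", "mask_B")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  missing <- setdiff(need, header)
  if (length(missing)) {
    stop("malformed recording header; missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("numeric", "numeric", "integer",
                                      "numeric", "integer"))
  if (!is.null(sidecar$n_samples) && nrow(d) != sidecar$n_samples) {
    stop(sprintf("field 'n_samples': sidecar declares %d samples, CSV has %d",
                 sidecar$n_samples, nrow(d)), call. = FALSE)
  }
  protocol <- if (is.null(sidecar$protocol) || length(sidecar$protocol) == 0L ||
                  NROW(sidecar$protocol) == 0L) {
    stim_protocol()
  } else {
    do.call(stim_protocol, as.list(sidecar$protocol[
      c("onset_ms", "duration_ms", "compartment", "role", "intensity")]))
  }
  rec <- structure(
    list(sampling_rate = sidecar$sampling_rate,
         time_ms = d$time_ms,
         trace_A = d$F_A, trace_B = d$F_B,
         mask_A = d$mask_A == 1L, mask_B = d$mask_B == 1L,
         protocol = protocol,
         provenance = if (is.null(sidecar$provenance)) {
           list(source = "imported")
         } else sidecar$provenance),
    class = "linescan_recording")
  validate_linescan_recording(rec)
}

#' Read and write ground-truth burst tables
#'
#' The simulator's ground truth (one record per burst: compartment,
#' ignition time, recruited fraction, ignition delay in synaptic steps and
#' origin) is stored as a JSON list.
#'
#' @param activity A `population_activity` (or its `bursts` data.frame).
#' @param path JSON file path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the burst data.frame.
#' @export
write_ground_truth <- function(activity, path) {
  bursts <- if (inherits(activity, "population_activity")) activity$bursts
  else as.data.frame(activity)
  jsonlite::write_json(bursts, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export burst events or rate tables as CSV
#' @param x A data.frame (burst events from [detect_bursts()] or a
#'   `rate_table` from [normalize_rates()]).
#' @param path Output CSV.
#' @export
write_events_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
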