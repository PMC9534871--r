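#' Waveform recording container
#'
#' A `edi_recording` holds time-aligned waveform channels sampled at a common
#' rate: the diaphragm electrical activity envelope (`edi`, in microvolts,
#' non-negative by construction of the envelope), and optionally airway
#' pressure (`pressure`, cmH2O) and flow (`flow`, L/min). Channels are indexed
#' by integer sample position (1-based, the R convention); all durations used
#' elsewhere in the package are specified in milliseconds and converted to
#' samples through `sampling_rate`.
#'
#' @param edi numeric vector of non-negative Edi envelope amplitudes (uV).
#' @param sampling_rate sampling rate in Hz (default 100, the rate at which
#'   the ventilator streams the Edi signal).
#' @param pressure optional numeric vector of airway pressure (cmH2O), same
#'   length as `edi`.
#' @param flow optional numeric vector of flow (L/min), same length as `edi`.
#' @param patient_id identifier string for the patient the recording belongs to.
#' @return An object of class `edi_recording`: a list with elements
#'   `patient_id`, `sampling_rate`, `edi`, and optionally `pressure`, `flow`.
#' @examples
#' rec <- recording(edi = abs(sin(seq(0, 10, by = 0.01))) * 10)
#' n_samples(rec)
#' @export
recording <- function(edi, sampling_rate = 100, pressure = NULL, flow = NULL,
                      patient_id = "unknown") {
  edi <- as.numeric(edi)
  if (length(edi) < 1L) stop("edi channel must have length >= 1")
  if (anyNA(edi)) stop("NaN/NA in edi channel at row ", which(is.na(edi))[1L])
  if (any(edi < 0)) stop("edi envelope must be non-negative")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0")
  }
  for (nm in c("pressure", "flow")) {
    ch <- get(nm)
    if (!is.null(ch) && length(ch) != length(edi)) {
      stop(nm, " channel length (", length(ch),
           ") differs from edi length (", length(edi), ")")
    }
  }
  structure(
    list(patient_id = as.character(patient_id),
         sampling_rate = as.numeric(sampling_rate),
         edi = edi,
         pressure = if (!is.null(pressure)) as.numeric(pressure),
         flow = if (!is.null(flow)) as.numeric(flow)),
    class = "edi_recording"
  )
}

#' @export
print.edi_recording <- function(x, ...) {
  dur <- length(x$edi) / x$sampling_rate
  cat(sprintf("<edi_recording> patient %s: %d samples @ %g Hz (%.1f s)%s%s\n",
              x$patient_id, length(x$edi), x$sampling_rate, dur,
              if (!is.null(x$pressure)) ", pressure" else "",
              if (!is.null(x$flow)) ", flow" else ""))
  invisible(x)
}

#' Number of samples in a recording
#' @param recording an `edi_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(recording) length(recording$edi)

#' Convert a duration in milliseconds to a whole number of samples
#' @param ms duration in milliseconds.
#' @param sampling_rate sampling rate in Hz.
#' @return integer number of samples (rounded).
#' @export
ms_to_samples <- function(ms, sampling_rate) {
  as.integer(round(ms / 1000 * sampling_rate))
}

#' Ordered set of inspiratory peak positions
#'
#' A `edi_peakset` records strictly increasing sample indices of inspiratory
#' Edi peaks together with their provenance: hand-annotated ground truth, the
#' local-maximum over-detector (`lm`), the CNN-pruned detector (`dnn`), or one
#' of the baselines (`fda`, `mad`).
#'
#' @param positions strictly increasing integer sample indices (1-based).
#' @param source one of `"ground_truth"`, `"lm"`, `"dnn"`, `"fda"`, `"mad"`.
#' @param patient_id identifier of the patient the peaks belong to.
#' @param n optional recording length for a bounds check.
#' @return An object of class `edi_peakset`.
#' @export
peak_set <- function(positions, source = c("ground_truth", "lm", "dnn",
                                           "fda", "mad"),
                     patient_id = "unknown", n = NULL) {
  source <- match.arg(source)
  positions <- as.integer(positions)
  if (anyNA(positions)) stop("peak positions must not contain NA")
  if (length(positions) > 1L && any(diff(positions) <= 0L)) {
    stop("peak positions must be strictly increasing (no duplicates)")
  }
  if (length(positions) && positions[1L] < 1L) stop("peak positions must be >= 1")
  if (!is.null(n) && length(positions) && positions[length(positions)] > n) {
    stop("peak position beyond recording bounds")
  }
  structure(list(positions = positions, source = source,
                 patient_id = as.character(patient_id)),
            class = "edi_peakset")
}

#' @export
print.edi_peakset <- function(x, ...) {
  cat(sprintf("<edi_peakset> %d peaks (source %s, patient %s)\n",
              length(x$positions), x$source, x$patient_id))
  invisible(x)
}

#' @export
length.edi_peakset <- function(x) length(x$positions)

#' Read a waveform recording from CSV
#'
#' Expects a comma-separated file with a header naming at least `time_s` and
#' `edi_uv`; `pressure_cmh2o` and `flow_lmin` are picked up when present. The
#' time column must be uniformly spaced (at most 1% jitter relative to the
#' median step); the sampling rate is inferred from the median spacing.
#'
#' @param path path to the CSV file.
#' @param patient_id patient identifier to attach (default: file stem).
#' @return an [recording()] object.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"edi_uv" %in% names(df)) stop("missing channel 'edi_uv' in ", path)
  if (!"time_s" %in% names(df)) stop("missing channel 'time_s' in ", path)
  df <- df[order(df$time_s), , drop = FALSE]
  if (anyNA(df$edi_uv)) {
    stop("NaN in edi at row ", which(is.na(df$edi_uv))[1L])
  }
  if (nrow(df) >= 2L) {
    dt <- diff(df$time_s)
    med <- stats::median(dt)
    if (med <= 0) stop("non-increasing time column")
    if (any(abs(dt - med) > 0.01 * med)) {
      stop("non-uniform time spacing beyond 1% jitter at row ",
           which(abs(dt - med) > 0.01 * med)[1L] + 1L)
    }
    fs <- 1 / med
  } else {
    fs <- 100
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  recording(edi = df$edi_uv,
            sampling_rate = fs,
            pressure = if ("pressure_cmh2o" %in% names(df)) df$pressure_cmh2o,
            flow = if ("flow_lmin" %in% names(df)) df$flow_lmin,
            patient_id = patient_id)
}

#' Write a waveform recording to CSV
#'
#' One row per sample; columns `time_s`, `edi_uv`, and whichever of
#' `pressure_cmh2o`, `flow_lmin` the recording carries. Period decimal marks,
#' UTF-8, mandatory header.
#'
#' @param recording an [recording()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "edi_recording"))
  n <- n_samples(recording)
  df <- data.frame(time_s = (seq_len(n) - 1L) / recording$sampling_rate,
                   edi_uv = recording$edi)
  if (!is.null(recording$pressure)) df$pressure_cmh2o <- recording$pressure
  if (!is.null(recording$flow)) df$flow_lmin <- recording$flow
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write peak annotations
#'
#' Plain-text format: one `# source=<source> patient_id=<id>` header line, then
#' one integer sample index per line, sorted and duplicate-free.
#'
#' @param path file path.
#' @return [read_peaks()] returns an [peak_set()]; [write_peaks()] returns
#'   `path` invisibly.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#")) {
    stop("missing '# source=... patient_id=...' header in ", path)
  }
  hdr <- lines[1L]
  get_field <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (!length(m)) stop("header lacks ", key, " field")
    sub(paste0(key, "="), "", m)
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  pos <- as.integer(body)
  if (anyNA(pos)) stop("non-integer peak index in ", path)
  if (length(pos) > 1L && any(diff(pos) <= 0L)) {
    stop("unsorted or duplicate peak indices in ", path)
  }
  peak_set(pos, source = get_field("source"), patient_id = get_field("patient_id"))
}

#' @param peaks an [peak_set()] object.
#' @rdname read_peaks
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "edi_peakset"))
  writeLines(c(sprintf("# source=%s patient_id=%s", peaks$source,
                       peaks$patient_id),
               as.character(peaks$positions)), path)
  invisible(path)
}

#' Read / write asynchrony event lists
#'
#' CSV with columns `type` (`double_triggering` / `autotriggering`), `start_s`,
#' `end_s`, `n_inflations`.
#'
#' @param events list of [asynchrony_event()] objects.
#' @param sampling_rate Hz, used to convert sample indices to seconds.
#' @param path file path.
#' @return [write_events()] returns `path` invisibly; [read_events()] a
#'   data.frame.
#' @export
write_events <- function(events, sampling_rate, path) {
  df <- events_to_frame(events, sampling_rate)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.csv(path)
}

#' @keywords internal
events_to_frame <- function(events, sampling_rate) {
  if (!length(events)) {
    return(data.frame(type = character(), start_s = numeric(),
                      end_s = numeric(), n_inflations = integer()))
  }
  data.frame(
    type = vapply(events, `[[`, "", "kind"),
    start_s = vapply(events, `[[`, 0, "start") / sampling_rate,
    end_s = vapply(events, `[[`, 0, "end") / sampling_rate,
    n_inflations = vapply(events, `[[`, 0L, "n_inflations")
  )
}
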