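#' Canonical 12-lead order
#'
#' The fixed lead order used throughout the package: limb leads, augmented
#' leads, then precordial leads.
#'
#' @format Character vector of length 12.
#' @export
LEAD_ORDER <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct a 12-lead ECG beat
#'
#' An `ecg_beat` holds one paced beat as a 12 x T voltage matrix (mV) with
#' its sampling rate. Rows follow [LEAD_ORDER].
#'
#' @param voltages Numeric 12 x T matrix of voltages in mV, one row per lead.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @return An object of class `ecg_beat` with elements `voltages`,
#'   `sampling_rate` and `lead_order`.
#' @export
ecg_beat <- function(voltages, sampling_rate) {
  voltages <- as.matrix(voltages)
  if (nrow(voltages) != 12L) {
    stop("an ECG beat must have exactly 12 lead rows, got ", nrow(voltages))
  }
  if (!is.numeric(voltages) || !all(is.finite(voltages))) {
    stop("beat voltages must be finite numeric values")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)")
  }
  rownames(voltages) <- LEAD_ORDER
  structure(
    list(voltages = voltages, sampling_rate = sampling_rate,
         lead_order = LEAD_ORDER),
    class = "ecg_beat"
  )
}

#' @export
print.ecg_beat <- function(x, ...) {
  cat(sprintf("<ecg_beat> 12 x %d samples @ %g Hz (%.0f ms)\n",
              ncol(x$voltages), x$sampling_rate,
              1000 * ncol(x$voltages) / x$sampling_rate))
  invisible(x)
}

check_same_shape <- function(beats) {
  t0 <- ncol(beats[[1L]]$voltages)
  fs <- beats[[1L]]$sampling_rate
  for (b in beats) {
    if (!inherits(b, "ecg_beat")) stop("all elements must be ecg_beat objects")
    if (ncol(b$voltages) != t0 || b$sampling_rate != fs) {
      stop("beats have mismatched shapes or sampling rates")
    }
  }
  invisible(TRUE)
}

#' Representative beat by elementwise averaging
#'
#' Averages a set of same-shape beats sample-by-sample to form the
#' representative beat of a pacing site.
#'
#' @param beats List of [ecg_beat] objects with identical dimensions and
#'   sampling rates.
#' @return An [ecg_beat] containing the elementwise mean.
#' @export
average_beats <- function(beats) {
  if (length(beats) == 0L) stop("cannot average an empty sequence of beats")
  check_same_shape(beats)
  acc <- beats[[1L]]$voltages
  if (length(beats) > 1L) {
    for (i in 2:length(beats)) acc <- acc + beats[[i]]$voltages
  }
  ecg_beat(acc / length(beats), beats[[1L]]$sampling_rate)
}

#' Composite 12-lead signal
#'
#' Per-sample sum of absolute voltages across the 12 leads. Used as a single
#' robust alignment signal: its maximum marks the dominant deflection of the
#' paced QRS complex without sign cancellation between leads.
#'
#' @param beat An [ecg_beat].
#' @return Numeric vector of length T, nonnegative.
#' @export
composite_signal <- function(beat) {
  stopifnot(inherits(beat, "ecg_beat"))
  colSums(abs(beat$voltages))
}

#' Construct a splice vector
#'
#' A splice vector is the concatenation of the 12 per-lead windows (in
#' canonical lead order) cut from a beat around its alignment point; it is
#' the waveform representation all morphology metrics operate on.
#'
#' @param values Numeric vector of length `12 * window_samples`, mV.
#' @param window_samples Window length W in samples.
#' @param center_index Sample index (in the source beat) of the alignment
#'   point the window was centered on.
#' @return An object of class `splice_vector`.
#' @export
splice_vector <- function(values, window_samples, center_index) {
  values <- as.numeric(values)
  if (length(values) != 12L * window_samples) {
    stop("splice vector length must be exactly 12 * window_samples")
  }
  structure(
    list(values = values, window_samples = as.integer(window_samples),
         center_index = as.integer(center_index)),
    class = "splice_vector"
  )
}

#' @export
print.splice_vector <- function(x, ...) {
  cat(sprintf("<splice_vector> 12 x %d samples, centered at sample %d\n",
              x$window_samples, x$center_index))
  invisible(x)
}

#' Extract the aligned 150-ms splice vector from a beat
#'
#' Cuts a window of `window_ms` (150 ms by default) from each lead, centered
#' on the maximum of the composite signal, and concatenates the 12 windows
#' in canonical lead order. With window length W the window starts
#' `floor(W/2)` samples before the center. Ties in the composite maximum are
#' broken by the earliest sample. Windows that would run past either edge of
#' the recording raise an error; no padding is applied.
#'
#' @param beat An [ecg_beat].
#' @param window_ms Window duration in milliseconds (default 150).
#' @return A [splice_vector] of length `12 * W` where
#'   `W = round(window_ms * sampling_rate / 1000)`.
#' @export
extract_splice <- function(beat, window_ms = 150) {
  stopifnot(inherits(beat, "ecg_beat"))
  W <- as.integer(round(window_ms * beat$sampling_rate / 1000))
  T_len <- ncol(beat$voltages)
  if (W < 1L) stop("window shorter than one sample")
  if (T_len < W) stop("beat shorter than the splice window")
  comp <- composite_signal(beat)
  center <- which.max(comp)  # earliest index on ties
  start <- center - W %/% 2L
  end <- start + W - 1L
  if (start < 1L || end > T_len) {
    stop(sprintf(paste0("splice window [%d, %d] exceeds beat extent ",
                        "[1, %d]; recording too short around the ",
                        "composite maximum"), start, end, T_len))
  }
  vals <- as.numeric(t(beat$voltages[, start:end, drop = FALSE]))
  splice_vector(vals, W, center)
}

#' Construct a pacing site
#'
#' Bundles a site identifier, its 3-D endocardial position (mm) and the raw
#' paced beats; the representative beat (elementwise average) and its splice
#' vector are derived on construction.
#'
#' @param site_id Character site identifier.
#' @param position Numeric 3-vector, mm.
#' @param beats List of [ecg_beat] objects (at least one), identical shape.
#' @param window_ms Splice window duration, ms.
#' @return An object of class `pacing_site` with fields `site_id`,
#'   `position`, `beats`, `representative` and `splice`.
#' @export
pacing_site <- function(site_id, position, beats, window_ms = 150) {
  position <- as.numeric(position)
  if (length(position) != 3L || !all(is.finite(position))) {
    stop("site position must be a finite 3-vector (mm)")
  }
  if (length(beats) < 1L) stop("a pacing site needs at least one beat")
  rep_beat <- average_beats(beats)
  structure(
    list(site_id = as.character(site_id), position = position,
         beats = beats, representative = rep_beat,
         splice = extract_splice(rep_beat, window_ms)),
    class = "pacing_site"
  )
}

#' @export
print.pacing_site <- function(x, ...) {
  cat(sprintf("<pacing_site> '%s' at (%.1f, %.1f, %.1f) mm, %d beat(s)\n",
              x$site_id, x$position[1], x$position[2], x$position[3],
              length(x$beats)))
  invisible(x)
}

#' Construct a patient dataset
#'
#' @param patient_id Character identifier.
#' @param sites List of [pacing_site] objects (at least two, unique ids).
#' @return An object of class `patient_dataset`.
#' @export
patient_dataset <- function(patient_id, sites) {
  if (length(sites) < 2L) stop("a patient dataset needs at least two sites")
  ids <- vapply(sites, function(s) s$site_id, character(1))
  if (anyDuplicated(ids)) stop("site ids must be unique")
  names(sites) <- ids
  structure(list(patient_id = as.character(patient_id), sites = sites),
            class = "patient_dataset")
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf("<patient_dataset> '%s': %d pacing sites\n",
              x$patient_id, length(x$sites)))
  invisible(x)
}

# Euclidean distance between two 3-vectors (mm).
point_distance <- function(a, b) sqrt(sum((a - b)^2))

# Matrix of positions (n x 3) for a list of sites.
site_positions <- function(sites) {
  do.call(rbind, lapply(sites, function(s) s$position))
}
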