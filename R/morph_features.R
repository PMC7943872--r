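#' Automated QRS onset detection
#'
#' Finds the QRS onset as the earliest sample of the contiguous run, ending
#' at the composite-signal maximum, on which the composite signal stays
#' above 5% of its maximum. Searching backward from the dominant deflection
#' makes the detector deterministic and insensitive to late repolarization
#' activity.
#'
#' @param beat An [ecg_beat] containing a dominant deflection.
#' @param threshold_frac Fraction of the composite maximum used as the onset
#'   threshold (default 0.05).
#' @return Integer sample index of the onset (1-based), always <= the
#'   composite argmax.
#' @export
detect_qrs_onset <- function(beat, threshold_frac = 0.05) {
  comp <- composite_signal(beat)
  m <- max(comp)
  if (m <= 0) stop("flat beat: no QRS onset detectable")
  peak <- which.max(comp)
  thr <- threshold_frac * m
  i <- peak
  while (i > 1L && comp[i - 1L] > thr) i <- i - 1L
  i
}

#' Initial 120-ms QRS integrals of leads III, V2 and V6
#'
#' Signed trapezoidal time-integral of the voltage over the first 120 ms
#' from QRS onset, on the three leads used as regression predictors by the
#' QRS-integral localizer. Signed (not rectified) integrals are required so
#' the predictors carry directional information.
#'
#' @param beat An [ecg_beat].
#' @param onset Integer onset sample index (see [detect_qrs_onset]).
#' @param window_ms Integration window from onset, ms (default 120).
#' @return Object of class `qrs_int_triple`: numeric 3-vector (mV*ms) named
#'   III, V2, V6, with attribute `integration_window_ms`.
#' @export
qrs_integrals <- function(beat, onset, window_ms = 120) {
  stopifnot(inherits(beat, "ecg_beat"))
  fs <- beat$sampling_rate
  n_int <- as.integer(round(window_ms * fs / 1000))  # intervals
  last <- onset + n_int
  if (onset < 1L || last > ncol(beat$voltages)) {
    stop(sprintf("QRS integration window [%d, %d] overruns beat of %d samples",
                 onset, last, ncol(beat$voltages)))
  }
  dt_ms <- 1000 / fs
  leads <- c("III", "V2", "V6")
  vals <- vapply(leads, function(l) {
    v <- beat$voltages[l, onset:last]
    dt_ms * (sum(v) - (v[1L] + v[length(v)]) / 2)  # trapezoid
  }, numeric(1))
  structure(vals, class = "qrs_int_triple", integration_window_ms = window_ms)
}

# Internal: reshape a splice vector into a 12 x W matrix (rows = leads).
splice_matrix <- function(s) {
  matrix(s$values, nrow = 12L, byrow = TRUE)
}

check_splice_pair <- function(a, b) {
  stopifnot(inherits(a, "splice_vector"), inherits(b, "splice_vector"))
  if (length(a$values) != length(b$values) ||
      a$window_samples != b$window_samples) {
    stop("splice vectors have mismatched lengths or window sizes")
  }
  invisible(TRUE)
}

#' E12 morphology distance between two splice vectors
#'
#' Sum over the 12 leads of the per-lead root-mean-square voltage difference
#' between two aligned 150-ms windows:
#' `E12 = sum_l sqrt( (1/N) * sum_t (V_lt - V'_lt)^2 )` with N the per-lead
#' window length in samples. Nonnegative, symmetric, and a metric on splice
#' vectors (each per-lead term is a scaled Euclidean norm).
#'
#' @param a,b [splice_vector] objects of equal length.
#' @return Scalar E12 value (mV).
#' @export
e12 <- function(a, b) {
  check_splice_pair(a, b)
  d <- splice_matrix(a) - splice_matrix(b)
  sum(sqrt(rowMeans(d^2)))
}

#' Mean 12-lead Pearson correlation between two splice vectors
#'
#' Per-lead Pearson correlation between the aligned windows, averaged over
#' the 12 leads. A lead that is constant in either input has an undefined
#' Pearson correlation; such leads are excluded and the average taken over
#' the remaining leads (an error is raised if no lead is usable).
#'
#' @param a,b [splice_vector] objects of equal length.
#' @return Scalar mean correlation in `[-1, 1]`.
#' @export
corr12 <- function(a, b) {
  check_splice_pair(a, b)
  ma <- splice_matrix(a)
  mb <- splice_matrix(b)
  rs <- numeric(0)
  for (l in 1:12) {
    x <- ma[l, ]
    y <- mb[l, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # degenerate lead
    rs <- c(rs, stats::cor(x, y))
  }
  if (length(rs) == 0L) {
    stop("all leads constant in one of the inputs: correlation undefined")
  }
  mean(rs)
}

#' Waveform-difference (dw) vector between two splice vectors
#'
#' The elementwise difference `b - a` of two splice vectors; the
#' morphological-domain counterpart of the position-difference vector
#' between two pacing sites. Antisymmetric:
#' `wave_diff(a, b) = -wave_diff(b, a)`.
#'
#' @param a,b [splice_vector] objects of equal length.
#' @param from_id,to_id Optional site identifiers for bookkeeping.
#' @return Object of class `wave_diff`: list with `values`, `from_id`,
#'   `to_id`.
#' @export
wave_diff <- function(a, b, from_id = NA_character_, to_id = NA_character_) {
  check_splice_pair(a, b)
  structure(
    list(values = b$values - a$values,
         from_id = as.character(from_id), to_id = as.character(to_id)),
    class = "wave_diff"
  )
}
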