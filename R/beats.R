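#' Map the cardiac cycles of a conditioned pressure trace
#'
#' Beat feet are detected as the local pressure minimum immediately preceding
#' each major upstroke.  Upstrokes are found as local maxima of dP/dt with a
#' 300 ms refractory period and an adaptive threshold at 50% of the median
#' upstroke-peak slope; cycles whose length falls outside the physiological
#' gate are discarded.  Each retained cycle gets its anacrotic fiducial (the
#' maximum of the discrete second derivative between foot and systolic peak)
#' via [locate_fiducial()].
#'
#' @param trace A conditioned [bp_trace()] (see [preprocess_trace()]).
#' @param sampling_rate Optional explicit sampling rate (Hz).
#' @param min_cycle_s,max_cycle_s Physiological gate on cycle length, seconds.
#' @param refractory_s Minimum spacing between detected upstrokes, seconds.
#' @param min_pulse_mmHg Minimum peak-to-trough excursion for the trace to be
#'   considered pulsatile at all.
#'
#' @return A tibble with one row per detected cycle: `beat`, `start`,
#'   `fiducial`, `peak`, `end` (1-based sample indices into the trace; `end`
#'   is the start of the next cycle) and `duration_s`.  Zero rows (with a
#'   warning) when no beats are found.
#' @export
#' @examples
#' sim <- generate_trace(beat_model_params(seed = 1), duration = 10)
#' beats <- segment_beats(preprocess_trace(sim$trace))
#' nrow(beats)
segment_beats <- function(trace, sampling_rate = NULL,
                          min_cycle_s = 0.3, max_cycle_s = 2,
                          refractory_s = 0.3, min_pulse_mmHg = 5) {
  fs <- trace_sampling_rate(trace, sampling_rate)
  x <- trace_pressure(trace)
  n <- length(x)
  empty <- tibble(beat = integer(), start = integer(), fiducial = integer(),
                  peak = integer(), end = integer(), duration_s = numeric())
  if (max(x) - min(x) < min_pulse_mmHg) {
    warn("No beats detected: trace is not pulsatile.")
    return(empty)
  }
  dx <- c(0, diff(x)) * fs
  cand <- find_peaks(dx, min_dist = max(1L, round(refractory_s * fs)))
  cand <- cand[dx[cand] > 0]
  if (length(cand) < 2L) {
    warn("No beats detected: fewer than two upstrokes found.")
    return(empty)
  }
  thr <- 0.5 * median(dx[cand])
  ups <- cand[dx[cand] >= thr]
  # the foot is the pressure minimum in the lookback window before the
  # upstroke peak (the diastolic tail decays into the foot)
  look <- round(0.35 * fs)
  feet <- vapply(ups, function(j) {
    lo <- max(1L, j - look)
    as.integer(lo + which.min(x[lo:j]) - 1L)
  }, integer(1))
  feet <- sort(unique(feet))
  if (length(feet) < 2L) {
    warn("No beats detected: fewer than two feet found.")
    return(empty)
  }
  starts <- feet[-length(feet)]
  ends <- feet[-1L]
  dur <- (ends - starts) / fs
  ok <- dur >= min_cycle_s & dur <= max_cycle_s
  starts <- starts[ok]; ends <- ends[ok]; dur <- dur[ok]
  if (length(starts) == 0L) {
    warn("No beats detected within the physiological cycle-length gate.")
    return(empty)
  }
  peak <- integer(length(starts))
  fid <- integer(length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(ends[i] - 1L)]
    peak[i] <- starts[i] + which.max(seg) - 1L
    f <- locate_fiducial(seg)
    fid[i] <- if (is.na(f)) NA_integer_ else starts[i] + f - 1L
  }
  tibble(beat = seq_along(starts), start = starts, fiducial = fid,
         peak = peak, end = ends, duration_s = dur)
}

#' Locate the anacrotic fiducial of one cycle
#'
#' The fiducial is defined as the maximum of the discrete (centered) second
#' derivative of pressure on the anacrotic limb, i.e. restricted to the
#' interval from the start of the cycle to its systolic peak.  Used to align
#' cycles for ensemble averaging in the absence of an ECG channel.
#'
#' @param segment Numeric vector of one cycle's pressure samples (the cycle
#'   starts at the beat foot).
#' @param min_rise_mmHg Minimum rise from the first sample to the peak for the
#'   limb to count as anacrotic; otherwise `NA` is returned and the beat is
#'   excluded from averaging.
#'
#' @return The 1-based index of the fiducial within `segment`, or `NA`.
#' @export
locate_fiducial <- function(segment, min_rise_mmHg = 1) {
  n <- length(segment)
  if (n < 4L) return(NA_integer_)
  peak <- which.max(segment)
  if (segment[peak] - segment[1L] <= min_rise_mmHg) return(NA_integer_)
  if (peak < 3L) return(NA_integer_)
  d2 <- segment[3L:n] - 2 * segment[2L:(n - 1L)] + segment[1L:(n - 2L)]
  # d2[k] is the curvature at sample k + 1; anacrotic limb: samples 2..peak
  k <- which.max(d2[seq_len(peak - 1L)])
  k + 1L
}

#' Two-step correlation-gated ensemble averaging
#'
#' Step 1 aligns all cycles at their anacrotic fiducials over the common
#' support (a fixed pre-fiducial margin and the shortest available
#' post-fiducial span) and averages them into a raw average.  Step 2
#' Pearson-correlates every cycle against the raw average, retains only those
#' with `r > r_threshold`, and re-averages the retained cycles into the
#' representative beat.
#'
#' @param trace The conditioned trace the segments index into.
#' @param segments Output of [segment_beats()]; computed from `trace` when
#'   omitted.
#' @param r_threshold Correlation gate (default 0.95).
#' @param min_beats Minimum number of retained beats; fewer aborts with an
#'   "insufficient concordant beats" error carrying the correlations.
#' @param pre_fiducial_s Margin kept before the fiducial, seconds.
#' @param sampling_rate Optional explicit sampling rate (Hz).
#'
#' @return An object of class `ensemble_beat`: a list with
#'   `representative` (tibble `time_s`/`pressure_mmHg`, time zero at the
#'   fiducial), `sampling_rate`, `fiducial_index`, `n_detected`, `n_retained`,
#'   `heart_rate` (from the median cycle length) and `beats` (per-beat
#'   diagnostics: indices, correlation against the raw average, retention
#'   flag).
#' @export
#' @examples
#' sim <- generate_trace(beat_model_params(seed = 1), duration = 20)
#' eb <- ensemble_average(preprocess_trace(sim$trace))
#' eb$n_retained
ensemble_average <- function(trace, segments = NULL, r_threshold = 0.95,
                             min_beats = 5L, pre_fiducial_s = 0.1,
                             sampling_rate = NULL) {
  fs <- trace_sampling_rate(trace, sampling_rate)
  x <- trace_pressure(trace)
  if (is.null(segments)) {
    segments <- segment_beats(trace, sampling_rate = fs)
  }
  usable <- segments[!is.na(segments$fiducial), , drop = FALSE]
  if (nrow(usable) < min_beats) {
    abort(sprintf("Insufficient beats: %d usable cycles, need at least %d.",
                  nrow(usable), min_beats))
  }
  # fixed pre-fiducial margin: it may reach back into the previous cycle's
  # diastolic tail (the foot sits a few samples before the fiducial); beats
  # too close to the trace edges to supply the full window are dropped
  pre <- round(pre_fiducial_s * fs)
  post <- min(usable$end - usable$fiducial)
  lo <- usable$fiducial - pre
  hi <- usable$fiducial + post - 1L
  inside <- lo >= 1L & hi <= length(x)
  usable <- usable[inside, , drop = FALSE]
  lo <- lo[inside]; hi <- hi[inside]
  if (nrow(usable) < min_beats) {
    abort(sprintf("Insufficient beats: %d alignable cycles, need at least %d.",
                  nrow(usable), min_beats))
  }
  m <- t(vapply(seq_len(nrow(usable)),
                function(i) x[lo[i]:hi[i]], numeric(pre + post)))
  raw_average <- colMeans(m)
  r <- as.numeric(stats::cor(t(m), raw_average))
  retained <- r > r_threshold
  if (sum(retained) < min_beats) {
    abort(
      message = sprintf(
        "Insufficient concordant beats: %d of %d cycles exceed r = %g.",
        sum(retained), length(r), r_threshold),
      class = "stumpwave_insufficient_beats",
      correlations = r
    )
  }
  representative <- colMeans(m[retained, , drop = FALSE])
  heart_rate <- 60 / (median(diff(sort(unique(c(usable$start, usable$end))))) / fs)
  beats <- usable
  beats$correlation <- r
  beats$retained <- retained
  structure(
    list(
      representative = tibble(
        time_s = (seq_along(representative) - 1L - pre) / fs,
        pressure_mmHg = representative
      ),
      sampling_rate = fs,
      fiducial_index = pre + 1L,
      n_detected = nrow(segments),
      n_retained = sum(retained),
      heart_rate = heart_rate,
      r_threshold = r_threshold,
      beats = beats
    ),
    class = "ensemble_beat"
  )
}

#' Wrap a single known cycle as an ensemble beat
#'
#' Useful for extracting morphometrics from a beat whose samples are already
#' known (e.g. a noise-free model beat), bypassing detection and averaging.
#' The cycle is assumed to start at its foot.
#'
#' @param beat Numeric vector of pressure samples, or a data frame with a
#'   `pressure_mmHg` column.
#' @param sampling_rate Sampling rate in Hz.
#' @return An `ensemble_beat` with `n_detected = n_retained = 1`.
#' @export
as_ensemble_beat <- function(beat, sampling_rate = 100) {
  x <- trace_pressure(beat)
  if (length(x) < 4L) abort("A beat needs at least 4 samples.")
  f <- locate_fiducial(x)
  if (is.na(f)) f <- 1L
  structure(
    list(
      representative = tibble(
        time_s = (seq_along(x) - f) / sampling_rate,
        pressure_mmHg = x
      ),
      sampling_rate = sampling_rate,
      fiducial_index = f,
      n_detected = 1L,
      n_retained = 1L,
      heart_rate = 60 / (length(x) / sampling_rate),
      r_threshold = NA_real_,
      beats = tibble(beat = 1L, start = 1L, fiducial = f, peak = which.max(x),
                     end = length(x) + 1L,
                     duration_s = length(x) / sampling_rate,
                     correlation = 1, retained = TRUE)
    ),
    class = "ensemble_beat"
  )
}

#' @export
print.ensemble_beat <- function(x, ...) {
  cat("<ensemble_beat>\n")
  cat(sprintf("  %d of %d cycles retained (r > %s), heart rate %.1f /min\n",
              x$n_retained, x$n_detected,
              format(x$r_threshold), x$heart_rate))
  cat(sprintf("  representative: %d samples at %g Hz, fiducial at index %d\n",
              nrow(x$representative), x$sampling_rate, x$fiducial_index))
  invisible(x)
}

#' @describeIn ensemble_average Per-beat diagnostics (correlations and
#'   retention flags) as a tibble.
#' @param x An `ensemble_beat`.
#' @param ... Unused.
#' @method tidy ensemble_beat
#' @export
tidy.ensemble_beat <- function(x, ...) {
  as_tibble(x$beats)
}

#' @describeIn ensemble_average One-row summary of the averaging step.
#' @method glance ensemble_beat
#' @export
glance.ensemble_beat <- function(x, ...) {
  tibble(
    n_detected = x$n_detected,
    n_retained = x$n_retained,
    retention = x$n_retained / max(1L, nrow(x$beats)),
    heart_rate = x$heart_rate,
    r_threshold = x$r_threshold,
    min_correlation = min(x$beats$correlation),
    sampling_rate = x$sampling_rate
  )
}
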