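#' Signal-conditioning settings
#'
#' Defaults follow the processing chain used for intraoperative stump
#' recordings: a 10 Hz low-pass stage followed by second-order
#' Savitzky-Golay polynomial smoothing over a 50 ms window.
#'
#' @param lowpass_hz Low-pass cutoff in Hz (must stay below the Nyquist
#'   frequency of the trace it is applied to).
#' @param sg_window_s Savitzky-Golay window length in seconds; converted to an
#'   odd sample count of at least 5 at the trace's sampling rate.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param lowpass_order Order of the Butterworth low-pass design (applied
#'   forward-backward, so the effective magnitude response is squared).
#'
#' @return An object of class `filter_settings`.
#' @export
filter_settings <- function(lowpass_hz = 10, sg_window_s = 0.050,
                            sg_order = 2L, lowpass_order = 4L) {
  if (!is_number(lowpass_hz) || lowpass_hz <= 0) {
    abort("`lowpass_hz` must be a single positive number.")
  }
  if (!is_number(sg_window_s) || sg_window_s <= 0) {
    abort("`sg_window_s` must be a single positive number.")
  }
  if (!is_number(sg_order) || sg_order < 1) {
    abort("`sg_order` must be >= 1.")
  }
  if (!is_number(lowpass_order) || lowpass_order < 1) {
    abort("`lowpass_order` must be >= 1.")
  }
  structure(list(lowpass_hz = lowpass_hz, sg_window_s = sg_window_s,
                 sg_order = as.integer(sg_order),
                 lowpass_order = as.integer(lowpass_order)),
            class = "filter_settings")
}

# Mirror-pad, apply `fun` to the padded series, trim.  Mirror padding avoids
# endpoint transients that would corrupt the first and last beats of a
# recording.
apply_padded <- function(x, pad, fun) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) return(fun(x))
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  fun(xp)[(pad + 1L):(pad + n)]
}

rebuild_trace <- function(trace, pressure, fs) {
  if (inherits(trace, "bp_trace")) {
    bp_trace(pressure, sampling_rate = fs,
             channel = attr(trace, "channel") %||% "ica_stump",
             subject_id = attr(trace, "subject_id") %||% NA_character_)
  } else {
    bp_trace(pressure, sampling_rate = fs)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-phase low-pass filter
#'
#' Applies a Butterworth low-pass forward and backward
#' ([signal::filtfilt()]) over a mirror-padded copy of the trace, giving unit
#' passband gain, no phase distortion and hence no systematic shift of beat
#' fiducials.
#'
#' @param trace A [bp_trace()] or data frame with `time_s`/`pressure_mmHg`.
#' @param settings A [filter_settings()] object.
#' @param sampling_rate Optional explicit sampling rate (Hz).
#' @return A filtered trace of the same length and sampling rate.
#' @export
lowpass_filter <- function(trace, settings = filter_settings(),
                           sampling_rate = NULL) {
  fs <- trace_sampling_rate(trace, sampling_rate)
  x <- trace_pressure(trace)
  nyq <- fs / 2
  if (settings$lowpass_hz >= nyq) {
    abort(sprintf("Low-pass cutoff (%g Hz) must be below the Nyquist frequency (%g Hz).",
                  settings$lowpass_hz, nyq))
  }
  bf <- signal::butter(settings$lowpass_order, settings$lowpass_hz / nyq,
                       type = "low")
  # demeaning plus generous mirror padding keeps the DC level exact and
  # confines start-up transients to the discarded pad
  mu <- mean(x)
  pad <- round(10 * fs / settings$lowpass_hz)
  y <- apply_padded(x - mu, pad, function(z) signal::filtfilt(bf, z)) + mu
  rebuild_trace(trace, y, fs)
}

# Window length in samples: nearest odd count, floored at both the polynomial
# constraint (order + 1) and 5 samples.
sg_window_samples <- function(settings, fs) {
  w <- round(settings$sg_window_s * fs)
  if (w %% 2L == 0L) w <- w + 1L
  w <- max(w, settings$sg_order + 1L + (settings$sg_order %% 2L), 5L)
  as.integer(w)
}

#' Savitzky-Golay polynomial smoothing
#'
#' Local least-squares polynomial smoothing ([signal::sgolayfilt()]).  An
#' order-2 filter reproduces any quadratic exactly — including at the trace
#' ends, where the filter falls back to one-sided polynomial fits — so
#' waveform peaks are not flattened the way a moving average would.
#'
#' @inheritParams lowpass_filter
#' @return A smoothed trace of the same length and sampling rate.
#' @export
savgol_smooth <- function(trace, settings = filter_settings(),
                          sampling_rate = NULL) {
  fs <- trace_sampling_rate(trace, sampling_rate)
  x <- trace_pressure(trace)
  w <- sg_window_samples(settings, fs)
  if (w > length(x)) {
    abort("Savitzky-Golay window is longer than the trace.")
  }
  y <- signal::sgolayfilt(x, p = settings$sg_order, n = w)
  rebuild_trace(trace, y, fs)
}

#' Condition a raw pressure trace
#'
#' Runs the fixed conditioning chain: low-pass filtering first, then
#' Savitzky-Golay smoothing.  Both stages are linear and zero-phase.
#'
#' @inheritParams lowpass_filter
#' @return The conditioned trace.
#' @export
#' @examples
#' sim <- generate_trace(beat_model_params(noise_sd = 2, seed = 1), duration = 10)
#' conditioned <- preprocess_trace(sim$trace)
preprocess_trace <- function(trace, settings = filter_settings(),
                             sampling_rate = NULL) {
  trace |>
    lowpass_filter(settings = settings, sampling_rate = sampling_rate) |>
    savgol_smooth(settings = settings, sampling_rate = sampling_rate)
}
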