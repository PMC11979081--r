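# The representative cycle of an ensemble beat: indices of foot, peak and
# cycle end within the representative samples.
beat_cycle_indices <- function(beat) {
  x <- beat$representative$pressure_mmHg
  n <- length(x)
  fid <- beat$fiducial_index
  # the foot is the pressure minimum adjacent to (at or just before) the
  # fiducial; everything before it is the previous cycle's diastolic tail
  foot <- which.min(x[seq_len(min(n, fid + 1L))])
  peak <- foot + which.max(x[foot:n]) - 1L
  list(foot = foot, peak = peak, end = n)
}

#' Detect the dicrotic notch of a representative beat
#'
#' The notch (incisura) marks aortic-valve closure and is used as the
#' systole/diastole boundary.  The search window runs from 50 ms after the
#' systolic peak to 80% of the cycle length.  Primary rule: the most
#' prominent local pressure minimum in the window.  Fallback (for morphologies
#' where the incisura is a slope break rather than a dip): the most prominent
#' interior local minimum of the second derivative, i.e. the localized
#' concave-down curvature dip at the systole-to-diastole corner.  A smoothly
#' decaying diastole without either feature reports "notch not found".
#'
#' @param beat An `ensemble_beat` (see [ensemble_average()]).
#' @param search_start_s Dead time after the systolic peak, seconds.
#' @param search_end_frac Upper end of the search window as a fraction of the
#'   cycle length.
#'
#' @return A list: `found` (logical), `index` (1-based index into the
#'   representative samples, `NA` when not found), `time_s`,
#'   `pressure_mmHg`, and `method` (`"local_minimum"`, `"second_derivative"`
#'   or `"none"`).
#' @export
detect_dicrotic_notch <- function(beat, search_start_s = 0.05,
                                  search_end_frac = 0.8) {
  stopifnot(inherits(beat, "ensemble_beat"))
  x <- beat$representative$pressure_mmHg
  fs <- beat$sampling_rate
  ci <- beat_cycle_indices(beat)
  cycle_len <- ci$end - ci$foot + 1L
  w_lo <- ci$peak + round(search_start_s * fs)
  w_hi <- ci$foot + round(search_end_frac * cycle_len) - 1L
  not_found <- list(found = FALSE, index = NA_integer_, time_s = NA_real_,
                    pressure_mmHg = NA_real_, method = "none")
  if (ci$peak <= ci$foot || ci$peak >= ci$end || w_hi - w_lo < 4L) {
    return(not_found)
  }
  win <- x[w_lo:w_hi]
  m <- length(win)

  # primary: most prominent local minimum
  mins <- which(win[2:(m - 1L)] < win[1:(m - 2L)] &
                  win[2:(m - 1L)] <= win[3:m]) + 1L
  if (length(mins) > 0L) {
    prom <- vapply(mins, function(i) {
      min(max(win[1:i]) - win[i], max(win[i:m]) - win[i])
    }, numeric(1))
    best <- mins[which.max(prom)]
    if (max(prom) > 0.05) {
      idx <- w_lo + best - 1L
      return(list(found = TRUE, index = idx,
                  time_s = beat$representative$time_s[idx],
                  pressure_mmHg = x[idx], method = "local_minimum"))
    }
  }

  # fallback for shoulder-type junctions (no dip): the systole-to-diastole
  # corner is a concave-down slope break, i.e. a localized dip of the second
  # derivative.  Candidates are interior local minima of d2; the most
  # prominent one wins, provided its prominence stands out against the
  # window's overall curvature range (a smoothly decaying diastole has no
  # prominent interior curvature dip and is reported as "not found").
  d2 <- win[3:m] - 2 * win[2:(m - 1L)] + win[1:(m - 2L)]
  md <- length(d2)
  cand <- which(d2[2:(md - 1L)] < d2[1:(md - 2L)] &
                  d2[2:(md - 1L)] <= d2[3:md]) + 1L
  cand <- cand[cand > 3L & cand < md - 2L]
  if (length(cand) > 0L) {
    prom <- vapply(cand, function(k) {
      min(max(d2[1:k]) - d2[k], max(d2[k:md]) - d2[k])
    }, numeric(1))
    k <- cand[which.max(prom)]
    if (max(prom) > 0.05 * (max(d2) - min(d2))) {
      # centroid refinement: the low-pass stage smears the corner's curvature
      # dip and the descent limb's curvature ramp tilts it late, so the corner
      # is re-localized as the centroid of the dip after removing a linear
      # curvature background fitted outside the dip
      k <- refine_curvature_dip(d2, k)
      idx <- min(w_lo + k, w_hi)  # d2[k] sits at window sample k + 1
      return(list(found = TRUE, index = idx,
                  time_s = beat$representative$time_s[idx],
                  pressure_mmHg = x[idx], method = "second_derivative"))
    }
  }
  not_found
}

refine_curvature_dip <- function(d2, k, halfwidth = 12L) {
  md <- length(d2)
  lo <- max(1L, k - halfwidth)
  hi <- min(md, k + halfwidth)
  lx <- lo:max(lo, k - 6L)
  rx <- min(hi, k + 6L):hi
  bx <- unique(c(lx, rx))
  if (length(bx) < 3L) return(k)
  fit <- stats::lm.fit(cbind(1, bx), d2[bx])$coefficients
  res <- d2[lo:hi] - (fit[1L] + fit[2L] * (lo:hi))
  depth <- res[k - lo + 1L]
  if (depth >= 0) return(k)
  # centroid over the dip's half-depth core only: a sharp (unsmeared) corner
  # keeps its single-sample locus, a smeared corner is re-centered
  w <- ifelse(res <= depth / 2, -res, 0)
  as.integer(round(sum((lo:hi) * w) / sum(w)))
}

#' Area-method estimate of the diastolic decay constant
#'
#' For a two-element Windkessel the diastolic pressure decays as
#' \eqn{P(t) = A + (P_0 - A) e^{-t/\tau}} with \eqn{\tau = R C}.  Integrating
#' over any diastolic window gives the area identity
#' \deqn{\tau = \frac{\int (P - A)\,dt}{P_{start} - P_{end}},}
#' which is exact for a pure exponential with matching asymptote \eqn{A} and
#' is substantially more noise-tolerant than log-linear fitting.
#'
#' @param pressure Numeric vector of diastolic pressure samples.
#' @param time_s Sample times in seconds; alternatively supply
#'   `sampling_rate`.
#' @param sampling_rate Sampling rate in Hz (used when `time_s` is missing).
#' @param asymptote Pressure the decay tends toward, mmHg (default 0).
#'
#' @return The estimated decay constant in seconds.
#' @export
#' @examples
#' t <- seq(0, 3, by = 0.01)
#' tau_area(50 * exp(-t / 1.5), time_s = t)  # ~1.5
tau_area <- function(pressure, time_s = NULL, sampling_rate = NULL,
                     asymptote = 0) {
  p <- as.numeric(pressure)
  n <- length(p)
  if (is.null(time_s)) {
    if (is.null(sampling_rate)) abort("Supply `time_s` or `sampling_rate`.")
    time_s <- (seq_len(n) - 1L) / sampling_rate
  }
  if (length(time_s) != n) abort("`time_s` and `pressure` lengths differ.")
  if (n < 3L) abort("tau undefined: diastolic segment too short.")
  if ((time_s[n] - time_s[1L]) < 0.1) {
    abort("tau undefined: diastolic segment shorter than 100 ms.")
  }
  p_start <- p[1L]
  p_end <- p[n]
  if (p_end <= asymptote) {
    abort("tau undefined: diastolic pressure does not stay above the asymptote.")
  }
  if (p_start - p_end < 0.5) {
    abort("tau undefined: diastolic pressure drop below 0.5 mmHg.")
  }
  trapz_area(time_s, p - asymptote) / (p_start - p_end)
}

#' @describeIn tau_area Area-method decay constant of an `ensemble_beat`'s
#'   diastole: the integration window starts `guard_s` after the dicrotic
#'   notch (skipping incisura ringing) and stops `end_guard_s` before the
#'   cycle end (where a zero-phase filter's anticipatory smear of the next
#'   systolic upstroke would otherwise bias the end-diastolic value).  The
#'   area identity holds on any sub-window of an exponential decay, so the
#'   guards do not bias the estimate.
#' @param beat An `ensemble_beat`.
#' @param notch_index Index of the dicrotic notch within the representative
#'   samples; detected with [detect_dicrotic_notch()] when omitted.
#' @param guard_s Guard interval after the notch, seconds.
#' @param end_guard_s Guard interval before the cycle end, seconds.
#' @export
estimate_tau_area <- function(beat, notch_index = NULL, asymptote = 0,
                              guard_s = 0.06, end_guard_s = 0.06) {
  stopifnot(inherits(beat, "ensemble_beat"))
  if (is.null(notch_index)) {
    notch <- detect_dicrotic_notch(beat)
    if (!notch$found) abort("tau undefined: dicrotic notch not found.")
    notch_index <- notch$index
  }
  fs <- beat$sampling_rate
  n <- nrow(beat$representative)
  hi <- n - round(end_guard_s * fs)
  lo <- notch_index + round(guard_s * fs)
  if (lo >= hi - 2L) abort("tau undefined: diastolic segment too short.")
  tau_area(beat$representative$pressure_mmHg[lo:hi],
           time_s = beat$representative$time_s[lo:hi],
           asymptote = asymptote)
}

#' Extract the pulse-wave morphometric panel from a representative beat
#'
#' Computes the amplitude, duration and area variables of the standard
#' stump-pressure waveform panel: systolic/diastolic/pulse/mean pressure, the
#' end-systolic (dicrotic notch) pressure `inc_bp`, systolic and diastolic
#' durations, total/systolic/diastolic areas under the pressure curve
#' (trapezoidal), the area-method decay constant and the heart rate.  When the
#' notch cannot be located, the amplitude features are still returned and the
#' notch-dependent ones are `NA` (with a warning).
#'
#' @param beat An `ensemble_beat` (see [ensemble_average()],
#'   [as_ensemble_beat()]).
#' @param notch_index Optional known notch index (see
#'   [detect_dicrotic_notch()]).
#' @param tau_asymptote Asymptote for the area-method decay constant, mmHg.
#' @param tau_guard_s,tau_end_guard_s Guard intervals after the notch and
#'   before the cycle end for the decay-constant window, seconds.
#'
#' @return A one-row tibble with columns `sbp`, `dbp`, `pp`, `mbp`, `inc_bp`,
#'   `t_sys`, `t_dia`, `area_total`, `area_sys`, `area_dia`, `tau`,
#'   `heart_rate`, `notch_found`, `n_retained`.
#' @export
#' @examples
#' beat <- as_ensemble_beat(generate_beat(beat_model_params())$pressure_mmHg)
#' extract_features(beat)
extract_features <- function(beat, notch_index = NULL, tau_asymptote = 0,
                             tau_guard_s = 0.06, tau_end_guard_s = 0.06) {
  stopifnot(inherits(beat, "ensemble_beat"))
  x <- beat$representative$pressure_mmHg
  tt <- beat$representative$time_s
  fs <- beat$sampling_rate
  ci <- beat_cycle_indices(beat)
  cyc <- ci$foot:ci$end
  sbp <- max(x[cyc])
  dbp <- x[ci$foot]
  mbp <- trapz_area(tt[cyc], x[cyc]) / (tt[ci$end] - tt[ci$foot])

  if (is.null(notch_index)) {
    notch <- detect_dicrotic_notch(beat)
    notch_index <- notch$index
    notch_found <- notch$found
  } else {
    notch_found <- TRUE
  }

  if (notch_found) {
    ni <- notch_index
    inc_bp <- x[ni]
    t_sys <- (ni - ci$foot) / fs
    t_dia <- (ci$end - ni) / fs
    area_sys <- trapz_area(tt[ci$foot:ni], x[ci$foot:ni])
    area_dia <- trapz_area(tt[ni:ci$end], x[ni:ci$end])
    area_total <- area_sys + area_dia
    tau <- tryCatch(
      estimate_tau_area(beat, notch_index = ni, asymptote = tau_asymptote,
                        guard_s = tau_guard_s, end_guard_s = tau_end_guard_s),
      error = function(e) NA_real_
    )
  } else {
    warn("Dicrotic notch not found: duration, area and tau features are NA.")
    inc_bp <- t_sys <- t_dia <- area_sys <- area_dia <- area_total <- tau <- NA_real_
  }

  tibble(
    sbp = sbp, dbp = dbp, pp = sbp - dbp, mbp = mbp, inc_bp = inc_bp,
    t_sys = t_sys, t_dia = t_dia,
    area_total = area_total, area_sys = area_sys, area_dia = area_dia,
    tau = tau, heart_rate = beat$heart_rate,
    notch_found = notch_found, n_retained = beat$n_retained
  )
}

#' ICA-to-systemic pressure ratios
#'
#' Element-wise ratios of paired same-subject waveform features, used to
#' normalise stump pressures for the prevailing systemic (radial) pressure.
#'
#' @param ica,radial One-row feature tibbles from [extract_features()] for the
#'   ICA stump and radial channels of the same subject.
#' @return A one-row tibble with `sbp_ratio`, `dbp_ratio`, `pp_ratio`,
#'   `mbp_ratio`, `inc_ratio`.
#' @export
#' @examples
#' f <- tibble::tibble(sbp = 74.8, dbp = 51.5, pp = 23.3, mbp = 60.7, inc_bp = 62.1)
#' r <- tibble::tibble(sbp = 124, dbp = 61.8, pp = 62.2, mbp = 85.3, inc_bp = 84.9)
#' compute_pressure_ratios(f, r)
compute_pressure_ratios <- function(ica, radial) {
  stopifnot(is.data.frame(ica), is.data.frame(radial),
            nrow(ica) == 1L, nrow(radial) == 1L)
  fields <- c(sbp_ratio = "sbp", dbp_ratio = "dbp", pp_ratio = "pp",
              mbp_ratio = "mbp", inc_ratio = "inc_bp")
  vals <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    den <- radial[[f]]
    num <- ica[[f]]
    if (is.na(den) || is.na(num)) return(NA_real_)
    if (den <= 0) {
      abort(sprintf("Radial `%s` must be positive to form a ratio.", f))
    }
    num / den
  })
  names(vals) <- names(fields)
  as_tibble(vals)
}

#' Run the full single-trace analysis chain
#'
#' Conditions the trace ([preprocess_trace()]), maps the cardiac cycles
#' ([segment_beats()]), builds the correlation-gated representative beat
#' ([ensemble_average()]) and extracts the morphometric panel
#' ([extract_features()]).
#'
#' @inheritParams ensemble_average
#' @param settings [filter_settings()] for the conditioning stage.
#' @param tau_asymptote,tau_guard_s,tau_end_guard_s Passed to
#'   [extract_features()].
#'
#' @return The one-row feature tibble, with the `ensemble_beat` attached as
#'   attribute `"ensemble"`.
#' @export
#' @examples
#' sim <- generate_trace(beat_model_params(seed = 1), duration = 20)
#' analyze_trace(sim$trace)
analyze_trace <- function(trace, settings = filter_settings(),
                          r_threshold = 0.95, min_beats = 5L,
                          tau_asymptote = 0, tau_guard_s = 0.02,
                          tau_end_guard_s = 0.06, sampling_rate = NULL) {
  conditioned <- preprocess_trace(trace, settings = settings,
                                  sampling_rate = sampling_rate)
  beat <- ensemble_average(conditioned, r_threshold = r_threshold,
                           min_beats = min_beats)
  features <- extract_features(beat, tau_asymptote = tau_asymptote,
                               tau_guard_s = tau_guard_s,
                               tau_end_guard_s = tau_end_guard_s)
  attr(features, "ensemble") <- beat
  features
}
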