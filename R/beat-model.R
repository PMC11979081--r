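#' Parameters of the synthetic arterial beat model
#'
#' The simulator's single-beat model is piecewise: a raised-cosine systolic
#' upstroke from the beat foot to `sbp`, a raised-cosine descent from `sbp` to
#' the dicrotic-notch pressure, and a two-element Windkessel diastole
#' \eqn{P(t) = A + (P_{notch} - A) e^{-(t - t_{notch})/\tau}} decaying toward
#' the asymptote \eqn{A} until the end of the cycle.  Every morphometric
#' quantity extracted downstream (pressures, durations, areas, the decay
#' constant) therefore has closed-form ground truth.
#'
#' Consecutive beats are chained continuously: each upstroke starts at the
#' previous cycle's end-diastolic pressure, so in steady state the realized
#' beat foot sits at
#' \eqn{A + (P_{notch} - A) e^{-(1 - f_{notch})\,T/\tau}} rather than at the
#' nominal `dbp` (which only anchors the first beat and the parameter ordering
#' constraints).  Ground-truth labels in [generate_trace()] report the
#' realized values.
#'
#' @param heart_rate Heart rate in beats per minute.
#' @param sbp,dbp Systolic and (nominal) diastolic pressure, mmHg.
#' @param notch_fraction Fraction of the cycle length at which the dicrotic
#'   notch occurs (0 < f < 1).
#' @param notch_pressure End-systolic (dicrotic notch) pressure, mmHg; must lie
#'   strictly between `dbp` and `sbp`.
#' @param tau Diastolic decay time constant in seconds (Windkessel
#'   \eqn{\tau = R C}).
#' @param asymptote Pressure the diastolic exponential decays toward, mmHg.
#' @param upstroke_fraction Fraction of the cycle from beat foot to systolic
#'   peak; must be below `notch_fraction`.
#' @param noise_sd Standard deviation of additive white measurement noise,
#'   mmHg.
#' @param drift_amplitude Amplitude of a slow (0.05 Hz) sinusoidal baseline
#'   drift, mmHg.
#' @param artifact_rate Per-beat probability of replacing the beat with a
#'   distorted (time-reversed, rescaled) artifact morphology.
#' @param seed Optional integer seed used by [generate_trace()].
#'
#' @return An object of class `beat_model_params` (a validated named list).
#' @seealso [generate_beat()], [generate_trace()], [generate_cohort()]
#' @export
#' @examples
#' p <- beat_model_params(sbp = 120, dbp = 80, tau = 1.2)
#' beat <- generate_beat(p)
#' max(beat$pressure_mmHg)
beat_model_params <- function(heart_rate = 60, sbp = 120, dbp = 80,
                              notch_fraction = 0.35, notch_pressure = 95,
                              tau = 1.2, asymptote = 0,
                              upstroke_fraction = 0.15,
                              noise_sd = 0, drift_amplitude = 0,
                              artifact_rate = 0, seed = NULL) {
  p <- list(
    heart_rate = heart_rate, sbp = sbp, dbp = dbp,
    notch_fraction = notch_fraction, notch_pressure = notch_pressure,
    tau = tau, asymptote = asymptote,
    upstroke_fraction = upstroke_fraction,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    artifact_rate = artifact_rate, seed = seed
  )
  validate_beat_model_params(p)
  structure(p, class = "beat_model_params")
}

validate_beat_model_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) abort(paste0("Invalid beat model parameters: ", msg))
  for (f in setdiff(names(p), "seed")) {
    chk(is_number(p[[f]]), sprintf("`%s` must be a single finite number", f))
  }
  chk(p$heart_rate > 0, "`heart_rate` must be > 0")
  chk(p$tau > 0, "`tau` must be > 0")
  chk(p$asymptote >= 0, "`asymptote` must be >= 0")
  chk(p$dbp > p$asymptote, "`dbp` must exceed `asymptote`")
  chk(p$sbp > p$notch_pressure, "`sbp` must exceed `notch_pressure`")
  chk(p$notch_pressure > p$dbp, "`notch_pressure` must exceed `dbp`")
  chk(p$upstroke_fraction > 0 && p$upstroke_fraction < 1,
      "`upstroke_fraction` must be in (0, 1)")
  chk(p$notch_fraction < 1, "`notch_fraction` must be < 1")
  chk(p$upstroke_fraction < p$notch_fraction,
      "`upstroke_fraction` must be below `notch_fraction`")
  chk(p$noise_sd >= 0, "`noise_sd` must be >= 0")
  chk(p$drift_amplitude >= 0, "`drift_amplitude` must be >= 0")
  chk(p$artifact_rate >= 0 && p$artifact_rate < 1,
      "`artifact_rate` must be in [0, 1)")
  if (!is.null(p$seed)) chk(is_number(p$seed), "`seed` must be a single number")
  invisible(p)
}

#' @export
print.beat_model_params <- function(x, ...) {
  cat("<beat_model_params>\n")
  cat(sprintf("  HR %g /min, SBP %g, DBP %g, notch %g mmHg @ %g of cycle\n",
              x$heart_rate, x$sbp, x$dbp, x$notch_pressure, x$notch_fraction))
  cat(sprintf("  tau %g s (asymptote %g mmHg), upstroke %g of cycle\n",
              x$tau, x$asymptote, x$upstroke_fraction))
  cat(sprintf("  noise sd %g mmHg, drift %g mmHg, artifact rate %g\n",
              x$noise_sd, x$drift_amplitude, x$artifact_rate))
  invisible(x)
}

# Noise-free samples of one cycle starting at `foot_pressure`.
# Returns the pressure vector plus the analytic end-diastolic value used to
# chain the next beat.
beat_cycle <- function(p, sampling_rate, foot_pressure = p$dbp) {
  cycle_s <- 60 / p$heart_rate
  n <- round(cycle_s * sampling_rate)
  if (n < 4L) abort("Cycle too short for the given sampling rate.")
  t <- (seq_len(n) - 1L) / sampling_rate
  t_up <- p$upstroke_fraction * cycle_s
  t_notch <- p$notch_fraction * cycle_s
  pr <- numeric(n)
  up <- t < t_up
  pr[up] <- foot_pressure +
    (p$sbp - foot_pressure) * (1 - cos(pi * t[up] / t_up)) / 2
  de <- t >= t_up & t < t_notch
  pr[de] <- p$notch_pressure + (p$sbp - p$notch_pressure) *
    (1 + cos(pi * (t[de] - t_up) / (t_notch - t_up))) / 2
  di <- t >= t_notch
  pr[di] <- p$asymptote +
    (p$notch_pressure - p$asymptote) * exp(-(t[di] - t_notch) / p$tau)
  end_pressure <- p$asymptote +
    (p$notch_pressure - p$asymptote) * exp(-(cycle_s - t_notch) / p$tau)
  list(pressure = pr, end_pressure = end_pressure,
       notch_offset = round(t_notch * sampling_rate))
}

#' Generate one noise-free cardiac cycle
#'
#' @inheritParams generate_trace
#' @param foot_pressure Pressure at the beat foot, mmHg. Defaults to the
#'   nominal `dbp`; [generate_trace()] chains beats by passing the previous
#'   cycle's end-diastolic pressure.
#'
#' @return A tibble with columns `time_s` and `pressure_mmHg` covering one
#'   cycle (the sample at the end of the cycle belongs to the next beat).
#' @export
#' @examples
#' beat <- generate_beat(beat_model_params(), sampling_rate = 100)
#' nrow(beat)  # one 1-s cycle at 100 Hz
generate_beat <- function(params, sampling_rate = 100, foot_pressure = NULL) {
  validate_beat_model_params(params)
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number.")
  }
  if (is.null(foot_pressure)) foot_pressure <- params$dbp
  cyc <- beat_cycle(params, sampling_rate, foot_pressure)
  tibble(
    time_s = (seq_along(cyc$pressure) - 1L) / sampling_rate,
    pressure_mmHg = cyc$pressure
  )
}

# Artifact morphology: the clean cycle time-reversed and rescaled toward the
# asymptote by 0.6; guaranteed by construction to correlate poorly with the
# clean template (asserted in the test suite).
artifact_cycle <- function(clean, asymptote) {
  asymptote + 0.6 * (rev(clean) - asymptote)
}

#' Simulate a continuous stump- or radial-pressure recording
#'
#' Concatenates chained model beats (see [beat_model_params()]), optionally
#' replacing beats with artifact morphologies, then adds a slow 0.05 Hz
#' sinusoidal baseline drift and white measurement noise.  Ground truth for
#' every beat foot, dicrotic notch and artifact flag is returned alongside the
#' trace so downstream detectors can be scored exactly.
#'
#' @param params A [beat_model_params()] object.
#' @param duration Recording length in seconds (must exceed one cycle).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel Channel label for the generated trace.
#' @param subject_id Subject identifier stored on the trace.
#'
#' @return A list with elements
#'   * `trace`: a [bp_trace()] tibble (`time_s`, `pressure_mmHg`);
#'   * `truth`: a list with `beat_start_indices`, `notch_indices`,
#'     `artifact_flags` (all 1-based, one per beat started within the
#'     recording), the realized steady-state `dbp_true`, `sbp_true`,
#'     `tau_true`, `notch_pressure_true`, the clean steady-state `template`
#'     cycle, `params`, `duration` and `sampling_rate`.
#' @export
#' @examples
#' sim <- generate_trace(beat_model_params(seed = 1), duration = 10)
#' length(sim$truth$beat_start_indices)
generate_trace <- function(params, duration = 60, sampling_rate = 100,
                           channel = "ica_stump", subject_id = "sim") {
  validate_beat_model_params(params)
  cycle_s <- 60 / params$heart_rate
  if (!is_number(duration) || duration <= cycle_s) {
    abort("`duration` must exceed one cycle length.")
  }
  if (!is.null(params$seed)) set.seed(params$seed)

  n_total <- round(duration * sampling_rate)

  # The end-diastolic pressure of a cycle does not depend on its foot value,
  # so the recording is generated in the periodic steady state: every clean
  # beat starts (and ends) at the realized diastolic foot pressure.
  dbp_true <- params$asymptote + (params$notch_pressure - params$asymptote) *
    exp(-(1 - params$notch_fraction) * cycle_s / params$tau)
  cyc <- beat_cycle(params, sampling_rate, dbp_true)
  template <- cyc$pressure
  artifact <- artifact_cycle(template, params$asymptote)
  n_cycle <- length(template)
  n_beats <- ceiling(n_total / n_cycle)

  artifacts <- runif(n_beats) < params$artifact_rate
  pressure <- unlist(lapply(seq_len(n_beats), function(b) {
    if (artifacts[b]) artifact else template
  }), use.names = FALSE)[seq_len(n_total)]
  starts <- (seq_len(n_beats) - 1L) * n_cycle + 1L
  notches <- starts + cyc$notch_offset
  keep <- starts <= n_total
  starts <- starts[keep]
  notches <- pmin(notches[keep], n_total)
  artifacts <- artifacts[keep]

  t <- (seq_len(n_total) - 1L) / sampling_rate
  pressure <- pressure +
    params$drift_amplitude * sin(2 * pi * 0.05 * t) +
    rnorm(n_total, 0, params$noise_sd)

  list(
    trace = bp_trace(pressure, sampling_rate = sampling_rate,
                     channel = channel, subject_id = subject_id),
    truth = list(
      beat_start_indices = starts,
      notch_indices = notches,
      artifact_flags = artifacts,
      sbp_true = params$sbp,
      dbp_true = dbp_true,
      tau_true = params$tau,
      notch_pressure_true = params$notch_pressure,
      template = template,
      params = params,
      duration = duration,
      sampling_rate = sampling_rate
    )
  )
}
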