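# Default per-group ICA stump pressure distributions (means and SDs, mmHg)
# and group sizes for the five circle-of-Willis variant groups, matching the
# cohort structure the package emulates.  tau is identical across groups by
# default (the simulator's null decay-constant effect).
cow_group_defaults <- function() {
  list(
    group_sizes = c(12L, 12L, 31L, 18L, 5L),
    ica_dbp_mean = c(51.5, 50.7, 40.7, 38.9, 35.0),
    ica_dbp_sd   = c(10.6, 19.0, 10.8, 10.2, 15.9),
    ica_pp_mean  = c(23.4, 27.7, 18.9, 12.2, 11.7),
    ica_pp_sd    = c(15.1, 15.3, 11.4,  8.2,  9.9),
    radial_dbp_mean = 62, radial_dbp_sd = 15,
    radial_pp_mean  = 71, radial_pp_sd  = 19,
    hr_mean = 68, hr_sd = 13,
    tau_mean = 1.2, tau_sd = 0.35,
    # fraction of pulse pressure above DBP at which the notch/mean pressure
    # sit; calibrated to the incisura and mean-pressure levels of the five
    # groups (inc ~ dbp + 0.46 pp, mbp ~ dbp + 0.41 pp)
    inc_frac_mean = 0.46, inc_frac_sd = 0.05,
    mbp_frac_mean = 0.41, mbp_frac_sd = 0.05,
    # group-conditional backflow grade probabilities (rows: CoW groups 1-5,
    # columns: grades 1-3); monotone - more compromised circles get weaker
    # backflow
    backflow_probs = matrix(c(
      0.02, 0.13, 0.85,
      0.03, 0.17, 0.80,
      0.08, 0.25, 0.67,
      0.12, 0.40, 0.48,
      0.35, 0.45, 0.20
    ), nrow = 5, byrow = TRUE),
    stenosis_min = 0, stenosis_max = 90
  )
}

#' Parameters of the cohort simulator
#'
#' Defines the five circle-of-Willis groups' sizes and per-group ICA stump
#' pressure distributions, a shared radial (systemic) pressure distribution,
#' a group-conditional backflow-grade rule, and a contralateral-stenosis
#' distribution.  Defaults reproduce the emulated cohort structure: group
#' sizes (12, 12, 31, 18, 5), per-group ICA DBP/PP means and SDs, identical
#' decay constants across groups, and a monotone backflow rule under which
#' more compromised circles show weaker backflow.
#'
#' Per-subject features are drawn as DBP and pulse pressure from the group
#' marginals (with symmetric two-sided truncation, which enforces positivity
#' while preserving the configured means exactly), SBP = DBP + PP, and
#' incisura/mean pressures at calibrated fractions of the pulse pressure.
#'
#' @param group_sizes Integer vector of the five group sizes (>= 0, at least
#'   two groups non-empty).
#' @param ica_dbp_mean,ica_dbp_sd,ica_pp_mean,ica_pp_sd Length-5 numeric
#'   vectors: per-group ICA diastolic and pulse-pressure distributions, mmHg.
#' @param tau_mean,tau_sd Decay-constant distribution, seconds (shared across
#'   groups by default).
#' @param backflow_probs 5x3 matrix of backflow-grade probabilities per group;
#'   rows must sum to 1.
#' @param seed Integer seed for reproducibility.
#' @param ... Overrides for the remaining defaults of `cow_group_defaults()`
#'   (`radial_dbp_mean`, `radial_pp_sd`, `hr_mean`, `stenosis_max`, ...).
#'
#' @return An object of class `cohort_sim_params`.
#' @export
#' @examples
#' params <- cohort_sim_params(seed = 1)
#' params$group_sizes
cohort_sim_params <- function(group_sizes = NULL,
                              ica_dbp_mean = NULL, ica_dbp_sd = NULL,
                              ica_pp_mean = NULL, ica_pp_sd = NULL,
                              tau_mean = NULL, tau_sd = NULL,
                              backflow_probs = NULL, seed = NULL, ...) {
  p <- cow_group_defaults()
  override <- c(
    list(group_sizes = group_sizes, ica_dbp_mean = ica_dbp_mean,
         ica_dbp_sd = ica_dbp_sd, ica_pp_mean = ica_pp_mean,
         ica_pp_sd = ica_pp_sd, tau_mean = tau_mean, tau_sd = tau_sd,
         backflow_probs = backflow_probs),
    list(...)
  )
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) {
      if (!nm %in% names(p)) abort(sprintf("Unknown simulator parameter `%s`.", nm))
      p[[nm]] <- override[[nm]]
    }
  }
  p$seed <- seed
  if (length(p$group_sizes) != 5L || any(p$group_sizes < 0)) {
    abort("`group_sizes` must be five non-negative counts.")
  }
  if (sum(p$group_sizes > 0) < 2L && sum(p$group_sizes) > 0) {
    warn("Fewer than two non-empty groups: cohort statistics stages will fail.")
  }
  if (sum(p$group_sizes) == 0L) abort("All group sizes are zero.")
  for (nm in c("ica_dbp_mean", "ica_dbp_sd", "ica_pp_mean", "ica_pp_sd")) {
    if (length(p[[nm]]) != 5L) abort(sprintf("`%s` must have length 5.", nm))
  }
  if (!is.matrix(p$backflow_probs) || any(dim(p$backflow_probs) != c(5L, 3L))) {
    abort("`backflow_probs` must be a 5x3 matrix.")
  }
  if (any(abs(rowSums(p$backflow_probs) - 1) > 1e-8) || any(p$backflow_probs < 0)) {
    abort("Backflow grade probabilities must be non-negative and sum to 1 per group.")
  }
  structure(p, class = "cohort_sim_params")
}

# Draw one group's worth of waveform features from a DBP/PP specification.
draw_channel_features <- function(n, dbp_mean, dbp_sd, pp_mean, pp_sd,
                                  inc_frac_mean, inc_frac_sd,
                                  mbp_frac_mean, mbp_frac_sd) {
  dbp <- rnorm_sym_trunc(n, dbp_mean, dbp_sd, lo = min(5, dbp_mean / 2))
  pp <- rnorm_sym_trunc(n, pp_mean, pp_sd, lo = min(3, pp_mean / 2))
  f_inc <- rnorm_sym_trunc(n, inc_frac_mean, inc_frac_sd, lo = 0.15)
  f_mbp <- rnorm_sym_trunc(n, mbp_frac_mean, mbp_frac_sd, lo = 0.15)
  tibble(
    sbp = dbp + pp, dbp = dbp, pp = pp,
    mbp = dbp + f_mbp * pp, inc_bp = dbp + f_inc * pp
  )
}

#' Simulate a cohort of subjects with known group structure
#'
#' Generates one record per subject: circle-of-Willis group, backflow grade
#' (from the group-conditional rule), contralateral stenosis, ICA stump and
#' radial waveform features, and ICA/radial pressure ratios.  With
#' `output = "traces"` each subject additionally carries simulated 60-s
#' pressure recordings (list columns `ica_trace` and `radial_trace`, each a
#' [generate_trace()] result) built from the subject's drawn parameters, for
#' exercising the full signal pipeline.
#'
#' @param params A [cohort_sim_params()] object.
#' @param output `"features"` (default) to draw waveform features directly
#'   from the configured distributions, or `"traces"` to also synthesize raw
#'   recordings per subject.
#' @param duration,sampling_rate Recording length and rate for
#'   `output = "traces"`.
#'
#' @return A tibble with one row per subject: `subject_id`, `cow_group`,
#'   `backflow_grade`, `contralateral_stenosis_pct`, `hr`, `ica_*` and
#'   `radial_*` feature columns, `ratio_*` columns, and `tau` columns.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_sim_params(seed = 7))
#' dplyr::count(cohort, cow_group)
generate_cohort <- function(params = cohort_sim_params(),
                            output = c("features", "traces"),
                            duration = 60, sampling_rate = 100) {
  stopifnot(inherits(params, "cohort_sim_params"))
  output <- match.arg(output)
  if (!is.null(params$seed)) set.seed(params$seed)

  groups <- rep(1:5, times = params$group_sizes)
  n <- length(groups)

  ica <- purrr::map_dfr(which(params$group_sizes > 0L), function(g) {
    draw_channel_features(
      params$group_sizes[g], params$ica_dbp_mean[g], params$ica_dbp_sd[g],
      params$ica_pp_mean[g], params$ica_pp_sd[g],
      params$inc_frac_mean, params$inc_frac_sd,
      params$mbp_frac_mean, params$mbp_frac_sd
    )
  })
  radial <- draw_channel_features(
    n, params$radial_dbp_mean, params$radial_dbp_sd,
    params$radial_pp_mean, params$radial_pp_sd,
    params$inc_frac_mean, params$inc_frac_sd,
    params$mbp_frac_mean, params$mbp_frac_sd
  )
  tau <- rnorm_sym_trunc(n, params$tau_mean, params$tau_sd,
                         lo = min(0.4, params$tau_mean / 2))
  hr <- rnorm_sym_trunc(n, params$hr_mean, params$hr_sd, lo = 40)
  backflow <- vapply(groups, function(g) {
    sample.int(3L, 1L, prob = params$backflow_probs[g, ])
  }, integer(1))
  stenosis <- runif(n, params$stenosis_min, params$stenosis_max)

  names(ica) <- paste0("ica_", names(ica))
  names(radial) <- paste0("radial_", names(radial))
  cohort <- dplyr::bind_cols(
    tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      cow_group = groups,
      backflow_grade = backflow,
      contralateral_stenosis_pct = stenosis,
      hr = hr
    ),
    ica, radial,
    tibble(ica_tau = tau)
  )
  cohort <- dplyr::mutate(
    cohort,
    ratio_sbp = .data$ica_sbp / .data$radial_sbp,
    ratio_dbp = .data$ica_dbp / .data$radial_dbp,
    ratio_pp = .data$ica_pp / .data$radial_pp,
    ratio_mbp = .data$ica_mbp / .data$radial_mbp,
    ratio_inc = .data$ica_inc_bp / .data$radial_inc_bp
  )

  if (output == "traces") {
    make_params <- function(sbp, dbp, inc_bp, tau, hr) {
      beat_model_params(
        heart_rate = hr, sbp = sbp, dbp = dbp,
        notch_pressure = min(max(inc_bp, dbp + 0.1 * (sbp - dbp)),
                             sbp - 0.1 * (sbp - dbp)),
        tau = tau, noise_sd = 1
      )
    }
    cohort$ica_trace <- purrr::map(seq_len(n), function(i) {
      generate_trace(
        make_params(cohort$ica_sbp[i], cohort$ica_dbp[i],
                    cohort$ica_inc_bp[i], cohort$ica_tau[i], cohort$hr[i]),
        duration = duration, sampling_rate = sampling_rate,
        channel = "ica_stump", subject_id = cohort$subject_id[i]
      )
    })
    cohort$radial_trace <- purrr::map(seq_len(n), function(i) {
      generate_trace(
        make_params(cohort$radial_sbp[i], cohort$radial_dbp[i],
                    cohort$radial_inc_bp[i], cohort$ica_tau[i], cohort$hr[i]),
        duration = duration, sampling_rate = sampling_rate,
        channel = "radial", subject_id = cohort$subject_id[i]
      )
    })
  }
  cohort
}
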