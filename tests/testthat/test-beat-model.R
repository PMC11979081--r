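test_that("parameter invariants are enforced with named violations", {
  expect_error(beat_model_params(sbp = 90, notch_pressure = 95),
               "notch_pressure")
  expect_error(beat_model_params(dbp = 100, notch_pressure = 95),
               "notch_pressure")
  expect_error(beat_model_params(tau = 0), "tau")
  expect_error(beat_model_params(upstroke_fraction = 0.5, notch_fraction = 0.4),
               "upstroke_fraction")
  expect_error(beat_model_params(artifact_rate = 1), "artifact_rate")
  expect_error(beat_model_params(noise_sd = -1), "noise_sd")
  expect_error(beat_model_params(asymptote = 90, dbp = 80), "dbp")
})

test_that("single-beat amplitude endpoints are exact by construction", {
  beat <- generate_beat(beat_model_params(sbp = 120, dbp = 80),
                        sampling_rate = 100)
  expect_identical(beat$pressure_mmHg[1], 80)
  expect_identical(max(beat$pressure_mmHg), 120)
  expect_equal(nrow(beat), 100)  # 1-s cycle at 100 Hz
})

test_that("diastolic samples follow the configured exponential decay", {
  p <- beat_model_params(tau = 1.2, asymptote = 0)
  beat <- generate_beat(p, sampling_rate = 100)
  t <- beat$time_s
  dia <- t >= p$notch_fraction * 1  # 1-s cycle
  fit <- stats::lm(log(beat$pressure_mmHg[dia]) ~ t[dia])
  expect_equal(unname(stats::coef(fit)[2]), -1 / 1.2, tolerance = 1e-6)
})

test_that("the waveform is continuous at the notch and upstroke junctions", {
  for (nf in c(0.3, 0.35, 0.45)) {
    p <- beat_model_params(notch_fraction = nf, upstroke_fraction = 0.15)
    beat <- generate_beat(p, sampling_rate = 1000)
    jumps <- abs(diff(beat$pressure_mmHg))
    # largest sample-to-sample step must be of the order of the local slope
    expect_lt(max(jumps), 1.0)
  }
})

test_that("diastole of a noise-free beat satisfies the area identity", {
  p <- beat_model_params(tau = 0.9, asymptote = 0)
  beat <- generate_beat(p, sampling_rate = 100)
  dia <- which(beat$time_s >= p$notch_fraction)
  a <- pracma::trapz(beat$time_s[dia], beat$pressure_mmHg[dia])
  drop <- beat$pressure_mmHg[dia[1]] - beat$pressure_mmHg[dia[length(dia)]]
  expect_equal(a / drop, 0.9, tolerance = 1e-3)
})

test_that("trace duration, beat count and determinism contracts hold", {
  sim <- clean_sim(seed = 3)
  expect_equal(nrow(sim$trace), 6000)
  expect_length(sim$truth$beat_start_indices, 60)
  expect_length(sim$truth$artifact_flags, 60)
  expect_true(all(diff(sim$truth$beat_start_indices) > 0))
  expect_true(all(sim$truth$notch_indices > sim$truth$beat_start_indices))

  sim2 <- clean_sim(seed = 3)
  expect_identical(sim$trace$pressure_mmHg, sim2$trace$pressure_mmHg)

  p7 <- beat_model_params(noise_sd = 2, artifact_rate = 0.1, seed = 7)
  a <- generate_trace(p7, duration = 20)
  b <- generate_trace(p7, duration = 20)
  expect_identical(a$trace$pressure_mmHg, b$trace$pressure_mmHg)
  expect_identical(a$truth$artifact_flags, b$truth$artifact_flags)

  expect_error(generate_trace(beat_model_params(), duration = 0.5), "duration")
})

test_that("artifact morphology correlates below the 0.95 gate by construction", {
  for (tau in c(0.5, 1.2, 2)) {
    p <- beat_model_params(tau = tau)
    sim <- generate_trace(p, duration = 5)
    template <- sim$truth$template
    artifact <- stumpwave:::artifact_cycle(template, p$asymptote)
    expect_lt(stats::cor(template, artifact), 0.95)
  }
})

test_that("cohort generator reproduces the configured group structure", {
  params <- cohort_sim_params(seed = 11)
  expect_identical(params$group_sizes, c(12L, 12L, 31L, 18L, 5L))
  expect_equal(params$ica_pp_mean, c(23.4, 27.7, 18.9, 12.2, 11.7))

  cohort <- generate_cohort(params)
  expect_equal(nrow(cohort), 78)
  expect_equal(as.integer(table(cohort$cow_group)), c(12L, 12L, 31L, 18L, 5L))
  expect_true(all(cohort$ica_sbp > cohort$ica_dbp))
  expect_true(all(cohort$ica_inc_bp > cohort$ica_dbp &
                    cohort$ica_inc_bp < cohort$ica_sbp))
  expect_true(all(cohort$backflow_grade %in% 1:3))
  expect_true(all(cohort$ratio_sbp == cohort$ica_sbp / cohort$radial_sbp))

  cohort2 <- generate_cohort(cohort_sim_params(seed = 11))
  expect_identical(cohort, cohort2)

  expect_error(cohort_sim_params(group_sizes = c(0, 0, 0, 0, 0)), "zero")
})

test_that("drawn ICA pressures recover the configured group means (Monte-Carlo)", {
  params <- suppressWarnings(
    cohort_sim_params(group_sizes = c(1000L, 0L, 0L, 0L, 0L), seed = 21)
  )
  draws <- purrr::map_dbl(1:50, function(i) {
    params$seed <- 21 + i
    mean(generate_cohort(params)$ica_sbp)
  })
  configured <- 51.5 + 23.4  # group-1 DBP + PP means
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - configured), 3 * se + 1e-9)
})

test_that("trace output mode yields analysable per-subject recordings", {
  params <- cohort_sim_params(group_sizes = c(2L, 0L, 2L, 0L, 0L), seed = 5)
  cohort <- generate_cohort(params, output = "traces", duration = 12)
  expect_true(all(c("ica_trace", "radial_trace") %in% names(cohort)))
  sim <- cohort$ica_trace[[1]]
  expect_s3_class(sim$trace, "bp_trace")
  f <- analyze_trace(sim$trace)
  expect_equal(f$sbp, sim$truth$sbp_true, tolerance = 0.05)
})

test_that("simulator configuration round-trips through YAML", {
  p <- beat_model_params(tau = 0.8, noise_sd = 1.5, seed = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(p, path)
  p2 <- read_sim_config(path)
  expect_s3_class(p2, "beat_model_params")
  expect_equal(p2$tau, 0.8)
  expect_equal(p2$noise_sd, 1.5)

  cp <- cohort_sim_params(seed = 9)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cp, path2)
  cp2 <- read_sim_config(path2)
  expect_s3_class(cp2, "cohort_sim_params")
  expect_equal(cp2$group_sizes, cp$group_sizes)
  expect_equal(cp2$backflow_probs, cp$backflow_probs)
})
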