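test_that("a flat trace yields no beats and downstream stages refuse to run", {
  flat <- bp_trace(rep(80, 1000), 100)
  expect_warning(beats <- segment_beats(flat), "not pulsatile")
  expect_equal(nrow(beats), 0)
  expect_error(suppressWarnings(ensemble_average(flat)), "Insufficient")
})

test_that("cycle mapping recovers the generator's beat feet", {
  sim <- clean_sim(seed = 4)
  beats <- segment_beats(preprocess_trace(sim$trace))
  expect_gte(nrow(beats), 59)
  expect_lte(nrow(beats), 61)
  err_ms <- vapply(beats$start, function(s) {
    10 * min(abs(sim$truth$beat_start_indices - s))
  }, numeric(1))
  expect_lte(max(err_ms), 20)

  sim75 <- generate_trace(beat_model_params(heart_rate = 75, seed = 4),
                          duration = 30)
  beats75 <- segment_beats(preprocess_trace(sim75$trace))
  n_truth <- length(sim75$truth$beat_start_indices)
  expect_gte(nrow(beats75), n_truth - 2L)
  expect_lte(nrow(beats75), n_truth)
  expect_true(all(abs(beats75$duration_s - 0.8) < 0.05))
})

test_that("the fiducial is the brute-force second-difference argmax on the anacrotic limb", {
  sim <- clean_sim(seed = 9, noise_sd = 1)
  cond <- preprocess_trace(sim$trace)
  beats <- segment_beats(cond)
  x <- cond$pressure_mmHg
  for (i in c(2, 10, 25, 40)) {
    seg <- x[beats$start[i]:(beats$end[i] - 1L)]
    got <- locate_fiducial(seg)
    # independent exhaustive search over the interval foot..systolic peak
    peak <- which.max(seg)
    best <- -Inf; best_k <- NA
    for (k in 2:peak) {
      if (k + 1 <= length(seg)) {
        d2 <- seg[k + 1] - 2 * seg[k] + seg[k - 1]
        if (d2 > best) { best <- d2; best_k <- k }
      }
    }
    expect_identical(got, best_k)
  }
})

test_that("the fiducial sits at the upstroke onset of a raised-cosine beat", {
  beat <- generate_beat(beat_model_params(), sampling_rate = 100)
  f <- locate_fiducial(beat$pressure_mmHg)
  expect_lte(abs(f - 1) * 10, 10)  # within 10 ms of the onset
})

test_that("fiducial detection under noise stays within 30 ms of its noise-free locus", {
  # the conditioned waveform's curvature maximum sits a fixed few samples
  # after the upstroke onset; noise robustness is judged as jitter about
  # that noise-free locus
  clean <- segment_beats(preprocess_trace(clean_sim(seed = 13)$trace))
  offset <- stats::median(vapply(clean$fiducial, function(fi) {
    d <- fi - clean_sim(seed = 13)$truth$beat_start_indices
    d[which.min(abs(d))]
  }, numeric(1)))

  sim <- clean_sim(seed = 13, noise_sd = 2)
  beats <- segment_beats(preprocess_trace(sim$trace))
  beats <- beats[!is.na(beats$fiducial), ]
  err_ms <- vapply(beats$fiducial, function(fi) {
    10 * min(abs(sim$truth$beat_start_indices + offset - fi))
  }, numeric(1))
  expect_gte(mean(err_ms <= 30), 0.95)
})

test_that("averaging identical beats returns the beat itself with r = 1", {
  p <- beat_model_params()
  sim <- generate_trace(p, duration = 20)
  cond <- sim$trace  # noise-free: skip conditioning, beats are identical
  eb <- ensemble_average(cond)
  expect_true(all(abs(eb$beats$correlation - 1) < 1e-9))
  expect_equal(eb$n_retained, nrow(eb$beats))
  # representative equals the template over the common support
  ci <- stumpwave:::beat_cycle_indices(eb)
  tmpl <- sim$truth$template
  n <- min(nrow(eb$representative) - ci$foot + 1, length(tmpl))
  expect_lt(max(abs(eb$representative$pressure_mmHg[ci$foot:(ci$foot + n - 1)] -
                      tmpl[seq_len(n)])), 1e-9)
  expect_equal(eb$heart_rate, 60)
})

test_that("time-reversed artifact cycles are gated out and the template is recovered", {
  p <- beat_model_params(artifact_rate = 0.1, seed = 5)
  sim <- generate_trace(p, duration = 60)
  expect_gt(sum(sim$truth$artifact_flags), 0)
  cond <- preprocess_trace(sim$trace)
  eb <- ensemble_average(cond)
  d <- tidy(eb)

  post <- min(d$end - d$fiducial)
  win_lo <- d$fiducial - (eb$fiducial_index - 1L)
  win_hi <- d$fiducial + post - 1L
  art_starts <- sim$truth$beat_start_indices[sim$truth$artifact_flags]
  touches_artifact <- vapply(seq_len(nrow(d)), function(i) {
    any(art_starts < win_hi[i] - 5 & (art_starts + 99) > win_lo[i] + 5)
  }, logical(1))
  # every window containing artifact content fails the r > 0.95 gate
  expect_true(all(d$correlation[touches_artifact] < 0.95))
  expect_true(all(!d$retained[touches_artifact]))
  # and the retained average matches the artifact-free pipeline output
  p0 <- beat_model_params(seed = 5)
  eb0 <- ensemble_average(preprocess_trace(generate_trace(p0, 60)$trace))
  n <- min(nrow(eb$representative), nrow(eb0$representative))
  rms <- sqrt(mean((eb$representative$pressure_mmHg[1:n] -
                      eb0$representative$pressure_mmHg[1:n])^2))
  expect_lt(rms, 0.5)
})

test_that("the correlation gate is monotone in its threshold", {
  sim <- clean_sim(seed = 17, noise_sd = 3, artifact_rate = 0.08)
  cond <- preprocess_trace(sim$trace)
  segments <- segment_beats(cond)
  retained <- vapply(c(0.5, 0.8, 0.95, 0.99),
                     function(thr) {
                       ensemble_average(cond, segments,
                                        r_threshold = thr)$n_retained
                     }, numeric(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("averaging is invariant to a whole-trace shift and idempotent", {
  sim <- clean_sim(seed = 19)
  cond <- preprocess_trace(sim$trace)
  eb <- ensemble_average(cond)

  k <- 37L
  x <- cond$pressure_mmHg
  shifted <- bp_trace(x[(k + 1):length(x)], 100)
  eb_s <- ensemble_average(shifted)
  n <- min(nrow(eb$representative), nrow(eb_s$representative))
  expect_lt(max(abs(eb$representative$pressure_mmHg[1:n] -
                      eb_s$representative$pressure_mmHg[1:n])), 1e-6)

  # idempotence: N copies of the representative reproduce it
  rep_cycle <- eb$representative$pressure_mmHg
  many <- bp_trace(rep(rep_cycle, 12), 100)
  eb2 <- ensemble_average(many)
  expect_true(all(eb2$beats$correlation > 0.999))
  ci2 <- stumpwave:::beat_cycle_indices(eb2)
  ci1 <- stumpwave:::beat_cycle_indices(eb)
  n <- min(ci1$end - ci1$foot, ci2$end - ci2$foot)
  expect_lt(max(abs(eb2$representative$pressure_mmHg[ci2$foot + 0:(n - 1)] -
                      eb$representative$pressure_mmHg[ci1$foot + 0:(n - 1)])), 0.02)
})

test_that("too few concordant beats raises a structured error", {
  sim <- clean_sim(seed = 23, duration = 8)
  cond <- preprocess_trace(sim$trace)
  segments <- segment_beats(cond)
  expect_error(ensemble_average(cond, segments, min_beats = 50L),
               "Insufficient")
  err <- tryCatch(
    ensemble_average(cond, segments, r_threshold = 0.999999, min_beats = 50L),
    error = function(e) e
  )
  expect_true(inherits(err, c("stumpwave_insufficient_beats", "rlang_error")))
})

test_that("the default correlation threshold is 0.95", {
  expect_identical(formals(ensemble_average)$r_threshold, 0.95)
})
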