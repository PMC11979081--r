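# Shared fixtures for the test suite: everything is generated in code.

seg_names <- c("acom", "a1_ipsi", "a1_contra", "pcom_ipsi", "pcom_contra",
               "p1_ipsi", "p1_contra")

all_normal_segments <- function() {
  stats::setNames(rep("normal", 7L), seg_names)
}

# Independent rule-table oracle for the circle-of-Willis classifier, written
# directly from the clinical definitions in set terms (deliberately different
# code path from the package implementation).
cow_oracle <- function(states) {
  ant <- states[c("a1_contra", "acom", "a1_ipsi")]
  post <- states[c("pcom_ipsi", "pcom_contra", "p1_ipsi", "p1_contra")]
  n_bad_ant <- sum(ant %in% c("hypoplastic", "absent"))
  n_bad_post <- sum(post %in% c("hypoplastic", "absent"))
  ant_path_open <- !"absent" %in% ant
  post_path_open <- states[["p1_ipsi"]] != "absent" &&
    states[["pcom_ipsi"]] != "absent"
  if (!ant_path_open && !post_path_open) return(5L)
  if (n_bad_ant > 0 && n_bad_post > 0) return(4L)
  if (n_bad_ant > 0) return(2L)
  if (n_bad_post > 0) return(3L)
  1L
}

# A standard noise-free study-style recording (60 s at 100 Hz, HR 60).
clean_sim <- function(tau = 1.2, seed = 1, duration = 60, ...) {
  generate_trace(
    beat_model_params(heart_rate = 60, sbp = 120, dbp = 80, tau = tau,
                      seed = seed, ...),
    duration = duration, sampling_rate = 100
  )
}

# Minimal valid metadata table as a data frame (written to CSV by io tests).
example_metadata <- function(n = 3) {
  df <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    operated_side = rep(c("left", "right"), length.out = n),
    stringsAsFactors = FALSE
  )
  for (s in seg_names) df[[s]] <- "normal"
  df$backflow_grade <- rep(c(3L, 2L, 1L), length.out = n)
  df$contralateral_stenosis_pct <- seq(10, 70, length.out = n)
  df
}
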