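#' Construct a validated blood-pressure trace
#'
#' A `bp_trace` is a tibble with columns `time_s` (seconds from the start of
#' the recording) and `pressure_mmHg`, carrying the sampling rate, channel
#' role and subject id as attributes.  All analysis functions re-derive the
#' sampling rate from the `time_s` column when the attribute has been dropped
#' by intermediate data wrangling.
#'
#' @param pressure Numeric vector of pressure samples, mmHg.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel Channel role, `"ica_stump"` or `"radial"`.
#' @param subject_id Subject identifier.
#'
#' @return A tibble of class `bp_trace`.
#' @export
#' @examples
#' bp_trace(c(80, 81, 82), sampling_rate = 100)
bp_trace <- function(pressure, sampling_rate,
                     channel = c("ica_stump", "radial"),
                     subject_id = NA_character_) {
  channel <- match.arg(channel)
  if (!is.numeric(pressure) || length(pressure) < 2L) {
    abort("A pressure trace needs at least 2 numeric samples.")
  }
  if (anyNA(pressure) || any(!is.finite(pressure))) {
    abort("All pressure samples must be finite.")
  }
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number.")
  }
  out <- tibble(
    time_s = (seq_along(pressure) - 1L) / sampling_rate,
    pressure_mmHg = as.numeric(pressure)
  )
  structure(out,
            class = c("bp_trace", class(out)),
            sampling_rate = sampling_rate,
            channel = channel,
            subject_id = subject_id)
}

# Resolve the sampling rate of a trace-like data frame: explicit argument,
# then attribute, then the time column (which must be uniform within 1e-6 s).
trace_sampling_rate <- function(trace, sampling_rate = NULL) {
  if (!is.null(sampling_rate)) {
    if (!is_number(sampling_rate) || sampling_rate <= 0) {
      abort("`sampling_rate` must be a single positive number.")
    }
    return(sampling_rate)
  }
  fs <- attr(trace, "sampling_rate")
  if (is_number(fs) && fs > 0) return(fs)
  if (!is.data.frame(trace) || !"time_s" %in% names(trace)) {
    abort("Cannot determine the sampling rate: supply `sampling_rate`.")
  }
  tt <- trace$time_s
  if (length(tt) < 2L) abort("A pressure trace needs at least 2 samples.")
  dt <- diff(tt)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6) {
    abort("Non-uniform sampling: the time column must have a constant step (within 1e-6 s).")
  }
  fs <- (length(tt) - 1L) / (tt[length(tt)] - tt[1L])
  # snap to a rounded rate when the time column was stored in decimal seconds
  if (abs(fs - round(fs, 6)) < 1e-6 * fs) fs <- round(fs, 6)
  fs
}

trace_pressure <- function(trace) {
  if (is.numeric(trace)) return(as.numeric(trace))
  if (is.data.frame(trace) && "pressure_mmHg" %in% names(trace)) {
    return(as.numeric(trace$pressure_mmHg))
  }
  abort("Expected a bp_trace (or a data frame with a `pressure_mmHg` column).")
}

#' Read a pressure trace from a delimited text file
#'
#' Two documented dialects are supported: a headed CSV with columns
#' `time_s,pressure_mmHg`, or a headerless single column of pressures with the
#' sampling rate supplied by the caller.  The time column, when present, must
#' be uniformly sampled (constant step within 1e-6 s) and is used to infer the
#' sampling rate.
#'
#' @param path Path to the file.
#' @param sampling_rate Required for headerless single-column files; for
#'   headed files it overrides the rate inferred from the time column.
#' @inheritParams bp_trace
#'
#' @return A [bp_trace()] tibble.
#' @export
read_trace <- function(path, sampling_rate = NULL,
                       channel = c("ica_stump", "radial"),
                       subject_id = NA_character_) {
  channel <- match.arg(channel)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1L)
  headed <- grepl("time_s", first, fixed = TRUE)
  if (headed) {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE)
    if (!all(c("time_s", "pressure_mmHg") %in% names(raw))) {
      abort("Headed trace files must have columns `time_s,pressure_mmHg`.")
    }
    if (nrow(raw) < 2L) abort("A pressure trace needs at least 2 rows.")
    tt <- suppressWarnings(as.numeric(raw$time_s))
    pp <- suppressWarnings(as.numeric(raw$pressure_mmHg))
    bad <- which(is.na(tt) | is.na(pp))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric value in %s at data line %d.", path, bad[1L]))
    }
    fs <- trace_sampling_rate(tibble(time_s = tt), sampling_rate)
    bp_trace(pp, sampling_rate = fs, channel = channel, subject_id = subject_id)
  } else {
    if (is.null(sampling_rate)) {
      abort("Headerless trace files require `sampling_rate`.")
    }
    vals <- readLines(path)
    vals <- vals[nzchar(trimws(vals))]
    if (length(vals) < 2L) abort("A pressure trace needs at least 2 rows.")
    pp <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(pp))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric value in %s at data line %d.", path, bad[1L]))
    }
    bp_trace(pp, sampling_rate = sampling_rate, channel = channel,
             subject_id = subject_id)
  }
}

#' Write a pressure trace to CSV
#'
#' Writes the documented `time_s,pressure_mmHg` dialect with full
#' double-precision round-trip fidelity, so
#' `read_trace(write_trace(trace, path))` reproduces the samples and sampling
#' rate exactly.
#'
#' @param trace A [bp_trace()] (or any data frame with `time_s` and
#'   `pressure_mmHg` columns).
#' @param path Output path.
#' @param sampling_rate Override for the sampling rate when `trace` carries
#'   none.
#' @return The input `trace`, invisibly.
#' @export
write_trace <- function(trace, path, sampling_rate = NULL) {
  fs <- trace_sampling_rate(trace, sampling_rate)
  pp <- trace_pressure(trace)
  if (length(pp) < 2L) abort("A pressure trace needs at least 2 samples.")
  if (anyNA(pp) || any(!is.finite(pp))) abort("All pressure samples must be finite.")
  out <- tibble(time_s = (seq_along(pp) - 1L) / fs, pressure_mmHg = pp)
  readr::write_csv(out, path)
  invisible(trace)
}

cow_segment_names <- c("acom", "a1_ipsi", "a1_contra", "pcom_ipsi",
                       "pcom_contra", "p1_ipsi", "p1_contra")
cow_segment_states <- c("normal", "hypoplastic", "absent")

#' Read a subject metadata table
#'
#' The documented CSV header is `subject_id,operated_side` followed by the
#' seven circle-of-Willis segment state columns
#' (`acom,a1_ipsi,a1_contra,pcom_ipsi,pcom_contra,p1_ipsi,p1_contra`, each one
#' of `normal`, `hypoplastic` or `absent`), then `backflow_grade` (1 weak and
#' discontinuous, 2 continuous but not pulsatile, 3 strong and pulsatile) and
#' `contralateral_stenosis_pct` (NASCET, 0-100).
#'
#' @param path Path to the CSV file.
#' @return A tibble with one validated row per subject (empty, with a
#'   warning, when the file holds only the header).
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- as_tibble(utils::read.csv(path, colClasses = "character",
                                  check.names = FALSE))
  required <- c("subject_id", "operated_side", cow_segment_names,
                "backflow_grade", "contralateral_stenosis_pct")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Metadata table is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    warn("Metadata table contains no subjects.")
    return(tibble(subject_id = character(), operated_side = character(),
                  !!!setNames(rep(list(character()), 7L), cow_segment_names),
                  backflow_grade = integer(),
                  contralateral_stenosis_pct = numeric()))
  }
  df$operated_side <- tolower(df$operated_side)
  bad <- which(!df$operated_side %in% c("left", "right"))
  if (length(bad) > 0L) {
    abort(sprintf("Row %d: `operated_side` must be 'left' or 'right'.", bad[1L]))
  }
  for (seg in cow_segment_names) {
    df[[seg]] <- tolower(df[[seg]])
    bad <- which(!df[[seg]] %in% cow_segment_states)
    if (length(bad) > 0L) {
      abort(sprintf("Row %d: unknown state '%s' for segment `%s`.",
                    bad[1L], df[[seg]][bad[1L]], seg))
    }
  }
  grade <- suppressWarnings(as.numeric(df$backflow_grade))
  bad <- which(is.na(grade) | !grade %in% c(1, 2, 3))
  if (length(bad) > 0L) {
    abort(sprintf("Row %d: `backflow_grade` must be 1, 2 or 3.", bad[1L]))
  }
  df$backflow_grade <- as.integer(grade)
  sten <- suppressWarnings(as.numeric(df$contralateral_stenosis_pct))
  bad <- which(is.na(sten) | sten < 0 | sten > 100)
  if (length(bad) > 0L) {
    abort(sprintf("Row %d: `contralateral_stenosis_pct` must be within [0, 100].",
                  bad[1L]))
  }
  df$contralateral_stenosis_pct <- sten
  df
}

#' Write a subject metadata table
#'
#' @param metadata A tibble in the layout produced by
#'   [read_metadata_table()].
#' @param path Output path.
#' @return The input `metadata`, invisibly.
#' @export
write_metadata_table <- function(metadata, path) {
  readr::write_csv(metadata, path)
  invisible(metadata)
}
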