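#' Derive a segment state from a measured diameter
#'
#' A circle-of-Willis segment is `normal` when its diameter is 0.8 mm or
#' greater, `hypoplastic` when visible but below 0.8 mm, and `absent` when not
#' visualized (`NA` diameter).
#'
#' @param diameter_mm Numeric vector of segment diameters in mm (`NA` = not
#'   visualized).
#' @return Character vector of states.
#' @export
#' @examples
#' segment_state_from_diameter(c(0.8, 0.79, NA))
segment_state_from_diameter <- function(diameter_mm) {
  if (!is.numeric(diameter_mm)) abort("`diameter_mm` must be numeric.")
  if (any(diameter_mm < 0, na.rm = TRUE)) {
    abort("Segment diameters must be non-negative.")
  }
  dplyr::case_when(
    is.na(diameter_mm) ~ "absent",
    diameter_mm >= 0.8 ~ "normal",
    diameter_mm > 0 ~ "hypoplastic",
    .default = "absent"
  )
}

cow_anterior <- c("a1_contra", "acom", "a1_ipsi")
cow_posterior <- c("pcom_ipsi", "pcom_contra", "p1_ipsi", "p1_contra")
cow_posterior_ipsi_path <- c("p1_ipsi", "pcom_ipsi")

#' Classify circle-of-Willis morphology into the five variant groups
#'
#' Deterministic rule-based classification from the states of the seven
#' segments.  The anterior semicircle is contralateral A1, the anterior
#' communicating artery and ipsilateral A1; the posterior semicircle is P1 and
#' P-com on each side.
#'
#' * **Group 1** (complete): all segments normal.
#' * **Group 2** (anterior compromised): at least one anterior segment
#'   hypoplastic or absent, posterior all normal.
#' * **Group 3** (posterior compromised): at least one posterior segment
#'   hypoplastic or absent, anterior all normal.
#' * **Group 4** (both compromised): non-normal segments in both semicircles.
#' * **Group 5** (isolated MCA): absent segments interrupt both primary
#'   collateral routes to the operated middle cerebral artery — the anterior
#'   path (contralateral A1 / A-com / ipsilateral A1 all in series, so any
#'   absent anterior segment interrupts it) and the ipsilateral posterior path
#'   (ipsilateral P1 / P-com).  Group 5 takes precedence over group 4.
#'
#' Contralateral posterior segments affect the semicircle-compromise status
#' only, not the group-5 path-interruption test (the vertebrobasilar collateral
#' reaches the operated side through the ipsilateral P1/P-com).
#'
#' @param segments Named character vector (or 7-column one-row data frame)
#'   with states `normal`/`hypoplastic`/`absent` for segments
#'   `acom`, `a1_ipsi`, `a1_contra`, `pcom_ipsi`, `pcom_contra`, `p1_ipsi`,
#'   `p1_contra` (ipsi/contra are relative to the operated side).
#'
#' @return Integer group 1-5, with attribute `multi_segment` flagging groups
#'   2/3 whose compromised semicircle has more than one non-normal segment.
#' @export
#' @examples
#' s <- c(acom = "normal", a1_ipsi = "normal", a1_contra = "normal",
#'        pcom_ipsi = "normal", pcom_contra = "normal",
#'        p1_ipsi = "normal", p1_contra = "normal")
#' classify_cow(s)           # 1
#' s["acom"] <- "hypoplastic"
#' classify_cow(s)           # 2
classify_cow <- function(segments) {
  if (is.data.frame(segments)) {
    if (nrow(segments) != 1L) abort("`segments` data frame must have one row.")
    segments <- unlist(segments[1L, , drop = TRUE])
  }
  segments <- setNames(tolower(as.character(segments)), names(segments))
  missing <- setdiff(cow_segment_names, names(segments))
  if (length(missing) > 0L) {
    abort(sprintf("Missing segment state(s): %s",
                  paste(missing, collapse = ", ")))
  }
  segments <- segments[cow_segment_names]
  bad <- !segments %in% cow_segment_states
  if (any(bad)) {
    abort(sprintf("Unknown segment state '%s' for `%s`.",
                  segments[bad][1L], names(segments)[bad][1L]))
  }
  ant <- segments[cow_anterior]
  post <- segments[cow_posterior]
  ant_compromised <- any(ant != "normal")
  post_compromised <- any(post != "normal")
  anterior_interrupted <- any(ant == "absent")
  posterior_path_interrupted <- any(segments[cow_posterior_ipsi_path] == "absent")

  group <- if (anterior_interrupted && posterior_path_interrupted) {
    5L
  } else if (ant_compromised && post_compromised) {
    4L
  } else if (ant_compromised) {
    2L
  } else if (post_compromised) {
    3L
  } else {
    1L
  }
  multi <- (group == 2L && sum(ant != "normal") > 1L) ||
    (group == 3L && sum(post != "normal") > 1L)
  structure(group, multi_segment = multi)
}

#' Classify every subject of a metadata table
#'
#' @param metadata A tibble as returned by [read_metadata_table()] (segment
#'   columns already expressed relative to the operated side).
#' @return The input with a `cow_group` integer column appended.
#' @export
classify_cow_table <- function(metadata) {
  stopifnot(is.data.frame(metadata))
  groups <- purrr::map_int(seq_len(nrow(metadata)), function(i) {
    as.integer(classify_cow(unlist(metadata[i, cow_segment_names])))
  })
  dplyr::mutate(metadata, cow_group = groups)
}
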