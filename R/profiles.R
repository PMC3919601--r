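#' Define a conformational state profile for the trace simulator
#'
#' A state profile names a ribosome conformational state and the five-level
#' reactivity code each landmark base should exhibit in that state.  The
#' packaged profiles (see [default_state_profiles()]) reproduce the reference
#' reactivity codes of the non-rotated and rotated control complexes and of
#' the rpL10 loop mutants A106R and S104D, plus an interpolated vacant
#' wild-type profile.
#'
#' @param state_name Label for the state.
#' @param landmark_targets Named integer vector, `base_id -> code` (0-4).
#' @param panel Panel the targets must belong to, default [landmark_panel()].
#' @return A list of class `state_profile`.
#' @export
state_profile <- function(state_name, landmark_targets,
                          panel = landmark_panel()) {
  targets <- as.integer(landmark_targets)
  names(targets) <- names(landmark_targets)
  if (length(targets) > 0) {
    if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
      abort("landmark_targets must be a named vector of base_id -> code")
    }
    unknown <- setdiff(names(targets), panel$base_id)
    if (length(unknown) > 0) {
      abort(paste0("targets not in the landmark panel: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(is.na(targets)) || any(targets < 0L | targets > 4L)) {
      abort("landmark codes must be integers in 0..4")
    }
  }
  structure(list(state_name = state_name, landmark_targets = targets),
            class = "state_profile")
}

# Reactivity codes observed for the four characterized complexes at the
# 15 panel bases (non-rotated and rotated controls, A106R and S104D mutants).
state_code_table <- function() {
  tibble::tribble(
    ~base_id, ~non_rotated, ~A106R, ~S104D, ~rotated,
    "A2207", 2L, 2L, 4L, 4L,
    "G913",  1L, 2L, 4L, 4L,
    "U2258", 2L, 2L, 3L, 4L,
    "A2262", 0L, 0L, 1L, 2L,
    "C1644", 1L, 1L, 2L, 2L,
    "G1645", 0L, 0L, 2L, 1L,
    "U2301", 0L, 0L, 1L, 1L,
    "G2302", 0L, 0L, 0L, 0L,
    "A1655", 1L, 2L, 2L, 2L,
    "U1656", 2L, 2L, 2L, 2L,
    "U2860", 1L, 2L, 0L, 0L,
    "U2924", 4L, 2L, 0L, 1L,
    "A2926", 4L, 2L, 1L, 1L,
    "U3023", 1L, 1L, 0L, 0L,
    "A3027", 2L, 3L, 0L, 0L
  )
}

#' The five packaged conformational state profiles
#'
#' Returns the non-rotated control, A106R-like, vacant wild-type,
#' S104D-like and rotated control profiles over the default landmark panel.
#' The four characterized states use the observed reference codes directly.
#' No codes were measured for vacant wild-type ribosomes across the full
#' panel; their reactivities are intermediate between the two end states, so
#' the vacant profile interpolates each base as the rounded midpoint of the
#' non-rotated and rotated codes, with half-integer ties rounded toward the
#' non-rotated code.
#'
#' @param panel Landmark panel, default [landmark_panel()].
#' @return Named list of [state_profile()] objects in continuum order:
#'   `non_rotated`, `A106R`, `vacant`, `S104D`, `rotated`.
#' @export
default_state_profiles <- function(panel = landmark_panel()) {
  tab <- state_code_table()
  as_targets <- function(codes) setNames(codes, tab$base_id)
  # midpoint with ties rounded toward the non-rotated code
  mid <- (tab$non_rotated + tab$rotated) / 2
  vac <- ifelse(tab$rotated >= tab$non_rotated, floor(mid), ceiling(mid))
  list(
    non_rotated = state_profile("non_rotated", as_targets(tab$non_rotated), panel),
    A106R = state_profile("A106R", as_targets(tab$A106R), panel),
    vacant = state_profile("vacant", as_targets(as.integer(vac)), panel),
    S104D = state_profile("S104D", as_targets(tab$S104D), panel),
    rotated = state_profile("rotated", as_targets(tab$rotated), panel)
  )
}

#' Assemble a rotation profile from landmark codes
#'
#' A rotation profile holds, for one sample, the discretized reactivity code
#' at each landmark base of the panel.  Bases not supplied are treated as
#' missing and are excluded (and reported) by downstream scoring.
#'
#' @param sample_name Label for the sample.
#' @param codes Named integer vector `base_id -> code`, or a data frame with
#'   columns `base_id` and `code`.
#' @return A list of class `rotation_profile` with fields `sample_name` and
#'   `codes` (named integer vector).
#' @export
rotation_profile <- function(sample_name, codes) {
  if (is.data.frame(codes)) {
    codes <- setNames(as.integer(codes$code), codes$base_id)
  }
  if (length(codes) == 0 || is.null(names(codes))) {
    abort("codes must be a non-empty named vector or data frame")
  }
  codes <- setNames(as.integer(codes), names(codes))
  ok <- !is.na(codes)
  if (any(codes[ok] < 0L | codes[ok] > 4L)) {
    abort("reactivity codes must lie in 0..4")
  }
  structure(list(sample_name = sample_name, codes = codes),
            class = "rotation_profile")
}

#' Extract landmark codes from discretized traces
#'
#' Joins one or more code traces (output of [discretize()]) against the
#' landmark panel by subunit and position, yielding the rotation profile for
#' the sample.  Panel bases not covered by any trace are marked missing.
#'
#' @param code_traces A code-trace tibble or list of them; each needs
#'   columns `subunit`, `position`, `code`.
#' @param panel Landmark panel.
#' @param sample_name Label for the resulting profile.
#' @return A [rotation_profile()].
#' @export
codes_to_profile <- function(code_traces, panel = landmark_panel(),
                             sample_name = "sample") {
  if (is.data.frame(code_traces)) code_traces <- list(code_traces)
  all_codes <- dplyr::bind_rows(lapply(code_traces, function(ct) {
    if (!all(c("subunit", "position", "code") %in% names(ct))) {
      abort("code traces need columns subunit, position, code")
    }
    ct[, c("subunit", "position", "code")]
  }))
  hit <- dplyr::left_join(
    as_tibble(panel)[, c("base_id", "subunit", "position")],
    all_codes,
    by = c("subunit", "position")
  )
  rotation_profile(sample_name, setNames(hit$code, hit$base_id))
}
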