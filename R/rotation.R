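#' Difference map between two normalized traces
#'
#' Subtracts trace B's normalized reactivities from trace A's, position by
#' position, and bins each difference in standard-deviation steps for
#' coloring secondary-structure diagrams: `bin = sign(delta) * min(4,
#' floor(|delta| / sigma))`.  The SD unit defaults to the pooled sample SD
#' of the two traces; `sigma = "per_trace"` uses trace A's own SD instead.
#'
#' @param traceA,traceB `normalized_trace` tibbles over identical positions.
#' @param sigma `"pooled"` (default) or `"per_trace"`.
#' @return A tibble of class `difference_map` with columns `position`,
#'   `delta`, `bin` and an attribute `sigma` (the SD unit used).
#' @export
difference_map <- function(traceA, traceB, sigma = c("pooled", "per_trace")) {
  sigma <- match.arg(sigma)
  if (nrow(traceA) != nrow(traceB) ||
      !all(traceA$position == traceB$position)) {
    abort("traces must cover identical positions")
  }
  stA <- trace_statistics(traceA)
  stB <- trace_statistics(traceB)
  nA <- nrow(traceA)
  nB <- nrow(traceB)
  s <- switch(sigma,
    pooled = sqrt(((nA - 1) * stA$sd^2 + (nB - 1) * stB$sd^2) / (nA + nB - 2)),
    per_trace = stA$sd
  )
  delta <- traceA$reactivity - traceB$reactivity
  bin <- if (s > 0) {
    as.integer(sign(delta) * pmin(4, floor(abs(delta) / s)))
  } else {
    integer(length(delta))
  }
  out <- tibble(position = traceA$position, delta = delta, bin = bin)
  structure(out, sigma = s,
            class = c("difference_map", class(as_tibble(out))))
}

#' Rotation score: position on the non-rotated/rotated continuum
#'
#' For every informative panel base (non-control, reference codes differing
#' between the end states) the sample's code is mapped to a normalized
#' position `clip((code - ref_nonrotated) / (ref_rotated - ref_nonrotated),
#' 0, 1)`; the score is the mean over available informative bases.  The
#' formula is calibrated so the non-rotated reference column scores exactly
#' 0 and the rotated column exactly 1, and it inverts automatically for
#' bases that are *more* reactive in the non-rotated state (AC gate bases,
#' SRL).  Missing bases are excluded and reported.  The B3 internal control
#' check is run alongside when B3 bases are present.
#'
#' @param profile A [rotation_profile()].
#' @param panel A [landmark_panel()].
#' @return An object of class `rotation_score`: list with `score` (in
#'   `[0, 1]`), `n_informative`, `per_base` (tibble of clipped positions),
#'   `missing` (base ids), `b3_check` and `sample_name`.
#' @export
rotation_score <- function(profile, panel = landmark_panel()) {
  stopifnot(inherits(profile, "rotation_profile"))
  info <- as_tibble(panel)[informative_bases(panel), ]
  code <- profile$codes[info$base_id]
  available <- !is.na(code)
  if (!any(available)) {
    abort("no informative landmark bases available in the profile")
  }
  used <- info[available, ]
  pos <- (as.numeric(code[available]) - used$ref_nonrotated) /
    (used$ref_rotated - used$ref_nonrotated)
  pos <- pmin(pmax(pos, 0), 1)
  per_base <- tibble(base_id = used$base_id, region = used$region,
                     code = as.integer(code[available]),
                     ref_nonrotated = used$ref_nonrotated,
                     ref_rotated = used$ref_rotated, position = pos)
  b3 <- tryCatch(b3_control_check(profile, panel),
                 error = function(e) NULL)
  structure(list(score = mean(pos), n_informative = sum(available),
                 per_base = per_base,
                 missing = info$base_id[!available],
                 b3_check = b3, sample_name = profile$sample_name),
            class = "rotation_score")
}

#' @export
print.rotation_score <- function(x, ...) {
  cat(sprintf("Rotation score for '%s': %.4f (%d informative bases",
              x$sample_name, x$score, x$n_informative))
  if (length(x$missing) > 0) {
    cat(sprintf(", %d missing", length(x$missing)))
  }
  cat(")\n")
  if (!is.null(x$b3_check)) {
    cat(sprintf("B3 internal control: %s (max deviation %d)\n",
                if (x$b3_check$pass) "pass" else "FAIL",
                x$b3_check$max_deviation))
  }
  cat(sprintf("Classification: %s\n", classify_rotation(x)))
  invisible(x)
}

#' B3 internal control check
#'
#' The B3 bridge is the pivot of intersubunit rotation and its bases should
#' not change reactivity between conformational states.  The check passes
#' when every available B3 base deviates from its non-rotated reference code
#' by at most `max_dev` level.
#'
#' @param profile A [rotation_profile()].
#' @param panel A [landmark_panel()].
#' @param max_dev Largest tolerated absolute code deviation (default 1).
#' @return List with `pass`, `max_deviation` and `deviations` (tibble).
#' @export
b3_control_check <- function(profile, panel = landmark_panel(),
                             max_dev = 1L) {
  b3 <- as_tibble(panel)[panel$region == "B3", ]
  code <- profile$codes[b3$base_id]
  available <- !is.na(code)
  if (!any(available)) abort("no B3 control bases available in the profile")
  b3 <- b3[available, ]
  dev <- abs(as.integer(code[available]) - b3$ref_nonrotated)
  list(pass = all(dev <= max_dev),
       max_deviation = max(dev),
       deviations = tibble(base_id = b3$base_id,
                           code = as.integer(code[available]),
                           ref_nonrotated = b3$ref_nonrotated,
                           deviation = dev))
}

#' Classify a rotation score on the continuum
#'
#' @param score A `rotation_score` object or a bare numeric score.
#' @param lower,upper Class boundaries (defaults 1/3 and 2/3).
#' @return `"non-rotated-shifted"`, `"intermediate"` or `"rotated-shifted"`.
#' @export
classify_rotation <- function(score, lower = 1 / 3, upper = 2 / 3) {
  s <- if (inherits(score, "rotation_score")) score$score else score
  dplyr::case_when(
    s < lower ~ "non-rotated-shifted",
    s > upper ~ "rotated-shifted",
    TRUE ~ "intermediate"
  )
}
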