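#' Net reactivity: control-channel subtraction
#'
#' Subtracts the control ((-)reagent) channel from the reagent-treated
#' ((+)reagent) channel position by position and floors the result at zero:
#' a base cannot be negatively reactive, and positions where the control
#' signal exceeds the treated signal are read as unreactive.
#'
#' @param peaks Peak table: a data frame with columns `position`,
#'   `plus_area` and `minus_area` (plus any annotation columns, which are
#'   preserved).  Both channels must cover the same strictly increasing
#'   positions and all areas must be non-negative.
#' @return The input tibble with an added `net` column.
#' @examples
#' peaks <- tibble::tibble(position = 1:2, plus_area = c(5, 3),
#'                         minus_area = c(1, 4))
#' net_reactivity(peaks)$net  # 4, 0
#' @export
net_reactivity <- function(peaks) {
  required <- c("position", "plus_area", "minus_area")
  missing <- setdiff(required, names(peaks))
  if (length(missing) > 0) {
    abort(paste0("peak table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (is.unsorted(peaks$position, strictly = TRUE)) {
    abort("peak table positions must be strictly increasing")
  }
  if (any(is.na(peaks$plus_area)) || any(is.na(peaks$minus_area))) {
    abort("peak areas must not be missing; the two channels must cover identical positions")
  }
  if (any(peaks$plus_area < 0) || any(peaks$minus_area < 0)) {
    abort("peak areas must be non-negative")
  }
  dplyr::mutate(as_tibble(peaks),
                net = pmax(.data$plus_area - .data$minus_area, 0))
}

#' Normalize net reactivities by the region median
#'
#' Divides every net reactivity of a primer region by the median of the
#' region's strictly positive net values, so that the typical reactive base
#' sits at 1.  Zero-floored positions are excluded from the normalizer (they
#' would deflate it) but retained in the trace; set `include_zeros = TRUE`
#' to use the plain median of all values instead.  The per-trace summary
#' statistics that drive discretization (median, mean, sample SD over all
#' positions of the normalized trace) are computed here and attached to the
#' result.
#'
#' @param net Output of [net_reactivity()], or any data frame with columns
#'   `position` and `net` (annotation columns `region_id`, `subunit`,
#'   `nucleotide` are carried through).
#' @param region_id Optional region label overriding any `region_id` column.
#' @param include_zeros Use all values (not just positive ones) for the
#'   normalizing median.
#' @return A tibble of class `normalized_trace` with columns `region_id`,
#'   `subunit` (if present), `position`, `nucleotide` (if present) and
#'   `reactivity`, and an attribute `stats` (list with `median`, `mean`,
#'   `sd`).
#' @export
normalize_by_region_median <- function(net, region_id = NULL,
                                       include_zeros = FALSE) {
  if (!all(c("position", "net") %in% names(net))) {
    abort("input needs columns position and net (run net_reactivity() first)")
  }
  values <- net$net
  pool <- if (include_zeros) values else values[values > 0]
  if (length(pool) == 0 || all(pool == 0)) {
    abort("cannot normalize: all net reactivities are zero")
  }
  normalizer <- median(pool)
  reactivity <- values / normalizer
  keep <- intersect(c("region_id", "subunit", "position", "nucleotide"),
                    names(net))
  out <- as_tibble(net)[, keep]
  out$region_id <- region_id %||% col_or(net, "region_id", "region")
  out$reactivity <- reactivity
  out <- out[, c("region_id", setdiff(keep, "region_id"), "reactivity")]
  new_normalized_trace(out)
}

new_normalized_trace <- function(df) {
  stats <- trace_stats(df$reactivity)
  structure(df, stats = stats,
            class = c("normalized_trace", class(as_tibble(df))))
}

# median / mean / sample SD over all positions of one trace
trace_stats <- function(v) {
  list(median = median(v), mean = mean(v),
       sd = if (length(v) >= 2) sd(v) else 0)
}

#' Per-trace summary statistics of a normalized trace
#' @param trace A `normalized_trace`.
#' @return List with `median`, `mean`, `sd` (sample SD, n-1).
#' @export
trace_statistics <- function(trace) {
  st <- attr(trace, "stats")
  if (is.null(st)) abort("trace has no statistics; not a normalized_trace?")
  st
}

#' Five-level discretization of a normalized trace
#'
#' Assigns each position a reactivity code from the trace's own summary
#' statistics: 0 below the trace median, 1 between the median and the mean,
#' 2 between the mean and one standard deviation above it, 3 between one and
#' two standard deviations above the mean, and 4 beyond that.  Bins are
#' lower-inclusive (a value exactly on a threshold takes the higher code).
#' If the trace is not right-skewed the thresholds can invert (mean below
#' median) or degenerate (SD = 0); the affected bins then collapse into the
#' lower code and a warning is issued, so a constant trace codes uniformly
#' as 1.
#'
#' @param trace A `normalized_trace` from [normalize_by_region_median()].
#' @return A tibble of class `code_trace` with columns `region_id`,
#'   `subunit` (if present), `position`, `code`, plus attribute `thresholds`.
#' @examples
#' net <- tibble::tibble(position = 1:6,
#'                       net = c(0.1, 0.2, 0.3, 0.4, 1.0, 2.5))
#' tr <- normalize_by_region_median(net, "demo")
#' discretize(tr)$code  # 0 0 0 1 2 3
#' @export
discretize <- function(trace) {
  st <- attr(trace, "stats")
  if (is.null(st)) {
    abort("trace statistics are missing; run normalize_by_region_median() first")
  }
  if (nrow(trace) < 2) abort("trace must have at least 2 positions")
  thresholds <- c(st$median, st$mean, st$mean + st$sd, st$mean + 2 * st$sd)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    warn("discretization thresholds are not strictly increasing; degenerate bins collapse into the lower code")
  }
  codes <- discretize_values(trace$reactivity, st)
  keep <- intersect(c("region_id", "subunit", "position"), names(trace))
  out <- as_tibble(trace)[, keep]
  out$code <- codes
  structure(out, thresholds = thresholds, stats = st,
            class = c("code_trace", class(as_tibble(out))))
}

# Core binning rule, shared with the simulator's placement/verification.
# Lower-inclusive bins; tied or inverted thresholds count once, so
# degenerate bins collapse into the lower code.
discretize_values <- function(v, st) {
  thr <- c(st$median, st$mean, st$mean + st$sd, st$mean + 2 * st$sd)
  eff <- cummax(thr)
  counts <- c(TRUE, diff(eff) > 0) # only strictly increasing steps bin
  codes <- integer(length(v))
  for (k in seq_along(eff)) {
    if (counts[k]) codes <- codes + (v >= eff[k])
  }
  codes
}
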