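col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

provenance_header <- function(seed = NULL, extra = NULL) {
  version <- as.character(utils::packageVersion("riborotate"))
  parts <- c(paste0("riborotate ", version),
             if (!is.null(seed)) paste0("seed=", seed),
             extra)
  paste0("# ", paste(parts, collapse = "; "))
}

#' Write / read a peak table as TSV
#'
#' Columns `position`, `nucleotide`, `plus_area`, `minus_area`; region and
#' subunit are preserved in `#`-prefixed header comments along with
#' provenance (package version and, when known, the generating seed).
#' Reactivities and areas are serialized to 6 significant digits.
#'
#' @param peaks A `peak_table` tibble.
#' @param path Output file.
#' @return `path`, invisibly (write); a `peak_table` tibble (read).
#' @export
write_peak_table <- function(peaks, path) {
  region_id <- col_or(peaks, "region_id", "region")[1]
  subunit <- col_or(peaks, "subunit", NA_character_)[1]
  header <- c(provenance_header(seed = attr(peaks, "seed")),
              paste0("# region_id=", region_id, "; subunit=", subunit))
  body <- sprintf("%d\t%s\t%.6g\t%.6g", peaks$position, peaks$nucleotide,
                  peaks$plus_area, peaks$minus_area)
  writeLines(c(header, "position\tnucleotide\tplus_area\tminus_area", body),
             path)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  region_id <- sub(".*region_id=([^;]+).*", "\\1", meta[grepl("region_id=", meta)][1])
  subunit <- sub(".*subunit=([^;]+).*", "\\1", meta[grepl("subunit=", meta)][1])
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(
                          position = readr::col_integer(),
                          nucleotide = readr::col_character(),
                          plus_area = readr::col_double(),
                          minus_area = readr::col_double()
                        ), progress = FALSE)
  if (nrow(df) == 0) abort(paste0("empty peak table: ", path))
  out <- tibble(region_id = if (is.na(region_id)) "region" else region_id,
                subunit = if (is.na(subunit)) NA_character_ else subunit,
                position = df$position, nucleotide = df$nucleotide,
                plus_area = df$plus_area, minus_area = df$minus_area)
  structure(out, class = c("peak_table", class(as_tibble(out))))
}

#' Write / read a normalized trace in SHAPE ".map" layout
#'
#' Four whitespace-separated columns with no header: position, reactivity,
#' standard error and nucleotide, with `-999` as the missing-value sentinel
#' in the reactivity and stderr fields.  Positions carrying the sentinel are
#' flagged missing on read and excluded from the per-trace statistics.
#' Values round-trip at 6 significant digits.
#'
#' @param trace A `normalized_trace`; an optional `stderr` column is
#'   serialized, otherwise the sentinel is written.
#' @param path File path.
#' @param region_id Region label for the trace read back.
#' @return `path`, invisibly (write); a `normalized_trace` (read) whose
#'   `missing` column marks sentinel positions.
#' @export
write_map <- function(trace, path) {
  reactivity <- trace$reactivity
  missing <- is.na(reactivity)
  if ("missing" %in% names(trace)) missing <- missing | trace$missing
  reactivity[missing] <- -999
  stderr_col <- col_or(trace, "stderr", rep(-999, nrow(trace)))
  stderr_col[is.na(stderr_col)] <- -999
  nt <- col_or(trace, "nucleotide", rep("N", nrow(trace)))
  writeLines(sprintf("%d\t%.6g\t%.6g\t%s", trace$position, reactivity,
                     stderr_col, nt), path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path, region_id = "region") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty map file: ", path))
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) < 3) {
      abort(sprintf("malformed map line %d in %s: expected at least 3 fields",
                    i, path))
    }
    pos <- suppressWarnings(as.integer(fields[1]))
    react <- suppressWarnings(as.numeric(fields[2]))
    err <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(pos) || is.na(react) || is.na(err)) {
      abort(sprintf("malformed map line %d in %s: non-numeric field", i, path))
    }
    list(position = pos, reactivity = react, stderr = err,
         nucleotide = if (length(fields) >= 4) fields[4] else "N")
  })
  df <- dplyr::bind_rows(parsed)
  df$missing <- df$reactivity <= -999
  df$reactivity[df$missing] <- NA_real_
  df$stderr[df$stderr <= -999] <- NA_real_
  out <- tibble(region_id = region_id, position = df$position,
                nucleotide = df$nucleotide, reactivity = df$reactivity,
                stderr = df$stderr, missing = df$missing)
  stats <- trace_stats(out$reactivity[!out$missing])
  structure(out, stats = stats,
            class = c("normalized_trace", class(as_tibble(out))))
}

#' Write a code trace as TSV
#' @param codes A `code_trace` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_code_trace <- function(codes, path) {
  if ("subunit" %in% names(codes)) {
    body <- sprintf("%d\t%d\t%s", codes$position, codes$code, codes$subunit)
    header <- "position\tcode\tsubunit"
  } else {
    body <- sprintf("%d\t%d", codes$position, codes$code)
    header <- "position\tcode"
  }
  writeLines(c(provenance_header(), header, body), path)
  invisible(path)
}

#' Read a typed assay CSV
#'
#' Schema-checked reader for the package's flat assay files.  Schemas:
#' `binding` (`dose_pmol`, `replicate`, `signal`, optional `background`;
#' doses strictly positive), `competition` (same columns, zero dose
#' allowed for the no-competitor control), `kinetics` (`time_min`,
#' `replicate`, `product`) and `luciferase` (`strain`, `reporter`,
#' `replicate`, `firefly`, `renilla`).  Rows come back sorted by the dose
#' or time axis; missing columns, negative doses and duplicate
#' (dose, replicate) keys are errors naming the offender.
#'
#' @param path CSV file with a header row.
#' @param schema One of `"binding"`, `"competition"`, `"kinetics"`,
#'   `"luciferase"`.
#' @return A tibble typed for the downstream fit function.
#' @export
read_assay_csv <- function(path, schema = c("binding", "competition",
                                            "kinetics", "luciferase")) {
  schema <- match.arg(schema)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- switch(schema,
    binding = c("dose_pmol", "replicate", "signal"),
    competition = c("dose_pmol", "replicate", "signal"),
    kinetics = c("time_min", "replicate", "product"),
    luciferase = c("strain", "reporter", "replicate", "firefly", "renilla")
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(schema, " CSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (schema %in% c("binding", "competition")) {
    if (any(df$dose_pmol < 0)) abort("doses must not be negative")
    if (schema == "binding" && any(df$dose_pmol == 0)) {
      abort("binding doses must be strictly positive (zero dose is allowed only in the competition schema)")
    }
    key <- paste(df$dose_pmol, df$replicate)
    if (anyDuplicated(key) > 0) {
      abort("duplicate (dose_pmol, replicate) keys in assay CSV")
    }
    df <- dplyr::arrange(df, .data$dose_pmol, .data$replicate)
    if (schema == "binding") {
      class(df) <- c("binding_assay", class(df))
    }
  } else if (schema == "kinetics") {
    if (any(df$time_min < 0)) abort("timepoints must be non-negative")
    df <- dplyr::arrange(df, .data$time_min, .data$replicate)
    class(df) <- c("time_course", class(df))
  } else {
    if (any(df$renilla <= 0)) abort("renilla readings must be positive")
  }
  df
}

#' Read / write a pipeline run configuration (YAML)
#'
#' Configurations round-trip losslessly; [config_hash()] gives a stable
#' digest recorded in output provenance headers so a result can be traced
#' to the exact configuration that produced it.
#'
#' @param config Named list of run parameters.
#' @param path YAML file.
#' @return The configuration list (read); `path` invisibly (write).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname write_run_config
#' @export
config_hash <- function(config) {
  rlang::hash(config)
}
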