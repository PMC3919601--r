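#' The default intersubunit-bridge landmark panel
#'
#' Fifteen rRNA bases in the intersubunit bridges B7a, B2a and B3, the
#' aa-tRNA accommodation corridor (AC) and the sarcin-ricin loop (SRL) whose
#' chemical reactivities discriminate the non-rotated from the rotated
#' conformation of the yeast 80S ribosome.  Each entry carries the yeast
#' rRNA position (18S or 25S numbering), the *E. coli* equivalent base where
#' one is annotated, and the five-level reactivity codes observed in the
#' non-rotated and rotated reference complexes.  B3 bases are flagged as
#' controls: the B3 bridge is the pivot of rotation and is not expected to
#' change, so those bases are used only for the internal control check and
#' never contribute to the rotation score.
#'
#' @return A tibble of class `landmark_panel` with columns `base_id`,
#'   `subunit` (`"18S"` or `"25S"`), `position` (1-based rRNA numbering),
#'   `ecoli_equiv`, `region` (B7a/B2a/B3/AC/SRL), `ref_nonrotated`,
#'   `ref_rotated` (integer codes 0-4) and `is_control`.
#' @examples
#' panel <- landmark_panel()
#' sum(informative_bases(panel))  # 11 bases carry rotational information
#' @export
landmark_panel <- function() {
  path <- system.file("extdata", "landmark_panel.csv", package = "riborotate",
                      mustWork = TRUE)
  panel <- readr::read_csv(
    path,
    col_types = readr::cols(
      base_id = readr::col_character(),
      subunit = readr::col_character(),
      position = readr::col_integer(),
      ecoli_equiv = readr::col_character(),
      region = readr::col_character(),
      ref_nonrotated = readr::col_integer(),
      ref_rotated = readr::col_integer(),
      is_control = readr::col_logical()
    ),
    na = "NA", progress = FALSE
  )
  validate_panel(panel)
  class(panel) <- c("landmark_panel", class(panel))
  panel
}

validate_panel <- function(panel) {
  required <- c("base_id", "subunit", "position", "region",
                "ref_nonrotated", "ref_rotated", "is_control")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("landmark panel is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  codes <- c(panel$ref_nonrotated, panel$ref_rotated)
  if (any(is.na(codes)) || any(codes < 0L | codes > 4L)) {
    abort("panel reference codes must be integers in 0..4")
  }
  if (anyDuplicated(panel$base_id) > 0) {
    abort("panel base_id values must be unique")
  }
  if (!all(panel$subunit %in% c("18S", "25S"))) {
    abort("panel subunit must be '18S' or '25S'")
  }
  invisible(panel)
}

#' Which panel bases are informative for the rotation score?
#'
#' A base is informative when it is not a B3 control and its reference codes
#' differ between the two conformational end states; bases whose codes are
#' identical in both states carry no information about rotation.
#'
#' @param panel A [landmark_panel()] tibble.
#' @return Logical vector along the panel rows.
#' @export
informative_bases <- function(panel) {
  !panel$is_control & panel$ref_rotated != panel$ref_nonrotated
}
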