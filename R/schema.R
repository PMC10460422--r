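#' Adult age bands of the burden summation domain
#'
#' The attributable-burden sum runs over fifteen five-year adult age bands:
#' 25--30, 30--35, ..., 90--95, and an open-ended >95 band. Younger ages are
#' excluded from the summation domain.
#'
#' @return Character vector of 15 age-band labels, ordered young to old.
#' @export
#' @examples
#' age_bands()
age_bands <- function() {
  lower <- seq(25L, 90L, by = 5L)
  c(paste0(lower, "-", lower + 5L), ">95")
}

#' Age bands counted as older adults (65 years and over)
#'
#' @return Character vector of the 7 bands with lower bound >= 65.
#' @export
older_bands <- function() {
  bands <- age_bands()
  bands[seq(which(bands == "65-70"), length(bands))]
}

#' The three-level cause-of-death hierarchy
#'
#' Level 1 is all-cause mortality; level 2 splits it into non-communicable
#' diseases (NCD), communicable/maternal/neonatal/nutritional diseases
#' (CMNND) and injuries; level 3 holds the six PM2.5-related causes plus
#' explicit remainder ("rest") causes so that children always sum to less
#' than their parent and envelope constraining is well defined.
#'
#' @return A data frame with columns `cause`, `level` (1--3) and `parent`
#'   (NA for the level-1 cause).
#' @export
#' @examples
#' cause_hierarchy()
cause_hierarchy <- function() {
  data.frame(
    cause = c(
      "all",
      "NCD", "CMNND", "injuries",
      "COPD", "lung_cancer", "IHD", "stroke", "diabetes_t2", "rest_NCD",
      "LRI", "rest_CMNND"
    ),
    level = c(1L, 2L, 2L, 2L, rep(3L, 6L), 3L, 3L),
    parent = c(
      NA, "all", "all", "all",
      rep("NCD", 6L), "CMNND", "CMNND"
    ),
    stringsAsFactors = FALSE
  )
}

#' The six causes of death linked to PM2.5 exposure
#'
#' Chronic obstructive pulmonary disease, lower respiratory infection, lung
#' cancer, ischaemic heart disease, stroke and type 2 diabetes.
#'
#' @return Character vector of six cause labels.
#' @export
pm25_causes <- function() {
  c("COPD", "LRI", "lung_cancer", "IHD", "stroke", "diabetes_t2")
}

#' Percent change between two values
#'
#' @param from,to scalars (or equal-length vectors); `from` must be nonzero.
#' @return `(to - from) / from * 100`.
#' @export
#' @examples
#' percent_change(28.1, 40.4)
percent_change <- function(from, to) {
  if (any(from == 0)) stop_invalid("`from` must be nonzero for a percent change")
  (to - from) / from * 100
}
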