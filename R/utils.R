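# Shared small helpers.

#' Normalize a drug or event-term label
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and case-folds to lower case. No dictionary mapping is
#' applied; two labels match if and only if they normalize identically.
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @examples
#' normalize_label(c("  Pulmonary   Embolism ", "BEVACIZUMAB"))
#' @export
normalize_label <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  tolower(x)
}

#' Round half away from zero
#'
#' Display rounding used for rates, percentages, RORs and confidence bounds:
#' ties round away from zero (so 0.125 -> 0.13 at 2 digits), matching the
#' convention of the tabulated results rather than banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
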