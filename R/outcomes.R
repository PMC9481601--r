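# Post-event outcome tabulation and fatality rates.

#' Tabulate outcomes for one event term
#'
#' Counts reports in each of the six outcome categories. Records with no
#' stated outcome are excluded from the denominator `n_reported` but counted
#' separately ("unclear" is a stated category and stays in the denominator;
#' missing does not). The fatality percentage is deaths over `n_reported`,
#' to one decimal; it is `NA` when no outcome was stated.
#'
#' @param rows analysis rows sharing one event term.
#' @return list with `pt`, named integer vector `counts` (six categories),
#'   `n_reported`, `n_missing`, `fatality_pct`.
#' @export
tabulate_outcomes <- function(rows) {
  counts <- vapply(outcome_levels,
                   function(l) sum(!is.na(rows$outcome) & rows$outcome == l),
                   integer(1))
  n_reported <- sum(counts)
  list(pt = if (nrow(rows)) rows$pt[1] else NA_character_,
       counts = counts,
       n_reported = n_reported,
       n_missing = sum(is.na(rows$outcome)),
       fatality_pct = if (n_reported > 0) {
         round_half_up(counts[["death"]] / n_reported * 100, 1)
       } else NA_real_)
}

#' Outcome percentage table across terms
#'
#' One row per term, in the order given (typically the descending-case order
#' of a signal screen): raw category counts, the stated-outcome denominator,
#' percentage columns (of stated outcomes, one decimal, summing to 100
#' within rounding slack) and the fatality percentage.
#'
#' @param table the data table (or a drug subset of it).
#' @param terms character vector of event terms defining rows and order.
#' @return data.frame with count columns `n_<category>`, `n_reported`,
#'   `n_missing`, percentage columns `pct_<category>`, and `fatality_pct`.
#' @export
outcome_report <- function(table, terms) {
  terms <- normalize_label(terms)
  rows <- lapply(terms, function(pt) {
    s <- tabulate_outcomes(table[table$pt == pt, , drop = FALSE])
    cnt <- as.list(s$counts)
    names(cnt) <- paste0("n_", outcome_levels)
    pct <- if (s$n_reported > 0) {
      round_half_up(s$counts / s$n_reported * 100, 1)
    } else rep(NA_real_, length(outcome_levels))
    pct <- as.list(pct)
    names(pct) <- paste0("pct_", outcome_levels)
    data.frame(pt = pt, cnt, n_reported = s$n_reported,
               n_missing = s$n_missing, pct,
               fatality_pct = s$fatality_pct)
  })
  if (!length(rows)) {
    empty <- as.data.frame(stats::setNames(
      rep(list(integer()), length(outcome_levels)),
      paste0("n_", outcome_levels)))
    empty_pct <- as.data.frame(stats::setNames(
      rep(list(numeric()), length(outcome_levels)),
      paste0("pct_", outcome_levels)))
    return(cbind(data.frame(pt = character()), empty,
                 data.frame(n_reported = integer(), n_missing = integer()),
                 empty_pct, data.frame(fatality_pct = numeric())))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
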