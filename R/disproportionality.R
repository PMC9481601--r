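# Reporting odds ratio machinery: 2x2 tables, Woolf intervals, Fisher tests,
# and the screening loop that produces one signal row per event term.
#
# In a spontaneous-report database the denominator is reports, not exposed
# patients, so the disproportionality contrast is between the event's share
# of the target drug's reports and its share of all other drugs' reports:
#
#              event    other events
#   target       a          b
#   others       c          d
#
#   ROR = (a/b) / (c/d) = ad / (bc)
#
# A term is flagged as a signal when it has at least `min_cases` reports and
# the lower Woolf 95% confidence bound of the ROR exceeds 1.

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Partitions the full data table four ways on (drug match, term match).
#' Counts are of unique (case, drug, term) reports, the data-table counting
#' unit. A drug absent from the table yields a zero target margin
#' (`a = b = 0`), returned rather than raised.
#'
#' @param table the full suspected-drug data table (all drugs).
#' @param drug target drug name.
#' @param pt target event preferred term.
#' @return named integer vector `c(a, b, c, d)`; `a + b + c + d == nrow(table)`.
#' @export
contingency <- function(table, drug, pt) {
  is_drug <- table$drug == normalize_label(drug)
  is_pt <- table$pt == normalize_label(pt)
  c(a = sum(is_drug & is_pt), b = sum(is_drug & !is_pt),
    c = sum(!is_drug & is_pt), d = sum(!is_drug & !is_pt))
}

check_cells <- function(ct, correction) {
  ct <- as.numeric(ct[c("a", "b", "c", "d")])
  if (any(is.na(ct)) || any(ct < 0)) {
    stop("contingency cells must be non-negative counts", call. = FALSE)
  }
  if (any(ct == 0)) {
    if (correction) return(ct + 0.5)
    zero <- c("a", "b", "c", "d")[ct == 0]
    stop("zero cell(s) ", paste(zero, collapse = ", "),
         " make the ROR undefined; enable the continuity correction",
         call. = FALSE)
  }
  ct
}

#' Reporting odds ratio
#'
#' @param ct named vector `c(a, b, c, d)` as from [contingency()].
#' @param correction apply the Haldane-Anscombe +0.5 continuity correction to
#'   all four cells when any cell is zero (off by default; with a zero cell
#'   and no correction an error names the offending cell).
#' @return the ROR `ad/(bc)`.
#' @export
ror <- function(ct, correction = FALSE) {
  ct <- check_cells(ct, correction)
  (ct[1] * ct[4]) / (ct[2] * ct[3])
}

#' Woolf confidence interval for the ROR
#'
#' The log-normal (Woolf) interval, the standard pharmacovigilance choice:
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @inheritParams ror
#' @param level confidence level (default 0.95, z = 1.959964).
#' @return named numeric `c(low, high)`; always contains the point estimate.
#' @export
ror_ci <- function(ct, level = 0.95, correction = FALSE) {
  ct <- check_cells(ct, correction)
  est <- (ct[1] * ct[4]) / (ct[2] * ct[3])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / ct))
  c(low = est * exp(-z * se), high = est * exp(z * se))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The classical probability-mass rule: with margins fixed, the p-value sums
#' the hypergeometric probabilities of every table no more probable than the
#' observed one (as implemented by [stats::fisher.test()]).
#'
#' @param ct named integer vector `c(a, b, c, d)`.
#' @return p-value in (0, 1].
#' @export
fisher_p <- function(ct) {
  m <- matrix(as.integer(ct[c("a", "b", "c", "d")]), nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Screen event terms for disproportionality signals
#'
#' For every term with at least `min_cases` target-drug reports, computes the
#' report count, reporting rate, ROR with Woolf interval, Fisher's exact
#' p-value and the signal flag (`cases >= min_cases` and lower bound > 1,
#' strictly). Terms with a zero cell get `NA` ROR and interval unless the
#' continuity correction is enabled, in which case the +0.5-corrected values
#' are reported with `corrected = TRUE`; p-values always come from the
#' uncorrected integer table.
#'
#' @param table the full data table (all drugs).
#' @param drug target drug name.
#' @param terms event-term set (character vector).
#' @param min_cases minimum target-drug report count for inclusion
#'   (default 5, inclusive).
#' @param level confidence level for the Woolf interval.
#' @param correction zero-cell continuity correction (default off).
#' @return a `ror_screen` data.frame sorted by descending case count, with
#'   columns `pt, cases, noncases, rate_pct` (rounded to 2 decimals),
#'   `ror, ci_low, ci_high, p_value` (full precision), `signal, corrected`.
#' @export
ror_screen <- function(table, drug, terms, min_cases = 5, level = 0.95,
                       correction = FALSE) {
  stopifnot(min_cases >= 1)
  terms <- normalize_label(terms)
  rows <- lapply(terms, function(pt) {
    ct <- contingency(table, drug, pt)
    if (ct["a"] < min_cases) return(NULL)
    est <- ci <- NULL
    corrected <- FALSE
    if (all(ct > 0)) {
      est <- ror(ct)
      ci <- ror_ci(ct, level = level)
    } else if (correction) {
      est <- ror(ct, correction = TRUE)
      ci <- ror_ci(ct, level = level, correction = TRUE)
      corrected <- TRUE
    } else {
      est <- NA_real_
      ci <- c(low = NA_real_, high = NA_real_)
    }
    data.frame(
      pt = pt,
      cases = as.integer(ct["a"]),
      noncases = as.integer(ct["b"]),
      rate_pct = round_half_up(ct[["a"]] / (ct[["a"]] + ct[["b"]]) * 100, 2),
      ror = unname(est),
      ci_low = unname(ci["low"]),
      ci_high = unname(ci["high"]),
      p_value = fisher_p(ct),
      signal = isTRUE(unname(ci["low"]) > 1),
      corrected = corrected
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) {
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    out <- data.frame(pt = character(), cases = integer(), noncases = integer(),
                      rate_pct = numeric(), ror = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p_value = numeric(),
                      signal = logical(), corrected = logical())
  }
  out <- out[order(-out$cases), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drug") <- normalize_label(drug)
  attr(out, "n_total") <- nrow(table)
  attr(out, "min_cases") <- min_cases
  attr(out, "level") <- level
  class(out) <- c("ror_screen", "data.frame")
  out
}

#' @export
print.ror_screen <- function(x, digits = 2, ...) {
  cat(sprintf("Disproportionality screen: drug = %s, %d term(s) with >= %d cases (data table: %d reports)\n\n",
              attr(x, "drug"), nrow(x), attr(x, "min_cases"),
              attr(x, "n_total")))
  disp <- data.frame(
    pt = x$pt, cases = x$cases, noncases = x$noncases,
    `rate%` = x$rate_pct,
    ROR = round_half_up(x$ror, digits),
    `95%CI` = sprintf("%s-%s", round_half_up(x$ci_low, digits),
                      round_half_up(x$ci_high, digits)),
    p = signif(x$p_value, 3),
    signal = ifelse(x$signal, "*", ""),
    check.names = FALSE
  )
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Write a screen as a results CSV
#'
#' Full-precision columns plus display-rounded companions (`ror_2dp`,
#' `ci_low_2dp`, `ci_high_2dp`), mirroring a tabulated signal report.
#'
#' @param screen a `ror_screen` object.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(screen, path) {
  out <- as.data.frame(screen)
  out$ror_2dp <- round_half_up(out$ror, 2)
  out$ci_low_2dp <- round_half_up(out$ci_low, 2)
  out$ci_high_2dp <- round_half_up(out$ci_high, 2)
  write_table(out, path)
}
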