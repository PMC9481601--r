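# Onset-day computation: partial-date resolution, dosing-episode
# reconstruction with the one-year gap rule, the +0.5 day convention, and
# the 730-day analysis horizon.

#' Reconstruct continuous dosing episodes for one case and drug
#'
#' Drug records are resolved to calendar dates ([resolve_date()]; records
#' with unresolvable start dates are skipped and counted), sorted by start,
#' and merged into continuous administration episodes. A gap of more than
#' `gap` days (default 365) between one record's end (its start, if no end is
#' recorded) and the next record's start opens a new episode: re-challenge
#' after a year or more off drug restarts the onset clock.
#'
#' @param drug_records data.frame of DRUG rows sharing one case and drug
#'   (columns `start_date`, `end_date` as partial-date strings).
#' @param gap maximum within-episode gap in days.
#' @param month_day day used to resolve year/month dates.
#' @return data.frame with `Date` columns `start`, `end`, one row per
#'   episode, ordered by start; attribute `n_skipped` counts records dropped
#'   for missing start dates.
#' @export
episodes <- function(drug_records, gap = 365, month_day = 1L) {
  start <- resolve_date(drug_records$start_date, month_day = month_day)
  end <- resolve_date(drug_records$end_date, month_day = month_day)
  keep <- !is.na(start)
  n_skipped <- sum(!keep)
  start <- start[keep]
  end <- end[keep]
  end[is.na(end) | end < start] <- start[is.na(end) | end < start]
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ep_start <- ep_end <- as.Date(character())
  for (i in seq_along(start)) {
    if (length(ep_end) &&
        as.numeric(start[i] - ep_end[length(ep_end)]) <= gap) {
      ep_end[length(ep_end)] <- max(ep_end[length(ep_end)], end[i])
    } else {
      ep_start <- c(ep_start, start[i])
      ep_end <- c(ep_end, end[i])
    }
  }
  out <- data.frame(start = ep_start, end = ep_end)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Time to onset for one report
#'
#' The onset clock starts at the first administration of the most recent
#' continuous dosing episode beginning on or before the onset date, and
#' `days = (onset - start) + 0.5` — the half-day convention places an event
#' on the first administration day at 0.5 days. Reports are rejected (with a
#' reason, never an error) when the onset precedes every episode, no episode
#' exists, or the time exceeds the analysis horizon (default 730 days, two
#' years).
#'
#' @param onset_date a `Date` (or partial-date string, resolved with the
#'   default policy).
#' @param eps episode table from [episodes()].
#' @param horizon maximum onset time retained, in days.
#' @return list with `days` (numeric or NA) and `status` (one of `"ok"`,
#'   `"missing_onset"`, `"no_episode"`, `"before_start"`,
#'   `"beyond_horizon"`).
#' @export
onset_days <- function(onset_date, eps, horizon = 730) {
  if (!inherits(onset_date, "Date")) onset_date <- resolve_date(onset_date)
  if (length(onset_date) != 1 || is.na(onset_date)) {
    return(list(days = NA_real_, status = "missing_onset"))
  }
  if (nrow(eps) == 0) return(list(days = NA_real_, status = "no_episode"))
  ok <- eps$start <= onset_date
  if (!any(ok)) return(list(days = NA_real_, status = "before_start"))
  start <- max(eps$start[ok])
  days <- as.numeric(onset_date - start) + 0.5
  if (days > horizon) return(list(days = NA_real_, status = "beyond_horizon"))
  list(days = days, status = "ok")
}

#' Onset-day samples for one drug-event pair
#'
#' Walks every analysis row for the pair, reconstructs the case's dosing
#' episodes from the (deduplicated) DRUG table, and applies [onset_days()].
#' Rejections are tallied, not raised.
#'
#' @param table the suspected-drug data table.
#' @param drug_table the deduplicated DRUG table (all records, used for
#'   episode reconstruction).
#' @param drug,pt target drug and event term.
#' @param horizon,gap,month_day dating-rule knobs (see [onset_days()],
#'   [episodes()]).
#' @return numeric vector of onset days, with attribute `rejected`: a named
#'   integer vector of counts by rejection status.
#' @export
tto_samples <- function(table, drug_table, drug, pt, horizon = 730,
                        gap = 365, month_day = 1L) {
  drug <- normalize_label(drug)
  pt <- normalize_label(pt)
  rows <- table[table$drug == drug & table$pt == pt, , drop = FALSE]
  dr <- drug_table[drug_table$drug == drug, , drop = FALSE]
  statuses <- c("missing_onset", "no_episode", "before_start",
                "beyond_horizon")
  rejected <- stats::setNames(integer(length(statuses)), statuses)
  days <- numeric(0)
  for (case in unique(rows$case_id)) {
    eps <- episodes(dr[dr$case_id == case, , drop = FALSE], gap = gap,
                    month_day = month_day)
    for (i in which(rows$case_id == case)) {
      res <- onset_days(resolve_date(rows$onset_date[i],
                                     month_day = month_day),
                        eps, horizon = horizon)
      if (res$status == "ok") {
        days <- c(days, res$days)
      } else {
        rejected[res$status] <- rejected[res$status] + 1L
      }
    }
  }
  attr(days, "rejected") <- rejected
  days
}

#' Histogram of onset days
#'
#' Left-closed bins of fixed width starting at 0; the final bin is closed on
#' the right so a sample exactly at the horizon is counted.
#'
#' @param days onset samples in `(0, horizon]`.
#' @param bin_width bin width in days (default 30).
#' @param horizon upper limit defining the last bin edge.
#' @return data.frame with columns `lower`, `upper`, `count`; counts sum to
#'   `length(days)`.
#' @export
onset_histogram <- function(days, bin_width = 30, horizon = 730) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("bin_width must be a positive number", call. = FALSE)
  }
  upper_edge <- ceiling(max(c(days, horizon)) / bin_width) * bin_width
  breaks <- seq(0, upper_edge, by = bin_width)
  idx <- pmin(findInterval(days, breaks, left.open = FALSE),
              length(breaks) - 1L)
  count <- vapply(seq_len(length(breaks) - 1L),
                  function(i) sum(idx == i), integer(1))
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             count = count)
}

#' Fit time-to-onset models for a set of terms
#'
#' Produces the per-term summary table: sample count, median and quartiles,
#' Weibull scale and shape with 95% intervals, and the failure-type
#' classification. Terms with no usable onset sample are reported with
#' `n = 0` and all estimates missing.
#'
#' @inheritParams tto_samples
#' @param terms character vector of event terms.
#' @return list with `fits` (named list of [weibull_tto()] objects or NULL)
#'   and `table` (the summary data.frame).
#' @export
tto_by_term <- function(table, drug_table, drug, terms, horizon = 730,
                        gap = 365, month_day = 1L) {
  terms <- normalize_label(terms)
  fits <- stats::setNames(vector("list", length(terms)), terms)
  rows <- lapply(terms, function(pt) {
    days <- tto_samples(table, drug_table, drug, pt, horizon = horizon,
                        gap = gap, month_day = month_day)
    if (length(days) == 0) {
      return(data.frame(pt = pt, n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, alpha = NA_real_, alpha_low = NA_real_,
                        alpha_high = NA_real_, beta = NA_real_,
                        beta_low = NA_real_, beta_high = NA_real_,
                        failure_type = "indeterminate"))
    }
    fit <- suppressWarnings(weibull_tto(days))
    fits[[pt]] <<- fit
    data.frame(pt = pt, n = fit$n, median = fit$median, q1 = fit$q1,
               q3 = fit$q3, alpha = fit$coefficients[["alpha"]],
               alpha_low = fit$alpha_ci[1], alpha_high = fit$alpha_ci[2],
               beta = fit$coefficients[["beta"]], beta_low = fit$beta_ci[1],
               beta_high = fit$beta_ci[2], failure_type = fit$failure_type)
  })
  if (length(rows)) {
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    out <- data.frame(pt = character(), n = integer(), median = numeric(),
                      q1 = numeric(), q3 = numeric(), alpha = numeric(),
                      alpha_low = numeric(), alpha_high = numeric(),
                      beta = numeric(), beta_low = numeric(),
                      beta_high = numeric(), failure_type = character())
  }
  list(fits = fits, table = out)
}
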