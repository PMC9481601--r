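# Building the suspected-drug analysis table and its subsets.

#' Default lung-toxicity event-term set
#'
#' The 29 MedDRA-style preferred terms used as the default lung-toxicity
#' definition. The set is shipped as a plain one-term-per-line text file and
#' can be replaced wholesale with [read_terms()]; no SMQ hierarchy expansion
#' is performed.
#'
#' @return character vector of 29 normalized preferred terms.
#' @export
lung_terms <- function() {
  read_terms(system.file("extdata", "lung_toxicity_terms.txt",
                         package = "pvlung", mustWork = TRUE))
}

#' Read an event-term set from a text file
#'
#' One term per line, UTF-8; blank lines ignored; terms normalized and
#' deduplicated preserving order.
#'
#' @param path text file path.
#' @return character vector of normalized terms.
#' @export
read_terms <- function(path) {
  if (!file.exists(path)) stop("term file does not exist: ", path, call. = FALSE)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- normalize_label(x)
  x <- x[nzchar(x)]
  if (!length(x)) stop("term file contains no terms: ", path, call. = FALSE)
  unique(x)
}

#' Restrict merged rows to suspected-drug involvement
#'
#' Only reports in which the reporter judged the drug causal ("suspected
#' drug" involvement) enter the analysis data table; concomitant and
#' interaction records are discarded here, as are records whose involvement
#' code was unrecognized.
#'
#' @param rows merged analysis rows from [merge_jader()].
#' @return the suspected-only data table (a data.frame); `nrow()` is the
#'   report count used as every downstream denominator.
#' @export
filter_suspected <- function(rows) {
  out <- rows[!is.na(rows$involvement) & rows$involvement == "suspected", ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset a data table by drug
#'
#' @param table data table (suspected-only analysis rows).
#' @param drug drug name; matched after [normalize_label()].
#' @return the matching rows.
#' @export
subset_drug <- function(table, drug) {
  out <- table[table$drug == normalize_label(drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset a data table by an event-term set
#'
#' @param table data table.
#' @param terms character vector of preferred terms (normalized on entry).
#' @return rows whose term belongs to `terms`.
#' @export
subset_terms <- function(table, terms) {
  out <- table[table$pt %in% normalize_label(terms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patient demographics of a data table
#'
#' Counts unique patients (case identifiers) once each — a case reporting two
#' lung terms is one patient — and tabulates sex and age band with
#' percentages of all patients, rounded to one decimal. Unknown categories
#' are kept, never dropped.
#'
#' @param table data table (typically a drug x term subset).
#' @return an object of class `pv_demographics`: list with `n_patients` and
#'   data.frames `sex` and `age` (columns `category`, `count`, `pct`).
#' @export
demographics <- function(table) {
  first <- table[!duplicated(table$case_id), , drop = FALSE]
  n <- nrow(first)
  tab <- function(x, levels) {
    cnt <- vapply(levels, function(l) sum(x == l), integer(1))
    data.frame(category = levels, count = as.integer(cnt),
               pct = if (n > 0) round_half_up(cnt / n * 100, 1) else rep(NA_real_, length(levels)),
               row.names = NULL)
  }
  out <- list(n_patients = n,
              sex = tab(first$sex, sex_levels),
              age = tab(first$age, age_levels))
  class(out) <- "pv_demographics"
  out
}

#' @export
print.pv_demographics <- function(x, ...) {
  cat("Patient demographics (unique cases): n =", x$n_patients, "\n\nSex:\n")
  print(x$sex, row.names = FALSE)
  cat("\nAge band:\n")
  print(x$age, row.names = FALSE)
  invisible(x)
}
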