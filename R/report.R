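# End-to-end orchestration: raw tables -> data table -> demographics,
# signal screen, time-to-onset, outcome report, with stage-count logging.

read_or_pass <- function(x, kind) {
  if (is.character(x) && length(x) == 1) return(read_jader(x, kind))
  normalize_jader(as.data.frame(x), kind)
}

#' Run the full analysis pipeline
#'
#' Deduplicates the DRUG and REAC tables, merges the three tables into
#' case-level rows, restricts to suspected-drug involvement, and produces
#' the four result tables: patient demographics of the drug-and-term subset,
#' the disproportionality screen over the term set, per-term Weibull
#' time-to-onset fits with histograms, and the outcome report for the
#' signal-flagged terms. When `out_dir` is given, writes `demographics.csv`,
#' `signals.csv`, `tto.csv`, `histograms.csv`, `outcomes.csv` and
#' `run_log.txt` (row counts at every stage). Any stage failure aborts with
#' the stage name and cause.
#'
#' @param demo,drug,reac paths to CSV tables or data.frames in the
#'   [read_jader()] schemas.
#' @param drug_name target drug.
#' @param terms event-term set (character vector, or a path readable by
#'   [read_terms()]); defaults to the packaged 29 lung-toxicity terms.
#' @param min_cases minimum case count for the screen (default 5).
#' @param horizon time-to-onset cap in days (default 730).
#' @param bin_width histogram bin width in days (default 30).
#' @param gap dosing-episode gap threshold in days (default 365).
#' @param correction zero-cell continuity correction for the screen.
#' @param out_dir optional output directory (created if needed).
#' @return invisibly, a list with `data_table`, `drug_subset`,
#'   `demographics`, `screen`, `tto` (fits + summary table), `histograms`,
#'   `outcomes`, and `log` (the stage-count lines).
#' @export
run_analysis <- function(demo, drug, reac, drug_name = "bevacizumab",
                         terms = lung_terms(), min_cases = 5, horizon = 730,
                         bin_width = 30, gap = 365, correction = FALSE,
                         out_dir = NULL) {
  stopifnot(min_cases >= 1, horizon > 0, bin_width > 0)
  if (is.character(terms) && length(terms) == 1 && file.exists(terms)) {
    terms <- read_terms(terms)
  }
  terms <- normalize_label(terms)
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  demo_t <- stage("read demo", read_or_pass(demo, "demo"))
  drug_t <- stage("read drug", read_or_pass(drug, "drug"))
  reac_t <- stage("read reac", read_or_pass(reac, "reac"))
  note("raw rows: demo=%d drug=%d reac=%d", nrow(demo_t), nrow(drug_t),
       nrow(reac_t))

  drug_t <- stage("dedup", dedup_reports(drug_t))
  reac_t <- stage("dedup", dedup_reports(reac_t))
  note("deduplicated rows: drug=%d reac=%d", nrow(drug_t), nrow(reac_t))

  merged <- stage("merge", merge_jader(demo_t, drug_t, reac_t))
  note("merged case-drug-event rows: %d", nrow(merged))

  dt <- stage("suspected filter", filter_suspected(merged))
  note("suspected-drug data table rows: %d", nrow(dt))

  dsub <- stage("drug subset", subset_drug(dt, drug_name))
  note("rows for drug '%s': %d", normalize_label(drug_name), nrow(dsub))

  tsub <- stage("term subset", subset_terms(dsub, terms))
  note("rows matching %d event terms: %d", length(terms), nrow(tsub))

  demog <- stage("demographics", demographics(tsub))
  screen <- stage("screen", ror_screen(dt, drug_name, terms,
                                       min_cases = min_cases,
                                       correction = correction))
  note("terms screened: %d; signals: %d", nrow(screen), sum(screen$signal))

  tto <- stage("time to onset",
               tto_by_term(dt, drug_t, drug_name, screen$pt,
                           horizon = horizon, gap = gap))
  hist_rows <- lapply(screen$pt, function(pt) {
    fit <- tto$fits[[pt]]
    if (is.null(fit)) return(NULL)
    h <- onset_histogram(fit$data, bin_width = bin_width, horizon = horizon)
    cbind(pt = pt, h)
  })
  hists <- do.call(rbind, c(Filter(Negate(is.null), hist_rows),
                            list(make.row.names = FALSE)))
  if (is.null(hists)) {
    hists <- data.frame(pt = character(), lower = numeric(),
                        upper = numeric(), count = integer())
  }

  sig_terms <- screen$pt[screen$signal]
  outc <- stage("outcomes", outcome_report(dsub, sig_terms))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    demog_df <- rbind(cbind(variable = "sex", demog$sex),
                      cbind(variable = "age", demog$age))
    write_table(demog_df, file.path(out_dir, "demographics.csv"))
    write_signals(screen, file.path(out_dir, "signals.csv"))
    write_table(tto$table, file.path(out_dir, "tto.csv"))
    write_table(hists, file.path(out_dir, "histograms.csv"))
    write_table(outc, file.path(out_dir, "outcomes.csv"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }

  invisible(list(data_table = dt, drug_subset = dsub, term_subset = tsub,
                 demographics = demog, screen = screen, tto = tto,
                 histograms = hists, outcomes = outc, log = log_lines))
}

#' Generate and write a synthetic database
#'
#' Runs [generate_reports()] and writes `demo.csv`, `drug.csv`, `reac.csv`
#' plus `sim_metadata.txt` echoing the resolved seed, so a run can be
#' reproduced from its output directory alone.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`; if neither is set a seed
#'   is drawn, logged, and recorded in the metadata.
#' @return invisibly, the list of written file paths.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed) || is.na(config$seed)) {
    config$seed <- sample.int(.Machine$integer.max, 1)
    message("no seed supplied; generated seed ", config$seed)
  }
  tabs <- generate_reports(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(demo = file.path(out_dir, "demo.csv"),
             drug = file.path(out_dir, "drug.csv"),
             reac = file.path(out_dir, "reac.csv"))
  for (k in names(paths)) write_table(tabs[[k]], paths[[k]])
  meta <- c(sprintf("seed: %d", config$seed),
            sprintf("n_cases: %d", config$n_cases),
            sprintf("drugs: %s", paste(config$drugs$name, collapse = "; ")),
            sprintf("events: %s", paste(config$events$pt, collapse = "; ")))
  writeLines(meta, file.path(out_dir, "sim_metadata.txt"))
  invisible(c(paths, metadata = file.path(out_dir, "sim_metadata.txt")))
}
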