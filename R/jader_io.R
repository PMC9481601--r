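# Reading, validating, deduplicating and merging the three report tables.
#
# The database ships as three CSV tables keyed by an opaque case identifier:
#   DEMO  case_id, sex, age                     (one row per patient/case)
#   DRUG  case_id, drug, involvement, start_date, end_date
#   REAC  case_id, pt, onset_date, outcome
# Categorical fields are normalized on read; unrecognized tokens map to
# "unknown"/missing so that denominators are never silently reduced.

jader_schema <- list(
  demo = c("case_id", "sex", "age"),
  drug = c("case_id", "drug", "involvement", "start_date", "end_date"),
  reac = c("case_id", "pt", "onset_date", "outcome")
)

analysis_columns <- c("case_id", "drug", "pt", "involvement", "sex", "age",
                      "onset_date", "start_date", "end_date", "outcome")

sex_levels <- c("male", "female", "unknown")
age_levels <- c(paste0(seq(10, 90, 10), "s"), "unknown")
involvement_levels <- c("suspected", "concomitant", "interaction")
outcome_levels <- c("recovery", "remission", "not_recovered", "sequelae",
                    "death", "unclear")

normalize_sex <- function(x) {
  x <- normalize_label(x)
  out <- rep("unknown", length(x))
  out[x %in% c("male", "m")] <- "male"
  out[x %in% c("female", "f")] <- "female"
  out
}

normalize_age <- function(x) {
  x <- normalize_label(x)
  ifelse(grepl("^[1-9]0s$", x), x, "unknown")
}

normalize_involvement <- function(x) {
  x <- normalize_label(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("suspected", "suspected drug", "suspect")] <- "suspected"
  out[x %in% c("concomitant", "concomitant drug")] <- "concomitant"
  out[x == "interaction"] <- "interaction"
  out
}

normalize_outcome <- function(x) {
  x <- normalize_label(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("recovery", "recovered")] <- "recovery"
  out[x == "remission"] <- "remission"
  out[x %in% c("not recovered", "not_recovered", "unrecovered")] <- "not_recovered"
  out[x %in% c("sequelae", "with sequelae", "with_sequelae")] <- "sequelae"
  out[x %in% c("death", "died", "fatal")] <- "death"
  out[x == "unclear"] <- "unclear"
  out
}

normalize_jader <- function(df, kind) {
  df$case_id <- trimws(as.character(df$case_id))
  switch(kind,
    demo = {
      df$sex <- normalize_sex(df$sex)
      df$age <- normalize_age(df$age)
    },
    drug = {
      df$drug <- normalize_label(df$drug)
      df$involvement <- normalize_involvement(df$involvement)
      df$start_date <- canonicalize_date(df$start_date)
      df$end_date <- canonicalize_date(df$end_date)
    },
    reac = {
      df$pt <- normalize_label(df$pt)
      df$onset_date <- canonicalize_date(df$onset_date)
      df$outcome <- normalize_outcome(df$outcome)
    }
  )
  df[, jader_schema[[kind]], drop = FALSE]
}

#' Read one of the three report tables
#'
#' Reads a UTF-8 CSV (header required), checks the documented column schema,
#' and normalizes every field: labels via [normalize_label()], categorical
#' codes to their controlled vocabularies (unrecognized sex/age tokens become
#' `"unknown"`, unrecognized involvement/outcome tokens become `NA`), and
#' dates to canonical partial-date strings (unparseable dates become missing,
#' never errors). Row count is preserved exactly.
#'
#' @param path path to a CSV file.
#' @param kind one of `"demo"`, `"drug"`, `"reac"`.
#' @param encoding file encoding; the tested contract is UTF-8, but the flag
#'   accepts e.g. `"Shift_JIS"` for raw regulator downloads.
#' @return data.frame with the schema columns for `kind`, all character.
#' @export
read_jader <- function(path, kind = c("demo", "drug", "reac"),
                       encoding = "UTF-8") {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = encoding, check.names = FALSE,
                        strip.white = FALSE)
  missing_cols <- setdiff(jader_schema[[kind]], names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s table %s is missing mandatory column(s): %s",
                 toupper(kind), path, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  normalize_jader(df, kind)
}

#' Write a table as CSV
#'
#' Writes a header row plus one line per record, UTF-8, comma-separated,
#' missing fields as empty strings. Round-trips losslessly through the
#' corresponding reader.
#'
#' @param df data.frame (a report table or a merged analysis table).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  ok <- try(utils::write.csv(df, path, row.names = FALSE, na = "",
                             fileEncoding = "UTF-8", quote = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("cannot write table to ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a merged analysis table written by [write_table()]
#'
#' @param path CSV path.
#' @return data.frame with the analysis-table columns.
#' @export
read_analysis_table <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(analysis_columns, names(df))
  if (length(missing_cols)) {
    stop("analysis table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$outcome[df$outcome == ""] <- NA_character_
  df$involvement[df$involvement == ""] <- NA_character_
  df[, analysis_columns, drop = FALSE]
}

#' Remove exact-duplicate records
#'
#' Duplicate reports are common in spontaneous-report extracts. The
#' reproducible, assumption-free duplicate rule used throughout this package
#' is exact equality of all fields within one table: only literal repeats are
#' dropped, two records differing in any field (e.g. the same reaction with
#' two onset dates) are both kept. First occurrence order is preserved and
#' the operation is idempotent.
#'
#' @param df a report table.
#' @return `df` without exact-duplicate rows.
#' @export
dedup_reports <- function(df) {
  df[!duplicated(df), , drop = FALSE]
}

#' Merge the three tables into case-level analysis rows
#'
#' Inner-joins DRUG and REAC on the case identifier (so a case with two drug
#' records and three reactions contributes their cartesian product), then
#' attaches demographics from DEMO (cases absent from DEMO get
#' `sex = age = "unknown"`; no rows are invented for cases lacking DRUG or
#' REAC entries). The result is collapsed to unique
#' (case, drug, term, involvement) combinations — the counting unit of every
#' downstream denominator — keeping the first-seen dates/outcome for each.
#'
#' @param demo,drug,reac deduplicated report tables.
#' @return data.frame of analysis rows with columns
#'   `case_id, drug, pt, involvement, sex, age, onset_date, start_date,
#'   end_date, outcome`, sorted by case, drug, term.
#' @export
merge_jader <- function(demo, drug, reac) {
  demo <- demo[!duplicated(demo$case_id), , drop = FALSE]
  m <- merge(drug, reac, by = "case_id", sort = FALSE)
  if (nrow(m)) {
    key <- paste(m$case_id, m$drug, m$pt, m$involvement, sep = "\r")
    m <- m[!duplicated(key), , drop = FALSE]
  }
  m <- merge(m, demo[, c("case_id", "sex", "age")], by = "case_id",
             all.x = TRUE, sort = FALSE)
  m$sex[is.na(m$sex)] <- "unknown"
  m$age[is.na(m$age)] <- "unknown"
  m <- m[order(m$case_id, m$drug, m$pt, m$involvement), analysis_columns,
         drop = FALSE]
  rownames(m) <- NULL
  m
}
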