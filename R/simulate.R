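# Synthetic spontaneous-report databases.
#
# The generator emulates the statistical structure the analysis assumes:
# cases keyed across three tables, suspected/concomitant involvement codes,
# partial dates, exact-duplicate rows, background event reporting rates with
# planted drug-event rate ratios, Weibull-distributed onset times anchored at
# the drug start date, and a six-category outcome field with missingness.
# It exists so every pipeline stage can be validated (type-I behaviour,
# power against planted signals, parameter recovery) without the
# non-redistributable real database.

#' Build and validate a simulation configuration
#'
#' @param n_cases number of cases (patients) to simulate.
#' @param drugs data.frame with columns `name` and `p_use` (marginal
#'   probability that a case has the drug as a suspected drug).
#' @param events data.frame with columns `pt` and `p_background` (per
#'   case-drug probability of the event firing when the rate ratio is 1).
#' @param rr matrix of reporting-rate ratios, drugs x events; 1 everywhere
#'   means no planted association.
#' @param onset_alpha,onset_beta Weibull scale (days) and shape of the
#'   onset-time model, either scalars or drugs x events matrices. Defaults
#'   (alpha 120 days, beta 1.1) mirror a typical sub-acute onset profile.
#' @param outcome_probs named probabilities over the six outcome categories;
#'   may sum to less than 1, the remainder being missing outcomes.
#' @param sex_probs,age_probs demographic marginals over the controlled
#'   categories.
#' @param missing_date_frac fraction of recorded dates degraded to
#'   year/month precision.
#' @param duplicate_frac fraction of exact-duplicate rows injected into the
#'   DRUG and REAC tables.
#' @param concomitant_frac extra concomitant-involvement drug rows, as a
#'   fraction of each drug's use probability.
#' @param start_window character vector of two dates bounding the uniform
#'   drug-start distribution (default the April 2004 - March 2021 study
#'   window).
#' @param max_duration_days administration length is uniform on
#'   0..`max_duration_days`.
#' @param seed RNG seed; the same configuration and seed yield identical
#'   tables.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 1000,
                       drugs = data.frame(name = c("drug a", "drug b"),
                                          p_use = c(0.3, 0.5)),
                       events = data.frame(pt = c("event x", "event y"),
                                           p_background = c(0.05, 0.10)),
                       rr = NULL,
                       onset_alpha = 120, onset_beta = 1.1,
                       outcome_probs = c(recovery = 0.34, remission = 0.17,
                                         not_recovered = 0.12,
                                         sequelae = 0.02, death = 0.08,
                                         unclear = 0.17),
                       sex_probs = c(male = 0.55, female = 0.40,
                                     unknown = 0.05),
                       age_probs = c("10s" = 0.005, "20s" = 0.01,
                                     "30s" = 0.03, "40s" = 0.06,
                                     "50s" = 0.13, "60s" = 0.30,
                                     "70s" = 0.30, "80s" = 0.10,
                                     "90s" = 0.015, unknown = 0.05),
                       missing_date_frac = 0.10, duplicate_frac = 0.05,
                       concomitant_frac = 0.10,
                       start_window = c("2004-04-01", "2021-03-31"),
                       max_duration_days = 300, seed = 1L) {
  nd <- nrow(drugs)
  ne <- nrow(events)
  if (is.null(rr)) rr <- matrix(1, nd, ne)
  as_mat <- function(x, what) {
    if (length(x) == 1) x <- matrix(x, nd, ne)
    if (!is.matrix(x) || any(dim(x) != c(nd, ne))) {
      stop(sprintf("'%s' must be a scalar or a %d x %d matrix", what, nd, ne),
           call. = FALSE)
    }
    x
  }
  cfg <- list(n_cases = as.integer(n_cases),
              drugs = data.frame(name = normalize_label(drugs$name),
                                 p_use = drugs$p_use),
              events = data.frame(pt = normalize_label(events$pt),
                                  p_background = events$p_background),
              rr = as_mat(rr, "rr"),
              onset_alpha = as_mat(onset_alpha, "onset_alpha"),
              onset_beta = as_mat(onset_beta, "onset_beta"),
              outcome_probs = outcome_probs, sex_probs = sex_probs,
              age_probs = age_probs,
              missing_date_frac = missing_date_frac,
              duplicate_frac = duplicate_frac,
              concomitant_frac = concomitant_frac,
              start_window = as.Date(start_window),
              max_duration_days = as.integer(max_duration_days),
              seed = as.integer(seed))

  check_prob <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("'", what, "' must contain probabilities in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_cases < 1) stop("'n_cases' must be positive", call. = FALSE)
  check_prob(cfg$drugs$p_use, "drugs$p_use")
  check_prob(cfg$events$p_background, "events$p_background")
  check_prob(cfg$outcome_probs, "outcome_probs")
  if (sum(cfg$outcome_probs) > 1 + 1e-8) {
    stop("'outcome_probs' must sum to at most 1", call. = FALSE)
  }
  if (!setequal(names(cfg$outcome_probs), outcome_levels)) {
    stop("'outcome_probs' must be named with the six outcome categories",
         call. = FALSE)
  }
  check_prob(cfg$sex_probs, "sex_probs")
  check_prob(cfg$age_probs, "age_probs")
  check_prob(cfg$missing_date_frac, "missing_date_frac")
  check_prob(cfg$duplicate_frac, "duplicate_frac")
  check_prob(cfg$concomitant_frac, "concomitant_frac")
  if (any(cfg$rr <= 0)) stop("'rr' rate ratios must be > 0", call. = FALSE)
  if (any(cfg$onset_alpha <= 0) || any(cfg$onset_beta <= 0)) {
    stop("Weibull onset parameters must be > 0", call. = FALSE)
  }
  if (anyDuplicated(cfg$drugs$name) || anyDuplicated(cfg$events$pt)) {
    stop("drug and event names must be unique after normalization",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

degrade_dates <- function(x, frac) {
  has <- nzchar(x)
  hit <- has & stats::runif(length(x)) < frac
  x[hit] <- substr(x[hit], 1, 7)
  x
}

#' Generate a synthetic report database
#'
#' Per case: demographics from the configured marginals; each drug used
#' (suspected) independently with its marginal probability; for every
#' (case, drug, event) an independent Bernoulli draw at
#' `min(1, p_background * rr)` decides whether the event is reported; onset
#' dates are the triggering drug's start date plus a Weibull draw (rounded
#' down to whole days); outcomes follow the configured category
#' probabilities. Concomitant drug rows, exact-duplicate rows and
#' year/month-degraded dates are injected at the configured fractions.
#'
#' @param config a [sim_config()].
#' @return list with data.frames `demo`, `drug`, `reac` in the
#'   [read_jader()] schemas. Deterministic given `(config, config$seed)`.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  nd <- nrow(config$drugs)
  ne <- nrow(config$events)
  case_id <- sprintf("C%07d", seq_len(n))

  demo <- data.frame(
    case_id = case_id,
    sex = sample(names(config$sex_probs), n, TRUE, config$sex_probs),
    age = sample(names(config$age_probs), n, TRUE, config$age_probs)
  )

  window_days <- as.integer(config$start_window[2] - config$start_window[1])
  use <- matrix(stats::runif(n * nd), n, nd) <
    matrix(config$drugs$p_use, n, nd, byrow = TRUE)
  # start dates kept as day numbers (days since 1970-01-01) inside matrices
  start <- matrix(NA_real_, n, nd)
  start[use] <- as.numeric(config$start_window[1]) +
    sample.int(window_days + 1L, sum(use), replace = TRUE) - 1L
  dur <- matrix(NA_integer_, n, nd)
  dur[use] <- sample.int(config$max_duration_days + 1L, sum(use),
                         replace = TRUE) - 1L

  drug_rows <- which(use, arr.ind = TRUE)
  drug_tab <- data.frame(
    case_id = case_id[drug_rows[, 1]],
    drug = config$drugs$name[drug_rows[, 2]],
    involvement = "suspected",
    start_date = format(as.Date(start[drug_rows], origin = "1970-01-01"),
                        "%Y-%m-%d"),
    end_date = format(as.Date(start[drug_rows] + dur[drug_rows],
                              origin = "1970-01-01"), "%Y-%m-%d")
  )

  # concomitant noise rows: no events attributed, dates drawn the same way
  con_use <- matrix(stats::runif(n * nd), n, nd) <
    matrix(config$drugs$p_use * config$concomitant_frac, n, nd, byrow = TRUE)
  con_use <- con_use & !use
  if (any(con_use)) {
    con_rows <- which(con_use, arr.ind = TRUE)
    con_start <- config$start_window[1] +
      sample.int(window_days + 1L, nrow(con_rows), replace = TRUE) - 1L
    drug_tab <- rbind(drug_tab, data.frame(
      case_id = case_id[con_rows[, 1]],
      drug = config$drugs$name[con_rows[, 2]],
      involvement = "concomitant",
      start_date = format(con_start, "%Y-%m-%d"),
      end_date = ""
    ))
  }

  # events: independent Bernoulli per (case, drug, event)
  reac_list <- vector("list", ne)
  for (k in seq_len(ne)) {
    p <- pmin(1, config$events$p_background[k] * config$rr[, k])
    fired <- use & (matrix(stats::runif(n * nd), n, nd) <
                      matrix(p, n, nd, byrow = TRUE))
    any_fired <- rowSums(fired) > 0
    if (!any(any_fired)) next
    cases <- which(any_fired)
    trig <- apply(fired[cases, , drop = FALSE], 1, which.max)
    delay <- floor(stats::rweibull(length(cases),
                                   shape = config$onset_beta[cbind(trig, k)],
                                   scale = config$onset_alpha[cbind(trig, k)]))
    onset <- start[cbind(cases, trig)] + delay
    reac_list[[k]] <- data.frame(
      case_id = case_id[cases],
      pt = config$events$pt[k],
      onset_date = format(as.Date(onset, origin = "1970-01-01"), "%Y-%m-%d")
    )
  }
  reac <- do.call(rbind, c(Filter(Negate(is.null), reac_list),
                           list(make.row.names = FALSE)))
  if (is.null(reac)) {
    reac <- data.frame(case_id = character(), pt = character(),
                       onset_date = character())
  }
  p_out <- c(config$outcome_probs[outcome_levels],
             missing = max(0, 1 - sum(config$outcome_probs)))
  reac$outcome <- sample(names(p_out), nrow(reac), TRUE, p_out)
  reac$outcome[reac$outcome == "missing"] <- ""

  drug_tab$start_date <- degrade_dates(drug_tab$start_date,
                                       config$missing_date_frac)
  drug_tab$end_date <- degrade_dates(drug_tab$end_date,
                                     config$missing_date_frac)
  reac$onset_date <- degrade_dates(reac$onset_date, config$missing_date_frac)

  dup <- function(df) {
    k <- round(config$duplicate_frac * nrow(df))
    if (k > 0 && nrow(df) > 0) {
      df <- rbind(df, df[sample.int(nrow(df), k, replace = TRUE), ,
                         drop = FALSE])
    }
    rownames(df) <- NULL
    df
  }
  drug_tab <- dup(drug_tab)
  reac <- dup(reac)
  reac$outcome[is.na(reac$outcome)] <- ""
  list(demo = demo,
       drug = drug_tab[, jader_schema$drug],
       reac = reac[, jader_schema$reac])
}

#' Expected contingency cells under a simulation configuration
#'
#' Analytic expectations of the 2x2 cells of the merged suspected-drug data
#' table for one drug-event pair. Because the three tables are joined on the
#' case identifier alone, an event fired by any of a case's drugs pairs with
#' every drug the case uses; the expectations account for that co-use
#' leakage (so under `rr = 1` the implied ROR sits very close to, but not
#' identically at, 1 when drugs differ in use probability).
#'
#' @param config a [sim_config()].
#' @param drug,pt target drug and event names.
#' @return named numeric vector `c(a, b, c, d, ror)`: expected cells and the
#'   implied (true) reporting odds ratio.
#' @export
expected_counts <- function(config, drug, pt) {
  stopifnot(inherits(config, "sim_config"))
  J <- match(normalize_label(drug), config$drugs$name)
  K <- match(normalize_label(pt), config$events$pt)
  if (is.na(J) || is.na(K)) stop("drug or event not in configuration",
                                 call. = FALSE)
  nd <- nrow(config$drugs)
  ne <- nrow(config$events)
  pu <- config$drugs$p_use
  pfire <- pmin(matrix(config$events$p_background, nd, ne, byrow = TRUE) *
                  config$rr, 1)
  # q[j, k] = P(event k reported for a case | case uses drug j)
  q <- matrix(0, nd, ne)
  for (j in seq_len(nd)) {
    for (k in seq_len(ne)) {
      others <- setdiff(seq_len(nd), j)
      q[j, k] <- 1 - (1 - pfire[j, k]) *
        prod(1 - pu[others] * pfire[others, k])
    }
  }
  n <- config$n_cases
  cell <- matrix(0, nd, ne)
  for (j in seq_len(nd)) cell[j, ] <- n * pu[j] * q[j, ]
  a <- cell[J, K]
  b <- sum(cell[J, -K])
  cc <- sum(cell[-J, K])
  d <- sum(cell[-J, -K])
  c(a = a, b = b, c = cc, d = d, ror = (a * d) / (b * cc))
}

#' Deterministic fixture reproducing the published bevacizumab margins
#'
#' Builds DEMO/DRUG/REAC tables whose merged suspected-drug data table
#' reproduces exactly the published target-drug margin: 20,399 bevacizumab
#' reports of which 1,679 carry one of the 29 lung-toxicity terms with the
#' printed per-term case counts, and the 1,679 lung-toxicity patients carry
#' the printed sex and age-band margins. A filler mass of comparator-drug
#' reports (default 20,000) carries the same event profile scaled
#' proportionally, so the full table is screenable end to end. Dates and
#' outcomes are blank: onset times and outcome distributions are not
#' recoverable from the published margins, and this synthetic fixture does
#' not invent them.
#'
#' @param n_filler number of comparator-drug reports.
#' @return list with data.frames `demo`, `drug`, `reac`.
#' @export
published_margin_fixture <- function(n_filler = 20000) {
  terms <- lung_terms()
  cases_per_term <- c(609L, 246L, 225L, 86L, 62L, 54L, 42L, 37L, 35L, 35L,
                      28L, 26L, 23L, 21L, 21L, 19L, 18L, 12L, 11L, 10L, 9L,
                      8L, 7L, 7L, 6L, 6L, 6L, 5L, 5L)
  stopifnot(length(terms) == length(cases_per_term))
  n_lung <- sum(cases_per_term)        # 1679
  n_target <- 20399L
  sex_counts <- c(male = 1071L, female = 546L, unknown = 62L)
  age_counts <- c("10s" = 2L, "20s" = 1L, "30s" = 22L, "40s" = 84L,
                  "50s" = 222L, "60s" = 585L, "70s" = 565L, "80s" = 94L,
                  "90s" = 1L, unknown = 103L)

  lung_id <- sprintf("L%05d", seq_len(n_lung))
  other_id <- sprintf("B%05d", seq_len(n_target - n_lung))
  fill_id <- sprintf("X%05d", seq_len(n_filler))

  demo <- data.frame(
    case_id = c(lung_id, other_id, fill_id),
    sex = c(rep(names(sex_counts), sex_counts),
            rep("unknown", length(other_id) + n_filler)),
    age = c(rep(names(age_counts), age_counts),
            rep("unknown", length(other_id) + n_filler))
  )

  drug <- data.frame(
    case_id = c(lung_id, other_id, fill_id),
    drug = c(rep("bevacizumab", n_target), rep("comparator drug", n_filler)),
    involvement = "suspected",
    start_date = "", end_date = ""
  )

  # filler events: same profile as the target margin, largest-remainder
  # apportionment so the filler total is exact
  profile <- c(cases_per_term, n_target - n_lung)
  exact <- profile * n_filler / n_target
  base <- floor(exact)
  short <- n_filler - sum(base)
  extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
  base[extra] <- base[extra] + 1L
  fill_pts <- rep(c(normalize_label(terms), "non-lung adverse event"), base)

  reac <- data.frame(
    case_id = c(lung_id, other_id, fill_id),
    pt = c(rep(normalize_label(terms), cases_per_term),
           rep("non-lung adverse event", length(other_id)),
           fill_pts),
    onset_date = "", outcome = ""
  )
  list(demo = demo, drug = drug, reac = reac)
}
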