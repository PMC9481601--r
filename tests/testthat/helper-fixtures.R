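# Small in-code fixtures and independent oracles used across the suite.

make_demo <- function(case_id, sex = "male", age = "60s") {
  n <- length(case_id)
  data.frame(case_id = case_id, sex = rep_len(sex, n), age = rep_len(age, n))
}

make_drug <- function(case_id, drug = "drug a", involvement = "suspected",
                      start_date = "", end_date = "") {
  n <- length(case_id)
  data.frame(case_id = case_id, drug = rep_len(drug, n),
             involvement = rep_len(involvement, n),
             start_date = rep_len(start_date, n),
             end_date = rep_len(end_date, n))
}

make_reac <- function(case_id, pt = "event x", onset_date = "",
                      outcome = "") {
  n <- length(case_id)
  data.frame(case_id = case_id, pt = rep_len(pt, n),
             onset_date = rep_len(onset_date, n),
             outcome = rep_len(outcome, n))
}

# Brute-force join oracle: nested loops over all row pairs, collapsed to
# unique (case, drug, term, involvement) combinations.
brute_force_merge_count <- function(drug, reac) {
  seen <- character()
  for (i in seq_len(nrow(drug))) {
    for (j in seq_len(nrow(reac))) {
      if (drug$case_id[i] == reac$case_id[j]) {
        key <- paste(drug$case_id[i], drug$drug[i], reac$pt[j],
                     drug$involvement[i], sep = "|")
        seen <- union(seen, key)
      }
    }
  }
  length(seen)
}

# Exhaustive hypergeometric oracle for the two-sided Fisher test
# (probability-mass rule), written from first principles with choose().
fisher_enum_p <- function(a, b, c, d) {
  row1 <- a + b
  col1 <- a + c
  N <- a + b + c + d
  lo <- max(0L, col1 - (N - row1))
  hi <- min(row1, col1)
  xs <- lo:hi
  probs <- choose(row1, xs) * choose(N - row1, col1 - xs) / choose(N, col1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A random small report database for property tests.
random_tables <- function(n_cases, seed) {
  set.seed(seed)
  ids <- sprintf("R%03d", seq_len(n_cases))
  drugs <- c("drug a", "drug b", "drug c")
  pts <- c("event x", "event y", "event z")
  inv <- c("suspected", "concomitant", "interaction")
  nd <- sample(1:4, n_cases, replace = TRUE)
  nr <- sample(0:3, n_cases, replace = TRUE)
  drug <- do.call(rbind, lapply(seq_len(n_cases), function(i) {
    make_drug(rep(ids[i], nd[i]),
              drug = sample(drugs, nd[i], replace = TRUE),
              involvement = sample(inv, nd[i], replace = TRUE))
  }))
  reac_rows <- lapply(seq_len(n_cases), function(i) {
    if (nr[i] == 0) return(NULL)
    make_reac(rep(ids[i], nr[i]), pt = sample(pts, nr[i], replace = TRUE))
  })
  reac <- do.call(rbind, Filter(Negate(is.null), reac_rows))
  if (is.null(reac)) reac <- make_reac(character(0))
  list(demo = make_demo(ids), drug = drug, reac = reac)
}
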