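test_that("episode reconstruction applies the one-year gap rule", {
  # single record -> single episode
  e1 <- episodes(make_drug("A1", start_date = "2018-03-01",
                           end_date = "2018-05-01"))
  expect_equal(nrow(e1), 1)

  # gap of 457 days between end and next start -> two episodes
  e2 <- episodes(make_drug(c("A1", "A1"),
                           start_date = c("2018-01-01", "2019-06-01"),
                           end_date = c("2018-03-01", "")))
  expect_equal(nrow(e2), 2)
  expect_equal(e2$start, as.Date(c("2018-01-01", "2019-06-01")))

  # gap of 184 days -> merged into one episode
  e3 <- episodes(make_drug(c("A1", "A1"),
                           start_date = c("2018-01-01", "2018-09-01"),
                           end_date = c("2018-03-01", "2018-10-01")))
  expect_equal(nrow(e3), 1)
  expect_equal(e3$end, as.Date("2018-10-01"))

  # records with unresolvable starts are skipped and counted
  e4 <- episodes(make_drug(c("A1", "A1"),
                           start_date = c("2018", "2018-09-01")))
  expect_equal(nrow(e4), 1)
  expect_equal(attr(e4, "n_skipped"), 1)
})

test_that("onset-day arithmetic follows the half-day convention and horizon", {
  eps <- episodes(make_drug("A1", start_date = "2019-02-10"))
  expect_equal(onset_days(as.Date("2019-02-10"), eps)$days, 0.5)
  expect_equal(onset_days(as.Date("2019-03-12"), eps)$days, 30.5)
  far <- onset_days(as.Date("2019-02-10") + 800, eps)
  expect_equal(far$status, "beyond_horizon")
  expect_equal(onset_days(as.Date("2019-02-10") + 800, eps,
                          horizon = 1000)$days, 800.5)
  early <- onset_days(as.Date("2019-01-01"), eps)
  expect_equal(early$status, "before_start")
  expect_equal(onset_days("", eps)$status, "missing_onset")
})

test_that("the clock restarts at the most recent episode", {
  eps <- episodes(make_drug(c("A1", "A1"),
                            start_date = c("2015-01-01", "2019-01-01"),
                            end_date = c("2015-02-01", "")))
  expect_equal(nrow(eps), 2)
  expect_equal(onset_days(as.Date("2019-01-31"), eps)$days, 30.5)
  # before the second episode begins, the first one is the reference
  expect_equal(onset_days(as.Date("2015-03-01"), eps, horizon = 1e6)$days,
               59.5)
})

test_that("onset days are invariant to shifting all dates", {
  base <- as.Date("2016-05-10")
  for (k in c(0, 17, 400)) {
    dr <- make_drug("A1", start_date = format(base + k, "%Y-%m-%d"))
    days <- onset_days(base + k + 45, episodes(dr))$days
    expect_equal(days, 45.5)
  }
})

test_that("tto_samples walks a pair and tallies rejections", {
  demo <- make_demo(c("A1", "A2", "A3", "A4"))
  drug <- make_drug(c("A1", "A2", "A3", "A4"),
                    start_date = c("2019-01-01", "2019-01-01",
                                   "2019-01-01", ""))
  reac <- make_reac(c("A1", "A2", "A3", "A4"),
                    onset_date = c("2019-01-31", "2021-06-01",
                                   "", "2019-02-01"))
  dt <- filter_suspected(merge_jader(demo, drug, reac))
  days <- tto_samples(dt, drug, "drug a", "event x")
  expect_equal(as.numeric(days), 30.5)
  rej <- attr(days, "rejected")
  expect_equal(unname(rej["beyond_horizon"]), 1L)  # 882 days
  expect_equal(unname(rej["missing_onset"]), 1L)
  expect_equal(unname(rej["no_episode"]), 1L)
})

test_that("onset histograms conserve counts with left-closed bins", {
  h <- onset_histogram(c(0.5, 30.5), bin_width = 30)
  expect_equal(h$count[1:2], c(1L, 1L))
  expect_equal(sum(h$count), 2)
  expect_equal(h$lower[1], 0)

  set.seed(13)
  x <- runif(500, 0.5, 730)
  h2 <- onset_histogram(x, bin_width = 30)
  expect_equal(sum(h2$count), 500)

  # a sample exactly at the horizon lands in the final bin
  h3 <- onset_histogram(730, bin_width = 30, horizon = 730)
  expect_equal(h3$count[nrow(h3)], 1L)
  expect_error(onset_histogram(10, bin_width = 0), "positive")
})

test_that("planted onset distributions are recovered through the pipeline", {
  cfg <- sim_config(
    n_cases = 4000,
    drugs = data.frame(name = "drug a", p_use = 0.6),
    events = data.frame(pt = "event x", p_background = 0.4),
    onset_alpha = 100, onset_beta = 2,
    missing_date_frac = 0, duplicate_frac = 0, concomitant_frac = 0,
    seed = 321)
  tb <- generate_reports(cfg)
  dt <- filter_suspected(merge_jader(tb$demo, tb$drug, tb$reac))
  days <- tto_samples(dt, tb$drug, "drug a", "event x")
  expect_gt(length(days), 800)
  fit <- weibull_tto(days)
  expect_lt(abs(coef(fit)[["alpha"]] - 100) / 100, 0.05)
  expect_lt(abs(coef(fit)[["beta"]] - 2) / 2, 0.075)
})

test_that("tto_by_term summarises terms including empty ones", {
  demo <- make_demo(c("A1", "A2"))
  drug <- make_drug(c("A1", "A2"), start_date = "2019-01-01")
  reac <- rbind(make_reac("A1", pt = "event x", onset_date = "2019-02-01"),
                make_reac("A2", pt = "event x", onset_date = "2019-03-01"))
  dt <- filter_suspected(merge_jader(demo, drug, reac))
  out <- tto_by_term(dt, drug, "drug a", c("event x", "event y"))
  expect_equal(out$table$n, c(2L, 0L))
  expect_equal(out$table$failure_type[2], "indeterminate")
  expect_s3_class(out$fits[["event x"]], "weibull_tto")
  expect_null(out$fits[["event y"]])
})
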