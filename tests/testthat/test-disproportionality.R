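test_that("contingency cells partition the data table", {
  tabs <- random_tables(60, 5)
  dt <- filter_suspected(merge_jader(tabs$demo, dedup_reports(tabs$drug),
                                     dedup_reports(tabs$reac)))
  ct <- contingency(dt, "drug a", "event x")
  expect_equal(sum(ct), nrow(dt))
  # brute-force four-way partition
  expect_equal(unname(ct["a"]),
               sum(dt$drug == "drug a" & dt$pt == "event x"))
  expect_equal(unname(ct["b"]),
               sum(dt$drug == "drug a" & dt$pt != "event x"))
  # absent drug: zero target margin returned, not raised
  ct0 <- contingency(dt, "absent", "event x")
  expect_equal(unname(ct0[c("a", "b")]), c(0L, 0L))
})

test_that("ROR follows ad/(bc) with its algebraic properties", {
  expect_equal(unname(ror(c(a = 10, b = 90, c = 20, d = 180))), 1.0)
  expect_equal(unname(ror(c(a = 10, b = 90, c = 10, d = 890))), 8900 / 900)
  # with the target-drug margin fixed, doubling the event count more than
  # doubles the ROR (the extra cases come out of cell b)
  base <- ror(c(a = 10, b = 90, c = 10, d = 890))
  expect_gt(ror(c(a = 20, b = 80, c = 10, d = 890)), 2 * base)
  expect_gt(ror(c(a = 20, b = 90, c = 10, d = 890)), base)
  # swapping the two rows gives the reciprocal
  expect_equal(unname(ror(c(a = 7, b = 13, c = 5, d = 11))),
               1 / unname(ror(c(a = 5, b = 11, c = 7, d = 13))))
  expect_error(ror(c(a = 0, b = 1, c = 1, d = 1)), "a")
  expect_equal(unname(ror(c(a = 0, b = 1, c = 1, d = 1), correction = TRUE)),
               (0.5 * 1.5) / (1.5 * 1.5))
})

test_that("Woolf interval matches the hand-computed formula and limits", {
  ci <- ror_ci(c(a = 10, b = 90, c = 10, d = 890))
  expect_equal(signif(unname(ci), 3), c(4.01, 24.4))
  est <- ror(c(a = 10, b = 90, c = 10, d = 890))
  # interval contains the point estimate; level -> 0 collapses onto it
  expect_true(ci["low"] <= est && est <= ci["high"])
  ci0 <- ror_ci(c(a = 10, b = 90, c = 10, d = 890), level = 1e-12)
  expect_equal(unname(ci0), rep(unname(est), 2), tolerance = 1e-6)
})

test_that("Fisher p matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_p(c(a = 1, b = 1, c = 1, d = 1)), 1.0)
  expect_equal(fisher_p(c(a = 3, b = 0, c = 0, d = 3)), 0.1)
  set.seed(4711)
  for (rep in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    ct <- c(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
    expect_equal(fisher_p(ct),
                 fisher_enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("screening applies the case threshold, sorting and signal rule", {
  # one case per row: 6 reports of event x under drug a, 4 of event y
  demo <- make_demo(sprintf("A%02d", 1:40))
  drug <- make_drug(sprintf("A%02d", 1:40),
                    drug = rep(c("drug a", "drug b"), each = 20))
  reac <- make_reac(sprintf("A%02d", 1:40),
                    pt = c(rep("event x", 6), rep("event y", 4),
                           rep("filler", 10),
                           rep("event x", 2), rep("filler", 18)))
  dt <- filter_suspected(merge_jader(demo, drug, reac))
  s <- ror_screen(dt, "drug a", c("event x", "event y"), min_cases = 5)
  expect_equal(s$pt, "event x")         # event y has 4 < 5 cases
  expect_equal(s$cases, 6L)
  expect_equal(s$rate_pct, round_half_up(6 / 20 * 100, 2))
  expect_identical(s$signal, unname(s$ci_low > 1))

  # inclusive threshold: exactly min_cases stays in
  s5 <- ror_screen(dt, "drug a", c("event x"), min_cases = 6)
  expect_equal(nrow(s5), 1)

  # zero other-drug cell: NA without correction, corrected values with it
  reac2 <- reac
  reac2$pt[21:40] <- "filler"
  dt2 <- filter_suspected(merge_jader(demo, drug, reac2))
  s_na <- ror_screen(dt2, "drug a", "event x")
  expect_true(is.na(s_na$ror) && !s_na$corrected && !s_na$signal)
  s_corr <- ror_screen(dt2, "drug a", "event x", correction = TRUE)
  expect_true(s_corr$corrected && is.finite(s_corr$ror))
})

test_that("results are sorted by descending case count", {
  tabs <- random_tables(80, 12)
  dt <- filter_suspected(merge_jader(tabs$demo, dedup_reports(tabs$drug),
                                     dedup_reports(tabs$reac)))
  s <- ror_screen(dt, "drug a", c("event x", "event y", "event z"),
                  min_cases = 1)
  expect_true(all(diff(s$cases) <= 0))
})

test_that("the Woolf interval covers the generator's planted odds ratio", {
  # sparse regime (rare drug use, rare events) so reports are close to
  # independent draws; with common co-use the shared-case correlation makes
  # the Woolf interval visibly conservative
  cfg0 <- sim_config(
    n_cases = 20000,
    drugs = data.frame(name = c("drug a", "drug b"), p_use = c(0.05, 0.08)),
    events = data.frame(pt = c("event x", "event y"),
                        p_background = c(0.015, 0.05)),
    rr = matrix(c(4, 1, 1, 1), 2, 2),
    duplicate_frac = 0, missing_date_frac = 0, concomitant_frac = 0)
  truth <- expected_counts(cfg0, "drug a", "event x")[["ror"]]
  hits <- 0L
  n_rep <- 500L
  for (i in seq_len(n_rep)) {
    cfg <- cfg0
    cfg$seed <- 20000L + i
    tb <- generate_reports(cfg)
    dt <- filter_suspected(merge_jader(tb$demo, tb$drug, tb$reac))
    ci <- ror_ci(contingency(dt, "drug a", "event x"))
    hits <- hits + (ci["low"] <= truth && truth <= ci["high"])
  }
  expect_gte(hits / n_rep, 0.92)
  expect_lte(hits / n_rep, 0.98)
})
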