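ref_table <- contingency_table(10, 20, 30, 240)

test_that("the worked contingency example matches hand arithmetic", {
  expect_identical(ror(ref_table)$value, 4)
  expect_identical(prr(ref_table)$value, 3.25)
  expect_equal(yates_chisq(ref_table), 300 * (1800 - 150)^2 /
                 (30 * 270 * 40 * 260))
  ix <- index_ab(ref_table)
  expect_identical(ix[["index_a"]], 25)
  expect_equal(ix[["index_b"]], 100 / 3)
})

test_that("proportional tables give null statistics", {
  t <- contingency_table(5, 50, 10, 100)
  expect_equal(ror(t)$value, 1)
  expect_equal(prr(t)$value, 1)
  expect_identical(yates_chisq(t), 0)  # |ad-bc| = 0, correction floored
})

test_that("zero cells yield undefined markers, not errors", {
  t <- contingency_table(10, 0, 30, 240)
  expect_true(is.na(ror(t)$value))
  expect_true(is.na(prr(t)$value))
  expect_true(is.na(yates_chisq(contingency_table(0, 0, 5, 5))))
  expect_true(is.na(index_ab(contingency_table(0, 5, 0, 5))[["index_a"]]))
  ix0 <- index_ab(contingency_table(0, 5, 3, 5))
  expect_identical(unname(ix0), c(0, 0))
  expect_identical(index_ab(contingency_table(4, 5, 0, 5))[["index_a"]], 100)
  expect_error(contingency_table(-1, 0, 0, 0), "nonnegative")
})

test_that("the Haldane option shifts all cells by 0.5", {
  t <- contingency_table(10, 0, 30, 240)
  r <- ror(t, haldane = TRUE)
  expect_equal(r$value, (10.5 * 240.5) / (0.5 * 30.5))
})

test_that("Wald intervals bracket the point estimate and match the formulas", {
  r <- ror(ref_table)
  z <- qnorm(0.975)
  se <- sqrt(1 / 10 + 1 / 20 + 1 / 30 + 1 / 240)
  expect_equal(r$ci_low, exp(log(4) - z * se))
  expect_equal(r$ci_high, exp(log(4) + z * se))
  expect_true(r$ci_low <= r$value && r$value <= r$ci_high)
  p <- prr(ref_table)
  se_p <- sqrt(1 / 10 - 1 / 40 + 1 / 20 - 1 / 260)
  expect_equal(p$ci_low, exp(log(3.25) - z * se_p))
  expect_equal(p$ci_high, exp(log(3.25) + z * se_p))
  # narrower level, narrower interval
  r90 <- ror(ref_table, level = 0.9)
  expect_gt(r90$ci_low, r$ci_low)
})

test_that("Yates statistic agrees with stats::chisq.test on all small tables", {
  # independent oracle over every table with N <= 12 and nonzero margins
  for (n in 2:12) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[parts$a + parts$b + parts$c <= n, ]
    parts$d <- n - parts$a - parts$b - parts$c
    for (i in seq_len(nrow(parts))) {
      a <- parts$a[i]; b <- parts$b[i]; c <- parts$c[i]; d <- parts$d[i]
      if (min(a + b, c + d, a + c, b + d) == 0) next
      m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
      expected <- suppressWarnings(
        unname(stats::chisq.test(m, correct = TRUE)$statistic))
      expect_equal(yates_chisq(contingency_table(a, b, c, d)), expected,
                   tolerance = 1e-10)
    }
  }
})

test_that("the statistic is invariant under transposition", {
  t1 <- contingency_table(7, 3, 2, 9)
  t2 <- contingency_table(7, 2, 3, 9)
  expect_equal(yates_chisq(t1), yates_chisq(t2))
})

test_that("positive-association tables order as ROR > PRR > 1", {
  set.seed(11)
  for (i in 1:200) {
    cells <- rpois(4, c(12, 20, 25, 200)) + 1L
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    if (t$a / (t$a + t$c) <= t$b / (t$b + t$d)) next
    expect_gt(ror(t)$value, prr(t)$value)
    expect_gt(prr(t)$value, 1)
  }
})

test_that("contingency_from_reports matches a brute-force recount", {
  gm <- load_grouping()
  db <- clean_reports(sim_as_db(generate_database(small_sim())))
  as_of <- "2014Q2"
  # oracle: iterate all (case, drug, reaction) triples directly
  oracle <- function(drug, disease) {
    keep <- db$demo$case_id[quarter_index(db$demo$quarter_received) <=
                              quarter_index(as_of)]
    a <- b <- c <- d <- 0L
    for (cid in keep) {
      sus <- db$drug$drug_code[db$drug$case_id == cid &
                                 db$drug$role == "suspected"]
      pts <- db$reac$pt_name[db$reac$case_id == cid]
      if (length(sus) == 0 || length(pts) == 0) next
      on_drug <- drug %in% sus
      has_dis <- disease %in% map_pt(pts, gm)
      if (on_drug && has_dis) a <- a + 1L
      else if (!on_drug && has_dis) b <- b + 1L
      else if (on_drug) c <- c + 1L
      else d <- d + 1L
    }
    c(a, b, c, d)
  }
  for (drug in c("D001", "D003")) {
    for (disease in names(gm)[c(1, 3)]) {
      t <- contingency_from_reports(db, drug, disease, gm, as_of)
      expect_identical(unlist(t, use.names = FALSE), oracle(drug, disease))
    }
  }
  expect_error(contingency_from_reports(db, "D001", "NoSuchDisease", gm,
                                        as_of), "unknown disease")
})

test_that("an as-of before every report empties the table", {
  gm <- load_grouping()
  db <- clean_reports(sim_as_db(generate_database(small_sim())))
  t <- contingency_from_reports(db, "D001", names(gm)[1], gm, "2005Q1")
  expect_identical(unlist(t, use.names = FALSE), rep(0L, 4))
})

test_that("the signal rule requires all three thresholds", {
  expect_true(apply_signal_rule(ref_table)$detected)
  expect_false(apply_signal_rule(contingency_table(2, 1, 1, 100))$detected)
  # undefined PRR (b = 0) fails its threshold
  expect_false(apply_signal_rule(contingency_table(10, 0, 30, 240))$detected)
  # proportional table: chi-squared 0 < 4
  expect_false(apply_signal_rule(contingency_table(5, 50, 10, 100))$detected)
  # custom thresholds
  expect_false(apply_signal_rule(ref_table, n_min = 11)$detected)
})

test_that("the revision crosstab reproduces its derived percentages", {
  ct <- crosstab_counts(35, 824, 53, 5896)
  expect_identical(ct$pct_detected_revised, 4)
  expect_identical(ct$pct_revised_missed, 60.2)
  expect_identical(sum(ct$table), 35L + 824L + 53L + 5896L)

  # empty margins are undefined
  none <- crosstab_counts(0, 0, 0, 120)
  expect_true(is.na(none$pct_detected_revised))
  expect_true(is.na(none$pct_revised_missed))

  # perfect detector
  perf <- crosstab_counts(10, 0, 0, 120)
  expect_identical(perf$pct_detected_revised, 100)
  expect_identical(perf$pct_revised_missed, 0)
})

test_that("crosstab_vs_revisions validates and counts pair status", {
  dec <- data.frame(drug_code = c("D1", "D1", "D2"),
                    disease = c("X", "Y", "X"),
                    detected = c(TRUE, FALSE, TRUE))
  rev <- data.frame(drug_code = c("D1", "D1"), disease = c("X", "Y"))
  ct <- crosstab_vs_revisions(dec, rev)
  expect_identical(unname(ct$table["yes", ]), c(1L, 1L))
  expect_identical(unname(ct$table["no", ]), c(1L, 0L))
  # a revised pair without any decision has unknown status
  rev2 <- rbind(rev, data.frame(drug_code = "D9", disease = "Z"))
  expect_error(crosstab_vs_revisions(dec, rev2), "without a signal decision")
  dec$detected[1] <- NA
  expect_error(crosstab_vs_revisions(dec, rev), "unknown detection")
})
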