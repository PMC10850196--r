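gm <- load_grouping()

# 8 patients of (D001, Rhabdomyolysis) spread over 2019Q1-2019Q4, plus one
# unrelated case; every derived value below is a hand count
hand_db <- function() {
  q <- rep(c("2019Q1", "2019Q2", "2019Q3", "2019Q4"), each = 2)
  ids <- paste0("P", 1:8)
  days <- c(5, 10, 20, 40, 100, 30, NA, 3)
  start <- as.Date("2019-01-05") + c(0, 10, 95, 100, 190, 200, 280, 285)
  demo <- data.frame(
    case_id = c(ids, "Q1"),
    version = c(1L, 3L, rep(1L, 6), 1L),
    sex = "F", age_band = "50s", weight_band = "60kg",
    quarter_received = c(q, "2019Q1"), stringsAsFactors = FALSE)
  drug <- data.frame(
    case_id = c(ids, "Q1"),
    drug_code = c(rep("D001", 8), "D002"),
    role = "suspected",
    start_date = c(format(start, "%Y-%m-%d"), "2019-01-01"),
    otc_flag = 0L,
    action = c(rep("continued", 4), "discontinued", rep("continued", 3),
               "continued"),
    rechallenge = c("unknown", "unknown", "readministered",
                    rep("unknown", 5), "unknown"),
    stringsAsFactors = FALSE)
  onset <- ifelse(is.na(days), NA, format(start[1:8] + days, "%Y-%m-%d"))
  reac <- data.frame(
    case_id = c(ids, "Q1"),
    pt_name = c(rep("Rhabdomyolysis", 8), "Hyperkaliemia"),
    onset_date = c(onset, "2019-01-15"),
    outcome = c("death", rep("recovered", 7), "recovered"),
    stringsAsFactors = FALSE)
  hist <- data.frame(case_id = c(ids, "Q1"), condition = "hypertension",
                     stringsAsFactors = FALSE)
  clean_reports(report_db(demo, drug, reac, hist))
}

test_that("the hand-counted fixture reproduces every feature exactly", {
  db <- hand_db()
  pair <- data.frame(drug_code = "D001", disease = "Rhabdomyolysis",
                     as_of_quarter = "2019Q4")
  f <- compute_features(pair, db, gm)
  expect_identical(nrow(f), 1L)
  expect_identical(f$n_patients, 8L)
  expect_identical(f$quarters_since_first, 4L)
  expect_identical(f$patients_per_quarter, 2)
  expect_equal(f$onset_days_mean, 208 / 7)
  expect_identical(f$onset_days_median, 20)
  expect_identical(f$n_onset_within_15, 3L)
  expect_identical(f$n_onset_within_30, 5L)
  expect_identical(f$n_onset_within_90, 6L)
  expect_identical(f$n_deaths, 1L)
  expect_identical(f$n_rechallenge, 1L)
  expect_identical(f$n_discontinued, 1L)
  expect_identical(c(f$new_patients_q1, f$new_patients_q2,
                     f$new_patients_q3, f$new_patients_q4),
                   c(2L, 2L, 2L, 2L))
  expect_identical(f$new_deaths_q1, 0L)
  expect_identical(f$new_onset15_q1, 1L)  # P8, 3 days
  expect_identical(f$new_onset30_q1, 1L)
  expect_identical(f$new_onset90_q1, 1L)
  expect_identical(f$reports_per_case, 1.25)   # (7 * 1 + 3) / 8
  expect_identical(f$missing_per_case, 0.125)  # P7's missing onset date
  # contingency: a = 8, b = 0, c = 0, d = 1
  expect_identical(f$index_a, 100)
  expect_identical(f$index_b, 100)
  expect_true(is.na(f$prr))
  expect_true(f$dispro_undefined)
})

test_that("a pair with no reports gets zero counts and missing onset", {
  db <- hand_db()
  pair <- data.frame(drug_code = "D002", disease = "Rhabdomyolysis",
                     as_of_quarter = "2019Q4")
  f <- compute_features(pair, db, gm)
  expect_identical(f$n_patients, 0L)
  expect_identical(f$quarters_since_first, 0L)
  expect_identical(f$patients_per_quarter, 0)
  expect_true(is.na(f$onset_days_mean))
  # a = 0: both coverage indexes are defined but zero here
  expect_identical(f$index_a, 0)
  expect_identical(f$index_b, 0)
  expect_false(f$onset_observed)
})

test_that("windowed onset counts are monotone and bounded by cumulative", {
  db <- clean_reports(sim_as_db(generate_database(small_sim())))
  pairs <- build_cohort(db, data.frame(drug_code = character(0),
                                       disease = character(0),
                                       announce_quarter = character(0),
                                       reason = character(0)),
                        data.frame(drug_code = character(0),
                                   disease = character(0)),
                        gm, c("2011Q3", "2015Q2"))
  f <- compute_features(pairs, db, gm)
  expect_true(all(f$n_onset_within_15 <= f$n_onset_within_30))
  expect_true(all(f$n_onset_within_30 <= f$n_onset_within_90))
  expect_true(all(f$n_onset_within_90 <= f$n_patients))
  expect_true(all(f$new_patients_q1 <= f$n_patients))
  expect_true(all(f$n_deaths <= f$n_patients))
  expect_true(all(f$quarters_since_first[f$n_patients > 0] >= 1))
  ix <- c(f$index_a, f$index_b)
  expect_true(all(ix[!is.na(ix)] >= 0 & ix[!is.na(ix)] <= 100))
})

test_that("count features match a brute-force per-report recount", {
  db <- clean_reports(sim_as_db(generate_database(small_sim())))
  as_of <- "2014Q2"
  ai <- quarter_index(as_of)
  targets <- data.frame(drug_code = c("D001", "D002"),
                        disease = names(gm)[c(1, 2)],
                        as_of_quarter = as_of, stringsAsFactors = FALSE)
  f <- compute_features(targets, db, gm)
  for (i in 1:2) {
    drug <- targets$drug_code[i]; disease <- targets$disease[i]
    hit <- integer(0)  # case ids of the pair, by explicit iteration
    qs <- deaths <- 0L
    for (j in seq_len(nrow(db$demo))) {
      cid <- db$demo$case_id[j]
      if (quarter_index(db$demo$quarter_received[j]) > ai) next
      sus <- db$drug$drug_code[db$drug$case_id == cid &
                                 db$drug$role == "suspected"]
      rows <- which(db$reac$case_id == cid)
      if (!(drug %in% sus) || length(rows) == 0) next
      match_rows <- rows[map_pt(db$reac$pt_name[rows], gm) %in% disease]
      if (length(match_rows) == 0) next
      hit <- c(hit, j)
      if (any(db$reac$outcome[match_rows] == "death")) deaths <- deaths + 1L
    }
    expect_identical(f$n_patients[i], length(hit))
    expect_identical(f$n_deaths[i], deaths)
    if (length(hit) > 0) {
      qn <- quarter_index(db$demo$quarter_received[hit])
      expect_identical(f$quarters_since_first[i], ai - min(qn) + 1L)
      expect_identical(f$new_patients_q1[i], sum(qn == ai))
      expect_identical(f$new_patients_q2[i], sum(qn == ai - 1L))
    }
  }
})

test_that("reports after the as-of quarter cannot influence the features", {
  sim <- generate_database(small_sim())
  db <- clean_reports(sim_as_db(sim))
  pair <- data.frame(drug_code = "D001", disease = names(gm)[1],
                     as_of_quarter = "2014Q2", stringsAsFactors = FALSE)
  base <- compute_features(pair, db, gm)
  base <- impute_onset_days(base, db, gm)

  # corrupt every future report: new outcomes, drugs, dates - then delete half
  late <- db$demo$case_id[quarter_index(db$demo$quarter_received) >
                            quarter_index("2014Q2")]
  mut <- db
  sel <- mut$reac$case_id %in% late
  mut$reac$outcome[sel] <- "death"
  mut$reac$pt_name[sel] <- "Rhabdomyolysis"
  mut$drug$drug_code[mut$drug$case_id %in% late] <- "D001"
  drop <- late[seq_along(late) %% 2 == 0]
  mut$demo <- mut$demo[!(mut$demo$case_id %in% drop), ]
  mut$drug <- mut$drug[!(mut$drug$case_id %in% drop), ]
  mut$reac <- mut$reac[!(mut$reac$case_id %in% drop), ]
  mut$hist <- mut$hist[!(mut$hist$case_id %in% drop), ]

  mutated <- compute_features(pair, mut, gm)
  mutated <- impute_onset_days(mutated, mut, gm)
  expect_identical(base, mutated)
})

test_that("missing onset summaries are imputed from donor drugs", {
  # drug A has observed onsets for disease X (per-drug median 12); drug B's
  # only case is missing both dates, so B inherits the donor median
  demo <- data.frame(case_id = c("A1", "A2", "A3", "B1", "C1"),
                     version = 1L, sex = "F", age_band = "50s",
                     weight_band = "60kg", quarter_received = "2019Q1",
                     stringsAsFactors = FALSE)
  drug <- data.frame(case_id = demo$case_id,
                     drug_code = c("DA", "DA", "DA", "DB", "DC"),
                     role = "suspected",
                     start_date = c("2019-01-01", "2019-01-01", "2019-01-01",
                                    NA, NA),
                     otc_flag = 0L, action = "continued",
                     rechallenge = "unknown", stringsAsFactors = FALSE)
  reac <- data.frame(case_id = demo$case_id,
                     pt_name = c(rep("Rhabdomyolysis", 4), "Hyperkaliemia"),
                     onset_date = c("2019-01-09", "2019-01-13", "2019-01-21",
                                    NA, NA),
                     outcome = "recovered", stringsAsFactors = FALSE)
  hist <- data.frame(case_id = character(0), condition = character(0))
  db <- clean_reports(report_db(demo, drug, reac, hist))
  pairs <- data.frame(
    drug_code = c("DB", "DA", "DC"),
    disease = c("Rhabdomyolysis", "Rhabdomyolysis", "Hyperkaliemia"),
    as_of_quarter = "2019Q1", stringsAsFactors = FALSE)
  f <- compute_features(pairs, db, gm)
  expect_true(is.na(f$onset_days_mean[f$drug_code == "DB"]))
  expect_warning(fi <- impute_onset_days(f, db, gm), "no donor")
  # DB imputed with DA's median (8, 12, 20 days -> 12)
  expect_identical(fi$onset_days_mean[fi$drug_code == "DB"], 12)
  expect_identical(fi$onset_days_median[fi$drug_code == "DB"], 12)
  expect_true(fi$onset_imputed[fi$drug_code == "DB"])
  # observed values are untouched
  expect_identical(fi$onset_days_median[fi$drug_code == "DA"],
                   f$onset_days_median[f$drug_code == "DA"])
  expect_false(fi$onset_imputed[fi$drug_code == "DA"])
  # no donor anywhere for Hyperkaliemia: stays missing
  expect_true(is.na(fi$onset_days_mean[fi$drug_code == "DC"]))
})

test_that("the model matrix is complete with NA encoded as 0", {
  db <- hand_db()
  pairs <- data.frame(drug_code = c("D001", "D002"),
                      disease = c("Rhabdomyolysis", "Rhabdomyolysis"),
                      as_of_quarter = "2019Q4",
                      label = c("positive", "negative"),
                      stringsAsFactors = FALSE)
  f <- suppressWarnings(impute_onset_days(compute_features(pairs, db, gm),
                                          db, gm))
  mm <- prepare_model_matrix(f)
  expect_identical(dim(mm$x), c(2L, 34L))
  expect_identical(colnames(mm$x), feature_names())
  expect_false(anyNA(mm$x))
  expect_identical(mm$y, c(1L, 0L))
  expect_error(prepare_model_matrix(f[, -5]), "lacks column")
})
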