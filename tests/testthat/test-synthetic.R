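test_that("no planted pairs means empty ground truth", {
  sim <- generate_database(sim_config(n_drugs = 3, n_diseases = 3,
                                      n_quarters = 8, seed = 1))
  expect_identical(nrow(sim$truth$positive_pairs), 0L)
  expect_identical(nrow(sim$revisions), 0L)
})

test_that("generation is deterministic for a fixed (config, seed)", {
  cfg <- small_sim(seed = 9)
  a <- generate_database(cfg)
  b <- generate_database(cfg)
  expect_identical(a$tables, b$tables)
  expect_identical(a$revisions, b$revisions)
  # and a different seed actually changes the stream
  c <- generate_database(small_sim(seed = 10))
  expect_false(identical(a$tables$reac, c$tables$reac))
})

test_that("invalid config fields are rejected with the field named", {
  expect_error(sim_config(n_drugs = 0), "n_drugs")
  expect_error(sim_config(missing_date_prob = 1.2), "missing_date_prob")
  expect_error(sim_config(baseline_rate = -1), "baseline_rate")
  expect_error(sim_config(n_diseases = 80), "n_diseases")
  expect_error(sim_config(launch_spread = 30, n_quarters = 24),
               "launch_spread")
  expect_error(
    sim_config(planted_pairs = plant_pairs("D001", "Rhabdomyolysis",
                                           rate_multiplier = 0.5,
                                           revision_quarter = "2013Q1")),
    "rate_multiplier")
  # revision too early for the ramp plus the two-quarter lag
  expect_error(
    sim_config(planted_pairs = plant_pairs("D001", "Rhabdomyolysis",
                                           ramp_quarters = 8,
                                           revision_quarter = "2012Q1")),
    "revision_quarter")
  expect_error(
    generate_database(sim_config(
      n_drugs = 2, n_diseases = 2, n_quarters = 24,
      planted_pairs = plant_pairs("D009", "Rhabdomyolysis",
                                  revision_quarter = "2014Q2"))),
    "unknown drug")
})

test_that("revision log carries one domestic record per planted pair", {
  sim <- generate_database(small_sim())
  expect_identical(nrow(sim$revisions), 1L)
  expect_identical(sim$revisions$reason, "domestic")
  expect_identical(sim$truth$positive_pairs$drug_code, "D001")
})

test_that("per-pair quarterly counts match the configured rate", {
  # one pair watched over many quarters: mean within 3 SE of baseline_rate
  rate <- 0.7
  cfg <- sim_config(n_drugs = 1, n_diseases = 1, n_quarters = 1200,
                    baseline_rate = rate, missing_date_prob = 0,
                    followup_versions_mean = 0, seed = 21)
  sim <- generate_database(cfg)
  counts <- table(factor(sim$tables$demo$quarter_received,
                         levels = index_to_quarter(
                           quarter_index(cfg$start_quarter) + 0:1199)))
  expect_identical(sum(counts), nrow(sim$tables$demo))
  se <- sqrt(rate / 1200)
  expect_lt(abs(mean(counts) - rate), 3 * se)
})

test_that("planted ramp elevates reporting for the planted pair", {
  # Monte-Carlo over replicate small databases: the planted pair's mean
  # empirical ROR at the revision quarter exceeds 1
  gm <- load_grouping()
  rors <- vapply(1:150, function(s) {
    sim <- generate_database(
      sim_config(n_drugs = 4, n_diseases = 4, n_quarters = 10,
                 baseline_rate = 0.5,
                 planted_pairs = plant_pairs("D001", names(gm)[1],
                                             rate_multiplier = 8,
                                             ramp_quarters = 4,
                                             revision_quarter = "2013Q4"),
                 missing_date_prob = 0, seed = 1000 + s))
    db <- clean_reports(sim_as_db(sim))
    t <- contingency_from_reports(db, "D001", names(gm)[1], gm, "2013Q4")
    ror(t)$value
  }, 0)
  expect_gt(mean(rors, na.rm = TRUE), 1)
})

test_that("with all anomaly probabilities zero, cleaning removes nothing", {
  cfg <- sim_config(n_drugs = 4, n_diseases = 4, n_quarters = 10,
                    otc_drug_fraction = 0, duplicate_prob = 0,
                    pre_admin_onset_prob = 0, seed = 3)
  db <- sim_as_db(generate_database(cfg))
  cleaned <- clean_reports(db)
  log <- exclusion_log(cleaned)
  expect_identical(log$pre_admin_onset + log$duplicate + log$otc, 0L)
  expect_identical(log$retained, nrow(db$reac))
})

test_that("configured anomalies appear and are removed by cleaning", {
  db <- sim_as_db(generate_database(small_sim()))
  log <- exclusion_log(clean_reports(db))
  expect_gt(log$pre_admin_onset, 0)
  expect_gt(log$duplicate, 0)
  expect_gt(log$otc, 0)
})

test_that("written CSVs round-trip through load_reports", {
  sim <- generate_database(small_sim())
  dir <- tempfile("simdb")
  write_database(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("demo.csv", "drug.csv", "reac.csv", "hist.csv", "revisions.csv",
      "listed.csv", "truth.csv")))))
  db <- load_reports(dir)
  expect_identical(db$demo, sim$tables$demo)
  expect_identical(db$reac, sim$tables$reac)
  expect_identical(db$drug, sim$tables$drug)
})

test_that("drug launches are staggered within the configured window", {
  cfg <- sim_config(n_drugs = 40, n_diseases = 3, n_quarters = 24,
                    launch_spread = 12, baseline_rate = 2, seed = 5)
  sim <- generate_database(cfg)
  sus <- sim$tables$drug[sim$tables$drug$role == "suspected", ]
  first_q <- tapply(quarter_index(sim$tables$demo$quarter_received[
    match(sus$case_id, sim$tables$demo$case_id)]), sus$drug_code, min)
  start <- quarter_index(cfg$start_quarter)
  expect_true(all(first_q >= start))
  # with rate 2 per pair-quarter, first reports track the launch quarter:
  # several drugs must start reporting well after the simulation start
  expect_gt(length(unique(first_q)), 5)
})
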