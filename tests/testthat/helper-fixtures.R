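# shared fixtures, all built in code

# hand-written database: 3 cases, 2 reactions each, one suspected drug per
# case; case C3's second reaction predates the drug start
tiny_db <- function() {
  demo <- data.frame(
    case_id = c("C1", "C2", "C3"),
    version = c(1L, 2L, 1L),
    sex = c("F", "M", NA),
    age_band = c("40s", "70s", "20s"),
    weight_band = c("60kg", "70kg", NA),
    quarter_received = c("2019Q1", "2019Q2", "2019Q4"),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    case_id = c("C1", "C2", "C2", "C3"),
    drug_code = c("D001", "D001", "D002", "D002"),
    role = c("suspected", "suspected", "concomitant", "suspected"),
    start_date = c("2019-01-10", "2019-04-01", NA, "2019-02-01"),
    otc_flag = 0L,
    action = c("continued", "discontinued", "unknown", "continued"),
    rechallenge = c("not_readministered", "readministered", "unknown",
                    "unknown"),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    case_id = c("C1", "C1", "C2", "C2", "C3", "C3"),
    pt_name = c("Rhabdomyolysis", "Hyperkaliemia",
                "Blood potassium increased", "Headache",
                "Rhabdomyolysis", "Hypotension"),
    onset_date = c("2019-01-20", "2019-02-01", "2019-04-15", "2019-04-20",
                   "2019-10-01", "2019-01-01"),
    outcome = c("recovered", "unrecovered", "death", "recovered",
                "recovering", "unknown"),
    stringsAsFactors = FALSE)
  hist <- data.frame(case_id = "C1", condition = "hypertension",
                     stringsAsFactors = FALSE)
  report_db(demo, drug, reac, hist)
}

write_tiny_csvs <- function(dir = tempfile("db")) {
  db <- tiny_db()
  dir.create(dir)
  utils::write.csv(db$demo, file.path(dir, "demo.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(db$drug, file.path(dir, "drug.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(db$reac, file.path(dir, "reac.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(db$hist, file.path(dir, "hist.csv"), row.names = FALSE,
                   na = "")
  dir
}

# small simulated database with every anomaly switched on
small_sim <- function(seed = 4L, ...) {
  gm <- load_grouping()
  sim_config(n_drugs = 6, n_diseases = 5, n_quarters = 16,
             planted_pairs = plant_pairs("D001", names(gm)[1],
                                         rate_multiplier = 10,
                                         ramp_quarters = 4,
                                         revision_quarter = "2014Q2"),
             otc_drug_fraction = 0.2, duplicate_prob = 0.05,
             pre_admin_onset_prob = 0.05, seed = seed, ...)
}

sim_as_db <- function(sim) {
  report_db(sim$tables$demo, sim$tables$drug, sim$tables$reac,
            sim$tables$hist)
}

# separable toy classification data
toy_xy <- function(n = 60, shift = 5, seed = 42) {
  set.seed(seed)
  list(x = cbind(f1 = c(rnorm(n / 2, 0), rnorm(n / 2, shift)),
                 f2 = rnorm(n)),
       y = rep(0:1, each = n / 2))
}
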