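#' Configure a synthetic spontaneous-report database
#'
#' Builds the configuration for [generate_database()], which emulates a
#' JADER-style spontaneous adverse-drug-reaction reporting database: four
#' normalized tables (DEMO, DRUG, REAC, HIST), a package-insert revision log,
#' and the ground-truth set of planted positive drug-disease pairs. Report
#' arrival is Poisson per drug-disease pair per quarter at `baseline_rate`;
#' each planted pair's rate is multiplied by `rate_multiplier` during the
#' `ramp_quarters` quarters ending at its `revision_quarter`, emulating the
#' domestic case accumulation that precedes a label change.
#'
#' Default rates describe the reporting regime the pipeline is meant for: most
#' drug-reaction pairs accrue sporadic background reports (a case every few
#' years), while an emerging clinically significant reaction accrues several
#' cases per quarter in the run-up to its revision, and about a fifth of cases
#' lack usable administration/onset dates.
#'
#' @param n_drugs number of prescription drugs (codes `"D001"`, ...).
#' @param n_diseases number of target diseases, drawn in order from the
#'   packaged grouping (at most 75).
#' @param n_quarters number of simulated quarters.
#' @param start_quarter first simulated quarter (`"YYYYQn"`).
#' @param baseline_rate expected reports per drug-disease pair per quarter
#'   (while the drug is on the market).
#' @param launch_spread quarters over which drug market-entry dates are
#'   staggered: each drug launches uniformly within the first `launch_spread +
#'   1` simulated quarters and produces no reports before launch. 0 launches
#'   every drug at the simulation start. Planted drugs launch early enough for
#'   their full ramp.
#' @param planted_pairs `NULL`, or a data frame with columns `drug`, `disease`,
#'   `rate_multiplier` (>= 1; 1 plants a label without any signal),
#'   `ramp_quarters`, `revision_quarter`. See [plant_pairs()].
#' @param missing_date_prob per-field probability that a date (onset, drug
#'   start) or demographic entry is missing.
#' @param death_prob probability a case's reaction outcome is death.
#' @param rechallenge_prob probability the suspected drug was re-administered.
#' @param discontinuation_prob probability the suspected drug was discontinued.
#' @param otc_drug_fraction over-the-counter drugs added to the market, as a
#'   fraction of `n_drugs`; their reports are later removed by cleaning.
#' @param duplicate_prob probability a reaction row is duplicated (same case
#'   id, preferred term and onset date).
#' @param pre_admin_onset_prob probability of the data-entry anomaly where the
#'   recorded onset precedes the suspected drug's start by 1-30 days.
#' @param onset_day_distribution days from administration to onset: a list
#'   `list(name = "gamma", shape =, scale =)`, `list(name = "lognormal",
#'   meanlog =, sdlog =)`, `list(name = "exponential", rate =)` or
#'   `list(name = "uniform", min =, max =)`.
#' @param followup_versions_mean mean number of follow-up reports per case
#'   beyond the first (case version is `1 + Poisson(mean)`).
#' @param seed integer seed; output is a pure function of the configuration.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_drugs = 5, n_diseases = 4, n_quarters = 12,
#'                   planted_pairs = plant_pairs("D001", "Rhabdomyolysis",
#'                                               revision_quarter = "2013Q4"))
#' @export
sim_config <- function(n_drugs = 20,
                       n_diseases = 15,
                       n_quarters = 24,
                       start_quarter = "2011Q3",
                       baseline_rate = 0.25,
                       launch_spread = 0L,
                       planted_pairs = NULL,
                       missing_date_prob = 0.2,
                       death_prob = 0.05,
                       rechallenge_prob = 0.02,
                       discontinuation_prob = 0.3,
                       otc_drug_fraction = 0,
                       duplicate_prob = 0,
                       pre_admin_onset_prob = 0,
                       onset_day_distribution = list(name = "gamma",
                                                     shape = 1.5, scale = 20),
                       followup_versions_mean = 0.5,
                       seed = 1L) {
  cfg <- list(n_drugs = n_drugs, n_diseases = n_diseases,
              n_quarters = n_quarters, start_quarter = start_quarter,
              baseline_rate = baseline_rate, launch_spread = launch_spread,
              planted_pairs = planted_pairs,
              missing_date_prob = missing_date_prob, death_prob = death_prob,
              rechallenge_prob = rechallenge_prob,
              discontinuation_prob = discontinuation_prob,
              otc_drug_fraction = otc_drug_fraction,
              duplicate_prob = duplicate_prob,
              pre_admin_onset_prob = pre_admin_onset_prob,
              onset_day_distribution = onset_day_distribution,
              followup_versions_mean = followup_versions_mean,
              seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Describe planted positive pairs
#'
#' Convenience constructor for the `planted_pairs` field of [sim_config()].
#' Arguments are recycled to a common length.
#'
#' @param drug drug codes (`"D001"` style) or 1-based drug indices.
#' @param disease target disease names from the packaged grouping.
#' @param rate_multiplier factor (>= 1) applied to the baseline reporting rate
#'   during the ramp; 1 plants a revision with no reporting signal.
#' @param ramp_quarters number of elevated quarters ending at the revision.
#' @param revision_quarter `"YYYYQn"` quarter of the package-insert revision.
#' @return data frame suitable for `sim_config(planted_pairs = ...)`.
#' @export
plant_pairs <- function(drug, disease, rate_multiplier = 16,
                        ramp_quarters = 8, revision_quarter) {
  if (is.numeric(drug)) drug <- sprintf("D%03d", as.integer(drug))
  data.frame(drug = drug, disease = disease,
             rate_multiplier = rate_multiplier,
             ramp_quarters = as.integer(ramp_quarters),
             revision_quarter = revision_quarter,
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != round(x)) {
      stop("invalid sim_config field '", nm, "': must be an integer >= ", min,
           call. = FALSE)
    }
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("invalid sim_config field '", nm, "': must be a probability in [0,1]",
           call. = FALSE)
    }
  }
  chk_count(cfg$n_drugs, "n_drugs")
  chk_count(cfg$n_diseases, "n_diseases")
  if (cfg$n_diseases > 75) {
    stop("invalid sim_config field 'n_diseases': the packaged grouping has 75 diseases",
         call. = FALSE)
  }
  chk_count(cfg$n_quarters, "n_quarters")
  chk_count(cfg$launch_spread, "launch_spread", min = 0)
  if (cfg$launch_spread >= cfg$n_quarters) {
    stop("invalid sim_config field 'launch_spread': must be smaller than ",
         "n_quarters", call. = FALSE)
  }
  quarter_index(cfg$start_quarter)
  if (!is.numeric(cfg$baseline_rate) || cfg$baseline_rate < 0) {
    stop("invalid sim_config field 'baseline_rate': must be a nonnegative rate",
         call. = FALSE)
  }
  for (nm in c("missing_date_prob", "death_prob", "rechallenge_prob",
               "discontinuation_prob", "otc_drug_fraction", "duplicate_prob",
               "pre_admin_onset_prob")) {
    chk_prob(cfg[[nm]], nm)
  }
  if (!is.numeric(cfg$followup_versions_mean) || cfg$followup_versions_mean < 0) {
    stop("invalid sim_config field 'followup_versions_mean': must be nonnegative",
         call. = FALSE)
  }
  d <- cfg$onset_day_distribution
  if (!is.list(d) || is.null(d$name) ||
      !d$name %in% c("gamma", "lognormal", "exponential", "uniform")) {
    stop("invalid sim_config field 'onset_day_distribution': unknown distribution",
         call. = FALSE)
  }
  chk_count(cfg$seed, "seed", min = -.Machine$integer.max)
  pp <- cfg$planted_pairs
  if (!is.null(pp)) {
    need <- c("drug", "disease", "rate_multiplier", "ramp_quarters",
              "revision_quarter")
    if (!is.data.frame(pp) || !all(need %in% names(pp))) {
      stop("invalid sim_config field 'planted_pairs': need columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(pp$rate_multiplier < 1)) {
      stop("invalid sim_config field 'planted_pairs': rate_multiplier must be >= 1",
           call. = FALSE)
    }
    if (any(pp$ramp_quarters < 2)) {
      stop("invalid sim_config field 'planted_pairs': ramp_quarters must be >= 2",
           call. = FALSE)
    }
    if (anyDuplicated(pp[c("drug", "disease")])) {
      stop("invalid sim_config field 'planted_pairs': duplicated drug-disease pair",
           call. = FALSE)
    }
    start_idx <- quarter_index(cfg$start_quarter)
    rev_idx <- quarter_index(pp$revision_quarter)
    if (any(rev_idx - start_idx + 1L < pp$ramp_quarters + 2L)) {
      stop("invalid sim_config field 'planted_pairs': revision_quarter must be ",
           "at least ramp_quarters + 2 quarters into the simulation",
           call. = FALSE)
    }
    if (any(rev_idx > start_idx + cfg$n_quarters - 1L)) {
      stop("invalid sim_config field 'planted_pairs': revision_quarter beyond ",
           "the simulated period", call. = FALSE)
    }
  }
  invisible(cfg)
}

draw_onset_days <- function(n, d) {
  x <- switch(d$name,
    gamma       = stats::rgamma(n, shape = d$shape, scale = d$scale),
    lognormal   = stats::rlnorm(n, meanlog = d$meanlog, sdlog = d$sdlog),
    exponential = stats::rexp(n, rate = d$rate),
    uniform     = stats::runif(n, min = d$min, max = d$max))
  pmax(0L, as.integer(round(x)))
}

#' Generate a synthetic spontaneous-report database
#'
#' Simulates the full reporting history defined by a [sim_config()]: DEMO
#' (one row per case: demographics, quarter received, number of reports
#' received for the case), DRUG (suspected and concomitant drug entries with
#' start dates, over-the-counter flags, action taken and rechallenge status),
#' REAC (preferred term, onset date, outcome) and HIST (medical history),
#' together with the package-insert revision log (one domestic-accumulation
#' record per planted pair) and the ground truth.
#'
#' Configured anomalies — duplicate reaction rows, onset dates preceding the
#' drug start, reports on over-the-counter drugs — are injected at their
#' probabilities so that [clean_reports()] has known work to do.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_result` with elements `tables` (named list
#'   `demo`, `drug`, `reac`, `hist` of data frames), `revisions` (the revision
#'   log: `drug_code`, `disease`, `announce_quarter`, `reason`), `listed`
#'   (drug-disease pairs listed on the package insert at period end), `truth`
#'   (list with `positive_pairs` and `revision_log`) and `config`.
#' @seealso [write_database()], [load_reports()]
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  gm <- load_grouping()
  diseases <- names(gm)[seq_len(config$n_diseases)]
  drugs <- sprintf("D%03d", seq_len(config$n_drugs))
  n_otc <- ceiling(config$n_drugs * config$otc_drug_fraction)
  otc_drugs <- if (n_otc > 0) sprintf("O%03d", seq_len(n_otc)) else character(0)
  all_drugs <- c(drugs, otc_drugs)

  start_idx <- quarter_index(config$start_quarter)
  q_idx <- start_idx + seq_len(config$n_quarters) - 1L

  pp <- config$planted_pairs
  if (!is.null(pp) && nrow(pp) > 0) {
    if (!all(pp$drug %in% drugs)) {
      stop("invalid sim_config field 'planted_pairs': unknown drug code(s): ",
           paste(setdiff(pp$drug, drugs), collapse = ", "), call. = FALSE)
    }
    if (!all(pp$disease %in% diseases)) {
      stop("invalid sim_config field 'planted_pairs': disease(s) outside the ",
           "simulated grouping: ",
           paste(setdiff(pp$disease, diseases), collapse = ", "), call. = FALSE)
    }
  }

  # staggered market entry: each drug launches uniformly within the first
  # launch_spread + 1 quarters; planted drugs early enough for their full ramp
  launch <- stats::setNames(
    start_idx + sample.int(config$launch_spread + 1L, length(all_drugs),
                           replace = TRUE) - 1L,
    all_drugs)
  if (!is.null(pp) && nrow(pp) > 0) {
    cap <- tapply(quarter_index(pp$revision_quarter) - pp$ramp_quarters,
                  pp$drug, min)
    for (d in names(cap)) launch[d] <- min(launch[d], max(start_idx, cap[d]))
  }

  # expected report count per (drug, disease, quarter); planted pairs run at
  # baseline * multiplier during the ramp_quarters quarters ending at revision
  grid <- expand.grid(drug = all_drugs, disease = diseases, qidx = q_idx,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- ifelse(grid$qidx >= launch[grid$drug], config$baseline_rate, 0)
  if (!is.null(pp) && nrow(pp) > 0) {
    rev_idx <- quarter_index(pp$revision_quarter)
    for (i in seq_len(nrow(pp))) {
      ramp <- (rev_idx[i] - pp$ramp_quarters[i] + 1L):rev_idx[i]
      hit <- grid$drug == pp$drug[i] & grid$disease == pp$disease[i] &
        grid$qidx %in% ramp
      grid$rate[hit] <- config$baseline_rate * pp$rate_multiplier[i]
    }
  }
  grid$n <- stats::rpois(nrow(grid), grid$rate)
  rep_rows <- grid[grid$n > 0, , drop = FALSE]
  idx <- rep.int(seq_len(nrow(rep_rows)), rep_rows$n)
  n_cases <- length(idx)

  if (n_cases == 0) {
    tables <- empty_report_tables()
  } else {
    case_id <- sprintf("C%07d", seq_len(n_cases))
    drug_code <- rep_rows$drug[idx]
    disease <- rep_rows$disease[idx]
    qidx <- rep_rows$qidx[idx]
    quarter <- index_to_quarter(qidx)

    # calendar placement: onset uniform within the received quarter, drug
    # start onset_days earlier
    qstart <- quarter_start_date(quarter)
    qlen <- as.integer(quarter_start_date(index_to_quarter(qidx + 1L)) - qstart)
    onset <- qstart + floor(stats::runif(n_cases) * qlen)
    onset_days <- draw_onset_days(n_cases, config$onset_day_distribution)
    start_date <- onset - onset_days

    # pre-administration anomaly: recorded onset 1-30 days before the start
    pre <- stats::runif(n_cases) < config$pre_admin_onset_prob
    onset[pre] <- start_date[pre] - sample(30L, sum(pre), replace = TRUE)

    miss <- function() stats::runif(n_cases) < config$missing_date_prob
    onset_chr <- format(onset, "%Y-%m-%d")
    start_chr <- format(start_date, "%Y-%m-%d")
    onset_chr[miss() & !pre] <- NA_character_
    start_chr[miss() & !pre] <- NA_character_

    sex <- sample(c("M", "F"), n_cases, replace = TRUE)
    age_band <- paste0(sample(0:8, n_cases, replace = TRUE) * 10, "s")
    weight_band <- paste0(sample(seq(30, 90, 10), n_cases, replace = TRUE), "kg")
    sex[miss()] <- NA_character_
    age_band[miss()] <- NA_character_
    weight_band[miss()] <- NA_character_

    demo <- data.frame(
      case_id = case_id,
      version = 1L + stats::rpois(n_cases, config$followup_versions_mean),
      sex = sex, age_band = age_band, weight_band = weight_band,
      quarter_received = quarter, stringsAsFactors = FALSE)

    action <- ifelse(stats::runif(n_cases) < config$discontinuation_prob,
                     "discontinued",
                     sample(c("continued", "unknown"), n_cases, replace = TRUE))
    rechal <- ifelse(stats::runif(n_cases) < config$rechallenge_prob,
                     "readministered",
                     sample(c("not_readministered", "unknown"), n_cases,
                            replace = TRUE))
    drug_tab <- data.frame(
      case_id = case_id, drug_code = drug_code, role = "suspected",
      start_date = start_chr,
      otc_flag = as.integer(substr(drug_code, 1, 1) == "O"),
      action = action, rechallenge = rechal, stringsAsFactors = FALSE)

    # some cases also carry a concomitant medication entry
    conc <- which(stats::runif(n_cases) < 0.3)
    if (length(conc) > 0 && length(all_drugs) > 1) {
      conc_code <- vapply(drug_code[conc], function(d) {
        sample(setdiff(all_drugs, d), 1L)
      }, "")
      drug_tab <- rbind(drug_tab, data.frame(
        case_id = case_id[conc], drug_code = conc_code, role = "concomitant",
        start_date = NA_character_,
        otc_flag = as.integer(substr(conc_code, 1, 1) == "O"),
        action = "unknown", rechallenge = "unknown", stringsAsFactors = FALSE))
    }

    pt <- vapply(disease, function(d) {
      pts <- gm[[d]]
      if (length(pts) == 1L) pts else sample(pts, 1L)
    }, "")
    outcome <- ifelse(stats::runif(n_cases) < config$death_prob, "death",
                      sample(c("recovered", "recovering", "unrecovered",
                               "unknown"), n_cases, replace = TRUE))
    reac <- data.frame(case_id = case_id, pt_name = unname(pt),
                       onset_date = onset_chr, outcome = outcome,
                       stringsAsFactors = FALSE)

    dup <- which(stats::runif(n_cases) < config$duplicate_prob)
    if (length(dup) > 0) reac <- rbind(reac, reac[dup, , drop = FALSE])

    hist_n <- stats::rbinom(n_cases, 2L, 0.2)
    hidx <- rep.int(seq_len(n_cases), hist_n)
    hist_tab <- data.frame(
      case_id = case_id[hidx],
      condition = sample(c("hypertension", "diabetes mellitus", "asthma",
                           "chronic kidney disease", "atrial fibrillation",
                           "depression"), length(hidx), replace = TRUE),
      stringsAsFactors = FALSE)

    ord <- order(drug_tab$case_id, drug_tab$role, drug_tab$drug_code)
    drug_tab <- drug_tab[ord, , drop = FALSE]
    rownames(demo) <- rownames(drug_tab) <- rownames(reac) <-
      rownames(hist_tab) <- NULL
    tables <- list(demo = demo, drug = drug_tab, reac = reac, hist = hist_tab)
  }

  if (!is.null(pp) && nrow(pp) > 0) {
    revisions <- data.frame(drug_code = pp$drug, disease = pp$disease,
                            announce_quarter = pp$revision_quarter,
                            reason = "domestic", stringsAsFactors = FALSE)
  } else {
    revisions <- data.frame(drug_code = character(0), disease = character(0),
                            announce_quarter = character(0),
                            reason = character(0), stringsAsFactors = FALSE)
  }
  listed <- revisions[, c("drug_code", "disease"), drop = FALSE]
  truth <- list(positive_pairs = listed, revision_log = revisions)

  structure(list(tables = tables, revisions = revisions, listed = listed,
                 truth = truth, config = config),
            class = "sim_result")
}

empty_report_tables <- function() {
  list(
    demo = data.frame(case_id = character(0), version = integer(0),
                      sex = character(0), age_band = character(0),
                      weight_band = character(0),
                      quarter_received = character(0),
                      stringsAsFactors = FALSE),
    drug = data.frame(case_id = character(0), drug_code = character(0),
                      role = character(0), start_date = character(0),
                      otc_flag = integer(0), action = character(0),
                      rechallenge = character(0), stringsAsFactors = FALSE),
    reac = data.frame(case_id = character(0), pt_name = character(0),
                      onset_date = character(0), outcome = character(0),
                      stringsAsFactors = FALSE),
    hist = data.frame(case_id = character(0), condition = character(0),
                      stringsAsFactors = FALSE))
}

#' Write a simulated database to CSV files
#'
#' Writes `demo.csv`, `drug.csv`, `reac.csv`, `hist.csv`, `revisions.csv`,
#' `listed.csv` and `truth.csv` into `dir` with the column schemas shared with
#' [load_reports()].
#'
#' @param sim a `sim_result` from [generate_database()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_database <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) {
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, na = "")
  }
  wr(sim$tables$demo, "demo.csv")
  wr(sim$tables$drug, "drug.csv")
  wr(sim$tables$reac, "reac.csv")
  wr(sim$tables$hist, "hist.csv")
  wr(sim$revisions, "revisions.csv")
  wr(sim$listed, "listed.csv")
  wr(sim$truth$positive_pairs, "truth.csv")
  invisible(dir)
}
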