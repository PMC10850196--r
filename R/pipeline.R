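#' Signal decisions for many pairs at once
#'
#' Applies the conventional disproportionality rule (cumulative reports >=
#' `n_min`, Yates chi-squared >= `chi_min`, PRR >= `prr_min`) to every
#' requested (suspected drug, disease) pair, counting unique patients among
#' reports received on or before `as_of_quarter`.
#'
#' @param db a cleaned `report_db`.
#' @param map an [load_grouping()] result.
#' @param as_of_quarter `"YYYYQn"` cutoff.
#' @param pairs data frame `drug_code`, `disease`; `NULL` scans every pair
#'   with at least one report at the cutoff.
#' @param n_min,chi_min,prr_min rule thresholds.
#' @return data frame: `drug_code`, `disease`, cells `a`-`d`, `n_reports`,
#'   `chisq`, `prr`, `detected`.
#' @export
compute_signals <- function(db, map, as_of_quarter, pairs = NULL,
                            n_min = 3, chi_min = 4, prr_min = 2) {
  stopifnot(inherits(db, "report_db"))
  ai <- quarter_index(as_of_quarter)
  pc <- pair_case_table(db, map)[qidx <= ai]
  mt <- margin_tables(db, map)
  counts <- pc[, .(a = .N), by = .(drug_code, disease)]
  if (is.null(pairs)) {
    tab <- counts
  } else {
    tab <- merge(as.data.table(pairs[c("drug_code", "disease")]), counts,
                 by = c("drug_code", "disease"), all.x = TRUE)
    data.table::set(tab, which(is.na(tab$a)), "a", 0L)
  }
  n_total <- nrow(mt$cases[qidx <= ai])
  nd <- mt$case_drug[qidx <= ai, .(n_drug = .N), by = drug_code]
  ns <- mt$case_disease[qidx <= ai, .(n_dis = .N), by = disease]
  tab <- merge(tab, nd, by = "drug_code", all.x = TRUE)
  tab <- merge(tab, ns, by = "disease", all.x = TRUE)
  data.table::set(tab, which(is.na(tab$n_drug)), "n_drug", 0L)
  data.table::set(tab, which(is.na(tab$n_dis)), "n_dis", 0L)
  out <- as.data.frame(tab)
  out$b <- out$n_dis - out$a
  out$c <- out$n_drug - out$a
  out$d <- n_total - out$n_dis - out$n_drug + out$a
  dec <- lapply(seq_len(nrow(out)), function(i) {
    sd <- apply_signal_rule(
      contingency_table(out$a[i], out$b[i], out$c[i], out$d[i]),
      n_min = n_min, chi_min = chi_min, prr_min = prr_min)
    c(chisq = sd$chisq, prr = sd$prr, detected = sd$detected)
  })
  dec <- as.data.frame(do.call(rbind, dec))
  out <- cbind(out[c("drug_code", "disease", "a", "b", "c", "d")],
               n_reports = out$a, dec)
  out$detected <- as.logical(out$detected)
  out[order(out$drug_code, out$disease), ]
}

#' Configure the full analysis pipeline
#'
#' @param sim a [sim_config()] describing the synthetic database (or `NULL`
#'   when passing an existing database to [run_pipeline()]).
#' @param period analysis period `c(first, last)` in `"YYYYQn"`; default =
#'   the simulated span.
#' @param lag quarters between revision announcement and feature cutoff.
#' @param split_ratio training fraction of the 0/1-labeled pairs.
#' @param cv_k cross-validation folds.
#' @param model a [model_spec()] for the final estimator.
#' @param efs_sizes subset sizes for exhaustive feature selection; `NULL`
#'   skips selection and keeps all 34 features.
#' @param efs_features candidate features for the selection (defaults to the
#'   recency, coverage and disproportionality features that dominate this kind
#'   of screen; the full 34-choose-4 enumeration is available by passing
#'   `feature_names()` and a matching budget).
#' @param tune_iterations random-search candidates for C/gamma; 0 skips
#'   tuning.
#' @param thresholds decision thresholds reported by the sweep.
#' @param seed root seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), period = NULL, lag = 2L,
                            split_ratio = 0.7, cv_k = 5L,
                            model = model_spec("rbf_svm"),
                            efs_sizes = 1:2,
                            efs_features = c("n_patients", "index_b",
                                             "new_patients_q1",
                                             "new_patients_q2",
                                             "patients_per_quarter",
                                             "quarters_since_first",
                                             "ror", "log_ror", "prr",
                                             "yates_chisq"),
                            tune_iterations = 0L,
                            thresholds = c(0.1, 0.5), seed = 1L) {
  if (is.null(period) && !is.null(sim)) {
    period <- c(sim$start_quarter,
                quarter_add(sim$start_quarter, sim$n_quarters - 1L))
  }
  structure(list(sim = sim, period = period, lag = as.integer(lag),
                 split_ratio = split_ratio, cv_k = as.integer(cv_k),
                 model = model, efs_sizes = efs_sizes,
                 efs_features = efs_features,
                 tune_iterations = as.integer(tune_iterations),
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full label-change prediction pipeline
#'
#' Orchestrates every stage on one seed: simulate (unless a database is
#' supplied), clean, build the labeled cohort, compute and impute the 34
#' features, apply the conventional signal rule and cross-tabulate it against
#' the actual revisions, then split, select features, optionally tune, fit
#' the final model and evaluate it on the held-out test set. Each stage's
#' output is returned so stages can be inspected or rerun individually, and a
#' manifest records seeds and row counts.
#'
#' @param config a [pipeline_config()].
#' @param db optionally, an existing (uncleaned) `report_db` with `revisions`
#'   and `listed` attributes taking the place of the simulation stage.
#' @param out_dir if non-`NULL`, the simulated CSV tables and a JSON manifest
#'   are written here.
#' @return list of class `pipeline_result` with elements `db` (cleaned),
#'   `exclusions`, `cohort`, `features`, `signals`, `crosstab`, `split`,
#'   `efs`, `tuning`, `model`, `report` and `manifest`.
#' @export
run_pipeline <- function(config, db = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  map <- load_grouping()

  if (is.null(db)) {
    sim <- generate_database(config$sim)
    if (!is.null(out_dir)) write_database(sim, out_dir)
    db <- report_db(sim$tables$demo, sim$tables$drug, sim$tables$reac,
                    sim$tables$hist)
    revisions <- sim$revisions
    listed <- sim$listed
  } else {
    revisions <- attr(db, "revisions")
    listed <- attr(db, "listed")
    if (is.null(revisions) || is.null(listed)) {
      stop("a supplied db needs 'revisions' and 'listed' attributes",
           call. = FALSE)
    }
  }

  clean <- clean_reports(db)
  cohort <- build_cohort(clean, revisions, listed, map, config$period,
                         lag = config$lag, seed = config$seed)
  if (!any(cohort$label == "positive")) {
    stop("cohort stage produced no positive pairs; check the revision log",
         call. = FALSE)
  }
  feats <- compute_features(cohort, clean, map)
  feats <- suppressWarnings(impute_onset_days(feats, clean, map))
  mm <- prepare_model_matrix(feats)

  revised <- unique(revisions[c("drug_code", "disease")])
  signals <- compute_signals(clean, map, config$period[2L],
                             pairs = cohort[c("drug_code", "disease")])
  crosstab <- crosstab_vs_revisions(signals, revised)

  split <- split_dataset(mm, ratio = config$split_ratio,
                         seed = config$seed + 1L)
  spec <- config$model

  efs_res <- NULL
  sel <- colnames(split$train$x)
  if (!is.null(config$efs_sizes)) {
    cand <- intersect(config$efs_features, colnames(split$train$x))
    efs_res <- efs(split$train$x, split$train$y, spec,
                   subset_sizes = config$efs_sizes, k = config$cv_k,
                   seed = config$seed + 2L, features = cand)
    sel <- efs_res$best
  }
  xtr <- split$train$x[, sel, drop = FALSE]
  xte <- split$test$x[, sel, drop = FALSE]

  tune_res <- NULL
  if (config$tune_iterations > 0 && spec$estimator == "rbf_svm") {
    tune_res <- tune_hyperparams(xtr, split$train$y, spec,
                                 iterations = config$tune_iterations,
                                 k = config$cv_k, seed = config$seed + 3L)
    spec <- tune_res$spec
  }

  cv <- cross_validate(spec, xtr, split$train$y, k = config$cv_k,
                       seed = config$seed + 4L)
  model <- train_model(spec, xtr, split$train$y)
  test_eval <- evaluate_model(model, xte, split$test$y)
  sweep <- threshold_sweep(model, xte, split$test$y,
                           thresholds = config$thresholds)

  report <- list(cv_mean = cv$mean, cv_sd = cv$sd,
                 test = test_eval$metrics, confusion = test_eval$confusion,
                 selected_features = sel, threshold_sweep = sweep)

  manifest <- data.frame(
    stage = c("simulate", "clean", "cohort", "features", "signals", "train"),
    rows = c(nrow(db$reac), nrow(clean$reac), nrow(cohort), nrow(feats),
             nrow(signals), length(split$train$y)),
    seed = c(if (is.null(config$sim)) NA_integer_ else config$sim$seed,
             NA, NA, NA, NA, config$seed),
    stringsAsFactors = FALSE)

  out <- structure(
    list(db = clean, exclusions = exclusion_log(clean), cohort = cohort,
         features = feats, signals = signals, crosstab = crosstab,
         split = split, efs = efs_res, tuning = tune_res, model = model,
         report = report, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(manifest = manifest, exclusions = out$exclusions,
           crosstab = list(table = as.vector(crosstab$table),
                           pct_detected_revised = crosstab$pct_detected_revised,
                           pct_revised_missed = crosstab$pct_revised_missed),
           report = list(cv_mean = as.list(report$cv_mean),
                         test = as.list(report$test),
                         selected_features = report$selected_features)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Planted-signal recovery benchmark configuration
#'
#' Builds the pipeline configuration for the package's standard end-to-end
#' recovery benchmark: a market of `n_drugs` prescription drugs (staggered
#' launch dates) and `n_diseases` target diseases observed over `n_quarters`
#' quarters, with `n_planted` drug-disease pairs carrying a domestic
#' package-insert revision. Each planted pair's reporting rate is
#' `rate_multiplier` times baseline during the `ramp_quarters` quarters before
#' its revision; `rate_multiplier = 1` yields the null benchmark in which the
#' "positive" labels carry no reporting signal at all, so any recovered
#' accuracy would indicate leakage.
#'
#' Revision quarters are spread over the second half of the observation
#' period, mimicking label changes arriving throughout a study window rather
#' than at its end.
#'
#' @param n_drugs,n_diseases,n_quarters market dimensions (defaults give
#'   2,250 drug-disease pairs).
#' @param n_planted number of planted positive pairs.
#' @param rate_multiplier reporting-rate multiplier during the ramp (>= 1).
#' @param ramp_quarters elevated quarters before each revision.
#' @param seed root seed (drives the planted-pair draw, the simulation and
#'   every model-side split).
#' @param ... further arguments passed to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
planted_benchmark_config <- function(n_drugs = 45, n_diseases = 50,
                                     n_quarters = 36, n_planted = 30,
                                     rate_multiplier = 16, ramp_quarters = 8,
                                     seed = 1L, ...) {
  gm <- load_grouping()
  stopifnot(n_diseases <= length(gm))
  start <- "2011Q3"
  set.seed(seed)
  # distinct planted pairs with revisions across the second half of the period
  pool <- expand.grid(drug = seq_len(n_drugs),
                      disease = names(gm)[seq_len(n_diseases)],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pick <- pool[sample.int(nrow(pool), n_planted), ]
  rev_lo <- ramp_quarters + 2L
  rev_hi <- n_quarters - 1L
  revq <- quarter_add(start, sample(max(rev_lo, n_quarters %/% 2L):rev_hi,
                                    n_planted, replace = TRUE))
  pp <- plant_pairs(pick$drug, pick$disease,
                    rate_multiplier = rate_multiplier,
                    ramp_quarters = ramp_quarters, revision_quarter = revq)
  sim <- sim_config(n_drugs = n_drugs, n_diseases = n_diseases,
                    n_quarters = n_quarters, start_quarter = start,
                    launch_spread = 2L * n_quarters %/% 3L,
                    planted_pairs = pp, otc_drug_fraction = 0.04,
                    duplicate_prob = 0.02, pre_admin_onset_prob = 0.01,
                    seed = seed + 1L)
  pipeline_config(sim = sim, seed = seed + 2L, ...)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  cohort: ", sum(x$cohort$label == "positive"), " positive / ",
      sum(x$cohort$label == "negative"), " negative pairs\n", sep = "")
  cat("  selected features: ",
      paste(x$report$selected_features, collapse = ", "), "\n", sep = "")
  cat(sprintf("  cv MCC %.3f (%.3f); test MCC %.3f, precision %.3f, recall %.3f, AUC %.3f\n",
              x$report$cv_mean[["mcc"]], x$report$cv_sd[["mcc"]],
              x$report$test[["mcc"]], x$report$test[["precision"]],
              x$report$test[["recall"]], x$report$test[["auc"]]))
  invisible(x)
}
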