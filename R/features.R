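#' Names of the 34 reporting-history features
#'
#' The feature set summarizes, for one (suspected drug, target disease) pair
#' and one as-of quarter, everything pharmacovigilance assessors weigh when
#' judging whether accumulated domestic cases warrant a label change:
#' cumulative patient counts (total, deaths, rechallenges, discontinuations),
#' time-to-onset summaries (mean/median days from administration to onset and
#' patients with onset within 15/30/90 days), per-case report quality (mean
#' missing fields per case, mean reports to the authority per case), the
#' relative-coverage indexes A and B, recency (quarters since the first
#' report, new patients in each of the last four quarters, new
#' deaths/rechallenges/discontinuations/short-onset patients in the last
#' quarter, mean patients per quarter) and disproportionality (PRR, log PRR
#' and its confidence bounds, Yates chi-squared, ROR, log ROR and its bounds).
#'
#' @return character vector of 34 feature column names, in canonical order.
#' @export
feature_names <- function() {
  c("n_patients", "n_deaths", "n_rechallenge", "n_discontinued",
    "onset_days_mean", "onset_days_median",
    "n_onset_within_15", "n_onset_within_30", "n_onset_within_90",
    "missing_per_case", "reports_per_case",
    "index_a", "index_b",
    "quarters_since_first",
    "new_patients_q1", "new_patients_q2", "new_patients_q3", "new_patients_q4",
    "new_deaths_q1", "new_rechallenge_q1", "new_discontinued_q1",
    "new_onset15_q1", "new_onset30_q1", "new_onset90_q1",
    "patients_per_quarter",
    "prr", "log_prr", "prr_ci_low", "prr_ci_high", "yates_chisq",
    "ror", "log_ror", "ror_ci_low", "ror_ci_high")
}

# pair-case table: one row per (drug, disease, case) with everything the
# per-pair aggregations need; built once per database
pair_case_table <- function(db, map) {
  demo <- as.data.table(db$demo)
  reac <- as.data.table(db$reac)
  sus <- as.data.table(db$drug)[role == "suspected"]
  if (nrow(reac) == 0 || nrow(sus) == 0) {
    return(data.table(drug_code = character(0), disease = character(0),
                      case_id = character(0), qidx = integer(0),
                      days = numeric(0), death = logical(0),
                      rechal = logical(0), disc = logical(0),
                      miss_total = numeric(0), version = integer(0)))
  }
  reac[, disease := map_pt(pt_name, map)]
  reac <- reac[!is.na(disease)]
  if (nrow(reac) == 0) return(pair_case_table(list(
    demo = db$demo, drug = db$drug[0, ], reac = db$reac[0, ],
    hist = db$hist), map))
  reac[, onset := as.Date(onset_date, format = "%Y-%m-%d")]
  sus[, start := as.Date(start_date, format = "%Y-%m-%d")]
  # earliest recorded start per (case, drug); flags collapsed per (case, drug)
  sus_agg <- sus[, .(
    start = if (all(is.na(start))) as.Date(NA) else min(start, na.rm = TRUE),
    rechal = any(rechallenge == "readministered"),
    disc = any(action == "discontinued")), by = .(case_id, drug_code)]
  m <- merge(reac[, .(case_id, disease, onset, outcome)], sus_agg,
             by = "case_id", allow.cartesian = TRUE)
  pc <- m[, .(
    days = {
      dd <- as.numeric(onset - start)
      dd <- dd[!is.na(dd)]
      if (length(dd) == 0) NA_real_ else min(dd)
    },
    death = any(outcome == "death", na.rm = TRUE),
    onset_missing = all(is.na(onset)),
    start_missing = all(is.na(start)),
    outcome_missing = all(is.na(outcome) | outcome == "unknown"),
    rechal = any(rechal), disc = any(disc)),
    by = .(drug_code, disease, case_id)]
  # per-case report quality: missing demographics + dates + outcome + history
  hist_cases <- unique(db$hist$case_id)
  demo_m <- demo[, .(case_id, version = as.integer(version),
                     qidx = quarter_index(quarter_received),
                     miss_base = is.na(sex) + is.na(age_band) +
                       is.na(weight_band) + !(case_id %in% hist_cases))]
  pc <- merge(pc, demo_m, by = "case_id")
  pc[, miss_total := miss_base + onset_missing + start_missing +
       outcome_missing]
  pc[, c("onset_missing", "start_missing", "outcome_missing",
         "miss_base") := NULL]
  pc
}

# case-level margin tables for contingency counting
margin_tables <- function(db, map) {
  reac <- as.data.table(db$reac)
  sus <- as.data.table(db$drug)[role == "suspected"]
  demo <- as.data.table(db$demo)[, .(case_id,
                                     qidx = quarter_index(quarter_received))]
  ids <- intersect(unique(reac$case_id), unique(sus$case_id))
  demo <- demo[case_id %in% ids]
  cd <- unique(sus[case_id %in% ids, .(case_id, drug_code)])
  dis <- map_pt(reac$pt_name, map)
  cdis <- unique(data.table(case_id = reac$case_id,
                            disease = dis)[!is.na(disease) & case_id %in% ids])
  cd <- merge(cd, demo, by = "case_id")
  cdis <- merge(cdis, demo, by = "case_id")
  list(cases = demo, case_drug = cd, case_disease = cdis)
}

#' Compute the 34-feature vector for each labeled pair
#'
#' For every row of the cohort, aggregates the cleaned reports received on or
#' before that pair's as-of quarter (suspected-role drug entries only) into
#' the feature set listed by [feature_names()]. Features are a pure function
#' of the pair and the reports at or before its cutoff: reports received in
#' later quarters cannot influence the result.
#'
#' Counting conventions: patients are unique case ids; "new patients from k
#' quarters ago" counts patients whose case was received exactly in quarter
#' `as_of - (k - 1)` (so k = 1 is the as-of quarter itself, and the four
#' windows are disjoint); "quarters since first report" counts quarters from
#' the first report's quarter through the as-of quarter, both inclusive;
#' days to onset is `onset date - suspected drug start date` in whole days
#' (per patient, the earliest such interval); the mean number of missing
#' values per case counts empty entries among sex, age, weight, onset date,
#' drug start date, outcome and medical history; reports per case is the mean
#' number of reports the authority received per case (the case version).
#'
#' Pairs with no reports at the cutoff get zero counts with the time-to-onset
#' summaries missing (see [impute_onset_days()]). Disproportionality values
#' that are undefined for the pair's contingency table (zero cells) are
#' returned as `NA` and flagged in `dispro_undefined`; [prepare_model_matrix()]
#' encodes them as 0 on the log scale before modeling.
#'
#' @param cohort a `labeled_cohort` from [build_cohort()], or any data frame
#'   with columns `drug_code`, `disease`, `as_of_quarter` (extra columns such
#'   as `label` are carried through).
#' @param db a cleaned `report_db`.
#' @param map an [load_grouping()] result.
#' @param level confidence level for the PRR/ROR intervals.
#' @return data frame: the cohort's columns, the 34 features, and the logical
#'   flags `dispro_undefined` and `onset_observed`.
#' @export
compute_features <- function(cohort, db, map, level = 0.95) {
  stopifnot(inherits(db, "report_db"))
  need <- c("drug_code", "disease", "as_of_quarter")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pc <- pair_case_table(db, map)
  mt <- margin_tables(db, map)
  meta <- as.data.table(as.data.frame(cohort))
  meta[, as_idx := quarter_index(as_of_quarter)]

  out <- vector("list", length(unique(meta$as_idx)))
  i <- 0L
  for (ai in sort(unique(meta$as_idx))) {
    i <- i + 1L
    batch <- meta[as_idx == ai]
    pcs <- pc[qidx <= ai][batch[, .(drug_code, disease)], , nomatch = NULL,
              on = c("drug_code", "disease")]
    agg <- if (nrow(pcs) == 0) NULL else pcs[, .(
      n_patients = .N,
      n_deaths = sum(death),
      n_rechallenge = sum(rechal),
      n_discontinued = sum(disc),
      onset_days_mean = if (all(is.na(days))) NA_real_
                        else mean(days, na.rm = TRUE),
      onset_days_median = if (all(is.na(days))) NA_real_
                          else stats::median(days, na.rm = TRUE),
      n_onset_within_15 = sum(days <= 15, na.rm = TRUE),
      n_onset_within_30 = sum(days <= 30, na.rm = TRUE),
      n_onset_within_90 = sum(days <= 90, na.rm = TRUE),
      missing_per_case = mean(miss_total),
      reports_per_case = mean(version),
      quarters_since_first = ai - min(qidx) + 1L,
      new_patients_q1 = sum(qidx == ai),
      new_patients_q2 = sum(qidx == ai - 1L),
      new_patients_q3 = sum(qidx == ai - 2L),
      new_patients_q4 = sum(qidx == ai - 3L),
      new_deaths_q1 = sum(death & qidx == ai),
      new_rechallenge_q1 = sum(rechal & qidx == ai),
      new_discontinued_q1 = sum(disc & qidx == ai),
      new_onset15_q1 = sum(days <= 15 & qidx == ai, na.rm = TRUE),
      new_onset30_q1 = sum(days <= 30 & qidx == ai, na.rm = TRUE),
      new_onset90_q1 = sum(days <= 90 & qidx == ai, na.rm = TRUE)),
      by = .(drug_code, disease)]
    res <- if (is.null(agg)) data.table::copy(batch) else
      merge(batch, agg, by = c("drug_code", "disease"), all.x = TRUE)
    # pairs without any report at the cutoff: zero counts, missing onset
    count_cols <- c("n_patients", "n_deaths", "n_rechallenge",
                    "n_discontinued", "n_onset_within_15",
                    "n_onset_within_30", "n_onset_within_90",
                    "quarters_since_first", "new_patients_q1",
                    "new_patients_q2", "new_patients_q3", "new_patients_q4",
                    "new_deaths_q1", "new_rechallenge_q1",
                    "new_discontinued_q1", "new_onset15_q1", "new_onset30_q1",
                    "new_onset90_q1")
    for (col in count_cols) {
      if (!col %in% names(res)) res[, (col) := NA_integer_]
      data.table::set(res, which(is.na(res[[col]])), col, 0L)
    }
    for (col in c("missing_per_case", "reports_per_case")) {
      if (!col %in% names(res)) res[, (col) := NA_real_]
      data.table::set(res, which(is.na(res[[col]])), col, 0)
    }
    for (col in c("onset_days_mean", "onset_days_median")) {
      if (!col %in% names(res)) res[, (col) := NA_real_]
    }
    res[, patients_per_quarter :=
          ifelse(n_patients > 0, n_patients / quarters_since_first, 0)]

    # contingency margins at this cutoff
    n_total <- nrow(mt$cases[qidx <= ai])
    nd <- mt$case_drug[qidx <= ai, .(n_drug = .N), by = drug_code]
    ns <- mt$case_disease[qidx <= ai, .(n_dis = .N), by = disease]
    res <- merge(res, nd, by = "drug_code", all.x = TRUE)
    res <- merge(res, ns, by = "disease", all.x = TRUE)
    data.table::set(res, which(is.na(res$n_drug)), "n_drug", 0L)
    data.table::set(res, which(is.na(res$n_dis)), "n_dis", 0L)

    ds <- lapply(seq_len(nrow(res)), function(j) {
      a <- res$n_patients[j]
      t <- contingency_table(a, res$n_dis[j] - a, res$n_drug[j] - a,
                             n_total - res$n_dis[j] - res$n_drug[j] + a)
      r <- ror(t, level = level)
      p <- prr(t, level = level)
      ix <- index_ab(t)
      c(index_a = unname(ix["index_a"]), index_b = unname(ix["index_b"]),
        prr = p$value, log_prr = p$log_value, prr_ci_low = p$ci_low,
        prr_ci_high = p$ci_high, yates_chisq = yates_chisq(t),
        ror = r$value, log_ror = r$log_value, ror_ci_low = r$ci_low,
        ror_ci_high = r$ci_high)
    })
    ds <- as.data.table(do.call(rbind, ds))
    res <- cbind(res, ds)
    res[, c("n_drug", "n_dis", "as_idx") := NULL]
    out[[i]] <- res
  }
  out <- data.table::rbindlist(out, use.names = TRUE)
  out[, dispro_undefined := is.na(ror) | is.na(prr) | is.na(yates_chisq)]
  out[, onset_observed := !is.na(onset_days_mean)]
  lead <- intersect(names(cohort), names(out))
  data.table::setcolorder(out, c(lead, setdiff(feature_names(), lead)))
  out <- as.data.frame(out)
  class(out) <- c("pair_features", "data.frame")
  out
}

#' Impute missing time-to-onset summaries from other drugs
#'
#' Pairs whose cases all lack usable administration/onset dates have missing
#' mean/median days to onset. Following standard practice for this feature,
#' the substitute is the median time to onset of the *same* reaction on other
#' prescription drugs: for each disease the per-drug median days are computed
#' from reports at the pair's as-of cutoff, and the median across donor drugs
#' (excluding the pair's own drug) replaces both missing fields. Pairs with an
#' observed value are untouched. If no donor drug has onset data for a
#' disease, the value stays missing and a warning is raised.
#'
#' @param features a `pair_features` data frame from [compute_features()].
#' @param db the cleaned `report_db` the features were computed from.
#' @param map an [load_grouping()] result.
#' @return `features` with `onset_days_mean`/`onset_days_median` imputed where
#'   possible and a logical `onset_imputed` column added.
#' @export
impute_onset_days <- function(features, db, map) {
  stopifnot(is.data.frame(features))
  pc <- pair_case_table(db, map)
  out <- as.data.table(as.data.frame(features))
  out[, onset_imputed := FALSE]
  need <- which(is.na(out$onset_days_mean) | is.na(out$onset_days_median))
  if (length(need) == 0) {
    out <- as.data.frame(out)
    class(out) <- c("pair_features", "data.frame")
    return(out)
  }
  failed <- character(0)
  for (ai in unique(quarter_index(out$as_of_quarter[need]))) {
    rows <- need[quarter_index(out$as_of_quarter[need]) == ai]
    donors <- pc[qidx <= ai & !is.na(days),
                 .(med_days = stats::median(days)),
                 by = .(drug_code, disease)]
    for (j in rows) {
      dd <- donors[disease == out$disease[j] & drug_code != out$drug_code[j],
                   med_days]
      if (length(dd) == 0) {
        failed <- c(failed, out$disease[j])
      } else {
        v <- stats::median(dd)
        if (is.na(out$onset_days_mean[j])) {
          data.table::set(out, j, "onset_days_mean", v)
        }
        if (is.na(out$onset_days_median[j])) {
          data.table::set(out, j, "onset_days_median", v)
        }
        data.table::set(out, j, "onset_imputed", TRUE)
      }
    }
  }
  if (length(failed) > 0) {
    warning("no donor onset data for disease(s): ",
            paste(unique(failed), collapse = ", "),
            "; time-to-onset left missing", call. = FALSE)
  }
  out <- as.data.frame(out)
  class(out) <- c("pair_features", "data.frame")
  out
}

#' Prepare a complete numeric model matrix from a feature table
#'
#' Encodes the conventions used before model fitting: undefined
#' disproportionality statistics become 0 (the log scale's null value) and any
#' residual missing time-to-onset summary becomes 0; the 34 feature columns
#' are returned as a numeric matrix alongside the 0/1 label vector.
#'
#' @param features a `pair_features` data frame (after [impute_onset_days()]).
#' @return list with `x` (numeric matrix, one column per feature), `y`
#'   (integer 0/1, 1 = positive; `NULL` if the table has no `label` column)
#'   and `meta` (the non-feature columns).
#' @export
prepare_model_matrix <- function(features) {
  fn <- feature_names()
  miss <- setdiff(fn, names(features))
  if (length(miss) > 0) {
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(as.data.frame(features)[fn])
  storage.mode(x) <- "double"
  x[is.na(x)] <- 0
  y <- if ("label" %in% names(features)) {
    as.integer(features$label == "positive")
  }
  list(x = x, y = y,
       meta = as.data.frame(features)[setdiff(names(features), fn)])
}
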