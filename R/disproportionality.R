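#' 2 x 2 contingency table for a drug-disease pair
#'
#' Every disproportionality statistic rests on the patient-level 2 x 2 table
#' for a (suspected drug, target disease) pair:
#' `a` = patients with the target reaction on the suspected drug, `b` =
#' patients with the target reaction on all other drugs, `c` = patients with
#' other reactions on the suspected drug, `d` = patients with other reactions
#' on all other drugs. Patients are unique case ids; a patient counts toward
#' the drug margin when the drug appears among their suspected-role entries
#' and toward the disease margin when any of their reported preferred terms
#' maps to the disease.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return list of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(round(cells)), names(cells))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d, "\n",
      sep = "")
  invisible(x)
}

#' Tabulate a pair's contingency table from cleaned reports
#'
#' Counts unique patients among reports received on or before `as_of_quarter`,
#' using suspected-role drug entries only. Patients with no retained reaction
#' record (or no suspected drug entry) do not enter the table.
#'
#' @param db a cleaned `report_db` (see [clean_reports()]).
#' @param drug drug code of interest.
#' @param disease target disease name (must exist in `map`).
#' @param map an [load_grouping()] result used to map preferred terms to the
#'   disease.
#' @param as_of_quarter `"YYYYQn"` cutoff; reports received later are ignored.
#' @return a `contingency_table`.
#' @export
contingency_from_reports <- function(db, drug, disease, map, as_of_quarter) {
  stopifnot(inherits(db, "report_db"))
  if (!disease %in% names(map)) {
    stop("unknown disease '", disease, "': not in the grouping map",
         call. = FALSE)
  }
  cs <- case_summaries(db, map, quarter_index(as_of_quarter))
  on_drug <- vapply(cs$drugs, function(d) drug %in% d, NA)
  has_dis <- vapply(cs$diseases, function(d) disease %in% d, NA)
  contingency_table(a = sum(on_drug & has_dis), b = sum(!on_drug & has_dis),
                    c = sum(on_drug & !has_dis), d = sum(!on_drug & !has_dis))
}

# per-case suspected-drug and disease sets at a cutoff; cases need >= 1
# retained reaction and >= 1 suspected drug entry to be classifiable
case_summaries <- function(db, map, as_of_idx) {
  demo <- db$demo
  keep <- demo$case_id[quarter_index(demo$quarter_received) <= as_of_idx]
  reac <- db$reac[db$reac$case_id %in% keep, , drop = FALSE]
  sus <- db$drug[db$drug$role == "suspected" & db$drug$case_id %in% keep, ,
                 drop = FALSE]
  ids <- intersect(unique(reac$case_id), unique(sus$case_id))
  reac <- reac[reac$case_id %in% ids, , drop = FALSE]
  sus <- sus[sus$case_id %in% ids, , drop = FALSE]
  dis <- map_pt(reac$pt_name, map)
  list(case_id = ids,
       drugs = split(sus$drug_code, factor(sus$case_id, levels = ids)),
       diseases = split(dis, factor(reac$case_id, levels = ids)))
}

z_level <- function(level) stats::qnorm(1 - (1 - level) / 2)

stat_result <- function(value, se_log = NA_real_, level = 0.95) {
  if (is.na(value) || value <= 0 || is.na(se_log)) {
    lo <- hi <- NA_real_
  } else {
    z <- z_level(level)
    lo <- exp(log(value) - z * se_log)
    hi <- exp(log(value) + z * se_log)
  }
  structure(list(value = value,
                 log_value = if (is.na(value) || value <= 0) NA_real_
                             else log(value),
                 ci_low = lo, ci_high = hi, level = level),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%.4g (log %.4g) [%.4g, %.4g] @%g%%\n", x$value, x$log_value,
              x$ci_low, x$ci_high, 100 * x$level))
  invisible(x)
}

haldane_shift <- function(t, haldane) {
  if (haldane) lapply(t[c("a", "b", "c", "d")], function(x) x + 0.5)
  else t[c("a", "b", "c", "d")]
}

#' Reporting odds ratio
#'
#' `ROR = (a/c) / (b/d) = ad/bc`, with a log-scale Wald confidence interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When `b*c = 0` (or, for
#' the interval, any cell is 0) the statistic is undefined and reported as
#' `NA` — undefined is a value here, not an error.
#'
#' @param t a `contingency_table`.
#' @param level confidence level for the interval.
#' @param haldane if `TRUE`, add the Haldane continuity correction of 0.5 to
#'   every cell before computing (off by default; the plain formula has no
#'   correction).
#' @return a `stat_result` with elements `value`, `log_value`, `ci_low`,
#'   `ci_high`, `level`.
#' @examples
#' ror(contingency_table(10, 20, 30, 240))  # 4.0
#' @export
ror <- function(t, level = 0.95, haldane = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  x <- haldane_shift(t, haldane)
  if (x$b * x$c == 0) return(stat_result(NA_real_, level = level))
  value <- (x$a * x$d) / (x$b * x$c)
  se <- if (x$a == 0 || x$d == 0) NA_real_
        else sqrt(1 / x$a + 1 / x$b + 1 / x$c + 1 / x$d)
  stat_result(value, se, level)
}

#' Proportional reporting ratio
#'
#' `PRR = (a/(a+c)) / (b/(b+d)) = a(b+d) / (b(a+c))`, with the standard
#' log-scale Wald interval
#' `exp(ln PRR +/- z * sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d)))`. Undefined (`NA`)
#' when the denominator `b * (a + c)` is 0.
#'
#' @inheritParams ror
#' @return a `stat_result`.
#' @examples
#' prr(contingency_table(10, 20, 30, 240))  # 3.25
#' @export
prr <- function(t, level = 0.95, haldane = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  x <- haldane_shift(t, haldane)
  if (x$b * (x$a + x$c) == 0) return(stat_result(NA_real_, level = level))
  value <- (x$a * (x$b + x$d)) / (x$b * (x$a + x$c))
  se <- if (x$a == 0) NA_real_
        else sqrt(1 / x$a - 1 / (x$a + x$c) + 1 / x$b - 1 / (x$b + x$d))
  stat_result(value, se, level)
}

#' Yates-corrected chi-squared statistic
#'
#' Pearson's chi-squared test statistic with Yates' continuity correction,
#' `N * (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))` with `N = a+b+c+d`,
#' floored at 0 when `|ad - bc| <= N/2` (the correction would otherwise
#' overshoot past independence). `NA` when any margin is 0.
#'
#' @param t a `contingency_table`.
#' @return a single numeric value (`NA` if undefined).
#' @examples
#' yates_chisq(contingency_table(10, 20, 30, 240))  # ~9.695
#' @export
yates_chisq <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) return(NA_real_)
  dev <- abs(a * d - b * c)
  if (dev <= n / 2) return(0)
  n * (dev - n / 2)^2 / prod(margins)
}

#' Index A and Index B
#'
#' Two relative-coverage percentages: Index A = `100 * a / (a + c)`, the share
#' of the suspected drug's reported reactions that are the target reaction;
#' Index B = `100 * a / (a + b)`, the share of the target reaction's reports
#' that the suspected drug accounts for. `NA` when the respective denominator
#' is 0.
#'
#' @param t a `contingency_table`.
#' @return named numeric vector `c(index_a =, index_b =)`, each in \[0, 100\]
#'   when defined.
#' @examples
#' index_ab(contingency_table(10, 20, 30, 240))  # A = 25, B = 33.33
#' @export
index_ab <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  c(index_a = if (t$a + t$c == 0) NA_real_ else 100 * t$a / (t$a + t$c),
    index_b = if (t$a + t$b == 0) NA_real_ else 100 * t$a / (t$a + t$b))
}

#' Conventional signal-detection rule
#'
#' The thresholds commonly applied in spontaneous-report screening: a signal
#' is flagged when the cumulative number of reports (cell `a`, unique
#' patients) is at least `n_min`, the Yates-corrected chi-squared is at least
#' `chi_min`, and the PRR is at least `prr_min`. An undefined statistic fails
#' its threshold.
#'
#' @param t a `contingency_table`.
#' @param n_min,chi_min,prr_min thresholds (defaults 3, 4, 2).
#' @return list of class `signal_decision`: `n_reports`, `chisq`, `prr`,
#'   `detected`.
#' @export
apply_signal_rule <- function(t, n_min = 3, chi_min = 4, prr_min = 2) {
  stopifnot(inherits(t, "contingency_table"))
  chi <- yates_chisq(t)
  pr <- prr(t)$value
  det <- t$a >= n_min && !is.na(chi) && chi >= chi_min &&
    !is.na(pr) && pr >= prr_min
  structure(list(n_reports = t$a, chisq = chi, prr = pr, detected = det),
            class = "signal_decision")
}

#' Cross-tabulate signal detections against package-insert revisions
#'
#' Summarizes how the conventional disproportionality rule relates to actual
#' label changes: the 2 x 2 of detected x revised, the percentage of detected
#' signals that led to a revision (reported to the nearest integer, as these
#' figures are conventionally printed), and the percentage of revised pairs
#' the rule missed (one decimal).
#'
#' @param decisions data frame with columns `drug_code`, `disease`, `detected`
#'   (logical), one row per pair; alternatively a list of `signal_decision`
#'   objects plus `pairs` giving their pair ids.
#' @param revised_pairs data frame with columns `drug_code`, `disease` listing
#'   every pair whose disease was added to the drug's package insert. Every
#'   decision pair must have a known status, i.e. the decisions must cover all
#'   revised pairs being assessed.
#' @return list with `table` (2 x 2 integer matrix, detection x revision),
#'   `pct_detected_revised`, `pct_revised_missed` (both `NA` when their margin
#'   is empty).
#' @examples
#' crosstab_counts(35, 824, 53, 5896)
#' @export
crosstab_vs_revisions <- function(decisions, revised_pairs) {
  need <- c("drug_code", "disease", "detected")
  if (!is.data.frame(decisions) || !all(need %in% names(decisions))) {
    stop("decisions must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyNA(decisions$detected)) {
    stop("pair with unknown detection status in decisions", call. = FALSE)
  }
  key <- function(d) paste(d$drug_code, d$disease, sep = "\r")
  revised_key <- key(revised_pairs)
  missing_rev <- setdiff(revised_key, key(decisions))
  if (length(missing_rev) > 0) {
    stop("revised pair(s) without a signal decision: ",
         gsub("\r", " / ", missing_rev[1L]), call. = FALSE)
  }
  revised <- key(decisions) %in% revised_key
  crosstab_counts(sum(decisions$detected & revised),
                  sum(decisions$detected & !revised),
                  sum(!decisions$detected & revised),
                  sum(!decisions$detected & !revised))
}

#' @param det_rev,det_norev,miss_rev,miss_norev the four detected x revised
#'   cell counts, for summarizing an already-tabulated cross-classification.
#' @rdname crosstab_vs_revisions
#' @export
crosstab_counts <- function(det_rev, det_norev, miss_rev, miss_norev) {
  tab <- matrix(as.integer(c(det_rev, det_norev, miss_rev, miss_norev)),
                nrow = 2, byrow = TRUE,
                dimnames = list(detected = c("yes", "no"),
                                revised = c("yes", "no")))
  n_det <- det_rev + det_norev
  n_rev <- det_rev + miss_rev
  list(table = tab,
       pct_detected_revised = if (n_det == 0) NA_real_
                              else round(100 * det_rev / n_det),
       pct_revised_missed = if (n_rev == 0) NA_real_
                            else round(100 * miss_rev / n_rev, 1))
}
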