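#' Assemble an in-memory report database
#'
#' Bundles the four spontaneous-reporting tables into a validated `report_db`
#' object. DEMO holds one row per case (patient) with its demographics, the
#' quarter the case was received and `version`, the number of reports the
#' authority received for the case; DRUG holds one row per drug entry with its
#' role (`suspected`, `concomitant` or `interacting`); REAC holds one row per
#' reported reaction (case x reaction records are the unit all cleaning and
#' counting operate on); HIST holds medical-history conditions.
#'
#' @param demo,drug,reac,hist data frames with the documented column schemas
#'   (see [load_reports()]).
#' @return an object of class `report_db`.
#' @export
report_db <- function(demo, drug, reac, hist) {
  db <- list(demo = demo, drug = drug, reac = reac, hist = hist)
  validate_report_db(db, src = "report_db()")
  structure(db, class = "report_db")
}

db_schema <- list(
  demo = c("case_id", "version", "sex", "age_band", "weight_band",
           "quarter_received"),
  drug = c("case_id", "drug_code", "role", "start_date", "otc_flag", "action",
           "rechallenge"),
  reac = c("case_id", "pt_name", "onset_date", "outcome"),
  hist = c("case_id", "condition"))

parse_iso_date <- function(x, what, src) {
  x[!is.na(x) & x == ""] <- NA_character_
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad) > 0) {
    stop("unparseable ", what, " in ", src, " at row ", bad[1L], ": '",
         x[bad[1L]], "' (expected YYYY-MM-DD)", call. = FALSE)
  }
  d
}

validate_report_db <- function(db, src = "input") {
  for (tb in names(db_schema)) {
    df <- db[[tb]]
    if (!is.data.frame(df)) {
      stop("table '", tb, "' missing or not a data frame in ", src,
           call. = FALSE)
    }
    miss <- setdiff(db_schema[[tb]], names(df))
    if (length(miss) > 0) {
      stop("schema mismatch in ", src, " table '", tb, "': missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  demo <- db$demo
  if (anyNA(demo$case_id) || any(demo$case_id == "")) {
    stop("empty case_id in demo table (", src, ")", call. = FALSE)
  }
  if (anyDuplicated(demo$case_id)) {
    stop("duplicated case_id in demo table (", src, "): ",
         demo$case_id[duplicated(demo$case_id)][1L], call. = FALSE)
  }
  v <- suppressWarnings(as.integer(demo$version))
  if (nrow(demo) > 0 && (anyNA(v) || any(v < 1L))) {
    stop("demo 'version' must be an integer >= 1 (", src, ")", call. = FALSE)
  }
  quarter_index(demo$quarter_received)  # errors on malformed quarters
  for (tb in c("drug", "reac", "hist")) {
    orphan <- setdiff(db[[tb]]$case_id, demo$case_id)
    if (length(orphan) > 0) {
      stop("table '", tb, "' (", src, ") references case_id absent from demo: ",
           paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
    }
  }
  ok_role <- c("suspected", "concomitant", "interacting")
  bad <- setdiff(unique(db$drug$role), ok_role)
  if (length(bad) > 0) {
    stop("drug 'role' (", src, ") outside {",
         paste(ok_role, collapse = ", "), "}: ", bad[1L], call. = FALSE)
  }
  if (nrow(db$reac) > 0 && (anyNA(db$reac$pt_name) || any(db$reac$pt_name == ""))) {
    stop("empty pt_name in reac table (", src, ")", call. = FALSE)
  }
  invisible(db)
}

#' Load report tables from CSV files
#'
#' Reads the four report tables written by [write_database()] (or prepared by
#' hand to the same schema), parses dates, and enforces referential integrity:
#' every `case_id` in DRUG/REAC/HIST must exist in DEMO. Column schemas:
#' `demo.csv` = case_id, version, sex, age_band, weight_band, quarter_received;
#' `drug.csv` = case_id, drug_code, role, start_date, otc_flag, action,
#' rechallenge; `reac.csv` = case_id, pt_name, onset_date, outcome;
#' `hist.csv` = case_id, condition. Dates are ISO-8601; empty strings are
#' missing values.
#'
#' @param dir directory containing `demo.csv`, `drug.csv`, `reac.csv`,
#'   `hist.csv`; alternatively a named list/vector of the four file paths.
#' @return a `report_db`.
#' @export
load_reports <- function(dir) {
  paths <- if (is.character(dir) && length(dir) == 1L && dir.exists(dir)) {
    stats::setNames(file.path(dir, paste0(names(db_schema), ".csv")),
                    names(db_schema))
  } else {
    unlist(dir)
  }
  if (!all(names(db_schema) %in% names(paths))) {
    stop("load_reports needs paths named ",
         paste(names(db_schema), collapse = ", "), call. = FALSE)
  }
  db <- lapply(names(db_schema), function(tb) {
    p <- paths[[tb]]
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
    df <- utils::read.csv(p, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
    miss <- setdiff(db_schema[[tb]], names(df))
    if (length(miss) > 0) {
      stop("schema mismatch in ", p, ": missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    df
  })
  names(db) <- names(db_schema)
  db$demo$version <- suppressWarnings(as.integer(db$demo$version))
  db$drug$otc_flag <- suppressWarnings(as.integer(db$drug$otc_flag))
  # validate date columns eagerly so a bad row is reported with its location
  parse_iso_date(db$drug$start_date, "start_date", paths[["drug"]])
  parse_iso_date(db$reac$onset_date, "onset_date", paths[["reac"]])
  validate_report_db(db, src = "loaded files")
  structure(db, class = "report_db")
}

#' Apply the study's exclusion rules to a report database
#'
#' Removes, in order, case x reaction records that are unsuitable for
#' disproportionality tabulation:
#' 1. records whose reaction onset date precedes the earliest start date among
#'    the case's suspected drugs (a recording anomaly — the reaction predates
#'    exposure); records missing either date are retained, since precedence
#'    cannot be established;
#' 2. duplicate records sharing (case id, preferred term, onset date), keeping
#'    one record of each set (rows are canonically ordered first, so the
#'    retained set does not depend on input row order);
#' 3. records of cases whose suspected drug is an over-the-counter product.
#'
#' The operation is idempotent and every input record is accounted for:
#' exclusion counts plus retained records equal the input record count.
#' All downstream tabulation uses suspected-role drug entries only.
#'
#' @param db a `report_db` from [load_reports()], [report_db()] or a previous
#'   `clean_reports()` call.
#' @return the cleaned `report_db`, with the exclusion log attached (retrieve
#'   it with [exclusion_log()]).
#' @export
clean_reports <- function(db) {
  stopifnot(inherits(db, "report_db"))
  reac <- db$reac
  n_in <- nrow(reac)
  sus <- db$drug[db$drug$role == "suspected", , drop = FALSE]

  log <- c(pre_admin_onset = 0L, duplicate = 0L, otc = 0L)
  if (n_in > 0) {
    # rule 1: onset strictly before the earliest suspected start date
    start <- parse_iso_date(sus$start_date, "start_date", "drug table")
    first_start <- tapply(start, sus$case_id, function(x) {
      if (all(is.na(x))) NA else min(x, na.rm = TRUE)
    })
    onset <- parse_iso_date(reac$onset_date, "onset_date", "reac table")
    fs <- as.Date(unname(first_start[reac$case_id]),
                  origin = as.Date("1970-01-01"))
    pre <- !is.na(onset) & !is.na(fs) & onset < fs
    log["pre_admin_onset"] <- sum(pre)
    reac <- reac[!pre, , drop = FALSE]

    # rule 2: one record per (case_id, pt, onset date); canonical row order
    # makes the retained multiset independent of input order
    key <- paste(reac$case_id, normalize_pt(reac$pt_name),
                 ifelse(is.na(reac$onset_date), "<missing>", reac$onset_date),
                 sep = "\r")
    ord <- order(key, reac$outcome, method = "radix")
    reac <- reac[ord, , drop = FALSE]
    dup <- duplicated(key[ord])
    log["duplicate"] <- sum(dup)
    reac <- reac[!dup, , drop = FALSE]

    # rule 3: suspected drug is over-the-counter
    otc_cases <- unique(sus$case_id[!is.na(sus$otc_flag) & sus$otc_flag == 1L])
    otc <- reac$case_id %in% otc_cases
    log["otc"] <- sum(otc)
    reac <- reac[!otc, , drop = FALSE]
    rownames(reac) <- NULL
  }

  out <- db
  out$reac <- reac
  attr(out, "exclusions") <- list(
    pre_admin_onset = unname(log["pre_admin_onset"]),
    duplicate = unname(log["duplicate"]),
    otc = unname(log["otc"]),
    retained = nrow(reac),
    input = n_in)
  attr(out, "cleaned") <- TRUE
  out
}

#' Exclusion log of a cleaned report database
#'
#' @param db a `report_db` returned by [clean_reports()].
#' @return list with counts `pre_admin_onset`, `duplicate`, `otc`, `retained`
#'   and `input` (the record = case x reaction row count before cleaning).
#' @export
exclusion_log <- function(db) {
  log <- attr(db, "exclusions")
  if (is.null(log)) stop("no exclusion log: run clean_reports() first",
                         call. = FALSE)
  log
}

#' @export
print.report_db <- function(x, ...) {
  cat("<report_db> ", nrow(x$demo), " cases, ", nrow(x$reac),
      " reaction records, ", nrow(x$drug), " drug entries",
      if (isTRUE(attr(x, "cleaned"))) " (cleaned)", "\n", sep = "")
  invisible(x)
}
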