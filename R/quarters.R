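#' Quarter identifiers
#'
#' Calendar quarters are written `"YYYYQn"` (e.g. `"2019Q4"`) throughout the
#' package: in the simulated report tables, the revision log, and every as-of
#' cutoff. Internally a quarter is an integer index (`year * 4 + quarter - 1`)
#' so that arithmetic and ordering never depend on string comparison.
#'
#' @param q character vector of `"YYYYQn"` quarter ids.
#' @param idx integer vector of quarter indices.
#' @param k integer number of quarters to add (may be negative).
#' @param date a `Date` vector.
#' @return `quarter_index()` returns an integer vector; `index_to_quarter()`
#'   and `quarter_add()` return `"YYYYQn"` strings; `quarter_of_date()` returns
#'   the `"YYYYQn"` quarter containing each date.
#' @examples
#' quarter_add("2020Q1", -2)  # "2019Q3"
#' quarter_of_date(as.Date("2019-07-15"))
#' @name quarters
NULL

#' @rdname quarters
#' @export
quarter_index <- function(q) {
  m <- regmatches(q, regexec("^([0-9]{4})Q([1-4])$", as.character(q)))
  bad <- vapply(m, length, 0L) != 3L & !is.na(q)
  if (any(bad)) {
    stop("malformed quarter id(s): ", paste(unique(q[bad]), collapse = ", "),
         " (expected \"YYYYQn\")", call. = FALSE)
  }
  out <- rep(NA_integer_, length(q))
  ok <- !is.na(q)
  if (any(ok)) {
    yr <- as.integer(vapply(m[ok], `[`, "", 2L))
    qn <- as.integer(vapply(m[ok], `[`, "", 3L))
    out[ok] <- yr * 4L + qn - 1L
  }
  out
}

#' @rdname quarters
#' @export
index_to_quarter <- function(idx) {
  idx <- as.integer(idx)
  sprintf("%04dQ%d", idx %/% 4L, idx %% 4L + 1L)
}

#' @rdname quarters
#' @export
quarter_add <- function(q, k) {
  index_to_quarter(quarter_index(q) + as.integer(k))
}

#' @rdname quarters
#' @export
quarter_of_date <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  qn <- (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L
  out <- sprintf("%04dQ%d", yr, qn)
  out[is.na(date)] <- NA_character_
  out
}

# first calendar day of a quarter id
quarter_start_date <- function(q) {
  idx <- quarter_index(q)
  as.Date(sprintf("%04d-%02d-01", idx %/% 4L, (idx %% 4L) * 3L + 1L))
}
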