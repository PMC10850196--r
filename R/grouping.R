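#' Load a preferred-term grouping table
#'
#' Maps MedDRA preferred terms (PTs) to target diseases — the clinically
#' significant adverse reactions (CSARs) whose addition to a package insert is
#' the prediction target. Reactions are tabulated per disease, so e.g. reports
#' of "Blood potassium increased" and "Hyperkaliemia" both count toward the
#' hyperkaliemia tally. The packaged default (`system.file("extdata",
#' "grouping.csv", package = "pvlabel")`) covers 75 target diseases.
#'
#' Matching is exact after case-folding and whitespace normalization; a PT may
#' belong to at most one disease, and a file violating this is rejected.
#'
#' @param path path to a two-column CSV with header `disease,pt`. Defaults to
#'   the packaged grouping.
#' @return an object of class `adr_grouping`: a named list mapping each disease
#'   to its character vector of PTs, with a normalized PT -> disease lookup
#'   attached.
#' @seealso [map_pt()]
#' @export
load_grouping <- function(path = system.file("extdata", "grouping.csv",
                                             package = "pvlabel")) {
  if (!file.exists(path)) stop("grouping file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("disease", "pt") %in% names(df))) {
    stop("grouping file must have columns 'disease' and 'pt': ", path,
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    gm <- structure(list(), lookup = character(0), class = "adr_grouping")
    return(gm)
  }
  df$disease <- trimws(df$disease)
  df$pt <- trimws(df$pt)
  if (any(df$disease == "" | is.na(df$disease))) {
    bad <- which(df$disease == "" | is.na(df$disease))[1L]
    stop("empty disease name at grouping row ", bad, call. = FALSE)
  }
  if (any(df$pt == "" | is.na(df$pt))) {
    bad <- which(df$pt == "" | is.na(df$pt))[1L]
    stop("empty preferred term at grouping row ", bad, call. = FALSE)
  }
  key <- normalize_pt(df$pt)
  dup <- duplicated(key)
  if (any(dup)) {
    clash <- df$pt[dup][1L]
    ds <- unique(df$disease[key == normalize_pt(clash)])
    stop("preferred term '", clash, "' assigned to more than one entry (",
         paste(ds, collapse = ", "), ")", call. = FALSE)
  }
  gm <- split(df$pt, df$disease)
  lookup <- stats::setNames(df$disease, key)
  structure(gm, lookup = lookup, class = "adr_grouping")
}

# case-fold and collapse internal whitespace so "blood  Potassium increased"
# matches the packaged term
normalize_pt <- function(pt) {
  tolower(gsub("\\s+", " ", trimws(pt)))
}

#' Map preferred terms to their target disease
#'
#' @param pt character vector of preferred-term strings.
#' @param map an `adr_grouping` from [load_grouping()].
#' @return character vector of disease names, `NA` where a PT is not in the
#'   grouping.
#' @examples
#' gm <- load_grouping()
#' map_pt(c("Blood potassium increased", "Rhabdomyolysis", "Headache"), gm)
#' @export
map_pt <- function(pt, map) {
  stopifnot(inherits(map, "adr_grouping"))
  lookup <- attr(map, "lookup")
  unname(lookup[normalize_pt(pt)])
}

#' @export
print.adr_grouping <- function(x, ...) {
  cat("<adr_grouping> ", length(x), " target diseases, ",
      sum(lengths(x)), " preferred terms\n", sep = "")
  invisible(x)
}
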