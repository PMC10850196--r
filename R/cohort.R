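#' Build the labeled drug-disease pair cohort
#'
#' Positive pairs come from the package-insert revision log: every revision
#' inside the analysis period whose reason is domestic case accumulation and
#' whose disease name is covered by the preferred-term grouping becomes a
#' positive pair, with features to be taken as of `lag` quarters (default 2)
#' before the announcement — revisions are announced weeks to months after the
#' underlying risk investigation starts, so the reporting stream that predicts
#' them is the one that existed about two quarters earlier.
#'
#' Negative pairs are (suspected drug, disease) combinations with at least one
#' retained report of the disease during the period whose disease is *not*
#' listed among the drug's clinically significant adverse reactions at period
#' end. Each negative's as-of quarter is, by default, sampled (seeded) from
#' the positives' as-of quarters — the matched index dates standard in
#' case-control designs. Giving every negative the period's final quarter
#' instead (`negative_as_of = "final"`) makes all negative feature vectors
#' share one set of disease margins; they then collapse onto a small number of
#' exactly duplicated points, and a flexible classifier can recognize
#' positives purely as novel cutoff geometry rather than by any reporting
#' signal. Matching removes that artifact. Pairs whose disease
#' was added to the insert for a non-domestic reason are excluded from both
#' classes. Revisions whose disease has no grouping entry are dropped with a
#' warning (they cannot be tabulated by preferred term).
#'
#' @param db a cleaned `report_db`.
#' @param revisions data frame `drug_code`, `disease`, `announce_quarter`,
#'   `reason` (`domestic`, `domestic_and_overseas`, `overseas`, `other`).
#' @param listed data frame `drug_code`, `disease`: pairs listed on the
#'   package insert at period end.
#' @param map an [load_grouping()] result.
#' @param period character vector `c(first_quarter, last_quarter)` of the
#'   analysis period, `"YYYYQn"`.
#' @param lag quarters between a revision announcement and its feature cutoff.
#' @param negative_as_of `"matched"` (default: negatives' as-of quarters are
#'   drawn with replacement from the positives') or `"final"` (all negatives
#'   use the period's final quarter).
#' @param seed seed for the matched as-of draw.
#' @return data frame of class `labeled_cohort` with columns `drug_code`,
#'   `disease`, `label` (`"positive"`/`"negative"`), `as_of_quarter`,
#'   `source`.
#' @export
build_cohort <- function(db, revisions, listed, map, period, lag = 2L,
                         negative_as_of = c("matched", "final"), seed = 1L) {
  negative_as_of <- match.arg(negative_as_of)
  stopifnot(inherits(db, "report_db"), length(period) == 2L)
  need <- c("drug_code", "disease", "announce_quarter", "reason")
  if (!is.data.frame(revisions) || !all(need %in% names(revisions))) {
    stop("revisions must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok_reason <- c("domestic", "domestic_and_overseas", "overseas", "other")
  bad <- setdiff(unique(revisions$reason), ok_reason)
  if (length(bad) > 0) {
    stop("unknown revision reason: ", bad[1L], call. = FALSE)
  }
  p0 <- quarter_index(period[1L])
  p1 <- quarter_index(period[2L])
  if (p0 > p1) stop("analysis period is empty: ", period[1L], " after ",
                    period[2L], call. = FALSE)

  rev_idx <- quarter_index(revisions$announce_quarter)
  in_period <- rev_idx >= p0 & rev_idx <= p1
  rev <- revisions[in_period, , drop = FALSE]
  rev_idx <- rev_idx[in_period]

  unmatched <- rev$reason == "domestic" & !(rev$disease %in% names(map))
  if (any(unmatched)) {
    warning(sum(unmatched), " domestic revision(s) dropped: disease not in ",
            "the preferred-term grouping (",
            paste(utils::head(unique(rev$disease[unmatched]), 3),
                  collapse = ", "), ")", call. = FALSE)
  }
  pos_sel <- rev$reason == "domestic" & !unmatched
  positives <- data.frame(
    drug_code = rev$drug_code[pos_sel],
    disease = rev$disease[pos_sel],
    label = rep("positive", sum(pos_sel)),
    as_of_quarter = index_to_quarter(rev_idx[pos_sel] - as.integer(lag)),
    source = sprintf("revision %s", rev$announce_quarter[pos_sel]),
    stringsAsFactors = FALSE)
  positives <- positives[!duplicated(positives[c("drug_code", "disease")]), ,
                         drop = FALSE]

  # reported pairs: suspected drug x mapped disease, within the period
  demo <- db$demo
  qidx <- quarter_index(demo$quarter_received)
  keep <- demo$case_id[qidx >= p0 & qidx <= p1]
  reac <- db$reac[db$reac$case_id %in% keep, , drop = FALSE]
  sus <- db$drug[db$drug$role == "suspected" & db$drug$case_id %in% keep, ,
                 drop = FALSE]
  dis <- map_pt(reac$pt_name, map)
  rr <- unique(data.frame(case_id = reac$case_id, disease = dis,
                          stringsAsFactors = FALSE)[!is.na(dis), ,
                                                    drop = FALSE])
  pairs <- unique(merge(rr, unique(sus[c("case_id", "drug_code")]),
                        by = "case_id")[c("drug_code", "disease")])

  pkey <- function(d) paste(d$drug_code, d$disease, sep = "\r")
  pos_key <- pkey(positives)
  listed_key <- if (nrow(listed) > 0) pkey(listed) else character(0)
  nondom_key <- pkey(rev[rev$reason != "domestic", , drop = FALSE])
  drop_key <- unique(c(pos_key, listed_key, nondom_key))
  neg <- pairs[!(pkey(pairs) %in% drop_key), , drop = FALSE]
  neg <- neg[order(neg$drug_code, neg$disease), , drop = FALSE]
  if (negative_as_of == "matched" && nrow(positives) > 0 && nrow(neg) > 0) {
    set.seed(seed)
    neg_as_of <- sample(positives$as_of_quarter, nrow(neg), replace = TRUE)
  } else {
    neg_as_of <- rep(period[2L], nrow(neg))
  }
  negatives <- data.frame(
    drug_code = neg$drug_code, disease = neg$disease,
    label = rep("negative", nrow(neg)), as_of_quarter = neg_as_of,
    source = rep("reported, unlisted at period end", nrow(neg)),
    stringsAsFactors = FALSE)

  out <- rbind(positives, negatives)
  rownames(out) <- NULL
  class(out) <- c("labeled_cohort", "data.frame")
  out
}
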