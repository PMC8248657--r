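# Columns every longitudinal cohort table must carry, in order.
cohort_columns <- c("subjid", "group", "visit_type", "visit_seq", "weight_kg",
                    hd_factors)

# Columns inspected for missingness: weight plus the 12 clinical factors.
analysis_columns <- c("weight_kg", hd_factors)

check_cohort_columns <- function(table) {
  miss <- setdiff(cohort_columns, names(table))
  if (length(miss)) {
    stop("cohort table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(table)
}

#' Drop visit rows with missing analysis values
#'
#' Removes every row that has a missing value in the weight column or in any
#' of the 12 clinical factor columns. Row order is preserved. The number of
#' dropped rows is attached as attribute `n_dropped`.
#'
#' @param table Longitudinal cohort table (see [read_cohort()]).
#' @return The filtered table.
#' @export
remove_missing <- function(table) {
  check_cohort_columns(table)
  keep <- stats::complete.cases(table[analysis_columns])
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Drop visit rows carrying boxplot outliers
#'
#' Tukey boxplot outlier filter: for each named factor the first and third
#' quartiles are computed once on the input table (linear interpolation,
#' `stats::quantile` type 7) and any row whose value falls outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` is dropped. Fences are not recomputed
#' after removals. Clinical HD scores with strongly skewed marginals
#' (total functional capacity, independence, irritability, motor and
#' depression scores) are screened by default.
#'
#' @param table Longitudinal cohort table.
#' @param factors Character vector of factor columns to screen.
#' @param k Fence multiplier, default 1.5.
#' @return The filtered table, with attribute `n_dropped`.
#' @export
remove_outliers <- function(table,
                            factors = c("tfcscore", "indepscl", "irascore",
                                        "motscore", "depscore"),
                            k = 1.5) {
  check_cohort_columns(table)
  bad <- setdiff(factors, names(table))
  if (length(bad)) stop("unknown factor column(s): ", paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(table))
  for (f in factors) {
    x <- table[[f]]
    if (!is.numeric(x)) stop("factor column is not numeric: ", f)
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
    fence <- c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
    keep <- keep & (is.na(x) | (x >= fence[1] & x <= fence[2]))
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Collapse a longitudinal table to one record per subject with the
#' percentage weight change
#'
#' For each subject the baseline weight `w_b` and the weight `w_f` at the
#' last follow-up (maximal `visit_seq`) are located and the percentage
#' weight change is computed as `((w_f - w_b) / w_b) * 100`. Subjects
#' lacking a baseline or lacking any follow-up are excluded; their counts
#' are attached as attribute `exclusions`. Clinical factor values on the
#' output record are taken from the last follow-up visit by default
#' (contemporaneous with `w_f`), or from the baseline visit.
#'
#' @param table Cleaned longitudinal cohort table.
#' @param factor_visit Which visit supplies the factor values: `"last"`
#'   (default) or `"baseline"`.
#' @return Data frame of subject records: `subjid`, `group`, `delta_w` and
#'   the 12 factor columns, one row per retained subject.
#' @export
#' @examples
#' tab <- data.frame(subjid = "S1", group = "pMan",
#'                   visit_type = c("Baseline", "FollowUp", "FollowUp"),
#'                   visit_seq = 0:2, weight_kg = c(100, 95, 90),
#'                   age = 45, mmsetotal = 28, indepscl = 100, fiscore = 25,
#'                   tfcscore = 13, motscore = 0, exfscore = 0, aptscore = 0,
#'                   irascore = 0, depscore = 0, psyscore = 0, sdmt1 = 50)
#' compute_weight_change(tab)$delta_w  # -10
compute_weight_change <- function(table, factor_visit = c("last", "baseline")) {
  check_cohort_columns(table)
  factor_visit <- match.arg(factor_visit)
  dup_seq <- duplicated(table[c("subjid", "visit_seq")])
  if (any(dup_seq)) {
    stop("duplicate visit_seq for subject ", table$subjid[which(dup_seq)[1]])
  }
  is_b <- table$visit_type == "Baseline"
  dup_b <- duplicated(table$subjid[is_b])
  if (any(dup_b)) {
    stop("duplicate baseline rows for subject ",
         table$subjid[is_b][which(dup_b)[1]])
  }
  base <- table[is_b, , drop = FALSE]
  if (any(!is.na(base$weight_kg) & base$weight_kg <= 0)) {
    bad <- base$subjid[which(!is.na(base$weight_kg) & base$weight_kg <= 0)[1]]
    stop("non-positive baseline weight for subject ", bad)
  }
  fu <- table[table$visit_type == "FollowUp", , drop = FALSE]
  fu <- fu[order(fu$subjid, fu$visit_seq), , drop = FALSE]
  last <- fu[!duplicated(fu$subjid, fromLast = TRUE), , drop = FALSE]

  subjects <- unique(table$subjid)
  bi <- match(subjects, base$subjid)
  li <- match(subjects, last$subjid)
  retained <- !is.na(bi) & !is.na(li)
  no_baseline <- sum(is.na(bi))
  no_followup <- sum(!is.na(bi) & is.na(li))

  bi <- bi[retained]
  li <- li[retained]
  w_b <- base$weight_kg[bi]
  w_f <- last$weight_kg[li]
  out <- data.frame(subjid = base$subjid[bi], group = base$group[bi],
                    delta_w = (w_f - w_b) / w_b * 100,
                    stringsAsFactors = FALSE)
  src <- if (factor_visit == "last") last[li, , drop = FALSE]
         else base[bi, , drop = FALSE]
  out[hd_factors] <- src[hd_factors]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(no_baseline = no_baseline,
                               no_followup = no_followup)
  out
}

#' Run the full cleaning pipeline on a longitudinal table
#'
#' Convenience composition with the fixed order: missing-value removal,
#' boxplot outlier removal, weight-change consolidation.
#'
#' @inheritParams compute_weight_change
#' @param outlier_factors Factors screened by [remove_outliers()]; `NULL`
#'   skips the outlier step.
#' @return Subject records as from [compute_weight_change()], with attribute
#'   `counts` recording the rows in, rows dropped at each step and subjects
#'   retained.
#' @export
preprocess_cohort <- function(table,
                              outlier_factors = c("tfcscore", "indepscl",
                                                  "irascore", "motscore",
                                                  "depscore"),
                              factor_visit = "last") {
  n_in <- nrow(table)
  table <- remove_missing(table)
  n_missing <- attr(table, "n_dropped")
  n_outlier <- 0L
  if (!is.null(outlier_factors) && length(outlier_factors)) {
    table <- remove_outliers(table, outlier_factors)
    n_outlier <- attr(table, "n_dropped")
  }
  rec <- compute_weight_change(table, factor_visit = factor_visit)
  attr(rec, "counts") <- c(
    rows_in = n_in, rows_dropped_missing = n_missing,
    rows_dropped_outlier = n_outlier,
    subjects_retained = nrow(rec),
    subjects_excluded = sum(attr(rec, "exclusions"))
  )
  rec
}
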