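# Default per-category marginals for the synthetic cohort: roughly unimodal
# "normal-like" densities over each factor's ordinal categories, shaped after
# what a largely premanifest cohort looks like (mostly functionally intact,
# a tail of psychiatric/cognitive severity). Purely illustrative defaults.
default_factor_marginals <- function() {
  list(
    age       = c(0.10, 0.25, 0.30, 0.20, 0.10, 0.05),
    mmsetotal = c(0.70, 0.20, 0.08, 0.02),
    indepscl  = c(0.02, 0.08, 0.25, 0.65),
    fiscore   = c(0.02, 0.05, 0.10, 0.23, 0.60),
    tfcscore  = c(0.03, 0.07, 0.25, 0.65),
    motscore  = c(0.45, 0.45, 0.07, 0.02, 0.01),
    exfscore  = c(0.40, 0.30, 0.18, 0.08, 0.04),
    aptscore  = c(0.45, 0.30, 0.15, 0.07, 0.03),
    irascore  = c(0.45, 0.30, 0.15, 0.07, 0.03),
    depscore  = c(0.40, 0.30, 0.18, 0.08, 0.04),
    psyscore  = c(0.80, 0.12, 0.05, 0.02, 0.01),
    sdmt1     = c(0.55, 0.25, 0.12, 0.08)
  )
}

# Background distribution of wtCat used when a planted consequent is NOT
# drawn (codes -3..+3); mildly loss-skewed, mass near 0.
background_wtcat <- c(0.02, 0.06, 0.12, 0.55, 0.15, 0.07, 0.03)

#' Specify a planted antecedent-to-weight-category dependency
#'
#' Describes a dependency to embed in a synthetic cohort: subjects whose
#' categorized factors match the antecedent receive the consequent weight
#' category with probability `target_confidence`. A `stratum_fraction` of
#' the cohort is forced into the antecedent categories so the dependency is
#' present at a controlled prevalence.
#'
#' @param antecedent Named integer vector of category codes, e.g.
#'   `c(tfcscore = 1, irascore = 4)`. Factor names must be distinct clinical
#'   factors.
#' @param consequent_category Weight category in `-3:3`.
#' @param target_confidence Probability in (0, 1] that a matching subject
#'   receives the consequent category.
#' @param stratum_fraction Fraction of subjects forced into the antecedent
#'   stratum.
#' @return An object of class `planted_rule`.
#' @export
planted_rule <- function(antecedent, consequent_category,
                         target_confidence = 0.95, stratum_fraction = 0.1) {
  if (is.null(names(antecedent)) || anyDuplicated(names(antecedent))) {
    stop("antecedent must be a named vector with distinct factor names")
  }
  if (!all(names(antecedent) %in% hd_factors)) {
    stop("unknown antecedent factor(s): ",
         paste(setdiff(names(antecedent), hd_factors), collapse = ", "))
  }
  if (!consequent_category %in% -3:3) stop("consequent_category must be in -3..3")
  if (target_confidence <= 0 || target_confidence > 1) {
    stop("target_confidence must be in (0, 1]")
  }
  if (stratum_fraction <= 0 || stratum_fraction >= 1) {
    stop("stratum_fraction must be in (0, 1)")
  }
  structure(list(antecedent = antecedent,
                 consequent_category = as.integer(consequent_category),
                 target_confidence = target_confidence,
                 stratum_fraction = stratum_fraction),
            class = "planted_rule")
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_subjects Number of subjects.
#' @param group Group label attached to every row (`"pMan"` or `"fCont"`).
#' @param followup_range Integer interval (length 2) for the number of annual
#'   follow-up visits per subject, default `c(3, 5)`; must lie within 1..10.
#' @param baseline_weight_mean,baseline_weight_sd Baseline weight (kg).
#' @param annual_drift_sd Standard deviation of the multiplicative annual
#'   weight drift, in percent per year.
#' @param factor_marginals Named list of per-category probability vectors,
#'   one per clinical factor; each must sum to 1.
#' @param planted_rules List of [planted_rule()] objects (strata are
#'   allocated disjointly in order).
#' @param missing_rate Fraction of factor cells set missing, in [0, 1).
#' @param outlier_rate Fraction of factor cells displaced by
#'   [inject_outliers()] when the generator is asked to, in [0, 1).
#' @param seed Integer seed; one random stream drives the whole cohort.
#' @param scheme Categorization scheme defining the raw intervals behind
#'   each category.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects,
                             group = "pMan",
                             followup_range = c(3L, 5L),
                             baseline_weight_mean = 75,
                             baseline_weight_sd = 12,
                             annual_drift_sd = 4,
                             factor_marginals = default_factor_marginals(),
                             planted_rules = list(),
                             missing_rate = 0,
                             outlier_rate = 0,
                             seed = 1L,
                             scheme = default_scheme()) {
  stopifnot(length(n_subjects) == 1L, n_subjects >= 1)
  followup_range <- as.integer(followup_range)
  if (length(followup_range) != 2L || followup_range[1] > followup_range[2] ||
      followup_range[1] < 1L || followup_range[2] > 10L) {
    stop("followup_range must be an integer interval within [1, 10]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (outlier_rate < 0 || outlier_rate >= 1) stop("outlier_rate must be in [0, 1)")
  miss <- setdiff(hd_factors, names(factor_marginals))
  if (length(miss)) stop("factor_marginals missing factor(s): ",
                         paste(miss, collapse = ", "))
  for (f in hd_factors) {
    p <- factor_marginals[[f]]
    ncat <- length(scheme_codes(scheme, f))
    if (length(p) != ncat) {
      stop(sprintf("marginal for '%s' must have %d probabilities", f, ncat))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("marginal for '%s' is not a probability vector", f))
    }
  }
  if (inherits(planted_rules, "planted_rule")) planted_rules <- list(planted_rules)
  total_strata <- 0
  for (r in planted_rules) {
    if (!inherits(r, "planted_rule")) stop("planted_rules must be planted_rule objects")
    for (f in names(r$antecedent)) {
      scheme_interval(scheme, f, r$antecedent[[f]])  # errors if undefined
    }
    base <- background_wtcat[match(r$consequent_category, -3:3)]
    if (r$target_confidence <= base) {
      stop("target_confidence must exceed the consequent's base rate")
    }
    total_strata <- total_strata + r$stratum_fraction
  }
  if (total_strata >= 1) stop("planted strata exceed the cohort")
  structure(list(n_subjects = as.integer(n_subjects), group = group,
                 followup_range = followup_range,
                 baseline_weight_mean = baseline_weight_mean,
                 baseline_weight_sd = baseline_weight_sd,
                 annual_drift_sd = annual_drift_sd,
                 factor_marginals = factor_marginals,
                 planted_rules = planted_rules,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 seed = as.integer(seed), scheme = scheme),
            class = "generator_config")
}

# Sample a raw score uniformly within the raw interval of (factor, code).
sample_raw_in_category <- function(scheme, factor, codes) {
  iv <- scheme[[factor]]
  idx <- match(codes, iv$code)
  lo <- iv$lo[idx]
  hi <- pmin(iv$hi[idx], hd_factor_caps[[factor]] + 1)
  # degenerate top interval (e.g. total functional capacity 13) collapses
  hi <- pmax(hi, lo + 1e-9)
  stats::runif(length(codes), lo, hi)
}

# Representative percentage weight change for a wtCat code: the interval
# midpoint, with +/-25 standing in for the unbounded very-severe bands.
wtcat_target_dw <- function(code) {
  mid <- c(`-3` = -25, `-2` = -15, `-1` = -7.5, `0` = 0,
           `1` = 7.5, `2` = 15, `3` = 25)
  unname(mid[as.character(code)])
}

#' Generate a seeded synthetic longitudinal cohort
#'
#' Simulates a longitudinal visit table with the structure the analysis
#' assumes: one baseline plus 3-5 annual follow-ups per subject, ordinal
#' clinical factor scores drawn per-category from configurable marginals and
#' jittered uniformly within each category's raw interval (so categorization
#' is exactly invertible), a multiplicative random-walk weight trajectory,
#' optional completely-at-random missingness over factor cells, and planted
#' antecedent-to-weight-category dependencies: every subject whose
#' categorized factors match a planted antecedent has their last follow-up
#' weight solved so the percentage weight change lands in the consequent
#' category with the rule's target confidence.
#'
#' @param config A [generator_config()].
#' @return Longitudinal cohort table (data frame) with the canonical
#'   columns `subjid, group, visit_type, visit_seq, weight_kg` and the 12
#'   factor columns. Deterministic given the config (including its seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  scheme <- config$scheme

  # 1. categorical factor profile per subject
  cats <- matrix(NA_integer_, n, length(hd_factors),
                 dimnames = list(NULL, hd_factors))
  for (f in hd_factors) {
    codes <- scheme_codes(scheme, f)
    cats[, f] <- sample(codes, n, replace = TRUE,
                        prob = config$factor_marginals[[f]])
  }

  # 2. force planted strata into their antecedent categories (disjoint,
  #    allocated from the top of the subject list in rule order)
  ptr <- 0L
  for (r in config$planted_rules) {
    m <- ceiling(r$stratum_fraction * n)
    idx <- ptr + seq_len(m)
    ptr <- ptr + m
    for (f in names(r$antecedent)) cats[idx, f] <- r$antecedent[[f]]
  }

  # 3. raw scores jittered inside each category's interval
  raw <- matrix(NA_real_, n, length(hd_factors),
                dimnames = list(NULL, hd_factors))
  for (f in hd_factors) raw[, f] <- sample_raw_in_category(scheme, f, cats[, f])

  # 4. planted consequents: every matching subject (forced or by chance)
  #    draws the consequent category with the target confidence
  target_dw <- rep(NA_real_, n)
  claimed <- rep(FALSE, n)
  for (r in config$planted_rules) {
    match_r <- rep(TRUE, n)
    for (f in names(r$antecedent)) {
      match_r <- match_r & (cats[, f] == r$antecedent[[f]])
    }
    idx <- which(match_r & !claimed)
    claimed[match_r] <- TRUE
    hit <- stats::runif(length(idx)) < r$target_confidence
    alt_codes <- setdiff(-3:3, r$consequent_category)
    alt_prob <- background_wtcat[match(alt_codes, -3:3)]
    alt <- sample(alt_codes, length(idx), replace = TRUE,
                  prob = alt_prob / sum(alt_prob))
    code <- ifelse(hit, r$consequent_category, alt)
    target_dw[idx] <- wtcat_target_dw(code)
  }

  # 5. weight trajectories
  k <- sample(seq(config$followup_range[1], config$followup_range[2]),
              n, replace = TRUE)
  w_b <- pmax(stats::rnorm(n, config$baseline_weight_mean,
                           config$baseline_weight_sd), 35)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    drift <- stats::rnorm(k[i], 0, config$annual_drift_sd / 100)
    w <- w_b[i] * cumprod(1 + drift)
    if (!is.na(target_dw[i])) {
      # planted weight change is established in the first follow-up year and
      # sustained, so the dependency survives the loss of individual visit
      # records during cleaning (the last follow-up satisfies the
      # weight-change equation exactly, whichever visit that turns out to be)
      w <- rep(w_b[i] * (1 + target_dw[i] / 100), k[i])
    }
    rec <- data.frame(
      subjid = sprintf("%s%06d", config$group, i),
      group = config$group,
      visit_type = c("Baseline", rep("FollowUp", k[i])),
      visit_seq = 0:k[i],
      weight_kg = round(c(w_b[i], w), 2),
      stringsAsFactors = FALSE)
    rows[[i]] <- rec
  }
  tab <- do.call(rbind, rows)
  fac <- raw[rep(seq_len(n), times = k + 1L), , drop = FALSE]
  # floor to 2 decimals: every interval bound is an integer, so flooring can
  # never move a raw score across a category boundary
  tab[hd_factors] <- as.data.frame(floor(fac * 100) / 100)

  # 6. completely-at-random missingness over factor cells
  if (config$missing_rate > 0) {
    ncell <- nrow(tab) * length(hd_factors)
    holes <- which(stats::runif(ncell) < config$missing_rate)
    if (length(holes)) {
      m <- as.matrix(tab[hd_factors])
      m[holes] <- NA_real_
      tab[hd_factors] <- as.data.frame(m)
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Displace a random subset of factor cells beyond the boxplot fence
#'
#' Injects outliers for exercising the boxplot cleaning step: a seeded
#' random subset of non-missing factor cells is displaced above
#' `Q3 + magnitude * IQR` of its column (quartiles of the input table).
#' The input is returned unmodified if `rate` is 0.
#'
#' @param table Longitudinal cohort table.
#' @param rate Fraction of factor cells to displace, in [0, 1).
#' @param magnitude Displacement multiplier (> 1.5 so the result lies
#'   outside the Tukey fence), default 3.
#' @param seed Integer seed.
#' @return A new table with displaced cells; the input is not modified.
#' @export
inject_outliers <- function(table, rate, magnitude = 3, seed = 1L) {
  check_cohort_columns(table)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (magnitude <= 1.5) stop("magnitude must exceed the 1.5 IQR fence")
  if (rate == 0) return(table)
  set.seed(seed)
  m <- as.matrix(table[hd_factors])
  eligible <- which(!is.na(m))
  n_out <- round(rate * length(eligible))
  if (n_out == 0L) return(table)
  cells <- sample(eligible, n_out)
  col_of <- (cells - 1L) %/% nrow(m) + 1L
  for (j in unique(col_of)) {
    x <- m[, j]
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- max(q[2] - q[1], 1)  # degenerate columns still get displaced
    m[cells[col_of == j]] <- q[2] + magnitude * iqr
  }
  table[hd_factors] <- as.data.frame(m)
  table
}

#' Write / read a longitudinal cohort table as CSV
#'
#' The CSV carries the canonical columns in fixed order; missing values are
#' encoded as empty fields. Reading validates that all required columns are
#' present and errors naming the first missing one.
#'
#' @param table Longitudinal cohort table.
#' @param path File path.
#' @return `read_cohort()` returns the table; `write_cohort()` its path,
#'   invisibly.
#' @export
write_cohort <- function(table, path) {
  check_cohort_columns(table)
  utils::write.csv(table[cohort_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_columns, names(tab))
  if (length(miss)) {
    stop("cohort file is missing required column '", miss[1], "'")
  }
  tab$subjid <- as.character(tab$subjid)
  for (f in c("weight_kg", hd_factors)) tab[[f]] <- as.numeric(tab[[f]])
  tab$visit_seq <- as.integer(tab$visit_seq)
  tab[cohort_columns]
}
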