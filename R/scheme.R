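fct_intervals <- function(lo, hi, code, label) {
  data.frame(lo = lo, hi = hi, code = as.integer(code), label = label,
             stringsAsFactors = FALSE)
}

#' Expert knowledge-based categorization scheme for HD clinical factors
#'
#' Returns the ordinal categorization scheme mapping raw clinical scores to
#' category codes, as defined by clinical Huntington's disease domain experts.
#' Each factor is covered by a list of half-open raw-score intervals
#' `[lo, hi)` carrying an integer category code and a severity label.
#' Cognitive scales (`mmsetotal`, `sdmt1`) are reverse-scored: lower raw
#' scores mean higher severity codes.
#'
#' The weight-change category `wtCat` is handled separately (see
#' [weight_category()]): it is symmetric in the magnitude of the percentage
#' weight change, with codes -3 (very severe loss, >= 20%) through +3
#' (very severe gain).
#'
#' @return An object of class `categorization_scheme`: a named list with one
#'   data frame (`lo`, `hi`, `code`, `label`) per clinical factor, plus a
#'   `wtCat` element holding the magnitude breakpoints `c(5, 10, 20)`.
#' @export
#' @examples
#' sch <- default_scheme()
#' sch$age          # age bands, code 0 (<30) .. 5 (>=70)
#' sch$irascore     # irritability: 0 normal .. 4 very severe
default_scheme <- function() {
  sch <- list(
    age = fct_intervals(
      lo = c(18, 30, 40, 50, 60, 70), hi = c(30, 40, 50, 60, 70, Inf),
      code = 0:5,
      label = c("<30", "30-39", "40-49", "50-59", "60-69", ">=70")),
    mmsetotal = fct_intervals(
      lo = c(25, 20, 10, 0), hi = c(Inf, 25, 20, 10),
      code = 0:3, label = c("normal", "mild", "moderate", "severe")),
    indepscl = fct_intervals(
      # 81-95 is "mild" (code 2); the normal band starts above 95
      lo = c(0, 41, 81, 96), hi = c(41, 81, 96, Inf),
      code = 0:3, label = c("severe", "moderate", "mild", "normal")),
    fiscore = fct_intervals(
      lo = c(0, 6, 11, 16, 21), hi = c(6, 11, 16, 21, Inf),
      code = 0:4,
      label = c("very severe", "severe", "moderate", "mild", "normal")),
    tfcscore = fct_intervals(
      lo = c(0, 6, 9, 13), hi = c(6, 9, 13, Inf),
      code = 0:3, label = c("severe", "moderate", "mild", "normal")),
    motscore = fct_intervals(
      lo = c(0, 1, 32, 63, 94), hi = c(1, 32, 63, 94, Inf),
      code = 0:4,
      label = c("normal", "mild", "moderate", "severe", "very severe")),
    sdmt1 = fct_intervals(
      # reverse-scored; the printed gap at raw 26 is closed by the lower band
      lo = c(43, 35, 27, 0), hi = c(Inf, 43, 35, 27),
      code = 0:3, label = c("normal", "mild", "moderate", "severe"))
  )
  pba <- fct_intervals(
    lo = c(0, 1, 5, 9, 13), hi = c(1, 5, 9, 13, Inf),
    code = 0:4,
    label = c("normal", "mild", "moderate", "severe", "very severe"))
  for (f in c("exfscore", "aptscore", "irascore", "depscore", "psyscore")) {
    sch[[f]] <- pba
  }
  sch <- sch[hd_factors]
  sch$wtCat <- list(magnitude_breaks = c(5, 10, 20))
  class(sch) <- "categorization_scheme"
  sch
}

#' Categorize a percentage weight change
#'
#' Maps the percentage weight change between baseline and last follow-up to
#' the ordinal weight category `wtCat`: 0 for |change| < 5%, +/-1 for
#' 5-10% (moderate), +/-2 for 10-20% (severe), +/-3 for >= 20% (very
#' severe), negative codes for loss and positive codes for gain.
#'
#' @param delta_w Numeric vector of percentage weight changes.
#' @param breaks Magnitude breakpoints (percent), default `c(5, 10, 20)`.
#' @return Integer vector of codes in `-3:3`.
#' @export
#' @examples
#' weight_category(c(-25, -15, -10, -2, 7, 20))  # -3 -2 -2  0  1  3
weight_category <- function(delta_w, breaks = c(5, 10, 20)) {
  if (any(!is.finite(delta_w))) {
    stop("delta_w must be finite to be categorized")
  }
  mag <- findInterval(abs(delta_w), breaks)
  as.integer(sign(delta_w) * mag)
}

# Look up the category code of raw values for one factor; NA never matches.
categorize_value <- function(scheme, factor, x) {
  iv <- scheme[[factor]]
  if (is.null(iv)) stop("unknown factor: ", factor)
  code <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(iv))) {
    hit <- !is.na(x) & x >= iv$lo[i] & x < iv$hi[i]
    code[hit] <- iv$code[i]
  }
  bad <- !is.na(x) & is.na(code)
  if (any(bad)) {
    stop(sprintf("value %s outside the declared range of factor '%s'",
                 format(x[which(bad)[1]]), factor))
  }
  code
}

# Raw-score interval [lo, hi) of a (factor, code) pair, with the open top
# interval capped at the scale maximum so it can be sampled from.
scheme_interval <- function(scheme, factor, code, capped = TRUE) {
  iv <- scheme[[factor]]
  if (is.null(iv) || is.null(iv$code)) stop("unknown factor: ", factor)
  row <- which(iv$code == code)
  if (length(row) != 1L) {
    stop(sprintf("category %s is not defined for factor '%s'", code, factor))
  }
  hi <- iv$hi[row]
  if (capped && !is.finite(hi)) hi <- hd_factor_caps[[factor]] + 1
  c(lo = iv$lo[row], hi = hi)
}

#' Categorize subject records into the ordinal knowledge base
#'
#' Replaces every raw clinical score in a set of consolidated subject records
#' with its expert-defined ordinal category code, and the percentage weight
#' change `delta_w` with the weight category `wtCat`. The result is the
#' categorical knowledge base used for rule mining, self-organizing maps and
#' dependence analysis.
#'
#' @param records Data frame of subject records as returned by
#'   [compute_weight_change()]: columns `subjid`, `group`, `delta_w` and the
#'   12 clinical factors.
#' @param scheme A `categorization_scheme`, default [default_scheme()].
#' @return Data frame (class `categorical_dataset`) with columns `subjid`,
#'   `group`, `wtCat` and the 12 factor columns as integer codes.
#' @export
categorize <- function(records, scheme = default_scheme()) {
  need <- c("subjid", "group", "delta_w", hd_factors)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records are missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(records[c("delta_w", hd_factors)])) {
    stop("records contain missing values; clean them before categorizing")
  }
  out <- data.frame(subjid = records$subjid, group = records$group,
                    wtCat = weight_category(records$delta_w,
                                            scheme$wtCat$magnitude_breaks),
                    stringsAsFactors = FALSE)
  for (f in hd_factors) {
    out[[f]] <- categorize_value(scheme, f, records[[f]])
  }
  class(out) <- c("categorical_dataset", "data.frame")
  out
}

# All category codes a factor can take under the scheme (wtCat included).
scheme_codes <- function(scheme, factor) {
  if (factor == "wtCat") {
    k <- length(scheme$wtCat$magnitude_breaks)
    return(as.integer(seq(-k, k)))
  }
  iv <- scheme[[factor]]
  if (is.null(iv)) stop("unknown factor: ", factor)
  as.integer(iv$code)
}

#' Normalised category frequencies of one factor
#'
#' Empirical per-category relative frequencies of a categorized factor,
#' computed separately within each subject group (the normalised density
#' view of the knowledge base).
#'
#' @param dataset A `categorical_dataset` from [categorize()].
#' @param factor Factor name (one of the 12 clinical factors or `"wtCat"`).
#' @param scheme Scheme used to enumerate the factor's categories.
#' @return Data frame with columns `group`, `category`, `frequency`;
#'   frequencies sum to 1 within each group.
#' @export
category_density <- function(dataset, factor, scheme = default_scheme()) {
  if (!factor %in% names(dataset)) stop("unknown factor: ", factor)
  if (nrow(dataset) == 0L) stop("dataset is empty")
  codes <- scheme_codes(scheme, factor)
  out <- do.call(rbind, lapply(split(dataset, dataset$group), function(d) {
    n <- tabulate(match(d[[factor]], codes), nbins = length(codes))
    data.frame(group = d$group[1], category = codes,
               frequency = n / sum(n), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a categorization scheme as JSON
#'
#' @param scheme A `categorization_scheme`.
#' @param path File path.
#' @return `read_scheme()` returns the scheme; `write_scheme()` its path,
#'   invisibly.
#' @export
write_scheme <- function(scheme, path) {
  body <- lapply(scheme[hd_factors], function(iv) {
    iv$hi[!is.finite(iv$hi)] <- NA  # JSON has no Inf; open tops become null
    iv
  })
  body$wtCat <- scheme$wtCat
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  body <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- lapply(body[hd_factors], function(iv) {
    hi <- as.numeric(iv$hi)
    hi[is.na(hi)] <- Inf
    fct_intervals(as.numeric(iv$lo), hi, iv$code, iv$label)
  })
  sch$wtCat <- list(magnitude_breaks = as.numeric(body$wtCat$magnitude_breaks))
  class(sch) <- "categorization_scheme"
  sch
}
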