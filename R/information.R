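# Composite variable: categories of several factors fused into one label.
composite_variable <- function(dataset, factors) {
  bad <- setdiff(factors, names(dataset))
  if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "))
  if (length(factors) == 1L) return(dataset[[factors]])
  do.call(paste, c(unname(dataset[factors]), sep = "\r"))
}

#' Cross-tabulate two categorical factors
#'
#' @param dataset A `categorical_dataset` (or any data frame).
#' @param factor_a,factor_b Column names; `factor_a` labels the rows.
#' @return Integer contingency matrix over the observed categories; the
#'   counts sum to the number of dataset rows.
#' @export
contingency_table <- function(dataset, factor_a, factor_b) {
  bad <- setdiff(c(factor_a, factor_b), names(dataset))
  if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "))
  unclass(table(dataset[[factor_a]], dataset[[factor_b]],
                dnn = c(factor_a, factor_b)))
}

#' Chi-square test of independence on a contingency table
#'
#' Pearson's chi-square with no continuity correction:
#' `chi2 = sum((O - E)^2 / E)` with expected counts from the margins and
#' `df = (r - 1)(c - 1)`. All-zero rows or columns are dropped with a
#' warning before testing.
#'
#' @param table Contingency matrix of nonnegative counts with at least two
#'   non-empty rows and columns.
#' @return List with `chi2`, `df` and the upper-tail `p_value`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(4, 1, 0, 5), 2))  # chi2 = 6.667, df = 1
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (sum(table) == 0) stop("table has no counts")
  zr <- rowSums(table) == 0
  zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero row(s) and ", sum(zc),
            " all-zero column(s) before testing")
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("need at least 2 non-empty rows and columns")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

# Shannon entropy (bits) of a count or probability vector; 0 log 0 := 0.
entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional entropy H(Y | X) in bits
#'
#' Plug-in estimate from empirical frequencies:
#' `H(Y|X) = sum_i p(X = x_i) H(Y | X = x_i)`, log base 2. For several
#' conditioning factors, X is the composite tuple variable.
#'
#' @param dataset Data frame of categorical columns.
#' @param target Name of Y.
#' @param given Name(s) of the conditioning factor(s) X.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(dataset, target, given) {
  if (nrow(dataset) == 0L) stop("dataset is empty")
  if (!target %in% names(dataset)) stop("unknown factor: ", target)
  x <- composite_variable(dataset, given)
  y <- dataset[[target]]
  joint <- table(x, y)
  n <- sum(joint)
  px <- rowSums(joint) / n
  h_cond <- apply(joint, 1, entropy_bits)
  sum(px * h_cond)
}

#' Mutual information I(Y; X) in bits
#'
#' Plug-in estimate `I = H(Y) - H(Y|X)`, log base 2. For a set of factors,
#' X is the exact composite tuple variable (not a chain-rule
#' approximation), so joint information over factor combinations can be
#' compared against single-factor information.
#'
#' @inheritParams conditional_entropy
#' @param given Name(s) of the informative factor(s).
#' @return Mutual information in bits (nonnegative).
#' @export
#' @examples
#' d <- data.frame(x = c(0, 0, 1, 1), y = c(0, 0, 1, 1))
#' mutual_information(d, "y", "x")  # 1 bit
mutual_information <- function(dataset, target, given) {
  if (nrow(dataset) == 0L) stop("dataset is empty")
  if (!target %in% names(dataset)) stop("unknown factor: ", target)
  h_y <- entropy_bits(table(dataset[[target]]))
  h_y - conditional_entropy(dataset, target, given)
}

#' Dependence report between a class variable and clinical factors
#'
#' For each factor (or factor combination) reports the plug-in mutual
#' information with the target and the chi-square test of independence on
#' their contingency table.
#'
#' @param dataset A `categorical_dataset`.
#' @param target Class column, default `"wtCat"`.
#' @param factors Character vector of single factors to report (default:
#'   every clinical factor present).
#' @param combos Optional list of character vectors: factor combinations
#'   reported jointly via the composite variable.
#' @return Data frame `factor`, `mutual_information`, `chi2`, `df`,
#'   `p_value` (chi-square columns are `NA` for combinations whose
#'   composite table is too sparse to test).
#' @export
dependence_report <- function(dataset, target = "wtCat",
                              factors = intersect(hd_factors, names(dataset)),
                              combos = list()) {
  specs <- c(as.list(factors), combos)
  rows <- lapply(specs, function(fs) {
    fs <- unlist(fs)
    mi <- mutual_information(dataset, target, fs)
    chi <- tryCatch({
      tab <- table(composite_variable(dataset, fs), dataset[[target]])
      chi_square_independence(tab)
    }, error = function(e) list(chi2 = NA_real_, df = NA_integer_,
                                p_value = NA_real_))
    data.frame(factor = paste(fs, collapse = "+"),
               mutual_information = mi, chi2 = chi$chi2, df = chi$df,
               p_value = chi$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
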