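# Items are "factor=code" strings; a row of the knowledge base is the
# transaction holding exactly one item per factor column.

item_string <- function(factor, category) paste0(factor, "=", category)

item_factor <- function(items) sub("=.*$", "", items)

# One-hot logical matrix of a categorical dataset: one column per observed
# (factor, category) item, ordered by factor then category.
item_matrix <- function(dataset, columns) {
  cols <- list()
  for (f in columns) {
    for (v in sort(unique(dataset[[f]]))) {
      cols[[item_string(f, v)]] <- dataset[[f]] == v
    }
  }
  do.call(cbind, cols)
}

#' Mine frequent itemsets with level-wise Apriori
#'
#' From-scratch Apriori over the items of a categorical dataset (each row
#' contributes one `factor=code` item per column). Candidate `k`-itemsets
#' are generated by joining frequent `(k-1)`-itemsets sharing a
#' `(k-2)`-prefix and pruned if any `(k-1)`-subset is infrequent (the
#' anti-monotonicity of support); exact support counts are returned.
#'
#' @param dataset A `categorical_dataset` (or any data frame of categorical
#'   columns).
#' @param min_support Minimum support as a fraction of rows, in (0, 1].
#' @param columns Columns to draw items from (default: all except
#'   `subjid`/`group`).
#' @param max_size Largest itemset size to return.
#' @return Data frame with columns `items` (list of character vectors),
#'   `size`, `support_count`, `support`.
#' @export
mine_frequent_itemsets <- function(dataset, min_support,
                                   columns = setdiff(names(dataset),
                                                     c("subjid", "group")),
                                   max_size = length(columns)) {
  if (nrow(dataset) == 0L) stop("dataset is empty")
  if (min_support <= 0 || min_support > 1) stop("min_support must be in (0, 1]")
  M <- item_matrix(dataset, columns)
  n <- nrow(M)
  min_count <- min_support * n - 1e-9
  counts <- colSums(M)
  freq_items <- colnames(M)[counts >= min_count]
  levels <- list()
  if (length(freq_items)) {
    levels[[1]] <- list(sets = as.list(freq_items),
                        counts = counts[freq_items])
  }
  k <- 1L
  while (k < max_size && length(levels) == k && length(levels[[k]]$sets) > 1) {
    prev <- levels[[k]]$sets
    prev_key <- vapply(prev, paste, "", collapse = "\r")
    cand_sets <- list()
    cand_counts <- numeric()
    # join step: pairs sharing the (k-1)-prefix in lexicographic item order
    prefix <- vapply(prev, function(s) paste(s[-k], collapse = "\r"), "")
    for (g in split(seq_along(prev), prefix)) {
      if (length(g) < 2) next
      for (a in seq_len(length(g) - 1)) {
        for (b in seq((a + 1), length(g))) {
          s <- sort(union(prev[[g[a]]], prev[[g[b]]]))
          # items of the same factor cannot co-occur in a row
          if (anyDuplicated(item_factor(s))) next
          # prune: all k-subsets must be frequent
          subs <- vapply(seq_along(s),
                         function(i) paste(s[-i], collapse = "\r"), "")
          if (!all(subs %in% prev_key)) next
          cnt <- sum(rowSums(M[, s, drop = FALSE]) == length(s))
          if (cnt >= min_count) {
            cand_sets[[length(cand_sets) + 1L]] <- s
            cand_counts <- c(cand_counts, cnt)
          }
        }
      }
    }
    if (!length(cand_sets)) break
    # joins can produce the same candidate twice; keep one
    key <- vapply(cand_sets, paste, "", collapse = "\r")
    keep <- !duplicated(key)
    levels[[k + 1L]] <- list(sets = cand_sets[keep], counts = cand_counts[keep])
    k <- k + 1L
  }
  sets <- unlist(lapply(levels, `[[`, "sets"), recursive = FALSE)
  cnts <- unlist(lapply(levels, `[[`, "counts"))
  if (is.null(sets)) sets <- list()
  out <- data.frame(size = vapply(sets, length, 1L),
                    support_count = as.integer(cnts %||% integer()),
                    stringsAsFactors = FALSE)
  out$items <- sets
  out$support <- out$support_count / n
  out[c("items", "size", "support_count", "support")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interest and validation measures of a class rule
#'
#' Computes the six measures attached to a rule `X => Y` from the four
#' counts that determine its 2x2 contingency table: support
#' `s = sigma(X u Y)/N`, confidence `c = sigma(X u Y)/sigma(X)`, lift
#' `s(X u Y)/(s(X) s(Y))`, conviction `(1 - s(Y))/(1 - c)` (`Inf` at
#' `c = 1`), the chi-square statistic of the 2x2 table `{X, not X} x
#' {Y, not Y}` with 1 df and its upper-tail p-value, and the strength
#' measure, the odds ratio `(a d)/(b c)` of that table (0 for perfectly
#' negative, 1 for independent, `Inf` for perfectly positive association;
#' `0/0` is taken as 1).
#'
#' @param antecedent_count `sigma(X)`, rows containing the antecedent.
#' @param consequent_count `sigma(Y)`, rows containing the consequent.
#' @param joint_count `sigma(X u Y)`, rows containing both.
#' @param n Total number of rows `N`.
#' @return Named list: `support_count`, `support`, `confidence`, `lift`,
#'   `conviction`, `chi2`, `p_value`, `strength`.
#' @export
#' @examples
#' rule_metrics(50, 40, 20, 100)  # exact independence: lift 1, conviction 1
rule_metrics <- function(antecedent_count, consequent_count, joint_count, n) {
  if (joint_count > min(antecedent_count, consequent_count) ||
      max(antecedent_count, consequent_count) > n || joint_count < 0 ||
      antecedent_count + consequent_count - joint_count > n ||
      antecedent_count <= 0) {
    stop("inconsistent counts: need 0 <= joint <= min(antecedent, consequent) <= n, antecedent > 0")
  }
  # doubles throughout: products of four counts overflow 32-bit integers
  a <- as.numeric(joint_count)
  b <- as.numeric(antecedent_count) - a
  cc <- as.numeric(consequent_count) - a
  d <- as.numeric(n) - as.numeric(antecedent_count) -
    as.numeric(consequent_count) + a
  s_y <- consequent_count / n
  support <- joint_count / n
  confidence <- joint_count / antecedent_count
  lift <- if (s_y > 0) confidence / s_y else Inf
  conviction <- if (confidence == 1) Inf else (1 - s_y) / (1 - confidence)
  # chi-square of the 2x2 table; 0 when a margin is degenerate
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi2 <- if (denom > 0) n * (a * d - b * cc)^2 / denom else 0
  p_value <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  num <- a * d
  den <- b * cc
  strength <- if (den == 0) { if (num == 0) 1 else Inf } else num / den
  list(support_count = as.integer(joint_count), support = support,
       confidence = confidence, lift = lift, conviction = conviction,
       chi2 = chi2, p_value = p_value, strength = strength)
}

# Build the class_rules data frame from parallel lists/vectors.
make_rules_df <- function(antecedents, consequent, metrics_list) {
  df <- data.frame(
    antecedent = vapply(antecedents, paste, "", collapse = ";"),
    consequent = consequent,
    length = vapply(antecedents, length, 1L) + 1L,
    stringsAsFactors = FALSE)
  for (m in c("support_count", "support", "confidence", "lift", "conviction",
              "chi2", "p_value", "strength")) {
    df[[m]] <- vapply(metrics_list, `[[`, numeric(1), m)
  }
  df$support_count <- as.integer(df$support_count)
  df$antecedent_items <- antecedents
  class(df) <- c("class_rules", "data.frame")
  df
}

sort_rules <- function(rules) {
  if (nrow(rules) == 0) return(rules)
  ord <- order(-rules$lift, -rules$confidence, rules$antecedent)
  out <- rules[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine class association rules with a weight-category consequent
#'
#' Level-wise Apriori restricted to class association rules: antecedents are
#' drawn from the clinical factor items, the consequent is fixed to one
#' weight category item, and candidate antecedents are pruned on the joint
#' support with the consequent (anti-monotone), so the search is exact.
#' Rules are filtered by minimum confidence, rule support and total length
#' (antecedent items plus the consequent), scored with all six measures of
#' [rule_metrics()], and returned in a deterministic order (lift
#' descending, then confidence descending, then lexicographic antecedent).
#'
#' @param dataset A `categorical_dataset` from [categorize()].
#' @param consequent Consequent item as `"wtCat=-3"` or
#'   `c(factor = "wtCat", category = -3)` style list.
#' @param min_confidence Minimum confidence, default 0.9.
#' @param min_len,max_len Total rule length bounds (consequent counted),
#'   defaults 2 and 5, i.e. antecedents of 1-4 items.
#' @param min_support Minimum rule support (fraction of rows), default 0.01.
#' @param columns Antecedent factor columns (default: every categorical
#'   column except the consequent's factor and identifiers).
#' @return A `class_rules` data frame: `antecedent` (semicolon-joined
#'   items), `consequent`, `length`, the six measures, and the antecedent
#'   item sets as a list column `antecedent_items`.
#' @export
mine_class_rules <- function(dataset, consequent = "wtCat=-3",
                             min_confidence = 0.9, min_len = 2L,
                             max_len = 5L, min_support = 0.01,
                             columns = NULL) {
  if (nrow(dataset) == 0L) stop("dataset is empty")
  if (is.list(consequent)) {
    consequent <- item_string(consequent$factor, consequent$category)
  }
  cons_factor <- item_factor(consequent)
  cons_value <- sub("^.*=", "", consequent)
  if (!cons_factor %in% names(dataset)) {
    stop("consequent factor not in dataset: ", cons_factor)
  }
  if (is.null(columns)) {
    columns <- setdiff(names(dataset), c("subjid", "group", cons_factor))
  }
  n <- nrow(dataset)
  y <- dataset[[cons_factor]] == as.numeric(cons_value)
  n_y <- sum(y)
  if (n_y == 0L) {
    warning("consequent category absent from dataset: ", consequent)
    return(make_rules_df(list(), character(), list()))
  }
  M <- item_matrix(dataset, columns)
  min_count <- min_support * n - 1e-9
  max_ante <- max_len - 1L

  # level-wise search pruned on joint support with the consequent
  joint1 <- colSums(M & y)
  keep1 <- which(joint1 >= min_count)
  level <- lapply(keep1, function(j) colnames(M)[j])
  joint <- joint1[keep1]
  all_sets <- list(level)
  all_joint <- list(joint)
  k <- 1L
  while (k < max_ante && length(level) > 1) {
    key_prev <- vapply(level, paste, "", collapse = "\r")
    prefix <- vapply(level, function(s) paste(s[-k], collapse = "\r"), "")
    cand_sets <- list()
    cand_joint <- numeric()
    for (g in split(seq_along(level), prefix)) {
      if (length(g) < 2) next
      for (a in seq_len(length(g) - 1)) {
        for (b in seq((a + 1), length(g))) {
          s <- sort(union(level[[g[a]]], level[[g[b]]]))
          if (anyDuplicated(item_factor(s))) next
          subs <- vapply(seq_along(s),
                         function(i) paste(s[-i], collapse = "\r"), "")
          if (!all(subs %in% key_prev)) next
          cnt <- sum((rowSums(M[, s, drop = FALSE]) == length(s)) & y)
          if (cnt >= min_count) {
            cand_sets[[length(cand_sets) + 1L]] <- s
            cand_joint <- c(cand_joint, cnt)
          }
        }
      }
    }
    if (!length(cand_sets)) break
    key <- vapply(cand_sets, paste, "", collapse = "\r")
    keep <- !duplicated(key)
    level <- cand_sets[keep]
    joint <- cand_joint[keep]
    all_sets[[k + 1L]] <- level
    all_joint[[k + 1L]] <- joint
    k <- k + 1L
  }

  antecedents <- list()
  metrics <- list()
  for (size in seq_along(all_sets)) {
    if (size + 1L < min_len) next
    sets <- all_sets[[size]]
    jnt <- all_joint[[size]]
    for (i in seq_along(sets)) {
      nx <- sum(rowSums(M[, sets[[i]], drop = FALSE]) == size)
      met <- rule_metrics(nx, n_y, jnt[i], n)
      if (met$confidence >= min_confidence) {
        antecedents[[length(antecedents) + 1L]] <- sets[[i]]
        metrics[[length(metrics) + 1L]] <- met
      }
    }
  }
  sort_rules(make_rules_df(antecedents, rep(consequent, length(antecedents)),
                           metrics))
}

#' Remove redundant class rules
#'
#' A rule is redundant if a strictly more general rule (same consequent,
#' antecedent a proper subset) exists in the set with confidence at least
#' as high; redundant rules are dropped, input order is preserved. The
#' operation is idempotent.
#'
#' @param rules A `class_rules` data frame.
#' @return The pruned `class_rules` data frame.
#' @export
eliminate_redundant <- function(rules) {
  nr <- nrow(rules)
  if (nr == 0) return(rules)
  keep <- rep(TRUE, nr)
  for (i in seq_len(nr)) {
    ai <- rules$antecedent_items[[i]]
    for (j in seq_len(nr)) {
      if (i == j || rules$consequent[j] != rules$consequent[i]) next
      aj <- rules$antecedent_items[[j]]
      if (length(aj) < length(ai) && all(aj %in% ai) &&
          rules$confidence[j] >= rules$confidence[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of antecedent items across a rule set
#'
#' Counts how often each `factor=category` item appears among the
#' antecedents of a rule set (the antecedent frequency histogram used to
#' summarize mined rule lists).
#'
#' @param rules A `class_rules` data frame.
#' @return Data frame with columns `factor`, `category`, `item`, `count`,
#'   sorted by decreasing count; the counts sum to the total number of
#'   antecedent items.
#' @export
antecedent_histogram <- function(rules) {
  items <- unlist(rules$antecedent_items)
  if (is.null(items) || !length(items)) {
    return(data.frame(factor = character(), category = integer(),
                      item = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(items)
  out <- data.frame(factor = item_factor(names(tab)),
                    category = as.integer(sub("^.*=", "", names(tab))),
                    item = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.class_rules <- function(x, ...) {
  cat(sprintf("Class association rules: %d rule(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- x[setdiff(names(x), "antecedent_items")]
    num <- vapply(show, is.numeric, TRUE)
    show[num] <- lapply(show[num], signif, 4)
    print.data.frame(show, ...)
  }
  invisible(x)
}
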