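# Independent oracles and fixture builders. Everything here is deliberately
# written from first principles (counting, closed forms) and never calls the
# package's miner/metric internals it is used to check.

hd_factor_names <- c("age", "mmsetotal", "indepscl", "fiscore", "tfcscore",
                     "motscore", "exfscore", "aptscore", "irascore",
                     "depscore", "psyscore", "sdmt1")

# A minimal, fully valid cohort row set: one subject, baseline + follow-ups.
make_subject <- function(subjid, weights, group = "pMan",
                         factors = list()) {
  defaults <- list(age = 45, mmsetotal = 28, indepscl = 100, fiscore = 22,
                   tfcscore = 13, motscore = 0, exfscore = 0, aptscore = 0,
                   irascore = 0, depscore = 0, psyscore = 0, sdmt1 = 50)
  defaults[names(factors)] <- factors
  k <- length(weights) - 1L
  tab <- data.frame(subjid = subjid, group = group,
                    visit_type = c("Baseline", rep("FollowUp", k)),
                    visit_seq = 0:k, weight_kg = weights,
                    stringsAsFactors = FALSE)
  for (f in hd_factor_names) tab[[f]] <- defaults[[f]]
  tab
}

make_cohort <- function(...) do.call(rbind, list(...))

# Random small knowledge base for miner oracle checks: `n` rows over
# `n_factors` antecedent columns with `n_cats` categories plus a wtCat
# column skewed toward the target class.
random_kb <- function(n, n_factors = 5, n_cats = 3, seed = 1) {
  set.seed(seed)
  kb <- data.frame(subjid = sprintf("S%04d", seq_len(n)),
                   group = "pMan", stringsAsFactors = FALSE)
  kb$wtCat <- sample(c(-3L, -2L, 0L), n, replace = TRUE,
                     prob = c(0.3, 0.2, 0.5))
  for (j in seq_len(n_factors)) {
    kb[[paste0("f", j)]] <- sample.int(n_cats, n, replace = TRUE) - 1L
  }
  kb
}

# Brute-force class-rule miner: exhaustive enumeration of every antecedent
# subset over distinct factors, metrics computed from the 2x2 table with
# textbook formulas. Independent of the package's Apriori path.
bf_mine_rules <- function(kb, consequent_value = -3L, min_confidence = 0.9,
                          min_len = 2L, max_len = 5L, min_support = 0.01) {
  cols <- setdiff(names(kb), c("subjid", "group", "wtCat"))
  y <- kb$wtCat == consequent_value
  n <- nrow(kb)
  n_y <- sum(y)
  out <- list()
  for (nf in seq_len(min(max_len - 1L, length(cols)))) {
    for (fs in utils::combn(cols, nf, simplify = FALSE)) {
      vals <- lapply(fs, function(f) sort(unique(kb[[f]])))
      grid <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grid))) {
        m <- rep(TRUE, n)
        for (j in seq_along(fs)) m <- m & kb[[fs[j]]] == grid[r, j]
        nx <- sum(m)
        nxy <- sum(m & y)
        if (nx == 0 || nxy / n < min_support - 1e-12) next
        conf <- nxy / nx
        if (conf < min_confidence || nf + 1L < min_len) next
        a <- nxy; b <- nx - nxy; cc <- n_y - nxy; d <- n - nx - n_y + nxy
        E <- outer(c(a + b, cc + d), c(a + cc, b + d)) / n
        O <- matrix(c(a, cc, b, d), 2)
        chi2 <- if (all(E > 0)) sum((O - E)^2 / E) else 0
        strength <- if (b * cc == 0) { if (a * d == 0) 1 else Inf }
                    else (a * d) / (b * cc)
        items <- sort(paste0(fs, "=", unlist(grid[r, ])))
        out[[length(out) + 1L]] <- data.frame(
          antecedent = paste(items, collapse = ";"),
          support_count = nxy, support = nxy / n, confidence = conf,
          lift = (nxy / n) / ((nx / n) * (n_y / n)),
          conviction = if (conf == 1) Inf else (1 - n_y / n) / (1 - conf),
          chi2 = chi2,
          p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
          strength = strength, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(antecedent = character(), support_count = integer(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric(), conviction = numeric(),
                      chi2 = numeric(), p_value = numeric(),
                      strength = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$antecedent), , drop = FALSE]
}

# Plug-in conditional entropy from a joint count table, straight from the
# defining sum (used to check the package's estimator).
bf_conditional_entropy <- function(joint) {
  n <- sum(joint)
  h <- 0
  for (i in seq_len(nrow(joint))) {
    px <- sum(joint[i, ]) / n
    if (px == 0) next
    py <- joint[i, ] / sum(joint[i, ])
    py <- py[py > 0]
    h <- h + px * -sum(py * log2(py))
  }
  h
}

# Transaction set realizing prescribed 2x2 counts as a two-column dataset:
# f1 = 1 marks the antecedent, wtCat = -3 the consequent.
counts_to_kb <- function(n, nx, ny, nxy) {
  x <- c(rep(1L, nx), rep(0L, n - nx))
  y <- integer(n)
  y[seq_len(nxy)] <- 1L                              # X and Y
  y[nx + seq_len(ny - nxy)] <- 1L                    # Y without X
  data.frame(subjid = sprintf("S%04d", seq_len(n)), group = "pMan",
             wtCat = ifelse(y == 1L, -3L, 0L), f1 = x,
             stringsAsFactors = FALSE)
}
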