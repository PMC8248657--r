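# Tiny market-basket style fixture: 4 rows over two binary "factors" where
# presence is coded 1, mirroring transactions {A}, {A,B}, {A,B}, {B}.
basket4 <- data.frame(A = c(1L, 1L, 1L, 0L), B = c(0L, 1L, 1L, 1L))

test_that("level-wise Apriori returns exact support counts", {
  fi <- mine_frequent_itemsets(basket4, min_support = 0.5)
  key <- vapply(fi$items, paste, "", collapse = ";")
  expect_setequal(key, c("A=1", "B=1", "A=1;B=1"))
  expect_identical(fi$support_count[match("A=1", key)], 3L)
  expect_identical(fi$support_count[match("B=1", key)], 3L)
  expect_identical(fi$support_count[match("A=1;B=1", key)], 2L)

  # min_support = 1 keeps only itemsets present in every row
  fi_all <- mine_frequent_itemsets(data.frame(A = c(1L, 1L), B = c(1L, 2L)),
                                   min_support = 1)
  expect_identical(vapply(fi_all$items, paste, "", collapse = ";"), "A=1")
  expect_error(mine_frequent_itemsets(basket4[0, ], 0.5), "empty")
})

test_that("anti-monotonicity: every subset of a frequent itemset is frequent", {
  kb <- random_kb(120, n_factors = 6, seed = 3)
  fi <- mine_frequent_itemsets(kb[paste0("f", 1:6)], min_support = 0.1)
  key <- vapply(fi$items, paste, "", collapse = "\r")
  for (i in which(fi$size > 1)) {
    s <- fi$items[[i]]
    for (j in seq_along(s)) {
      expect_true(paste(s[-j], collapse = "\r") %in% key)
    }
  }
  # supports are exact: recount a few itemsets directly
  for (i in sample(nrow(fi), min(20, nrow(fi)))) {
    s <- fi$items[[i]]
    m <- rep(TRUE, nrow(kb))
    for (it in s) {
      f <- sub("=.*", "", it)
      m <- m & kb[[f]] == as.integer(sub(".*=", "", it))
    }
    expect_identical(sum(m), fi$support_count[i])
  }
})

test_that("rule metrics match hand-computed 2x2 values", {
  # perfect rule: conf 1, conviction and strength infinite
  m <- rule_metrics(4, 5, 4, 10)
  expect_equal(m$support, 0.4)
  expect_equal(m$confidence, 1)
  expect_equal(m$lift, 2)
  expect_identical(m$conviction, Inf)
  expect_equal(m$chi2, 10 * (4 * 5 - 0 * 1)^2 / (4 * 6 * 5 * 5))
  expect_identical(m$strength, Inf)

  # exact independence
  ind <- rule_metrics(50, 40, 20, 100)
  expect_equal(ind$lift, 1)
  expect_equal(ind$conviction, 1)
  expect_equal(ind$chi2, 0)
  expect_equal(ind$p_value, 1)
  expect_equal(ind$strength, 1)

  # odds ratio from a=3, b=1, c=2, d=4
  expect_equal(rule_metrics(4, 5, 3, 10)$strength, (3 * 4) / (1 * 2))
  # never co-occurring: strength 0
  expect_equal(rule_metrics(30, 40, 0, 100)$strength, 0)
  expect_error(rule_metrics(4, 5, 6, 10), "counts")
  expect_error(rule_metrics(0, 5, 0, 10), "counts")
})

test_that("metric algebra holds on random count configurations", {
  set.seed(77)
  pick <- function(v) v[sample.int(length(v), 1)]
  for (rep in 1:200) {
    n <- pick(20:500)
    nx <- pick(seq_len(n))
    ny <- pick(seq_len(n))
    nxy <- pick(seq(max(0, nx + ny - n), min(nx, ny)))
    if (nxy == 0 || nx == 0) next
    m <- rule_metrics(nx, ny, nxy, n)
    expect_lte(m$support, min(nx, ny) / n)
    expect_gte(m$confidence, m$support)
    expect_equal(m$lift * (ny / n), m$confidence, tolerance = 1e-12)
    expect_gte(m$chi2, 0)
    if (abs(m$lift - 1) < 1e-12) expect_lt(m$chi2, 1e-9)
    if (m$chi2 < 1e-12 && ny < n && nx < n) {
      expect_equal(m$lift, 1, tolerance = 1e-6)
    }
  }
})

test_that("a planted high-confidence rule is mined with the counted confidence", {
  pr <- planted_rule(c(tfcscore = 1, irascore = 4), -3L, 0.95, 0.12)
  cfg <- generator_config(2000, planted_rules = list(pr), seed = 42)
  kb <- categorize(preprocess_cohort(generate_cohort(cfg),
                                     outlier_factors = NULL))
  rules <- mine_class_rules(kb, "wtCat=-3", min_confidence = 0.9,
                            max_len = 3, min_support = 0.01)
  hit <- rules[rules$antecedent == "irascore=4;tfcscore=1", ]
  expect_identical(nrow(hit), 1L)
  m <- kb$tfcscore == 1 & kb$irascore == 4
  expect_equal(hit$confidence, sum(kb$wtCat[m] == -3) / sum(m))
  expect_equal(hit$support_count, sum(kb$wtCat[m] == -3))
})

test_that("miner equals brute-force enumeration on small datasets", {
  for (seed in c(1, 2, 3)) {
    kb <- random_kb(200, n_factors = 5, n_cats = 3, seed = seed)
    mined <- mine_class_rules(kb, "wtCat=-3", min_confidence = 0.5,
                              min_len = 2, max_len = 4, min_support = 0.03)
    oracle <- bf_mine_rules(kb, -3L, min_confidence = 0.5,
                            min_len = 2, max_len = 4, min_support = 0.03)
    mined <- mined[order(mined$antecedent), ]
    expect_identical(mined$antecedent, oracle$antecedent)
    for (col in c("support_count", "support", "confidence", "lift",
                  "conviction", "chi2", "p_value", "strength")) {
      expect_equal(mined[[col]], oracle[[col]], tolerance = 1e-12, info = col)
    }
  }
})

test_that("an absent consequent yields an empty result with a warning", {
  kb <- random_kb(50, seed = 9)
  expect_warning(r <- mine_class_rules(kb, "wtCat=3"), "absent")
  expect_identical(nrow(r), 0L)
  # impossible confidence threshold
  r2 <- mine_class_rules(kb, "wtCat=-3", min_confidence = 1,
                         min_support = 0.02)
  expect_true(all(r2$confidence == 1))
})

test_that("redundant rules are eliminated exactly and idempotently", {
  mk <- function(items, conf) {
    hdwtrules:::make_rules_df(list(items), "wtCat=-3",
      list(list(support_count = 10L, support = 0.1, confidence = conf,
                lift = 2, conviction = 2, chi2 = 5, p_value = 0.02,
                strength = 3)))
  }
  r1 <- rbind(mk(c("A=1", "B=1"), 0.92), mk("A=1", 0.95))
  class(r1) <- c("class_rules", "data.frame")
  expect_identical(eliminate_redundant(r1)$antecedent, "A=1")

  r2 <- rbind(mk(c("A=1", "B=1"), 0.97), mk("A=1", 0.95))
  class(r2) <- c("class_rules", "data.frame")
  expect_identical(nrow(eliminate_redundant(r2)), 2L)

  # brute-force check on a real mined set + idempotence
  kb <- random_kb(300, n_factors = 6, seed = 11)
  rules <- mine_class_rules(kb, "wtCat=-3", min_confidence = 0.6,
                            min_support = 0.02)
  pruned <- eliminate_redundant(rules)
  for (i in seq_len(nrow(pruned))) {
    for (j in seq_len(nrow(pruned))) {
      if (i == j) next
      ai <- pruned$antecedent_items[[i]]
      aj <- pruned$antecedent_items[[j]]
      redundant <- length(aj) < length(ai) && all(aj %in% ai) &&
        pruned$confidence[j] >= pruned$confidence[i]
      expect_false(redundant)
    }
  }
  expect_identical(eliminate_redundant(pruned), pruned)
})

test_that("antecedent histograms count items and conserve totals", {
  kb <- random_kb(300, n_factors = 6, seed = 13)
  rules <- mine_class_rules(kb, "wtCat=-3", min_confidence = 0.6,
                            min_support = 0.02)
  hist <- antecedent_histogram(rules)
  expect_identical(sum(hist$count),
                   length(unlist(rules$antecedent_items)))
  expect_identical(nrow(antecedent_histogram(rules[0, ])), 0L)
  # counting contract on a fixed pair of rules
  mk <- function(items) hdwtrules:::make_rules_df(
    list(items), "wtCat=-3",
    list(list(support_count = 1L, support = 0.1, confidence = 1, lift = 1,
              conviction = 1, chi2 = 0, p_value = 1, strength = 1)))
  rr <- rbind(mk(c("A=1", "B=2")), mk(c("A=1", "C=0")))
  h <- antecedent_histogram(rr)
  expect_identical(h$count[h$item == "A=1"], 2L)
  expect_setequal(h$item, c("A=1", "B=2", "C=0"))
})

test_that("mined rules respect thresholds and deterministic ordering", {
  kb <- random_kb(400, n_factors = 6, seed = 17)
  rules <- mine_class_rules(kb, "wtCat=-3", min_confidence = 0.55,
                            min_len = 2, max_len = 4, min_support = 0.02)
  expect_true(all(rules$confidence >= 0.55))
  expect_true(all(rules$support >= 0.02))
  expect_true(all(rules$length >= 2 & rules$length <= 4))
  expect_true(all(diff(rules$lift) <= 1e-12))
  expect_identical(mine_class_rules(kb, "wtCat=-3", min_confidence = 0.55,
                                    min_len = 2, max_len = 4,
                                    min_support = 0.02)$antecedent,
                   rules$antecedent)
})
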