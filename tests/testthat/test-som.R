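# 16 well-separated point clouds in 4 dimensions (corners of a hypercube
# scaled by 10), each with `per` jittered samples — a fixture the map should
# organize cleanly.
cluster_fixture <- function(per = 20, jitter = 0.4, seed = 5) {
  set.seed(seed)
  centers <- as.matrix(expand.grid(x1 = c(0, 10), x2 = c(0, 10),
                                   x3 = c(0, 10), x4 = c(0, 10)))
  X <- centers[rep(seq_len(16), each = per), ] +
    matrix(runif(16 * per * 4, -jitter, jitter), ncol = 4)
  list(data = as.data.frame(X), cluster = rep(seq_len(16), each = per))
}

test_that("training is deterministic given the seed", {
  fix <- cluster_fixture()
  cfg <- som_config(epochs = 20, seed = 11)
  m1 <- train_som(fix$data, cfg)
  m2 <- train_som(fix$data, cfg)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$quantization_error, m2$quantization_error)
  m3 <- train_som(fix$data, som_config(epochs = 20, seed = 12))
  expect_false(identical(m3$codebook, m1$codebook))
})

test_that("quantization error decreases from the first to the final epoch", {
  fix <- cluster_fixture()
  m <- train_som(fix$data, som_config(epochs = 40, seed = 3))
  qe <- m$quantization_error
  expect_lt(qe[length(qe)], qe[1])

  # also on ordinary categorized records
  kb <- categorize(preprocess_cohort(
    generate_cohort(generator_config(300, seed = 8)), outlier_factors = NULL))
  m2 <- train_som(kb, som_config(epochs = 30, seed = 4))
  expect_lte(m2$quantization_error[30], m2$quantization_error[1])
})

test_that("best matching unit is the nearest codebook, ties to the lowest index", {
  m <- list(codebook = rbind(c(0, 0), c(1, 1)),
            grid = som_grid <- data.frame(node = 1:2, row = 1L, col = 1:2),
            config = list(scale = FALSE),
            columns = c("a", "b"))
  class(m) <- "som_model"
  expect_identical(best_matching_unit(m, c(0.9, 0.9)), 2L)
  expect_identical(best_matching_unit(m, c(1, 1)), 2L)     # exact codebook
  expect_identical(best_matching_unit(m, c(0, 0)), 1L)
  expect_identical(best_matching_unit(m, c(0.5, 0.5)), 1L) # equidistant
  expect_error(best_matching_unit(m, c(1, 2, 3)), "width")
})

test_that("node counts conserve records and report empty nodes", {
  fix <- cluster_fixture(per = 15)
  m <- train_som(fix$data, som_config(epochs = 25, seed = 7))
  counts <- node_counts(m, fix$data)
  expect_identical(sum(counts$count), nrow(fix$data))
  expect_identical(nrow(counts), 16L)
  expect_true(all(counts$count >= 0))
})

test_that("well-separated clusters map to one node or adjacent nodes", {
  fix <- cluster_fixture(per = 20)
  m <- train_som(fix$data, som_config(epochs = 60, seed = 2))
  bmu <- best_matching_unit(m, as.matrix(fix$data))
  ok <- 0L
  for (cl in 1:16) {
    nodes <- bmu[fix$cluster == cl]
    main <- as.integer(names(which.max(table(nodes))))
    rc <- m$grid[match(nodes, m$grid$node), c("row", "col")]
    mrc <- m$grid[m$grid$node == main, c("row", "col")]
    adj <- abs(rc$row - mrc$row) <= 1 & abs(rc$col - mrc$col) <= 1
    ok <- ok + sum(adj)
  }
  expect_gte(ok / length(bmu), 0.95)
})

test_that("codebook components stay within the training data range", {
  fix <- cluster_fixture()
  fix$data$const <- 7                       # constant input column
  m <- train_som(fix$data, som_config(epochs = 30, seed = 9))
  for (f in colnames(m$codebook)) {
    expect_gte(min(m$codebook[, f]), min(fix$data[[f]]) - 1e-9)
    expect_lte(max(m$codebook[, f]), max(fix$data[[f]]) + 1e-9)
  }
  # constant factor: every node converges to (or stays at) the constant
  expect_true(all(abs(component_heatmap(m, "const") - 7) < 1e-6))
})

test_that("component heatmaps and codes profile agree and round-trip", {
  fix <- cluster_fixture()
  m <- train_som(fix$data, som_config(epochs = 15, seed = 6))
  prof <- codes_profile(m)
  expect_identical(nrow(prof), 16L)
  hm <- component_heatmap(m, "x2")
  expect_identical(dim(hm), c(4L, 4L))
  expect_equal(hm[cbind(prof$row, prof$col)], prof$x2)
  expect_error(component_heatmap(m, "nosuch"), "unknown")

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(prof, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$x2, prof$x2, tolerance = 1e-12)
})

test_that("node class distributions normalize and aggregate to the marginal", {
  kb <- categorize(preprocess_cohort(
    generate_cohort(generator_config(300, seed = 14)), outlier_factors = NULL))
  m <- train_som(kb, som_config(epochs = 25, seed = 5))
  dist <- node_class_distribution(m, kb, "wtCat")
  counts <- node_counts(m, kb)
  for (nd in counts$node[counts$count > 0]) {
    expect_equal(sum(dist$frequency[dist$node == nd]), 1)
  }
  # weighting node frequencies by node counts recovers the marginal
  cats <- sort(unique(kb$wtCat))
  marg <- vapply(cats, function(cc) {
    sum(dist$frequency[dist$category == cc] * counts$count) / sum(counts$count)
  }, numeric(1))
  expected <- as.numeric(table(factor(kb$wtCat, levels = cats))) / nrow(kb)
  expect_equal(marg, expected, tolerance = 1e-12)
  expect_error(node_class_distribution(m, kb, "nosuch"), "unknown")
})

test_that("training requires at least as many records as nodes", {
  small <- cluster_fixture(per = 1)$data[1:10, ]
  expect_error(train_som(small, som_config(epochs = 5)), "fewer records")
})
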