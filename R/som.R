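# Grid coordinates of node i on a rows x cols rectangular lattice, indexed
# row-major from the bottom-left corner (node 1) to the top-right.
som_grid_coords <- function(rows, cols) {
  idx <- seq_len(rows * cols)
  data.frame(node = idx,
             row = (idx - 1L) %/% cols + 1L,
             col = (idx - 1L) %% cols + 1L)
}

#' Self-organizing map training configuration
#'
#' @param grid_rows,grid_cols Map dimensions, default 4 x 4 (16 nodes).
#' @param epochs Training epochs (full passes over the data), default 500.
#' @param lr_initial,lr_final Learning rate, decayed linearly across
#'   epochs, defaults 0.05 to 0.01.
#' @param radius_initial,radius_final Neighborhood radius (grid distance),
#'   decayed linearly; defaults `max(grid)/2` to 1.
#' @param scale Min-max scale each input column to [0, 1] before training
#'   (codebooks are reported on the original scale), default `FALSE`:
#'   ordinal category codes are used as numbers directly.
#' @param seed Integer seed driving initialization and the per-epoch
#'   sample shuffle.
#' @return An object of class `som_config`.
#' @export
som_config <- function(grid_rows = 4L, grid_cols = 4L, epochs = 500L,
                       lr_initial = 0.05, lr_final = 0.01,
                       radius_initial = NULL, radius_final = 1,
                       scale = FALSE, seed = 1L) {
  if (is.null(radius_initial)) radius_initial <- max(grid_rows, grid_cols) / 2
  stopifnot(grid_rows >= 1, grid_cols >= 1, epochs >= 1,
            lr_initial > 0, lr_final > 0, lr_initial >= lr_final,
            radius_initial >= radius_final, radius_final > 0)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 epochs = as.integer(epochs),
                 lr_initial = lr_initial, lr_final = lr_final,
                 radius_initial = radius_initial, radius_final = radius_final,
                 scale = scale, seed = as.integer(seed)),
            class = "som_config")
}

som_input_matrix <- function(dataset, columns = NULL, include_class = TRUE) {
  if (is.null(columns)) {
    columns <- setdiff(names(dataset), c("subjid", "group"))
    if (!include_class) columns <- setdiff(columns, "wtCat")
  }
  as.matrix(dataset[columns])
}

#' Train a self-organizing map on categorized records
#'
#' Online competitive learning: each epoch presents every record in a
#' seeded random order; the best matching unit (BMU) is the node whose
#' codebook vector is nearest in Euclidean distance, and all nodes within
#' the current neighborhood radius of the BMU on the grid move toward the
#' record, scaled by the learning rate and a Gaussian neighborhood kernel
#' `exp(-d^2 / (2 sigma^2))` with `sigma` equal to the current radius.
#' Learning rate and radius decay linearly across epochs. Codebooks are
#' initialized uniformly within each input column's observed range. The
#' mean sample-to-BMU distance (quantization error) is recorded after
#' every epoch.
#'
#' @param dataset A `categorical_dataset` or numeric data frame/matrix.
#' @param config A [som_config()].
#' @param columns Input columns; by default every categorical column
#'   including `wtCat` (set `include_class = FALSE` to exclude it).
#' @param include_class Keep the `wtCat` column among the inputs.
#' @return An object of class `som_model`: codebook matrix (nodes x
#'   features, original scale), grid coordinates, training config and the
#'   per-epoch quantization error trace.
#' @export
train_som <- function(dataset, config = som_config(), columns = NULL,
                      include_class = TRUE) {
  X <- som_input_matrix(dataset, columns, include_class)
  n <- nrow(X)
  p <- ncol(X)
  n_nodes <- config$grid_rows * config$grid_cols
  if (n < n_nodes) stop("fewer records than map nodes")
  if (anyNA(X)) stop("inputs contain missing values")
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  if (config$scale) {
    rng <- pmax(hi - lo, 1e-12)
    X <- sweep(sweep(X, 2, lo), 2, rng, "/")
    lo_s <- rep(0, p); hi_s <- rep(1, p)
  } else {
    lo_s <- lo; hi_s <- hi
  }

  set.seed(config$seed)
  grid <- som_grid_coords(config$grid_rows, config$grid_cols)
  gdist2 <- as.matrix(stats::dist(grid[c("row", "col")]))^2

  # codebook stored transposed (features x nodes) for a cheap inner loop
  W <- matrix(stats::runif(p * n_nodes, lo_s, hi_s), nrow = p)
  Xt <- t(X)
  epochs <- config$epochs
  qe <- numeric(epochs)
  for (e in seq_len(epochs)) {
    frac <- if (epochs == 1) 0 else (e - 1) / (epochs - 1)
    alpha <- config$lr_initial + frac * (config$lr_final - config$lr_initial)
    sigma <- config$radius_initial +
      frac * (config$radius_final - config$radius_initial)
    kern <- exp(-gdist2 / (2 * sigma^2))
    kern[gdist2 > sigma^2] <- 0          # only nodes within the radius move
    ord <- sample.int(n)
    for (i in ord) {
      x <- Xt[, i]
      d2 <- colSums((W - x)^2)
      bmu <- which.min(d2)
      h <- alpha * kern[bmu, ]
      upd <- which(h > 0)
      W[, upd] <- W[, upd] + (x - W[, upd, drop = FALSE]) *
        rep(h[upd], each = p)
    }
    # quantization error with the codebook frozen at end of epoch
    D <- outer(rowSums(X^2), colSums(W^2), "+") - 2 * (X %*% W)
    qe[e] <- mean(sqrt(pmax(apply(D, 1, min), 0)))
  }

  codebook <- t(W)
  if (config$scale) {
    codebook <- sweep(sweep(codebook, 2, pmax(hi - lo, 1e-12), "*"), 2, lo, "+")
  }
  colnames(codebook) <- colnames(X)
  structure(list(codebook = codebook, grid = grid, config = config,
                 columns = colnames(X), scale_lo = lo, scale_hi = hi,
                 quantization_error = qe),
            class = "som_model")
}

#' Best matching unit of a record
#'
#' Index of the map node whose codebook vector is nearest to the record in
#' Euclidean distance; ties break to the lowest node index.
#'
#' @param model A `som_model`.
#' @param record Numeric vector (length = number of codebook features) or a
#'   matrix/data frame of such rows.
#' @return Integer node index (vector for multiple rows).
#' @export
best_matching_unit <- function(model, record) {
  if (is.null(dim(record))) record <- matrix(record, nrow = 1)
  record <- as.matrix(record)
  if (ncol(record) != ncol(model$codebook)) {
    stop("record length does not match the codebook width")
  }
  W <- t(model$codebook)
  if (model$config$scale) {
    rng <- pmax(model$scale_hi - model$scale_lo, 1e-12)
    record <- sweep(sweep(record, 2, model$scale_lo), 2, rng, "/")
    W <- (W - model$scale_lo) / rng
  }
  D <- outer(rowSums(record^2), colSums(W^2), "+") - 2 * (record %*% W)
  apply(D, 1, which.min)
}

#' Records per map node (count plot)
#'
#' @param model A `som_model`.
#' @param dataset Dataset whose rows are assigned to their BMUs; must carry
#'   the model's input columns.
#' @return Data frame `node`, `row`, `col`, `count`; counts sum to the
#'   number of records and empty nodes report 0.
#' @export
node_counts <- function(model, dataset) {
  X <- as.matrix(dataset[model$columns])
  bmu <- best_matching_unit(model, X)
  out <- model$grid
  out$count <- tabulate(bmu, nbins = nrow(model$grid))
  out
}

#' Per-node category distribution of a factor (class distribution map)
#'
#' Frequencies of a factor's categories within each map node; per-node
#' frequencies sum to 1 (empty nodes report all-zero rows).
#'
#' @param model A `som_model`.
#' @param dataset Dataset carrying the model's input columns and `factor`.
#' @param factor Column whose distribution is mapped, default `"wtCat"`.
#' @return Data frame `node`, `row`, `col`, `category`, `frequency`.
#' @export
node_class_distribution <- function(model, dataset, factor = "wtCat") {
  if (!factor %in% names(dataset)) stop("unknown factor: ", factor)
  X <- as.matrix(dataset[model$columns])
  bmu <- best_matching_unit(model, X)
  cats <- sort(unique(dataset[[factor]]))
  out <- merge(model$grid, data.frame(category = cats))
  out$frequency <- 0
  for (nd in seq_len(nrow(model$grid))) {
    in_node <- bmu == nd
    if (!any(in_node)) next
    f <- tabulate(match(dataset[[factor]][in_node], cats),
                  nbins = length(cats))
    out$frequency[out$node == nd] <- f / sum(f)
  }
  out[order(out$node, out$category), ]
}

#' Codebook component of one factor across the map (component heatmap)
#'
#' @param model A `som_model`.
#' @param factor Codebook column name.
#' @return Matrix of shape (grid_rows, grid_cols) with the factor's
#'   codebook component per node (row 1 = bottom of the map), with
#'   attributes `min` and `max` for color scaling.
#' @export
component_heatmap <- function(model, factor) {
  if (!factor %in% colnames(model$codebook)) stop("unknown factor: ", factor)
  v <- model$codebook[, factor]
  m <- matrix(NA_real_, model$config$grid_rows, model$config$grid_cols)
  m[cbind(model$grid$row, model$grid$col)] <- v
  attr(m, "min") <- min(v)
  attr(m, "max") <- max(v)
  m
}

#' Full codebook profile of every node (codes plot data)
#'
#' @param model A `som_model`.
#' @return Data frame `node`, `row`, `col` plus one column per codebook
#'   feature.
#' @export
codes_profile <- function(model) {
  cbind(model$grid, as.data.frame(model$codebook))
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("Self-organizing map: %d x %d grid, %d features, %d epochs\n",
              x$config$grid_rows, x$config$grid_cols, ncol(x$codebook),
              x$config$epochs))
  cat(sprintf("final quantization error: %.4f\n",
              x$quantization_error[length(x$quantization_error)]))
  invisible(x)
}
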