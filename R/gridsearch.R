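#' The hyperparameter search space
#'
#' Defaults are the published ranges: 1-4 convolution blocks; 6, 8, 16,
#' 24, 32, 44 or 64 filters; kernel sizes 2, 4, 5, 7, 8, 10, 13; pool
#' size 2 or 4; pool stride 2 or 4; dropout 0.3, 0.35, 0.4, 0.45 or 0.5.
#' One value per axis is shared across all convolution blocks of a
#' candidate.
#'
#' @param conv_layers,filters,kernel_size,pool_size,pool_stride,dropout
#'   Numeric vectors, one per axis; each must be non-empty.
#' @return An `m6a_search_space` list.
#' @export
search_space <- function(conv_layers = c(1L, 2L, 3L, 4L),
                         filters = c(6L, 8L, 16L, 24L, 32L, 44L, 64L),
                         kernel_size = c(2L, 4L, 5L, 7L, 8L, 10L, 13L),
                         pool_size = c(2L, 4L),
                         pool_stride = c(2L, 4L),
                         dropout = c(0.3, 0.35, 0.4, 0.45, 0.5)) {
  axes <- list(conv_layers = as.integer(conv_layers),
               filters = as.integer(filters),
               kernel_size = as.integer(kernel_size),
               pool_size = as.integer(pool_size),
               pool_stride = as.integer(pool_stride),
               dropout = as.numeric(dropout))
  empty <- names(axes)[vapply(axes, length, integer(1)) == 0L]
  if (length(empty) > 0L)
    stop("empty search-space axis: ", paste(empty, collapse = ", "),
         call. = FALSE)
  structure(axes, class = "m6a_search_space")
}

# Largest feasible group count (<= 4) for group normalization given the
# filter count; the fixed stack uses 4, but 6 or 44 filters need a divisor.
gn_groups_for <- function(filters) {
  if (filters %% 4L == 0L) 4L else if (filters %% 2L == 0L) 2L else 1L
}

#' Build a candidate model spec from one grid point
#'
#' Stacks `conv_layers` blocks of Conv1D/ELU/GroupNorm/MaxPool (all blocks
#' share the candidate's filter count, kernel size and pooling), followed
#' by Flatten, Dropout, Dense(32, ELU) and the sigmoid output unit, with
#' the standard L2 penalties (0.001 conv, 0.0001 dense).
#'
#' @param conv_layers,filters,kernel_size,pool_size,pool_stride,dropout
#'   Scalar hyperparameters.
#' @param input_shape Integer pair `(length, channels)`.
#' @return An `m6a_model_spec`; errors if the shape calculus underflows
#'   (kernel or pool exceeding the remaining length).
#' @export
candidate_model_spec <- function(conv_layers, filters, kernel_size,
                                 pool_size, pool_stride, dropout,
                                 input_shape = c(51L, 4L)) {
  blocks <- list()
  for (b in seq_len(conv_layers)) {
    blocks <- c(blocks, list(
      conv1d_spec(filters, kernel_size, 1L, weight_l2 = 0.001, bias_l2 = 0.001),
      activation_spec("elu"),
      group_norm_spec(gn_groups_for(filters)),
      max_pool_spec(pool_size, pool_stride)))
  }
  model_spec(c(blocks, list(
    flatten_spec(),
    dropout_spec(dropout),
    dense_spec(32L, weight_l2 = 1e-4, bias_l2 = 1e-4, activation = "elu"),
    dense_spec(1L),
    activation_spec("sigmoid"))), input_shape = input_shape)
}

#' Enumerate the hyperparameter grid
#'
#' Forms the full Cartesian product of the axes (first axis varying
#' fastest, in the order conv_layers, filters, kernel_size, pool_size,
#' pool_stride, dropout) and marks each candidate feasible or not by
#' running the shape calculus. Infeasible candidates (window underflow on
#' the sequence axis) are retained in the table but never scored.
#'
#' @param space An [search_space()].
#' @param input_shape Integer pair `(length, channels)`.
#' @return Data frame with one row per candidate: the six axis values,
#'   `feasible`, and `n_parameters` (NA when infeasible).
#' @export
enumerate_grid <- function(space = search_space(), input_shape = c(51L, 4L)) {
  stopifnot(inherits(space, "m6a_search_space"))
  grid <- expand.grid(conv_layers = space$conv_layers,
                      filters = space$filters,
                      kernel_size = space$kernel_size,
                      pool_size = space$pool_size,
                      pool_stride = space$pool_stride,
                      dropout = space$dropout,
                      KEEP.OUT.ATTRS = FALSE)
  grid$candidate <- seq_len(nrow(grid))
  grid$feasible <- FALSE
  grid$n_parameters <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    sp <- tryCatch(
      candidate_model_spec(grid$conv_layers[i], grid$filters[i],
                           grid$kernel_size[i], grid$pool_size[i],
                           grid$pool_stride[i], grid$dropout[i],
                           input_shape = input_shape),
      error = function(e) NULL)
    if (!is.null(sp)) {
      grid$feasible[i] <- TRUE
      grid$n_parameters[i] <- count_parameters(sp)
    }
  }
  grid
}

#' Grid search selected by minimum validation loss
#'
#' Evaluates (a budgeted subsample of) the feasible grid on one fixed
#' stratified 90/10 train/validation split — not nested cross-validation —
#' training each candidate with the standard protocol and recording the
#' minimum validation loss seen during its run. Candidates are ranked by
#' ascending validation loss; ties break toward higher validation
#' accuracy, then fewer parameters.
#'
#' @param space An [search_space()].
#' @param dataset An `m6a_dataset`.
#' @param config A [training_config()] applied to every candidate.
#' @param budget Optional number of candidates to evaluate; a seeded
#'   uniform subsample of the feasible grid. Clamped (with a warning) to
#'   the feasible grid size.
#' @param seed Seed for the split and the subsample (defaults to
#'   `config$seed`).
#' @param input_shape Integer pair `(length, channels)`.
#' @return An `m6a_search_result`: `leaderboard` (evaluated candidates,
#'   ranked), `grid` (full enumeration), `best` (top row) and
#'   `best_spec` (its `m6a_model_spec`).
#' @export
run_search <- function(space = search_space(), dataset,
                       config = training_config(), budget = NULL,
                       seed = config$seed, input_shape = c(51L, 4L)) {
  stopifnot(inherits(dataset, "m6a_dataset"))
  grid <- enumerate_grid(space, input_shape = input_shape)
  feas <- which(grid$feasible)
  if (length(feas) == 0L) stop("no feasible candidate in the grid", call. = FALSE)
  if (!is.null(budget)) {
    budget <- as.integer(budget)
    if (budget > length(feas)) {
      warning(sprintf("budget %d exceeds the %d feasible candidates; clamping",
                      budget, length(feas)))
      budget <- length(feas)
    }
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    feas <- sort(sample(feas, budget))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  enc <- encode_dataset(dataset)
  fold <- make_folds(dataset$label, k = 10L, seed = seed, stratify = TRUE)
  val_idx <- which(fold == 1L)
  tr_idx <- which(fold != 1L)
  tr <- list(x = enc$x[tr_idx, , , drop = FALSE], y = enc$y[tr_idx])
  va <- list(x = enc$x[val_idx, , , drop = FALSE], y = enc$y[val_idx])
  rows <- vector("list", length(feas))
  for (j in seq_along(feas)) {
    i <- feas[j]
    sp <- candidate_model_spec(grid$conv_layers[i], grid$filters[i],
                               grid$kernel_size[i], grid$pool_size[i],
                               grid$pool_stride[i], grid$dropout[i],
                               input_shape = input_shape)
    fit <- train_fold(sp, config, tr, va)
    rows[[j]] <- cbind(grid[i, c("candidate", "conv_layers", "filters",
                                 "kernel_size", "pool_size", "pool_stride",
                                 "dropout", "n_parameters")],
                       data.frame(val_loss = fit$min_val_loss,
                                  val_acc = fit$best_val_acc,
                                  best_epoch = fit$best_epoch))
  }
  lb <- do.call(rbind, rows)
  lb <- lb[order(lb$val_loss, -lb$val_acc, lb$n_parameters), , drop = FALSE]
  rownames(lb) <- NULL
  best <- lb[1, , drop = FALSE]
  best_spec <- candidate_model_spec(best$conv_layers, best$filters,
                                    best$kernel_size, best$pool_size,
                                    best$pool_stride, best$dropout,
                                    input_shape = input_shape)
  structure(list(leaderboard = lb, grid = grid, best = best,
                 best_spec = best_spec, seed = seed, config = config),
            class = "m6a_search_result")
}

#' @export
print.m6a_search_result <- function(x, ...) {
  cat(sprintf("grid search: %d candidates evaluated (of %d feasible / %d total)\n",
              nrow(x$leaderboard), sum(x$grid$feasible), nrow(x$grid)))
  print(utils::head(x$leaderboard, 5), row.names = FALSE)
  invisible(x)
}
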