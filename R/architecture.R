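# Declarative layer specifications and a pure shape-inference calculus.
# All convolutions are "valid" (no padding); pooling uses floor arithmetic.

#' Layer specification constructors
#'
#' Build the declarative pieces of a [model_spec()]. Each returns a plain
#' list with a `type` field; [infer_shapes()] and [build_model()] consume
#' them.
#'
#' @param filters,kernel_size,stride Conv1D: number of filters, kernel
#'   width (nt) and stride. Convolution is unpadded ("valid").
#' @param weight_l2,bias_l2 L2 penalty coefficients added to the loss as
#'   `lambda * sum(w^2)`.
#' @param fun Activation name, `"elu"` or `"sigmoid"`.
#' @param groups Number of channel groups for group normalization; must
#'   divide the incoming channel count.
#' @param epsilon Numerical stabilizer inside the normalization.
#' @param pool_size,pool_stride Max-pooling window and stride.
#' @param rate Dropout rate in `[0, 1)` (inverted dropout, training only).
#' @param units Dense layer width.
#' @param activation Dense activation: `"elu"`, `"sigmoid"` or `"none"`.
#' @return A layer spec list.
#' @name layer_specs
NULL

#' @rdname layer_specs
#' @export
conv1d_spec <- function(filters, kernel_size, stride = 1L,
                        weight_l2 = 0, bias_l2 = 0) {
  stopifnot(filters >= 1L, kernel_size >= 1L, stride >= 1L,
            weight_l2 >= 0, bias_l2 >= 0)
  list(type = "conv1d", filters = as.integer(filters),
       kernel_size = as.integer(kernel_size), stride = as.integer(stride),
       weight_l2 = weight_l2, bias_l2 = bias_l2)
}

#' @rdname layer_specs
#' @export
activation_spec <- function(fun = c("elu", "sigmoid")) {
  fun <- match.arg(fun)
  list(type = "activation", fun = fun)
}

#' @rdname layer_specs
#' @export
group_norm_spec <- function(groups, epsilon = 1e-5) {
  stopifnot(groups >= 1L, epsilon > 0)
  list(type = "group_norm", groups = as.integer(groups), epsilon = epsilon)
}

#' @rdname layer_specs
#' @export
max_pool_spec <- function(pool_size, pool_stride) {
  stopifnot(pool_size >= 1L, pool_stride >= 1L)
  list(type = "max_pool", pool_size = as.integer(pool_size),
       pool_stride = as.integer(pool_stride))
}

#' @rdname layer_specs
#' @export
dropout_spec <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}

#' @rdname layer_specs
#' @export
flatten_spec <- function() list(type = "flatten")

#' @rdname layer_specs
#' @export
dense_spec <- function(units, weight_l2 = 0, bias_l2 = 0,
                       activation = c("none", "elu", "sigmoid")) {
  activation <- match.arg(activation)
  stopifnot(units >= 1L, weight_l2 >= 0, bias_l2 >= 0)
  list(type = "dense", units = as.integer(units), weight_l2 = weight_l2,
       bias_l2 = bias_l2, activation = activation)
}

#' Assemble a model specification
#'
#' @param layers List of layer specs (see [layer_specs]).
#' @param input_shape Integer pair `(length, channels)`; default `(51, 4)`
#'   for one-hot encoded 51-nt windows.
#' @return An object of class `m6a_model_spec`. Construction fails if the
#'   shape calculus cannot be carried through the stack.
#' @export
model_spec <- function(layers, input_shape = c(51L, 4L)) {
  stopifnot(is.list(layers), length(input_shape) == 2L, all(input_shape >= 1L))
  out <- structure(list(layers = layers,
                        input_shape = as.integer(input_shape)),
                   class = "m6a_model_spec")
  infer_shapes(out)  # errors on an infeasible stack
  out
}

#' The default two-block convolutional architecture
#'
#' The fixed stack used for m6A window classification:
#' Input(51,4) -> Conv1D(16,5,1) -> ELU -> GroupNorm(4) -> MaxPool(4,2) ->
#' Conv1D(16,5,1) -> ELU -> GroupNorm(4) -> MaxPool(4,2) -> Flatten ->
#' Dropout(0.35) -> Dense(32, ELU) -> Dense(1) -> Sigmoid.
#' Both convolutions carry L2 penalties of 0.001 on weights and bias; the
#' 32-unit dense layer carries 0.0001 on both; the final unit is
#' unregularized.
#'
#' @param input_shape Integer pair `(length, channels)`.
#' @return An `m6a_model_spec`.
#' @export
default_model_spec <- function(input_shape = c(51L, 4L)) {
  model_spec(list(
    conv1d_spec(16L, 5L, 1L, weight_l2 = 0.001, bias_l2 = 0.001),
    activation_spec("elu"),
    group_norm_spec(4L),
    max_pool_spec(4L, 2L),
    conv1d_spec(16L, 5L, 1L, weight_l2 = 0.001, bias_l2 = 0.001),
    activation_spec("elu"),
    group_norm_spec(4L),
    max_pool_spec(4L, 2L),
    flatten_spec(),
    dropout_spec(0.35),
    dense_spec(32L, weight_l2 = 1e-4, bias_l2 = 1e-4, activation = "elu"),
    dense_spec(1L),
    activation_spec("sigmoid")
  ), input_shape = input_shape)
}

#' Infer per-layer output shapes
#'
#' Pure arithmetic over a model spec. Valid convolution and max pooling
#' shrink the sequence axis as `floor((L - k)/s) + 1`; activations, group
#' normalization and dropout preserve shape; flatten collapses
#' `(L, C)` to `L*C`; dense maps to its unit count.
#'
#' @param spec An `m6a_model_spec`.
#' @return List of shapes, one per layer (plus the input as element
#'   `"input"`): integer pairs `(length, channels)` before flatten, single
#'   integers after. Errors if a kernel or pool window exceeds the current
#'   length, or group counts do not divide channels.
#' @export
infer_shapes <- function(spec) {
  stopifnot(inherits(spec, "m6a_model_spec") || is.list(spec))
  shape <- as.integer(spec$input_shape)
  out <- list(input = shape)
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    nm <- sprintf("%s_%d", ly$type, i)
    shape <- switch(ly$type,
      conv1d = {
        if (length(shape) != 2L)
          stop("conv1d requires a (length, channels) input", call. = FALSE)
        if (ly$kernel_size > shape[1])
          stop(sprintf("infeasible architecture: kernel %d exceeds length %d at layer %d",
                       ly$kernel_size, shape[1], i), call. = FALSE)
        c((shape[1] - ly$kernel_size) %/% ly$stride + 1L, ly$filters)
      },
      max_pool = {
        if (length(shape) != 2L)
          stop("max_pool requires a (length, channels) input", call. = FALSE)
        if (ly$pool_size > shape[1])
          stop(sprintf("infeasible architecture: pool %d exceeds length %d at layer %d",
                       ly$pool_size, shape[1], i), call. = FALSE)
        c((shape[1] - ly$pool_size) %/% ly$pool_stride + 1L, shape[2])
      },
      group_norm = {
        if (length(shape) != 2L || shape[2] %% ly$groups != 0L)
          stop(sprintf("group_norm: %d groups do not divide %d channels at layer %d",
                       ly$groups, shape[2], i), call. = FALSE)
        shape
      },
      activation = shape,
      dropout = shape,
      flatten = prod(shape),
      dense = {
        if (length(shape) != 1L)
          stop("dense requires a flat input (insert flatten)", call. = FALSE)
        ly$units
      },
      stop("unknown layer type: ", ly$type, call. = FALSE))
    out[[nm]] <- as.integer(shape)
  }
  out
}

#' Count trainable parameters
#'
#' Closed forms: Conv1D has `(k * C_in + 1) * f` parameters, group
#' normalization `2 * C` (per-channel scale and shift), dense
#' `(d_in + 1) * units`; other layers have none.
#'
#' @param spec An `m6a_model_spec`.
#' @return Integer total.
#' @export
count_parameters <- function(spec) {
  shapes <- infer_shapes(spec)
  total <- 0L
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    inshape <- shapes[[i]]  # shape entering layer i (shapes[[1]] is input)
    total <- total + switch(ly$type,
      conv1d = (ly$kernel_size * inshape[2] + 1L) * ly$filters,
      group_norm = 2L * inshape[2],
      dense = (inshape[1] + 1L) * ly$units,
      0L)
  }
  as.integer(total)
}

#' @export
print.m6a_model_spec <- function(x, ...) {
  shapes <- infer_shapes(x)
  cat(sprintf("m6a_model_spec: input (%s), %d layers, %d parameters\n",
              paste(x$input_shape, collapse = ", "), length(x$layers),
              count_parameters(x)))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    desc <- switch(ly$type,
      conv1d = sprintf("Conv1D(%d, %d, %d)", ly$filters, ly$kernel_size, ly$stride),
      activation = toupper(ly$fun),
      group_norm = sprintf("GroupNorm(%d)", ly$groups),
      max_pool = sprintf("MaxPool1D(%d, %d)", ly$pool_size, ly$pool_stride),
      dropout = sprintf("Dropout(%.2f)", ly$rate),
      flatten = "Flatten",
      dense = sprintf("Dense(%d%s)", ly$units,
                      if (ly$activation == "none") "" else paste0(", ", ly$activation)))
    cat(sprintf("  %-22s (%s)\n", desc, paste(shapes[[i + 1L]], collapse = ", ")))
  }
  invisible(x)
}

#' Training hyperparameters
#'
#' Defaults follow the published protocol: SGD with momentum 0.95,
#' learning rate 0.003, binary cross-entropy loss, at most 100 epochs of
#' mini-batches of 32, early stopping with patience 30 on validation
#' accuracy, checkpointing the best-validation-accuracy weights.
#'
#' @param learning_rate SGD step size.
#' @param momentum SGD momentum coefficient.
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param monitor Validation quantity watched for checkpointing and early
#'   stopping: `"val_acc"` (default, maximized) or `"val_loss"`
#'   (minimized).
#' @param seed Integer seed controlling weight init, shuffling, dropout.
#' @return A `m6a_training_config` list.
#' @export
training_config <- function(learning_rate = 0.003, momentum = 0.95,
                            epochs = 100L, batch_size = 32L,
                            patience = 30L, monitor = c("val_acc", "val_loss"),
                            seed = 1L) {
  monitor <- match.arg(monitor)
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, epochs >= 1L,
            batch_size >= 1L, patience >= 1L, patience <= epochs)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patience = as.integer(patience), monitor = monitor,
                 seed = as.integer(seed)),
            class = "m6a_training_config")
}
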