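#' Build a trainable model from a specification
#'
#' Initializes Glorot-uniform weights (zero biases, unit group-norm scale)
#' under the configuration seed and returns an untrained model handle.
#'
#' @param spec An [model_spec()] / [default_model_spec()].
#' @param config A [training_config()]; its `seed` drives initialization.
#' @return An object of class `m6a_model` holding the spec, parameters and
#'   config snapshot.
#' @export
build_model <- function(spec, config = training_config()) {
  stopifnot(inherits(spec, "m6a_model_spec"),
            inherits(config, "m6a_training_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  params <- nn_init_params(spec)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(spec = spec, params = params, config = config,
                 trained = FALSE, history = NULL),
            class = "m6a_model")
}

#' @export
print.m6a_model <- function(x, ...) {
  cat(sprintf("m6a_model (%s): %d parameters, seed %d\n",
              if (x$trained) "trained" else "untrained",
              count_parameters(x$spec), x$config$seed))
  print(x$spec)
  invisible(x)
}

#' Predict methylation probabilities
#'
#' Runs the forward pass in inference mode (dropout off; group
#' normalization is per-sample, so no training/inference discrepancy
#' exists for it). Output is the sigmoid probability of the positive
#' (methylated) class.
#'
#' @param object An `m6a_model`.
#' @param newdata An `m6a_dataset`, an encoded list from
#'   [encode_dataset()], or a 3-D array `(n, length, 4)`.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.m6a_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "m6a_dataset")) encode_dataset(newdata)$x
       else if (is.list(newdata) && !is.null(newdata$x)) newdata$x
       else newdata
  stopifnot(is.array(x), length(dim(x)) == 3L)
  exp_shape <- object$spec$input_shape
  if (!identical(as.integer(dim(x)[2:3]), exp_shape))
    stop(sprintf("input shape (%d, %d) does not match the model's expected (%d, %d)",
                 dim(x)[2], dim(x)[3], exp_shape[1], exp_shape[2]), call. = FALSE)
  as.numeric(nn_forward(object$spec, object$params, x, training = FALSE)$out)
}

# Accuracy and BCE loss of a parameter set on an encoded set (inference
# mode, no L2 term in the reported loss).
evaluate_params <- function(spec, params, x, y, threshold = 0.5) {
  z <- as.numeric(nn_forward(spec, params, x, training = FALSE,
                             upto = length(spec$layers) - 1L)$out)
  p <- sigmoid(z)
  acc <- mean((p >= threshold) == (y == 1L))
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  list(acc = acc, loss = loss, scores = p)
}

#' Train a model on a train/validation split
#'
#' Mini-batch SGD with momentum on binary cross-entropy (plus L2
#' penalties), shuffling the training set each epoch. After every epoch
#' the monitored validation quantity (accuracy by default; loss with
#' `monitor = "val_loss"`) is measured; the parameters achieving the best
#' value are checkpointed and training halts early when it has not
#' improved for `patience` consecutive epochs (or at the epoch cap). The
#' returned model carries the checkpointed best weights.
#' Validation loss is recorded per epoch for hyperparameter selection.
#'
#' @param spec An `m6a_model_spec`.
#' @param config A [training_config()].
#' @param train,validation `m6a_dataset`s or encoded lists
#'   (see [encode_dataset()]); must be disjoint, non-empty sets.
#' @param verbose Print per-epoch progress.
#' @return A trained `m6a_model` whose `history` holds the per-epoch log
#'   (`epoch`, `train_loss`, `val_loss`, `val_acc`), `best_epoch`,
#'   `best_val_acc`, `best_val_loss` (validation loss at the checkpointed
#'   epoch) and `min_val_loss` (minimum over epochs).
#' @export
train_fold <- function(spec, config, train, validation, verbose = FALSE) {
  stopifnot(inherits(spec, "m6a_model_spec"),
            inherits(config, "m6a_training_config"))
  enc <- function(d) if (inherits(d, "m6a_dataset")) encode_dataset(d) else d
  tr <- enc(train); va <- enc(validation)
  if (is.null(tr$x) || length(tr$y) == 0L) stop("empty training set", call. = FALSE)
  if (is.null(va$x) || length(va$y) == 0L) stop("empty validation set", call. = FALSE)

  set.seed(config$seed)
  params <- nn_init_params(spec)
  velocity <- nn_zero_like(params)
  n <- length(tr$y)
  monitor <- config$monitor %||% "val_acc"
  best <- list(acc = -Inf, loss = Inf, params = params, epoch = 0L)
  since_improve <- 0L
  log <- vector("list", config$epochs)
  min_val_loss <- Inf
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq.int(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      lg <- nn_loss_grads(spec, params,
                          tr$x[idx, , , drop = FALSE], tr$y[idx],
                          training = TRUE)
      st <- nn_sgd_step(params, lg$grads, velocity,
                        config$learning_rate, config$momentum)
      params <- st$params; velocity <- st$velocity
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    ev <- evaluate_params(spec, params, va$x, va$y)
    min_val_loss <- min(min_val_loss, ev$loss)
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                               val_loss = ev$loss, val_acc = ev$acc)
    if (verbose)
      message(sprintf("epoch %3d  train_loss %.4f  val_loss %.4f  val_acc %.4f",
                      epoch, ep_loss / nb, ev$loss, ev$acc))
    improved <- if (monitor == "val_loss") ev$loss < best$loss else ev$acc > best$acc
    if (improved) {
      best <- list(acc = ev$acc, loss = ev$loss, params = params, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$patience) break
    }
  }
  structure(list(spec = spec, params = best$params, config = config,
                 trained = TRUE,
                 history = do.call(rbind, log[!vapply(log, is.null, logical(1))]),
                 best_epoch = best$epoch, best_val_acc = best$acc,
                 best_val_loss = best$loss, min_val_loss = min_val_loss),
            class = "m6a_model")
}

#' Save / load a model as JSON
#'
#' The checkpoint embeds the layer specification, input shape, training
#' configuration and all weights as plain-text JSON, so saved models are
#' portable and diffable. Floating point values are serialized at full
#' precision (~15 significant digits).
#'
#' @param model An `m6a_model`.
#' @param path Output/input file path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   reconstructed `m6a_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "m6a_model"))
  payload <- list(
    format = "m6acnn-model-1",
    input_shape = model$spec$input_shape,
    layers = model$spec$layers,
    config = unclass(model$config),
    trained = model$trained,
    params = lapply(model$params, function(p) {
      if (is.null(p)) return(NULL)
      lapply(p, function(w) {
        if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
        else list(dim = length(w), data = as.numeric(w))
      })
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) NULL)
  if (!identical(payload$format, "m6acnn-model-1"))
    stop("not an m6acnn model checkpoint: ", path, call. = FALSE)
  layers <- lapply(payload$layers, function(ly) {
    for (nm in c("filters", "kernel_size", "stride", "groups", "pool_size",
                 "pool_stride", "units"))
      if (!is.null(ly[[nm]])) ly[[nm]] <- as.integer(ly[[nm]])
    ly
  })
  spec <- model_spec(layers, input_shape = as.integer(unlist(payload$input_shape)))
  cfg <- do.call(training_config, payload$config)
  params <- lapply(payload$params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(w) {
      d <- as.integer(unlist(w$dim))
      v <- as.numeric(unlist(w$data))
      if (length(d) == 2L) matrix(v, d[1], d[2]) else v
    })
  })
  structure(list(spec = spec, params = params, config = cfg,
                 trained = isTRUE(payload$trained), history = NULL),
            class = "m6a_model")
}
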