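# Minimal 1-D CNN engine: forward/backward over the declarative layer
# specs, trained with SGD + momentum. Batches are arrays (batch, length,
# channels); after flatten, matrices (batch, features). Convolution is
# implemented as im2col + matrix multiply; the column layout matches the
# natural flattening of the (kernel, channels, filters) weight array, i.e.
# column index = tap + (channel - 1) * kernel_size.

# ELU has alpha fixed at 1 (conventional default); both directions are
# compiled (src/kernels.cpp), with the gradient recovered from the
# activation output. The dim attribute survives the round trip.
elu <- function(x) {
  y <- cpp_elu(as.numeric(x))
  dim(y) <- dim(x)
  y
}
elu_grad_from_out <- function(y) {
  g <- cpp_elu_grad_from_out(as.numeric(y))
  dim(g) <- dim(y)
  g
}
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# Initialize trainable parameters for each layer. Uses the ambient RNG;
# callers seed it. Conv weights are (kernel*C_in) x filters matrices;
# dense weights d_in x units; group norm gets per-channel gamma/beta.
nn_init_params <- function(spec) {
  shapes <- infer_shapes(spec)
  params <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    inshape <- shapes[[i]]
    params[[i]] <- switch(ly$type,
      conv1d = {
        fan_in <- ly$kernel_size * inshape[2]
        fan_out <- ly$kernel_size * ly$filters
        list(W = matrix(glorot_uniform(fan_in, fan_out, fan_in * ly$filters),
                        fan_in, ly$filters),
             b = rep(0, ly$filters))
      },
      dense = list(
        W = matrix(glorot_uniform(inshape[1], ly$units, inshape[1] * ly$units),
                   inshape[1], ly$units),
        b = rep(0, ly$units)),
      group_norm = list(gamma = rep(1, inshape[2]), beta = rep(0, inshape[2])),
      NULL)
  }
  params
}

nn_forward_layer <- function(ly, par, x, training, cache_wanted) {
  cache <- NULL
  out <- switch(ly$type,
    conv1d = {
      d <- dim(x)
      st <- cpp_conv1d_forward(x, par$W, par$b, ly$kernel_size, ly$stride,
                               cache_wanted)
      if (cache_wanted) cache <- list(cols = st$cols, in_dim = d)
      st$out
    },
    activation = {
      y <- if (ly$fun == "elu") elu(x) else sigmoid(x)
      if (cache_wanted) cache <- list(y = y)
      y
    },
    group_norm = {
      st <- cpp_groupnorm_forward(x, par$gamma, par$beta, ly$groups,
                                  ly$epsilon)
      if (cache_wanted)
        cache <- list(xhat = st$xhat, inv_sd = st$inv_sd, dim = dim(x))
      st$y
    },
    max_pool = {
      st <- cpp_maxpool_forward(x, ly$pool_size, ly$pool_stride)
      if (cache_wanted) cache <- list(arg = st$arg, in_dim = dim(x))
      st$out
    },
    dropout = {
      if (training && ly$rate > 0) {
        keep <- 1 - ly$rate
        mask <- array(rbinom(length(x), 1L, keep) / keep, dim = dim(x) %||% length(x))
        if (is.matrix(x)) mask <- matrix(mask, nrow(x), ncol(x))
        if (cache_wanted) cache <- list(mask = mask)
        x * mask
      } else {
        if (cache_wanted) cache <- list(mask = NULL)
        x
      }
    },
    flatten = {
      d <- dim(x)
      if (cache_wanted) cache <- list(in_dim = d)
      matrix(x, d[1], prod(d[-1]))
    },
    dense = {
      z <- x %*% par$W
      z <- z + rep(par$b, each = nrow(z))
      a <- switch(ly$activation, none = z, elu = elu(z), sigmoid = sigmoid(z))
      if (cache_wanted) cache <- list(x = x, a = a)
      a
    },
    stop("unknown layer type: ", ly$type))
  list(out = out, cache = cache)
}

# Full forward pass. `training` enables dropout; `upto` stops before layer
# index upto+1 (used to fuse the final sigmoid with the loss).
nn_forward <- function(spec, params, x, training = FALSE,
                       cache_wanted = FALSE, upto = length(spec$layers)) {
  caches <- if (cache_wanted) vector("list", upto) else NULL
  for (i in seq_len(upto)) {
    st <- nn_forward_layer(spec$layers[[i]], params[[i]], x, training,
                           cache_wanted)
    x <- st$out
    if (cache_wanted) caches[[i]] <- st$cache
  }
  list(out = x, caches = caches)
}

nn_backward_layer <- function(ly, par, cache, dy) {
  switch(ly$type,
    conv1d = {
      d <- cache$in_dim
      bk <- cpp_conv1d_backward(dy, cache$cols, par$W, d[2], d[3],
                                ly$kernel_size, ly$stride)
      list(dx = bk$dx, dpar = list(W = bk$dW, b = as.numeric(bk$db)))
    },
    activation = {
      if (ly$fun == "elu") list(dx = dy * elu_grad_from_out(cache$y), dpar = NULL)
      else list(dx = dy * cache$y * (1 - cache$y), dpar = NULL)
    },
    group_norm = {
      bk <- cpp_groupnorm_backward(dy, cache$xhat, cache$inv_sd, par$gamma,
                                   ly$groups)
      list(dx = bk$dx, dpar = list(gamma = as.numeric(bk$dgamma),
                                   beta = as.numeric(bk$dbeta)))
    },
    max_pool = {
      list(dx = cpp_maxpool_backward(dy, cache$arg, cache$in_dim[2],
                                     ly$pool_stride),
           dpar = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, dpar = NULL)
      else list(dx = dy * cache$mask, dpar = NULL)
    },
    flatten = list(dx = array(dy, dim = cache$in_dim), dpar = NULL),
    dense = {
      dz <- switch(ly$activation,
                   none = dy,
                   elu = dy * elu_grad_from_out(cache$a),
                   sigmoid = dy * cache$a * (1 - cache$a))
      list(dx = tcrossprod(dz, par$W),
           dpar = list(W = crossprod(cache$x, dz), b = colSums(dz)))
    })
}

l2_penalty <- function(spec, params) {
  pen <- 0
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type %in% c("conv1d", "dense")) {
      pen <- pen + ly$weight_l2 * sum(params[[i]]$W^2) +
        ly$bias_l2 * sum(params[[i]]$b^2)
    }
  }
  pen
}

# Loss and gradients for one mini-batch. The trailing sigmoid activation is
# fused with binary cross-entropy for numerical stability: with logits z,
# loss = mean(softplus(z) - y*z) and dz = (sigmoid(z) - y)/B.
nn_loss_grads <- function(spec, params, x, y, training = TRUE) {
  nl <- length(spec$layers)
  last <- spec$layers[[nl]]
  fuse <- last$type == "activation" && last$fun == "sigmoid"
  if (!fuse)
    stop("the model must end in a sigmoid activation for BCE training",
         call. = FALSE)
  fw <- nn_forward(spec, params, x, training = training, cache_wanted = TRUE,
                   upto = nl - 1L)
  z <- as.numeric(fw$out)
  B <- length(z)
  stopifnot(B == length(y))
  data_loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  loss <- data_loss + l2_penalty(spec, params)
  dz <- matrix((sigmoid(z) - y) / B, B, 1L)
  grads <- vector("list", nl)
  dy <- dz
  for (i in seq.int(nl - 1L, 1L)) {
    bk <- nn_backward_layer(spec$layers[[i]], params[[i]], fw$caches[[i]], dy)
    grads[i] <- list(bk$dpar)  # [i]<- keeps NULL slots instead of shrinking
    dy <- bk$dx
  }
  # L2 contributions (loss adds lambda * sum(w^2), so gradient 2*lambda*w)
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type %in% c("conv1d", "dense") && !is.null(grads[[i]])) {
      grads[[i]]$W <- grads[[i]]$W + 2 * ly$weight_l2 * params[[i]]$W
      grads[[i]]$b <- grads[[i]]$b + 2 * ly$bias_l2 * params[[i]]$b
    }
  }
  list(loss = loss, data_loss = data_loss, grads = grads)
}

# One SGD + momentum update: v <- mu*v - lr*g; w <- w + v.
nn_sgd_step <- function(params, grads, velocity, lr, momentum) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      v <- momentum * velocity[[i]][[nm]] - lr * g
      velocity[[i]][[nm]] <- v
      params[[i]][[nm]] <- params[[i]][[nm]] + v
    }
  }
  list(params = params, velocity = velocity)
}

nn_zero_like <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(w) w * 0)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
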