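test_that("the default spec is the published 13-layer stack", {
  sp <- default_model_spec()
  expect_length(sp$layers, 13L)
  conv1 <- sp$layers[[1]]
  expect_equal(conv1[c("filters", "kernel_size", "stride")],
               list(filters = 16L, kernel_size = 5L, stride = 1L))
  expect_equal(conv1$weight_l2, 0.001)
  expect_equal(conv1$bias_l2, 0.001)
  expect_equal(sp$layers[[10]]$rate, 0.35)
  dense <- sp$layers[[11]]
  expect_equal(dense$units, 32L)
  expect_equal(dense$weight_l2, 1e-4)
  expect_identical(sp$layers[[13]]$fun, "sigmoid")
})

test_that("shape inference reproduces the published output-shape column", {
  shapes <- unname(infer_shapes(default_model_spec()))
  expect_equal(shapes, list(
    c(51L, 4L),            # input
    c(47L, 16L),           # Conv1D(16, 5, 1)
    c(47L, 16L),           # ELU
    c(47L, 16L),           # GroupNorm(4)
    c(22L, 16L),           # MaxPool1D(4, 2)
    c(18L, 16L),           # Conv1D(16, 5, 1)
    c(18L, 16L),           # ELU
    c(18L, 16L),           # GroupNorm(4)
    c(8L, 16L),            # MaxPool1D(4, 2)
    128L,                  # Flatten
    128L,                  # Dropout
    32L,                   # Dense(32)
    1L,                    # Dense(1)
    1L))                   # Sigmoid
})

test_that("shape calculus handles degenerate and infeasible stacks", {
  sp <- model_spec(list(conv1d_spec(7L, 1L, 1L)), input_shape = c(33L, 5L))
  expect_equal(unname(infer_shapes(sp))[[2]], c(33L, 7L))
  expect_error(model_spec(list(conv1d_spec(4L, 60L)), input_shape = c(51L, 4L)),
               "infeasible")
  expect_error(model_spec(list(max_pool_spec(52L, 2L)), input_shape = c(51L, 4L)),
               "infeasible")
  expect_error(model_spec(list(group_norm_spec(3L)), input_shape = c(51L, 4L)),
               "do not divide")
})

test_that("conv/pool lengths agree with a brute-force window enumerator", {
  set.seed(7)
  for (rep in 1:100) {
    L <- sample(5:80, 1)
    w <- sample(seq_len(min(L, 13L)), 1)
    s <- sample(1:4, 1)
    sp <- model_spec(list(conv1d_spec(3L, w, s)), input_shape = c(L, 4L))
    expect_equal(unname(infer_shapes(sp))[[2]][1], window_count_oracle(L, w, s))
    sp2 <- model_spec(list(max_pool_spec(w, s)), input_shape = c(L, 4L))
    expect_equal(unname(infer_shapes(sp2))[[2]][1], window_count_oracle(L, w, s))
  }
})

test_that("parameter counting follows the closed forms", {
  expect_equal(count_parameters(model_spec(list(), input_shape = c(51L, 4L))), 0L)
  expect_equal(count_parameters(model_spec(list(conv1d_spec(16L, 5L)),
                                           input_shape = c(51L, 4L))),
               (5L * 4L + 1L) * 16L)  # 336
  sp <- model_spec(list(flatten_spec(), dense_spec(32L)),
                   input_shape = c(32L, 4L))
  expect_equal(count_parameters(sp), (128L + 1L) * 32L)  # 4128
  # full default: conv 336 + gn 32 + conv (5*16+1)*16 + gn 32 + dense 4128 + dense 33
  expect_equal(count_parameters(default_model_spec()),
               336L + 32L + 1296L + 32L + 4128L + 33L)
})

test_that("built models emit probabilities and match the shape calculus", {
  model <- build_model(default_model_spec(), training_config(seed = 3))
  x <- array(one_hot_encode(random_rna(1)), dim = c(1L, 51L, 4L))
  p <- predict(model, x)
  expect_length(p, 1L)
  expect_gt(p, 0)
  expect_lt(p, 1)
  # per-layer output dims equal the spec calculus
  shapes <- infer_shapes(model$spec)
  h <- array(one_hot_encode(random_rna(1)), dim = c(1L, 51L, 4L))
  for (i in seq_along(model$spec$layers)) {
    st <- m6acnn:::nn_forward_layer(model$spec$layers[[i]], model$params[[i]],
                                    h, training = FALSE, cache_wanted = FALSE)
    h <- st$out
    got <- if (is.null(dim(h))) length(h) else as.integer(dim(h)[-1])
    expect_equal(got, as.integer(shapes[[i + 1L]]),
                 info = sprintf("layer %d", i))
  }
})

test_that("an untrained model is at chance on balanced random data", {
  accs <- vapply(0:4, function(s) {
    ds <- simulate_null_dataset(200L, seed = 100L + s)
    model <- build_model(default_model_spec(), training_config(seed = s))
    enc <- encode_dataset(ds)
    mean((predict(model, enc$x) >= 0.5) == (enc$y == 1))
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("analytic gradients match finite differences everywhere", {
  spec <- tiny_spec()
  set.seed(42)
  params <- m6acnn:::nn_init_params(spec)
  B <- 5L
  x <- array(runif(B * 10 * 4), dim = c(B, 10, 4))
  y <- rbinom(B, 1, 0.5)
  lg <- m6acnn:::nn_loss_grads(spec, params, x, y, training = TRUE)
  eps <- 1e-6
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      w <- params[[i]][[nm]]
      # spot-check a deterministic subset of each tensor
      for (j in unique(round(seq(1, length(w), length.out = 12)))) {
        p1 <- params; p1[[i]][[nm]][j] <- w[j] + eps
        p2 <- params; p2[[i]][[nm]][j] <- w[j] - eps
        num <- (m6acnn:::nn_loss_grads(spec, p1, x, y, TRUE)$loss -
                m6acnn:::nn_loss_grads(spec, p2, x, y, TRUE)$loss) / (2 * eps)
        ana <- lg$grads[[i]][[nm]][j]
        expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-5)
      }
    }
  }
})

test_that("dropout only affects training: inference is deterministic", {
  sp <- tiny_spec(dropout = 0.5)
  model <- build_model(sp, training_config(seed = 9))
  x <- array(runif(3 * 10 * 4), dim = c(3, 10, 4))
  expect_identical(predict(model, x), predict(model, x))
  # training mode with an active dropout mask perturbs the loss
  set.seed(1)
  l1 <- m6acnn:::nn_loss_grads(sp, model$params, x, c(1, 0, 1), TRUE)$loss
  set.seed(2)
  l2 <- m6acnn:::nn_loss_grads(sp, model$params, x, c(1, 0, 1), TRUE)$loss
  expect_false(identical(l1, l2))
})

test_that("model checkpoints round-trip through JSON", {
  model <- build_model(tiny_spec(), training_config(seed = 5))
  x <- array(runif(4 * 10 * 4), dim = c(4, 10, 4))
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(predict(back, x), predict(model, x), tolerance = 1e-12)
  expect_equal(back$spec$layers, model$spec$layers)
  expect_error(load_model(write_temp_fasta(random_rna(1))), "not an m6acnn")
})

test_that("training config validates its invariants", {
  expect_error(training_config(patience = 50L, epochs = 20L))
  expect_error(training_config(learning_rate = 0))
  expect_error(training_config(monitor = "nonsense"))
  cfg <- training_config()
  expect_equal(cfg$learning_rate, 0.003)
  expect_equal(cfg$momentum, 0.95)
  expect_equal(cfg$epochs, 100L)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$patience, 30L)
})
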