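test_that("simulated datasets have the requested structure", {
  ds <- simulate_dataset(30L, 20L, seed = 1L)
  cts <- dataset_counts(ds)
  expect_equal(unname(cts), c(30L, 20L, 50L))
  expect_true(all(nchar(ds$seq) == 51L))
  # generated data pass the strict validations
  expect_silent(m6a_dataset(ds$id, ds$seq, ds$label))
})

test_that("motif planting follows the insertion probability", {
  mm <- motif_model()  # GGACU at offset 24, probability 1
  ds <- simulate_dataset(200L, 200L, model = mm, seed = 2L)
  at_offset <- substr(ds$seq, 25L, 29L) == "GGACU"
  expect_true(all(at_offset[ds$label == 1L]))
  expect_true(all(!at_offset[ds$label == 0L]))  # rejected among negatives
  # fractional insertion: binomial check within 3 standard errors
  p <- 0.5
  ds2 <- simulate_dataset(2000L, 0L,
                          model = motif_model(insertion_probability = p),
                          seed = 3L)
  obs <- mean(substr(ds2$seq, 25L, 29L) == "GGACU")
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(obs - p), 3 * se + 0.001)  # +chance hits at ~4^-5
})

test_that("generation is deterministic per seed and validates the motif", {
  a <- simulate_dataset(25L, 25L, seed = 7L)
  b <- simulate_dataset(25L, 25L, seed = 7L)
  expect_identical(a, b)
  expect_false(identical(a, simulate_dataset(25L, 25L, seed = 8L)))
  expect_error(simulate_dataset(5L, 5L, model = motif_model(offset = 49L)),
               "exceeds")
  expect_error(motif_model(motif = "GGXCU"), "A, C, G, U")
})

test_that("null datasets are balanced and content-independent", {
  ds <- simulate_null_dataset(100L, seed = 4L)
  expect_equal(unname(dataset_counts(ds))[1:2], c(50L, 50L))
  expect_identical(ds, simulate_null_dataset(100L, seed = 4L))
  expect_error(simulate_null_dataset(7L), "even")
})

test_that("accuracy rises with the planted signal strength", {
  cfg <- quick_config(seed = 0L, epochs = 8L, patience = 8L)
  acc_at <- vapply(c(0, 0.5, 1), function(p) {
    ds <- simulate_dataset(150L, 150L,
                           model = motif_model(insertion_probability = p),
                           seed = 50L)
    cross_validate(ds, default_model_spec(), cfg, k = 5L)$mean[["ACC"]]
  }, numeric(1))
  # non-decreasing within one pooled fold-level standard error
  se <- sqrt(0.25 / 60) / sqrt(5)  # ~0.029 per CV mean
  expect_gte(acc_at[2], acc_at[1] - se)
  expect_gte(acc_at[3], acc_at[2] - se)
  expect_gt(acc_at[3], acc_at[1])  # full signal clearly beats no signal
  expect_lt(acc_at[1], 0.65)       # no signal stays near chance
})

test_that("FASTA export writes both classes plus a manifest", {
  ds <- simulate_dataset(10L, 12L, seed = 6L)
  dir <- tempfile()
  paths <- write_dataset_fasta(ds, dir, prefix = "toy",
                               manifest = list(seed = 6L))
  expect_true(all(file.exists(paths)))
  back <- bind_datasets(read_fasta(paths[["pos"]], 1L),
                        read_fasta(paths[["neg"]], 0L))
  expect_equal(sort(back$seq), sort(ds$seq))
  man <- read.delim(paths[["manifest"]])
  expect_true("seed" %in% man$key)
})
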