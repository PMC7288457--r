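# Shared fixtures and independent oracles used across the suite.

# A small but structurally complete architecture (every layer type) for
# engine-level tests; cheap enough for finite-difference gradient checks.
tiny_spec <- function(input_shape = c(10L, 4L), dropout = 0) {
  model_spec(list(
    conv1d_spec(4L, 3L, 1L, weight_l2 = 0.01, bias_l2 = 0.02),
    activation_spec("elu"),
    group_norm_spec(2L),
    max_pool_spec(3L, 2L),
    flatten_spec(),
    dropout_spec(dropout),
    dense_spec(5L, weight_l2 = 0.001, bias_l2 = 0.001, activation = "elu"),
    dense_spec(1L),
    activation_spec("sigmoid")), input_shape = input_shape)
}

# Fast training configuration for tests that only need the mechanics.
quick_config <- function(seed = 1L, epochs = 15L, patience = 15L, ...) {
  training_config(epochs = epochs, patience = patience, seed = seed, ...)
}

random_rna <- function(n, length = 51L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
          collapse = ""), character(1))
}

# Brute-force sliding-window count: output positions of a window of size w
# moved by stride s over length L (the oracle for the conv/pool length
# arithmetic).
window_count_oracle <- function(L, w, s) {
  starts <- seq.int(0L, L - w)  # all feasible 0-based starts
  sum(starts %% s == 0L)
}

# Literal transcription of the four confusion-matrix statistics.
metrics_oracle <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(ACC = (tp + tn) / (tp + tn + fp + fn),
       Sn = tp / (tp + fn),
       Sp = tn / (tn + fp),
       MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Mann-Whitney pairwise concordance (ties count one half): the AUC oracle.
concordance_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

write_temp_fasta <- function(seqs, ids = sprintf("s%d", seq_along(seqs)),
                             width = NULL) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    body <- if (is.null(width)) seqs[i] else
      substring(seqs[i], seq(1, nchar(seqs[i]), width),
                pmin(seq(1, nchar(seqs[i]), width) + width - 1, nchar(seqs[i])))
    c(paste0(">", ids[i]), body)
  }))
  writeLines(lines, path)
  path
}
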