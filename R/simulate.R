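# Planted-motif synthetic benchmark generator. Emulates the structure of
# the public m6A window benchmarks (balanced 51-nt positive/negative sets)
# without their genomic background or redundancy structure.

#' Motif model for synthetic positives
#'
#' Positives carry a short consensus motif at a fixed window offset with a
#' given per-record probability; all other positions (and all negative
#' sequences) are i.i.d. draws from the background composition. The
#' defaults plant the DRACH-like consensus `GGACU` at 0-based offset 24
#' in a 51-nt window, placing its adenosine one position right of the
#' window midpoint (offset 24 + 2 = 26 0-based; the midpoint is 25). The
#' classifier does not care where the signal sits, only that it is fixed.
#'
#' @param motif Short RNA string over `{A, C, G, U}`.
#' @param offset 0-based start position of the motif within the window.
#' @param insertion_probability Per-positive probability that the motif is
#'   planted (1 = every positive carries it).
#' @param background Named numeric composition over A, C, G, U; must sum
#'   to 1 (default uniform).
#' @return An `m6a_motif_model` list.
#' @export
motif_model <- function(motif = "GGACU", offset = 24L,
                        insertion_probability = 1,
                        background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  motif <- normalize_residues(motif)
  if (!all(strsplit(motif, "")[[1]] %in% RNA_ALPHABET))
    stop("motif must be over {A, C, G, U}", call. = FALSE)
  stopifnot(offset >= 0L, insertion_probability >= 0,
            insertion_probability <= 1, length(background) == 4L,
            abs(sum(background) - 1) < 1e-8, all(background >= 0))
  names(background) <- RNA_ALPHABET
  structure(list(motif = motif, offset = as.integer(offset),
                 insertion_probability = insertion_probability,
                 background = background),
            class = "m6a_motif_model")
}

random_windows <- function(n, length, background) {
  if (n == 0L) return(character(0))
  chars <- sample(RNA_ALPHABET, n * length, replace = TRUE, prob = background)
  apply(matrix(chars, n, length), 1L, paste, collapse = "")
}

has_motif_at <- function(seqs, motif, offset) {
  substr(seqs, offset + 1L, offset + nchar(motif)) == motif
}

#' Generate a balanced synthetic labeled dataset
#'
#' Positives carry the motif at the model's offset with its insertion
#' probability (remaining positions are background); negatives are pure
#' background, re-drawn if the motif arises at the offset by chance (it
#' may still occur elsewhere). Deterministic given `seed`.
#'
#' @param n_pos,n_neg Numbers of positive / negative records.
#' @param length Window length in nt (default 51).
#' @param model An [motif_model()].
#' @param seed Integer seed.
#' @return An `m6a_dataset` with `n_pos` positives followed by `n_neg`
#'   negatives.
#' @export
simulate_dataset <- function(n_pos, n_neg, length = 51L,
                             model = motif_model(), seed = 1L) {
  stopifnot(n_pos >= 0L, n_neg >= 0L, inherits(model, "m6a_motif_model"))
  if (model$offset + nchar(model$motif) > length)
    stop(sprintf("motif (offset %d, length %d) exceeds the %d-nt window",
                 model$offset, nchar(model$motif), length), call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  pos <- random_windows(n_pos, length, model$background)
  plant <- runif(n_pos) < model$insertion_probability
  if (any(plant)) {
    substr(pos[plant], model$offset + 1L,
           model$offset + nchar(model$motif)) <- model$motif
  }
  neg <- random_windows(n_neg, length, model$background)
  bad <- which(has_motif_at(neg, model$motif, model$offset))
  while (length(bad) > 0L) {
    neg[bad] <- random_windows(length(bad), length, model$background)
    bad <- bad[has_motif_at(neg[bad], model$motif, model$offset)]
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  m6a_dataset(c(sprintf("pos_%d", seq_len(n_pos)),
                sprintf("neg_%d", seq_len(n_neg))),
              c(pos, neg),
              c(rep(1L, n_pos), rep(0L, n_neg)),
              required_length = length)
}

#' Generate a permuted-label null dataset
#'
#' Negative control: all sequences are pure background and the n/2
#' positive labels are assigned by a random permutation, independent of
#' sequence content. Any classifier's expected accuracy on it is 0.5.
#'
#' @param n Total number of records (must be even for exact balance).
#' @param length Window length in nt.
#' @param background Named composition over A, C, G, U.
#' @param seed Integer seed.
#' @return An `m6a_dataset` with exactly `n/2` records per class.
#' @export
simulate_null_dataset <- function(n, length = 51L,
                                  background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, U = 0.25),
                                  seed = 1L) {
  stopifnot(n >= 2L)
  if (n %% 2L != 0L) stop("n must be even for exact class balance", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  seqs <- random_windows(n, length, background)
  labels <- integer(n)
  labels[sample.int(n, n %/% 2L)] <- 1L
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  m6a_dataset(sprintf("null_%d", seq_len(n)), seqs, labels,
              required_length = length)
}
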