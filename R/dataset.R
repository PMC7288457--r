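#' Construct a labeled sequence dataset
#'
#' A labeled dataset is a data frame with columns `id`, `seq`, `label`
#' (1 = methylated / positive, 0 = non-methylated / negative) of class
#' `m6a_dataset`. All sequences must share one length; sequences are
#' normalized and validated on construction.
#'
#' @param ids Character vector of identifiers.
#' @param seqs Character vector of residue strings.
#' @param labels Integer/numeric vector of 0/1 labels.
#' @param required_length Required window length; `NULL` to accept any
#'   single shared length.
#' @param permissive_n Tolerate non-ACGU characters (see
#'   [validate_sequence()]).
#' @param require_central_a Require the central adenosine.
#' @return An `m6a_dataset` data frame.
#' @export
m6a_dataset <- function(ids, seqs, labels, required_length = 51L,
                        permissive_n = FALSE, require_central_a = FALSE) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(labels))
  if (length(seqs) == 0L) stop("dataset is empty", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 (negative) or 1 (positive)", call. = FALSE)
  seqs <- vapply(seq_along(seqs), function(i) {
    validate_sequence(seqs[i], required_length = required_length,
                      permissive_n = permissive_n,
                      require_central_a = require_central_a, id = ids[i])
  }, character(1))
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L)
    stop("all sequences must share one length; found lengths: ",
         paste(sort(lens), collapse = ", "), call. = FALSE)
  out <- data.frame(id = as.character(ids), seq = seqs,
                    label = as.integer(labels), stringsAsFactors = FALSE)
  class(out) <- c("m6a_dataset", "data.frame")
  out
}

#' @export
print.m6a_dataset <- function(x, ...) {
  cts <- dataset_counts(x)
  cat(sprintf("m6a_dataset: %d sequences of length %d nt (%d positive, %d negative)\n",
              nrow(x), nchar(x$seq[1]), cts[["positive"]], cts[["negative"]]))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more records\n", nrow(x) - 6L))
  invisible(x)
}

#' Positive/negative/total counts of a dataset
#'
#' @param dataset An `m6a_dataset`.
#' @return Named integer vector `positive`, `negative`, `total`.
#' @export
dataset_counts <- function(dataset) {
  stopifnot(inherits(dataset, "m6a_dataset"))
  p <- sum(dataset$label == 1L)
  c(positive = p, negative = nrow(dataset) - p, total = nrow(dataset))
}

#' Concatenate labeled datasets
#'
#' @param ... `m6a_dataset` objects with equal sequence lengths.
#' @return The merged `m6a_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "m6a_dataset")))
  out <- do.call(rbind, lapply(parts, as.data.frame))
  lens <- unique(nchar(out$seq))
  if (length(lens) != 1L)
    stop("datasets have differing sequence lengths: ",
         paste(lens, collapse = ", "), call. = FALSE)
  class(out) <- c("m6a_dataset", "data.frame")
  out
}

#' Read one class of sequences from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file with
#' Biostrings, attaches one binary label to every record, normalizes
#' residues (upper-case, T to U) and validates alphabet and length.
#'
#' @param path Path to a FASTA file.
#' @param label Label attached to every record: 1 = methylated, 0 = not.
#' @inheritParams m6a_dataset
#' @return An `m6a_dataset`.
#' @export
read_fasta <- function(path, label, required_length = 51L,
                       permissive_n = FALSE, require_central_a = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  stopifnot(length(label) == 1L, label %in% c(0, 1))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L)
    stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  m6a_dataset(ids, as.character(set), rep(as.integer(label), length(set)),
              required_length = required_length, permissive_n = permissive_n,
              require_central_a = require_central_a)
}

#' Read a labeled dataset from a two-column TSV
#'
#' Tab-separated alternative to FASTA input: column 1 is the sequence,
#' column 2 the 0/1 label. A header line is detected and skipped when the
#' second field is not numeric. Row numbers become identifiers.
#'
#' @param path Path to a TSV file.
#' @inheritParams m6a_dataset
#' @return An `m6a_dataset`.
#' @export
read_labeled_tsv <- function(path, required_length = 51L,
                             permissive_n = FALSE, require_central_a = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("labeled TSV must have two columns: sequence, label", call. = FALSE)
  if (nrow(df) > 0L && is.na(suppressWarnings(as.numeric(df[1, 2]))))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0L) stop("labeled TSV is empty", call. = FALSE)
  m6a_dataset(sprintf("seq%d", seq_len(nrow(df))), as.character(df[[1]]),
              as.integer(df[[2]]), required_length = required_length,
              permissive_n = permissive_n,
              require_central_a = require_central_a)
}

#' Write a dataset as a positive/negative FASTA pair plus manifest
#'
#' @param dataset An `m6a_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @param manifest Optional named list recorded alongside (seed,
#'   generator parameters, ...).
#' @return Invisibly, the paths written.
#' @export
write_dataset_fasta <- function(dataset, dir, prefix = "dataset",
                                manifest = list()) {
  stopifnot(inherits(dataset, "m6a_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pos = file.path(dir, paste0(prefix, "_pos.fasta")),
             neg = file.path(dir, paste0(prefix, "_neg.fasta")),
             manifest = file.path(dir, paste0(prefix, "_manifest.tsv")))
  for (cls in c("pos", "neg")) {
    sub <- dataset[dataset$label == (cls == "pos"), , drop = FALSE]
    set <- Biostrings::BStringSet(setNames(sub$seq, sub$id))
    Biostrings::writeXStringSet(set, paths[[cls]])
  }
  cts <- dataset_counts(dataset)
  man <- c(list(n_pos = unname(cts["positive"]), n_neg = unname(cts["negative"]),
                length = nchar(dataset$seq[1])), manifest)
  write.table(data.frame(key = names(man),
                         value = vapply(man, function(v) paste(format(v), collapse = ","),
                                        character(1))),
              paths[["manifest"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Encode a dataset as a 3-D input tensor
#'
#' Stacks the per-sequence one-hot matrices into an array of dimension
#' `(n, length, 4)` suitable for the network, plus the label vector.
#'
#' @param dataset An `m6a_dataset`.
#' @param permissive_n Encode ambiguity codes as all-zero rows.
#' @return List with `x` (array `n x L x 4`) and `y` (integer labels).
#' @export
encode_dataset <- function(dataset, permissive_n = FALSE) {
  stopifnot(inherits(dataset, "m6a_dataset"))
  n <- nrow(dataset)
  L <- nchar(dataset$seq[1])
  x <- array(0, dim = c(n, L, 4L))
  for (i in seq_len(n))
    x[i, , ] <- one_hot_encode(dataset$seq[i], permissive_n = permissive_n)
  list(x = x, y = dataset$label)
}
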