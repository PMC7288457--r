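#' @importFrom stats predict runif rbinom setNames sd
#' @importFrom utils head modifyList read.delim write.table
NULL

# Fixed channel order of the one-hot encoding: A, C, G, U.
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize raw residue strings to the RNA alphabet
#'
#' Upper-cases the input and replaces DNA-style `T` with `U`. No validation
#' is performed here; see [validate_sequence()].
#'
#' @param x Character vector of residue strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_residues("acgt")  # "ACGU"
normalize_residues <- function(x) {
  chartr("T", "U", toupper(x))
}

#' Validate a fixed-length RNA window
#'
#' Checks that a residue string is over the alphabet `{A, C, G, U}` and has
#' exactly the required length. Ambiguity codes (e.g. `N`) are rejected in
#' strict mode; with `permissive_n = TRUE` they are tolerated and later
#' encoded as all-zero rows by [one_hot_encode()]. Since m6A windows are
#' centered on an adenosine, `require_central_a = TRUE` additionally checks
#' that the central position carries an `A` (off by default: the check is a
#' biological expectation, not a format requirement).
#'
#' @param residues Single residue string (already normalized, or not: the
#'   function normalizes first).
#' @param required_length Expected window length in nt (default 51).
#' @param permissive_n Tolerate non-ACGU characters (`FALSE` by default).
#' @param require_central_a Require `A` at the central position.
#' @param id Optional identifier used in error messages.
#' @return The normalized residue string, invisibly unchanged otherwise.
#' @export
validate_sequence <- function(residues, required_length = 51L,
                              permissive_n = FALSE,
                              require_central_a = FALSE,
                              id = NULL) {
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- normalize_residues(residues)
  who <- if (is.null(id)) "sequence" else sprintf("sequence '%s'", id)
  if (!is.null(required_length) && nchar(res) != required_length) {
    stop(sprintf("%s has length %d, expected %d", who, nchar(res),
                 required_length), call. = FALSE)
  }
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% RNA_ALPHABET))
  if (length(bad) > 0L && !permissive_n) {
    stop(sprintf("%s contains invalid residue '%s' at position %d",
                 who, chars[bad[1]], bad[1]), call. = FALSE)
  }
  if (require_central_a) {
    center <- (nchar(res) + 1L) %/% 2L
    if (chars[center] != "A") {
      stop(sprintf("%s lacks the central adenosine (position %d is '%s')",
                   who, center, chars[center]), call. = FALSE)
    }
  }
  res
}

#' One-hot encode an RNA window
#'
#' Maps `A`, `C`, `G`, `U` to the indicator vectors (1,0,0,0), (0,1,0,0),
#' (0,0,1,0), (0,0,0,1), producing an `L x 4` binary matrix with positions
#' in rows and channels in the fixed order A, C, G, U. With
#' `permissive_n = TRUE` any other character becomes an all-zero row.
#'
#' @param residues Single residue string over `{A, C, G, U}` (use
#'   [validate_sequence()] first).
#' @param permissive_n Encode non-ACGU characters as all-zero rows.
#' @return Binary matrix of dimension `nchar(residues) x 4`, with column
#'   names `A`, `C`, `G`, `U`.
#' @export
#' @examples
#' one_hot_encode("ACGU")  # the 4x4 identity matrix
one_hot_encode <- function(residues, permissive_n = FALSE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, RNA_ALPHABET)
  if (anyNA(idx) && !permissive_n) {
    pos <- which(is.na(idx))[1]
    stop(sprintf("invalid residue '%s' at position %d (use permissive_n for ambiguity codes)",
                 chars[pos], pos), call. = FALSE)
  }
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, RNA_ALPHABET))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a residue string
#'
#' Inverse of [one_hot_encode()]: each row must be a valid indicator vector
#' (entries in \{0,1\}, summing to 1), unless `permissive_n = TRUE` in which
#' case all-zero rows decode to `N`.
#'
#' @param mat Binary matrix with 4 columns (channels A, C, G, U).
#' @param permissive_n Decode all-zero rows as `N` instead of erroring.
#' @return Residue string.
#' @export
one_hot_decode <- function(mat, permissive_n = FALSE) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L)
  if (!all(mat %in% c(0, 1)))
    stop("one-hot matrix entries must be 0 or 1", call. = FALSE)
  rs <- rowSums(mat)
  if (permissive_n) {
    if (!all(rs %in% c(0, 1)))
      stop("one-hot matrix rows must sum to 0 or 1", call. = FALSE)
  } else if (!all(rs == 1)) {
    stop(sprintf("one-hot matrix row %d does not sum to 1",
                 which(rs != 1)[1]), call. = FALSE)
  }
  out <- rep("N", nrow(mat))
  hit <- rs == 1
  out[hit] <- RNA_ALPHABET[max.col(mat[hit, , drop = FALSE], ties.method = "first")]
  paste(out, collapse = "")
}
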