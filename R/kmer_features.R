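#' Build the k-mer vocabulary for a window length
#'
#' The vocabulary is the complete set of 20^k length-k strings over the
#' standard amino-acid alphabet, ordered lexicographically over
#' `ACDEFGHIKLMNPQRSTVWY`. The ordering is deterministic and platform
#' independent; it is part of the persisted model metadata so feature masks
#' and trained weights stay aligned across runs. For k >= 4 the string list
#' is not materialized (160 000 and 3.2 million entries); k-mer strings are
#' decoded on demand with [kmer_strings()].
#'
#' @param k window length, between 1 and 5.
#' @return a `kmer_vocab` object with fields `k`, `alphabet` and `size`.
#' @export
build_vocabulary <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) || k < 1 || k > 5) {
    stop("k must be an integer between 1 and 5, got: ", paste(k, collapse = ","))
  }
  k <- as.integer(k)
  structure(list(k = k, alphabet = AA_ALPHABET, size = as.integer(20^k)),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat("kmer_vocab: k =", x$k, "|", format(x$size, big.mark = " "),
      "k-mers over", x$alphabet, "\n")
  invisible(x)
}

#' Decode vocabulary indices into k-mer strings
#'
#' @param vocab a `kmer_vocab`.
#' @param indices 1-based vocabulary positions; default all (refuse for k >= 4).
#' @return character vector of k-mer strings.
#' @export
kmer_strings <- function(vocab, indices = NULL) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  if (is.null(indices)) {
    if (vocab$size > 20000L) {
      stop("refusing to materialize all ", vocab$size,
           " k-mers; pass explicit indices")
    }
    indices <- seq_len(vocab$size)
  }
  stopifnot(all(indices >= 1), all(indices <= vocab$size))
  x <- as.numeric(indices) - 1
  out <- matrix("", nrow = length(indices), ncol = vocab$k)
  for (pos in vocab$k:1) {
    out[, pos] <- AA_CHARS[(x %% 20) + 1]
    x <- x %/% 20
  }
  apply(out, 1L, paste0, collapse = "")
}

# residues -> 0-based alphabet codes, NA for anything non-standard
aa_codes <- function(sequence) {
  match(strsplit(sequence, "")[[1]], AA_CHARS) - 1L
}

# sliding-window k-mer indices (1-based into the vocabulary); NA marks a
# window containing a non-standard residue (an invalid window)
kmer_window_indices <- function(sequence, k) {
  codes <- aa_codes(sequence)
  n_win <- length(codes) - k + 1L
  if (n_win < 1L) return(numeric(0))
  idx <- numeric(n_win)
  for (j in seq_len(k)) idx <- idx * 20 + codes[j:(j + n_win - 1L)]
  idx + 1
}

#' Relative k-mer frequencies of one sequence
#'
#' Slides a window of length k with step 1. A window is valid iff all its
#' residues are in the 20-letter standard alphabet. Each vocabulary entry is
#' the count of that k-mer among valid windows divided by the number of valid
#' windows, so the vector sums to 1 for any sequence with at least one valid
#' window and is length-invariant. Sequences shorter than k (or with no valid
#' window) get an all-zero vector and a warning.
#'
#' @param sequence amino-acid string (validated, upper case).
#' @param vocab a `kmer_vocab`.
#' @return numeric vector of length `vocab$size`.
#' @export
kmer_frequencies <- function(sequence, vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"), is.character(sequence),
            length(sequence) == 1L)
  idx <- kmer_window_indices(sequence, vocab$k)
  out <- numeric(vocab$size)
  valid <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    warning("sequence shorter than k: no valid window, returning zero vector")
    return(out)
  }
  if (length(valid) == 0L) {
    warning("no valid k-mer window (non-standard residues), returning zero vector")
    return(out)
  }
  counts <- tabulate(as.integer(valid), nbins = vocab$size)
  out[] <- counts / length(valid)
  out
}

#' Encode a corpus as a k-mer frequency matrix
#'
#' One row per record in corpus order; rows align with record ids; shape is
#' (n_records x 20^k). The full-vocabulary matrix is held sparse (each row
#' has at most L-k+1 nonzero entries), which keeps k = 4 and k = 5 feasible;
#' applying a feature mask densifies it.
#'
#' @param corpus a `tf_corpus` (or a records data.frame).
#' @param vocab a `kmer_vocab`.
#' @return a `feature_matrix`: list with `values` (dgCMatrix), `row_ids`,
#'   `k`, `masked = FALSE`.
#' @export
encode_corpus <- function(corpus, vocab) {
  records <- if (inherits(corpus, "tf_corpus")) corpus$records else corpus
  if (nrow(records) == 0L) stop("cannot encode an empty corpus")
  k <- vocab$k
  trip <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    idx <- kmer_window_indices(records$sequence[i], k)
    valid <- idx[!is.na(idx)]
    if (length(valid) == 0L) next
    tab <- table(valid)
    trip[[i]] <- list(i = rep.int(i, length(tab)),
                      j = as.numeric(names(tab)),
                      x = as.numeric(tab) / length(valid))
  }
  keep <- !vapply(trip, is.null, logical(1))
  values <- Matrix::sparseMatrix(
    i = unlist(lapply(trip[keep], `[[`, "i")),
    j = unlist(lapply(trip[keep], `[[`, "j")),
    x = unlist(lapply(trip[keep], `[[`, "x")),
    dims = c(nrow(records), vocab$size)
  )
  new_feature_matrix(values, records$id, k, masked = FALSE)
}

new_feature_matrix <- function(values, row_ids, k, masked, mask_indices = NULL) {
  structure(list(values = values, row_ids = as.character(row_ids),
                 k = as.integer(k), masked = isTRUE(masked),
                 mask_indices = mask_indices),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x$values), " x ", ncol(x$values),
      " (k = ", x$k, if (x$masked) ", masked" else "", ")\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Restrict a feature matrix to the features of a mask
#'
#' Columns are restricted to the mask's vocabulary indices, in mask order
#' (best feature first). Row sums are no longer guaranteed to be 1. The
#' result is densified: masked matrices are what the classifiers consume.
#'
#' @param matrix an unmasked `feature_matrix`.
#' @param mask a `feature_mask` with the same k.
#' @return a masked `feature_matrix` with a dense `values` matrix.
#' @export
apply_mask <- function(matrix, mask) {
  stopifnot(inherits(matrix, "feature_matrix"), inherits(mask, "feature_mask"))
  if (mask$k != matrix$k) {
    stop("k mismatch: matrix k = ", matrix$k, ", mask k = ", mask$k)
  }
  if (matrix$masked) stop("matrix is already masked")
  if (any(mask$indices < 1) || any(mask$indices > ncol(matrix$values))) {
    stop("mask index out of range for a ", ncol(matrix$values), "-column matrix")
  }
  vals <- as.matrix(matrix$values[, mask$indices, drop = FALSE])
  dimnames(vals) <- NULL
  new_feature_matrix(vals, matrix$row_ids, matrix$k, masked = TRUE,
                     mask_indices = mask$indices)
}
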