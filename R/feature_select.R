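#' One-way ANOVA F-statistic per feature
#'
#' For each feature (column), computes the one-way ANOVA F statistic of the
#' feature values grouped by `labels`: the between-group mean square divided
#' by the within-group mean square. Features that are essentially constant
#' (zero between-group and zero within-group variance) score 0; features with
#' zero within-group but positive between-group variance score `Inf` and rank
#' first. The computation uses group-sum identities over the sparse matrix,
#' so the full k = 4/5 vocabulary never needs to be densified.
#'
#' @param matrix a `feature_matrix` (masked or not) or a numeric matrix /
#'   dgCMatrix.
#' @param labels per-row group labels (>= 2 distinct groups, each non-empty;
#'   rows with `NA` labels are excluded).
#' @return numeric vector of F statistics, one per column.
#' @export
anova_f_scores <- function(matrix, labels) {
  X <- if (inherits(matrix, "feature_matrix")) matrix$values else matrix
  labels <- as.character(labels)
  keep <- !is.na(labels)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  n <- nrow(X)
  grp <- factor(labels, levels = unique(labels))
  g <- nlevels(grp)
  if (g < 2L) stop("ANOVA needs at least 2 groups, got ", g)
  if (n <= g) stop("need more rows (", n, ") than groups (", g, ")")
  ng <- as.numeric(table(grp))

  ind <- Matrix::sparseMatrix(i = as.integer(grp), j = seq_len(n), x = 1,
                              dims = c(g, n))
  S <- as.matrix(ind %*% X)          # g x p group sums
  Q <- as.matrix(ind %*% (X * X))    # g x p group sums of squares
  grand <- colSums(S) / n
  sumsq <- colSums(Q)
  means <- S / ng
  ssb <- colSums(ng * sweep(means, 2L, grand, "-")^2)
  tss <- pmax(sumsq - n * grand^2, 0)
  ssw <- pmax(tss - ssb, 0)

  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  # columns whose total variation is at floating-point noise level relative
  # to their magnitude are constant: degenerate rule, score 0
  noise <- tss <= 1e-10 * pmax(sumsq, .Machine$double.xmin)
  f[noise] <- 0
  f
}

#' Select the top-n features by score
#'
#' Indices of the n largest scores, ties at the cutoff broken by the smaller
#' vocabulary index; if n exceeds the number of features, all are retained.
#'
#' @param scores per-feature score vector (e.g. from [anova_f_scores()]).
#' @param n target number of retained features.
#' @param k window length the scores belong to (recorded in the mask).
#' @return a `feature_mask`: list with `k`, `indices` (score-descending),
#'   `scores` (aligned with `indices`), `n_selected`.
#' @export
select_top_features <- function(scores, n, k) {
  stopifnot(is.numeric(scores), length(scores) >= 1L, n >= 1)
  n_keep <- min(as.integer(n), length(scores))
  ord <- order(-scores, seq_along(scores))[seq_len(n_keep)]
  structure(list(k = as.integer(k), indices = as.integer(ord),
                 scores = as.numeric(scores[ord]), n_selected = n_keep),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat("feature_mask: k =", x$k, "|", length(x$indices), "features retained\n")
  invisible(x)
}

#' Default retained-feature count per k
#'
#' 200 features for k = 2 (of 400); 1000 for k = 3, 4, 5.
#'
#' @param k window length.
#' @return integer count.
#' @export
default_n_features <- function(k) {
  stopifnot(k >= 1, k <= 5)
  if (k <= 2) 200L else 1000L
}

#' Compute the global ANOVA feature mask for a labeled corpus
#'
#' One mask per k, computed with the multi-class family label as the grouping
#' factor. Unlabeled (non-TF) rows never contribute to the mask.
#'
#' @param matrix unmasked `feature_matrix` of the training rows.
#' @param labels per-row family labels (`NA` for unlabeled rows).
#' @param n number of features to retain; default [default_n_features()].
#' @return a `feature_mask`.
#' @export
compute_feature_mask <- function(matrix, labels, n = default_n_features(matrix$k)) {
  scores <- anova_f_scores(matrix, labels)
  select_top_features(scores, n, matrix$k)
}

#' Persist / load a feature mask as JSON
#'
#' Scores are serialized as strings with full precision so `Inf` and exact
#' values round-trip.
#'
#' @param mask a `feature_mask`.
#' @param path JSON file path.
#' @return `path` (write) or the `feature_mask` (read).
#' @export
write_mask <- function(mask, path) {
  obj <- list(k = mask$k, alphabet = AA_ALPHABET,
              indices = mask$indices,
              scores = sprintf("%.17g", mask$scores),
              n_selected = mask$n_selected)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$alphabet, AA_ALPHABET)) {
    stop("mask was built for a different alphabet: ", obj$alphabet)
  }
  structure(list(k = as.integer(obj$k), indices = as.integer(obj$indices),
                 scores = as.numeric(obj$scores),
                 n_selected = as.integer(obj$n_selected)),
            class = "feature_mask")
}
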