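#' Stratified train/test split of a labeled corpus
#'
#' Per family, `round(test_fraction * family size)` records go to the test
#' set after a seeded shuffle, except that at least one record always stays
#' in training (a family of 1 contributes no test record). Unlabeled records
#' are not part of the split. Each family's shuffle uses its own RNG stream
#' derived from the master seed, so splits are stable when families are added
#' or removed.
#'
#' @param corpus a labeled `tf_corpus`.
#' @param test_fraction test share, strictly between 0 and 1.
#' @param seed master integer seed.
#' @return a `split_spec`: list with `train_ids`, `test_ids`, `fraction`,
#'   `seed`, `stratify_by = "family"`.
#' @export
stratified_split <- function(corpus, test_fraction = 0.2, seed = 42L) {
  stopifnot(inherits(corpus, "tf_corpus"),
            test_fraction > 0, test_fraction < 1)
  if (length(corpus$families) == 0L) stop("corpus has no labeled families")
  train_ids <- character(0)
  test_ids <- character(0)
  for (fam in corpus$families) {
    ids <- corpus$records$id[!is.na(corpus$records$family) &
                               corpus$records$family == fam]
    n <- length(ids)
    n_test <- as.integer(floor(test_fraction * n + 0.5))
    if (n - n_test < 1L) n_test <- n - 1L   # minimum-train rule
    withr_seed(derive_seed(seed, paste0("split:", fam)), {
      ids <- ids[sample.int(n)]
    })
    test_ids <- c(test_ids, ids[seq_len(n_test)])
    train_ids <- c(train_ids, ids[setdiff(seq_len(n), seq_len(n_test))])
  }
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 fraction = test_fraction, seed = as.integer(seed),
                 stratify_by = "family"),
            class = "split_spec")
}

# run expr under a temporary RNG state (Mersenne-Twister, fixed seed)
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  eval.parent(substitute(expr))
}

# largest-remainder (Hamilton) apportionment of `total` into shares
# proportional to `sizes`; deterministic tie-breaks: larger remainder first,
# then larger donor, then earlier position
largest_remainder_quota <- function(sizes, total) {
  if (total == 0 || sum(sizes) == 0) return(integer(length(sizes)))
  exact <- total * sizes / sum(sizes)
  base <- floor(exact)
  left <- as.integer(round(total - sum(base)))
  quota <- as.integer(base)
  if (left > 0L) {
    rem <- exact - base
    ord <- order(-rem, -sizes, seq_along(sizes))
    bump <- ord[seq_len(left)]
    quota[bump] <- quota[bump] + 1L
  }
  quota
}

#' Build the balanced binary training subset for one family
#'
#' Positives are all members of the target family (restricted to `ids` when
#' given, typically the training split). Negatives are the same number of
#' sequences drawn from the other families, allocated proportionally to
#' family size by largest-remainder rounding and sampled without replacement
#' within each donor family. If the target family outnumbers all other
#' families combined, every other sequence becomes a negative and the
#' positives are down-sampled to match (with a warning).
#'
#' @param corpus a labeled `tf_corpus`.
#' @param family target family name.
#' @param seed master integer seed; the draw uses a stream derived from
#'   `(family, seed)`.
#' @param ids optional id subset to restrict to (e.g. `split$train_ids`).
#' @return a `binary_subset`: list with `family`, `positive_ids`,
#'   `negative_ids`, `seed`.
#' @export
build_binary_subset <- function(corpus, family, seed = 42L, ids = NULL) {
  stopifnot(inherits(corpus, "tf_corpus"))
  rec <- corpus$records[!is.na(corpus$records$family), , drop = FALSE]
  if (!is.null(ids)) rec <- rec[rec$id %in% ids, , drop = FALSE]
  if (!family %in% rec$family) stop("family not present: ", family)

  pos <- rec$id[rec$family == family]
  donors <- rec[rec$family != family, , drop = FALSE]
  donor_fams <- unique(donors$family)
  donor_sizes <- vapply(donor_fams,
                        function(f) sum(donors$family == f), integer(1))
  stream <- derive_seed(seed, paste0("subset:", family))

  if (length(pos) > nrow(donors)) {
    warning("family '", family, "' larger than all others combined; ",
            "down-sampling positives to ", nrow(donors))
    neg <- donors$id
    withr_seed(stream, pos <- sort(sample(pos, nrow(donors))))
  } else {
    quota <- largest_remainder_quota(donor_sizes, length(pos))
    neg <- character(0)
    withr_seed(stream, {
      for (i in seq_along(donor_fams)) {
        pool <- donors$id[donors$family == donor_fams[i]]
        neg <- c(neg, pool[sample.int(length(pool), quota[i])])
      }
    })
  }
  structure(list(family = family, positive_ids = pos, negative_ids = neg,
                 seed = as.integer(seed)),
            class = "binary_subset")
}

#' @export
print.binary_subset <- function(x, ...) {
  cat("binary_subset '", x$family, "': ", length(x$positive_ids),
      " positives vs ", length(x$negative_ids), " negatives\n", sep = "")
  invisible(x)
}
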