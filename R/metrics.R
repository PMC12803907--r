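#' One-vs-rest confusion counts per class
#'
#' For each class, counts TP/FP/FN/TN treating that class as positive. A
#' prediction of `"unknown"` is an error against the true class: it
#' contributes a false negative to the true class and a true negative to
#' every other class — it can never be a true or false positive.
#'
#' @param y_true per-sequence true family labels (never `"unknown"`).
#' @param y_pred per-sequence predicted labels, possibly `"unknown"`.
#' @param classes ordered family names; every `y_true` must be among them.
#' @return a `confusion_counts` data.frame: `class`, `TP`, `FP`, `FN`, `TN`,
#'   `support` (true class size).
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(classes)) classes <- unique(y_true)
  if (!all(y_true %in% classes)) {
    stop("true labels outside the class set: ",
         paste(unique(setdiff(y_true, classes)), collapse = ", "))
  }
  n <- length(y_true)
  out <- data.frame(class = classes, TP = 0L, FP = 0L, FN = 0L, TN = 0L,
                    support = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    out$TP[i] <- tp; out$FP[i] <- fp; out$FN[i] <- fn
    out$TN[i] <- n - tp - fp - fn
    out$support[i] <- sum(y_true == cl)
  }
  class(out) <- c("confusion_counts", class(out))
  out
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Micro / macro / weighted metrics from confusion counts
#'
#' Micro metrics are computed on the globally summed TP/FP/FN (accuracy is
#' total TP over total sequences; in single-label evaluation without
#' rejections micro precision = recall = F1 = accuracy). Macro metrics are
#' the unweighted mean of the per-class metrics over classes with at least
#' one true member; weighted metrics weight each class by its true size.
#' Per-class precision/recall with empty denominators are defined as 0.
#'
#' @param counts a `confusion_counts` (from [confusion()]).
#' @return a `metrics_report` list: `micro`, `macro`, `weighted` (each with
#'   precision/recall/f1; micro also has accuracy), `per_class` table,
#'   `n` total sequences.
#' @export
averaged_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP[1] + counts$FP[1] + counts$FN[1] + counts$TN[1]
  per <- t(mapply(prf, counts$TP, counts$FP, counts$FN))
  per_class <- cbind(counts[, c("class", "TP", "FP", "FN", "TN", "support")],
                     as.data.frame(per))

  tp <- sum(counts$TP); fp <- sum(counts$FP); fn <- sum(counts$FN)
  micro <- as.list(prf(tp, fp, fn))
  micro$accuracy <- if (n > 0) tp / n else 0

  present <- counts$support > 0
  w <- counts$support[present] / sum(counts$support[present])
  macro <- list(precision = mean(per[present, "precision"]),
                recall = mean(per[present, "recall"]),
                f1 = mean(per[present, "f1"]))
  weighted <- list(precision = sum(w * per[present, "precision"]),
                   recall = sum(w * per[present, "recall"]),
                   f1 = sum(w * per[present, "f1"]))
  structure(list(micro = micro, macro = macro, weighted = weighted,
                 per_class = per_class, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (n = %d)\n", x$n))
  cat(sprintf("  micro:    acc %.4f  P %.4f  R %.4f  F1 %.4f\n",
              x$micro$accuracy, x$micro$precision, x$micro$recall, x$micro$f1))
  cat(sprintf("  macro:    P %.4f  R %.4f  F1 %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  cat(sprintf("  weighted: P %.4f  R %.4f  F1 %.4f\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1))
  invisible(x)
}

#' Evaluate a prediction report against true labels
#'
#' @param report a `prediction_report` (or data.frame with `id`,
#'   `final_label`).
#' @param truth data.frame with `id`, `family`, or a labeled `tf_corpus`.
#' @param classes ordered class names; default the families seen in truth.
#' @return a `metrics_report` with `n_unknown`, `method` and `threshold`
#'   echoed when available.
#' @export
evaluate_predictions <- function(report, truth, classes = NULL) {
  if (inherits(truth, "tf_corpus")) {
    truth <- truth$records[!is.na(truth$records$family), c("id", "family")]
  }
  hit <- match(report$id, truth$id)
  if (all(is.na(hit))) stop("no overlapping ids between predictions and truth")
  if (anyNA(hit)) {
    stop("predictions contain ids absent from truth: ",
         paste(head(report$id[is.na(hit)], 10), collapse = ", "))
  }
  y_true <- truth$family[hit]
  res <- averaged_metrics(confusion(y_true, report$final_label, classes))
  res$n_unknown <- sum(report$final_label == "unknown")
  res$method <- report$method[1] %||% NA_character_
  res$threshold <- report$threshold[1] %||% NA_real_
  res
}

#' Threshold sweep on fixed predictions
#'
#' Scores the corpus once with [score_all()] (and the stacker when
#' `method = "two_stage"`), then re-applies the thresholded argmax per
#' threshold — no re-inference — and evaluates each against the truth.
#'
#' @param ensemble a `tf_ensemble`.
#' @param corpus a labeled `tf_corpus` to evaluate on.
#' @param method `"two_stage"` or `"max_vote"`.
#' @param thresholds ascending thresholds; default `c(0, 0.5, 0.95)`.
#' @return data.frame, one row per threshold: `threshold`, `n_classified`,
#'   `n_unknown`, `micro_accuracy`, `micro_f1`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `weighted_f1`.
#' @export
threshold_sweep <- function(ensemble, corpus, method = c("two_stage", "max_vote"),
                            thresholds = c(0, 0.5, 0.95)) {
  method <- match.arg(method)
  stopifnot(!is.unsorted(thresholds))
  P <- score_all(ensemble, corpus)
  scores <- if (method == "two_stage") {
    S <- predict_proba(ensemble$stacker, P)
    rownames(S) <- rownames(P); colnames(S) <- ensemble$families
    S
  } else P
  truth <- corpus$records[!is.na(corpus$records$family), c("id", "family")]
  keep <- rownames(scores) %in% truth$id
  scores <- scores[keep, , drop = FALSE]
  y_true <- truth$family[match(rownames(scores), truth$id)]

  rows <- lapply(thresholds, function(th) {
    fin <- finalize_labels(scores, ensemble$families, th)
    m <- averaged_metrics(confusion(y_true, fin$final_label,
                                    ensemble$families))
    data.frame(threshold = th,
               n_classified = sum(fin$final_label != "unknown"),
               n_unknown = sum(fin$final_label == "unknown"),
               micro_accuracy = m$micro$accuracy,
               micro_f1 = m$micro$f1,
               macro_precision = m$macro$precision,
               macro_recall = m$macro$recall,
               macro_f1 = m$macro$f1,
               weighted_f1 = m$weighted$f1)
  })
  do.call(rbind, rows)
}

#' Mann-Whitney U test for two score samples
#'
#' Rank-sum U with midranks for ties. The two-sided p-value comes from exact
#' permutation enumeration whenever n1*n2 <= 64 (valid with ties), otherwise
#' from the normal approximation with tie correction and continuity
#' correction. `U` is reported for the first sample, so
#' `mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U == length(a)*length(b)`.
#'
#' @param a,b numeric score samples (e.g. per-family accuracies of two
#'   methods).
#' @return list with `U`, `p_value`, `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) > 0, length(b) > 0)
  n1 <- length(a); n2 <- length(b)
  u_stat <- function(x_idx, ranks, n1) {
    sum(ranks[x_idx]) - n1 * (n1 + 1) / 2
  }
  pooled <- c(a, b)
  ranks <- rank(pooled)            # midranks for ties
  U <- u_stat(seq_len(n1), ranks, n1)

  if (n1 * n2 <= 64) {
    # exact null: every assignment of n1 of the pooled values to sample 1
    combos <- utils::combn(n1 + n2, n1)
    mu <- n1 * n2 / 2
    u_all <- apply(combos, 2L, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  mu <- n1 * n2 / 2
  z <- (abs(U - mu) - 0.5) / sigma   # continuity correction
  p <- min(1, 2 * pnorm(-max(z, 0)))
  list(U = U, p_value = p, method = "normal")
}
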