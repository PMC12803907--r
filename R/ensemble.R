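#' Train the full per-family ensemble
#'
#' Pipeline: stratified 80/20 split of the labeled records, k-mer encoding,
#' global ANOVA feature mask on the labeled training rows, one balanced
#' binary classifier per family (negatives proportionally sampled from the
#' training split only), then a stacking meta-classifier trained on the base
#' probabilities of all labeled training sequences.
#'
#' Each family's classifier is trained as a cross-fitted committee: the
#' balanced subset is split into `n_folds` stratified folds, one network is
#' trained per fold on the other folds, and the committee predicts the mean
#' of its members. The fold-held-out predictions supply out-of-fold inputs
#' for the stacker, so the meta-classifier learns from realistic (not
#' memorized) base probabilities.
#'
#' @param corpus a labeled `tf_corpus`.
#' @param k k-mer window length (2-5). Default 3 (the configuration that
#'   performs best with a 0.5 confidence threshold).
#' @param n_features retained feature count; default [default_n_features()].
#' @param test_fraction held-out share used by the internal split.
#' @param seed master seed; all child streams derive from it.
#' @param config a [train_config()] shared by base learners and stacker.
#' @param standardize feature transform fitted on the training rows and
#'   persisted with the bundle: `"count"` (default) multiplies the relative
#'   frequencies by the mean valid-window count, restoring count-like O(1)
#'   magnitudes; `"zscore"` z-scores per feature; `"none"` leaves raw
#'   frequencies. Raw frequencies (magnitude ~1/L) are too small to train
#'   on, and per-feature z-scoring blows up rare k-mers, so count scaling is
#'   the default.
#' @param n_folds folds of the cross-fitted committee per family (>= 1;
#'   1 trains a single network on the whole subset and feeds the stacker
#'   in-sample probabilities).
#' @param max_restarts networks whose best validation loss stays above
#'   `restart_loss` (training got stuck near chance, which happens on the
#'   smallest subsets for some initializations) are retrained up to this
#'   many times with fresh derived seeds; the attempt with the lowest
#'   validation loss is kept. Deterministic given the master seed.
#' @param restart_loss validation-loss bar that triggers a restart.
#' @param with_stacker train the second-stage meta-classifier? Default TRUE.
#' @return a `tf_ensemble`: list with `k`, `mask`, `families`, `binaries`
#'   (one classifier per family), `stacker` (or NULL), `scaler`, `split`
#'   (the `split_spec` used), and `meta`.
#' @export
train_ensemble <- function(corpus, k = 3L,
                           n_features = default_n_features(k),
                           test_fraction = 0.2, seed = 42L,
                           config = train_config(),
                           standardize = c("count", "zscore", "none"),
                           n_folds = 3L, max_restarts = 2L,
                           restart_loss = 0.3, with_stacker = TRUE) {
  stopifnot(inherits(corpus, "tf_corpus"), n_folds >= 1L)
  standardize <- match.arg(standardize)
  if (length(corpus$families) < 2L) stop("need at least 2 labeled families")
  vocab <- build_vocabulary(k)
  split <- stratified_split(corpus, test_fraction, seed)

  rec <- corpus$records
  lab <- !is.na(rec$family)
  train_rec <- rec[lab & rec$id %in% split$train_ids, , drop = FALSE]
  train_corpus <- new_corpus(train_rec)
  enc <- encode_corpus(train_corpus, vocab)
  mask <- compute_feature_mask(enc, train_rec$family, n = n_features)
  Xtr <- apply_mask(enc, mask)
  scaler <- fit_scaler(Xtr$values, type = standardize,
                       sequences = train_rec$sequence, k = k)
  Xtr$values <- apply_scaler(Xtr$values, scaler)

  families <- corpus$families
  binaries <- setNames(vector("list", length(families)), families)
  # out-of-fold base probabilities on the labeled training rows, the
  # stacker's training input
  P_oof <- matrix(0, nrow(Xtr$values), length(families),
                  dimnames = list(NULL, families))
  for (fi in seq_along(families)) {
    fam <- families[fi]
    sub <- build_binary_subset(corpus, fam, seed = seed, ids = split$train_ids)
    sel <- match(c(sub$positive_ids, sub$negative_ids), Xtr$row_ids)
    y <- rep(c(1, 0), c(length(sub$positive_ids), length(sub$negative_ids)))
    R <- min(n_folds, length(sel) %/% 4L)  # need a few rows per fold
    if (R < 2L) R <- 1L
    fold <- integer(length(sel))
    withr_seed(derive_seed(seed, paste0("folds:", fam)), {
      fold[y == 1] <- sample(rep_len(seq_len(R), sum(y == 1)))
      fold[y == 0] <- sample(rep_len(seq_len(R), sum(y == 0)))
    })
    members <- vector("list", R)
    pred_tr <- matrix(0, nrow(Xtr$values), R)
    for (r in seq_len(R)) {
      keep <- if (R == 1L) rep(TRUE, length(sel)) else fold != r
      members[[r]] <- train_with_restarts(
        Xtr$values[sel[keep], , drop = FALSE], y[keep],
        spec = mlp_spec(ncol(Xtr$values), output_dim = 1L),
        config = config,
        seed_key = paste0("binary:", fam, ":", r), master = seed,
        max_restarts = max_restarts, restart_loss = restart_loss
      )
      members[[r]]$training_meta$family <- fam
      pred_tr[, r] <- predict_proba(members[[r]], Xtr$values)
    }
    binaries[[fam]] <- mlp_committee(members)
    P_oof[, fi] <- rowMeans(pred_tr)
    if (R > 1L) P_oof[sel, fi] <- pred_tr[cbind(sel, fold)]
  }

  stacker <- NULL
  if (isTRUE(with_stacker)) {
    stacker <- NULL
    for (try in 0:max_restarts) {
      key <- if (try == 0) "stacker" else paste0("stacker:retry", try)
      cand <- train_stacker(P_oof, train_rec$family, families,
                            config = config,
                            seed = derive_seed(seed, key))
      if (is.null(stacker) ||
          cand$training_meta$best_val_loss <
            stacker$training_meta$best_val_loss) {
        stacker <- cand
      }
      if (stacker$training_meta$best_val_loss <= restart_loss) break
    }
  }

  structure(list(k = as.integer(k), mask = mask, families = families,
                 binaries = binaries, stacker = stacker, scaler = scaler,
                 split = split,
                 meta = list(seed = as.integer(seed),
                             n_features = mask$n_selected,
                             n_train = nrow(train_rec),
                             standardize = standardize,
                             n_folds = as.integer(n_folds))),
            class = "tf_ensemble")
}

# train a binary network, retrying with fresh derived seeds while the best
# validation loss suggests training got stuck near chance level
train_with_restarts <- function(X, y, spec, config, seed_key, master,
                                max_restarts, restart_loss) {
  best <- NULL
  for (try in 0:max_restarts) {
    key <- if (try == 0) seed_key else paste0(seed_key, ":retry", try)
    cand <- train_binary(X, y, spec = spec, config = config,
                         seed = derive_seed(master, key))
    if (is.null(best) ||
        cand$training_meta$best_val_loss < best$training_meta$best_val_loss) {
      best <- cand
    }
    if (best$training_meta$best_val_loss <= restart_loss) break
  }
  best
}

# feature transform fitted on training rows; "count" multiplies relative
# frequencies by the mean valid-window count (length-invariant, count-like
# magnitudes); "zscore" is classical per-feature standardization
fit_scaler <- function(X, type = "count", sequences = NULL, k = NULL) {
  switch(type,
    none = list(type = "none"),
    count = {
      factor <- if (!is.null(sequences)) {
        mean(pmax(nchar(sequences) - k + 1L, 0L))
      } else 200
      list(type = "count", factor = factor)
    },
    zscore = {
      mu <- colMeans(X)
      sd <- sqrt(colMeans(sweep(X, 2L, mu)^2))
      sd[sd < 1e-8] <- 1
      list(type = "zscore", mean = mu, sd = sd)
    },
    stop("unknown scaler type: ", type)
  )
}

apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  switch(scaler$type,
    none = X,
    count = X * scaler$factor,
    zscore = sweep(sweep(X, 2L, scaler$mean), 2L, scaler$sd, "/"),
    stop("unknown scaler type: ", scaler$type)
  )
}

#' @export
print.tf_ensemble <- function(x, ...) {
  cat("tf_ensemble: k =", x$k, "|", length(x$families), "families |",
      x$mask$n_selected, "features |",
      if (is.null(x$stacker)) "no stacker" else "with stacker", "\n")
  invisible(x)
}

#' Base-learner probability matrix for a corpus
#'
#' Encodes the corpus at the ensemble's k, applies its feature mask and
#' (when the ensemble was trained with standardization) its persisted
#' feature scaler, then runs every per-family binary classifier. Column j holds the sigmoid output of
#' the classifier for `families[j]`; columns are NOT normalized across
#' families (each is an independent binary probability).
#'
#' @param ensemble a `tf_ensemble`.
#' @param corpus a `tf_corpus` (or an already-masked `feature_matrix`).
#' @return numeric matrix, n_sequences x n_families, entries in \[0, 1\],
#'   rows in corpus order, columns named by family.
#' @export
score_all <- function(ensemble, corpus) {
  stopifnot(inherits(ensemble, "tf_ensemble"))
  X <- if (inherits(corpus, "feature_matrix")) {
    if (!corpus$masked) stop("feature_matrix input must already be masked")
    if (corpus$k != ensemble$k) stop("k mismatch between matrix and ensemble")
    corpus
  } else {
    apply_mask(encode_corpus(corpus, build_vocabulary(ensemble$k)),
               ensemble$mask)
  }
  if (!is.null(ensemble$scaler)) {
    X$values <- apply_scaler(X$values, ensemble$scaler)
  }
  P <- vapply(ensemble$families,
              function(fam) predict_proba(ensemble$binaries[[fam]], X$values),
              numeric(nrow(X$values)))
  if (!is.matrix(P)) P <- matrix(P, nrow = 1L,
                                 dimnames = list(NULL, ensemble$families))
  rownames(P) <- X$row_ids
  P
}

# thresholded argmax shared by both voting methods; ties at the maximum go
# to the lowest family index; the comparison is >= so a probability exactly
# equal to the threshold is accepted
finalize_labels <- function(scores, families, threshold) {
  stopifnot(is.matrix(scores), ncol(scores) == length(families),
            threshold >= 0, threshold <= 1)
  j <- max.col(scores, ties.method = "first")
  conf <- scores[cbind(seq_len(nrow(scores)), j)]
  label <- ifelse(conf >= threshold, families[j], "unknown")
  data.frame(final_label = label, confidence = conf,
             stringsAsFactors = FALSE)
}

#' Max-voting finalizer
#'
#' Selects the family whose base classifier emits the highest probability;
#' if that maximum is below the threshold the sequence is rejected as
#' `"unknown"` (with the maximum still reported as the confidence). A
#' threshold of 0 always assigns a family.
#'
#' @param row numeric vector of per-family base probabilities, or a matrix
#'   with one row per sequence.
#' @param threshold confidence threshold in \[0, 1\].
#' @param families family names backing the entries; defaults to the vector
#'   names / matrix colnames.
#' @return data.frame with `final_label` and `confidence`.
#' @export
max_vote <- function(row, threshold = 0.5, families = NULL) {
  if (!is.matrix(row)) row <- matrix(row, nrow = 1L,
                                     dimnames = list(NULL, names(row)))
  if (is.null(families)) families <- colnames(row)
  if (is.null(families)) families <- paste0("class", seq_len(ncol(row)))
  finalize_labels(row, families, threshold)
}

#' Two-stage (stacking) finalizer
#'
#' Maps the base-probability vector through the stacking meta-classifier to
#' normalized per-family scores, then applies the same thresholded argmax as
#' [max_vote()] to the stacker scores.
#'
#' @param row base-probability vector or matrix (one row per sequence).
#' @param stacker the trained softmax `mlp_model`.
#' @param threshold confidence threshold in \[0, 1\].
#' @return data.frame with `final_label`, `confidence`, plus the stacker
#'   score matrix as attribute `"stacker_scores"`.
#' @export
two_stage <- function(row, stacker, threshold = 0.5) {
  if (!is.matrix(row)) row <- matrix(row, nrow = 1L)
  if (ncol(row) != stacker$spec$input_dim) {
    stop("row has ", ncol(row), " families but the stacker expects ",
         stacker$spec$input_dim)
  }
  S <- predict_proba(stacker, row)
  families <- stacker$training_meta$families %||%
    paste0("class", seq_len(ncol(S)))
  out <- finalize_labels(S, families, threshold)
  attr(out, "stacker_scores") <- S
  out
}

#' Classify a corpus with the ensemble
#'
#' Runs [score_all()] then the chosen finalizer on every sequence. The
#' report carries the full per-family probability matrix (base-learner
#' outputs, and the stacker's normalized scores when `method = "two_stage"`),
#' the final label (family or `"unknown"`), and the confidence backing it.
#'
#' @param ensemble a `tf_ensemble`.
#' @param corpus a `tf_corpus`.
#' @param method `"two_stage"` (default; requires a stacker) or `"max_vote"`.
#' @param threshold confidence threshold in \[0, 1\]; default 0.5.
#' @return a `prediction_report` data.frame: `id`, one `prob_<family>`
#'   column per family, `stacker_<family>` columns when two-stage,
#'   `final_label`, `confidence`, `method`, `threshold`. The raw base and
#'   stacker matrices ride along as attributes `base_scores` and
#'   `stacker_scores`.
#' @export
predict_families <- function(ensemble, corpus, method = c("two_stage", "max_vote"),
                             threshold = 0.5) {
  method <- match.arg(method)
  stopifnot(threshold >= 0, threshold <= 1)
  if (method == "two_stage" && is.null(ensemble$stacker)) {
    stop("two_stage prediction requires a trained stacker")
  }
  records <- if (inherits(corpus, "tf_corpus")) corpus$records else corpus
  if (nrow(records) == 0L) {
    rep0 <- data.frame(id = character(), final_label = character(),
                       confidence = double(), method = character(),
                       threshold = double(), stringsAsFactors = FALSE)
    class(rep0) <- c("prediction_report", class(rep0))
    return(rep0)
  }
  P <- score_all(ensemble, corpus)
  report_from_scores(P, ensemble, method, threshold)
}

# build a prediction_report from a fixed base-score matrix (no re-inference);
# used by predict_families and by threshold sweeps
report_from_scores <- function(P, ensemble, method, threshold) {
  fams <- ensemble$families
  if (method == "two_stage") {
    fin <- two_stage(P, ensemble$stacker, threshold)
    S <- attr(fin, "stacker_scores")
  } else {
    fin <- max_vote(P, threshold, families = fams)
    S <- NULL
  }
  out <- data.frame(id = rownames(P), stringsAsFactors = FALSE)
  for (i in seq_along(fams)) out[[paste0("prob_", fams[i])]] <- P[, i]
  if (!is.null(S)) {
    for (i in seq_along(fams)) out[[paste0("stacker_", fams[i])]] <- S[, i]
  }
  out$final_label <- fin$final_label
  out$confidence <- fin$confidence
  out$method <- method
  out$threshold <- threshold
  rownames(out) <- NULL
  attr(out, "base_scores") <- P
  attr(out, "stacker_scores") <- S
  class(out) <- c("prediction_report", class(out))
  out
}

#' Per-family assignment summary of a prediction report
#'
#' Counts, per family, the sequences assigned to it by the final vote and the
#' sequences whose probability for that family clears the threshold
#' (regardless of the final label) — the content of the per-family bar-chart
#' report.
#'
#' @param report a `prediction_report`.
#' @return data.frame with `family`, `n_assigned`, `n_above_threshold`.
#' @export
family_summary <- function(report) {
  P <- attr(report, "stacker_scores") %||% attr(report, "base_scores")
  fams <- colnames(P) %||% sub("^prob_", "",
                               grep("^prob_", names(report), value = TRUE))
  thr <- report$threshold[1] %||% 0.5
  data.frame(
    family = fams,
    n_assigned = vapply(fams, function(f) sum(report$final_label == f), integer(1)),
    n_above_threshold = vapply(seq_along(fams),
                               function(i) sum(P[, i] >= thr), integer(1)),
    row.names = NULL
  )
}

#' Write a prediction report as TSV and JSON
#'
#' @param report a `prediction_report`.
#' @param path_tsv,path_json output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, path_tsv = NULL, path_json = NULL) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  if (!is.null(path_tsv)) {
    write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(df, path_json, dataframe = "rows")
  }
  invisible(c(path_tsv, path_json))
}

# --- ensemble persistence ---------------------------------------------------

#' Save / load an ensemble bundle
#'
#' The bundle is a directory of plain-text files: `manifest.json` (k, family
#' order, seeds, version), `mask.json`, one spec/weights pair per binary
#' classifier, and the stacker pair when present. Weights round-trip at full
#' precision, so a reloaded ensemble reproduces predictions exactly.
#'
#' @param ensemble a `tf_ensemble`.
#' @param dir bundle directory (created if missing).
#' @return `dir` (save) / the `tf_ensemble` (load).
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(format = "kmerTF-bundle", version = 1L, k = ensemble$k,
         families = ensemble$families, meta = ensemble$meta,
         has_stacker = !is.null(ensemble$stacker)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  write_mask(ensemble$mask, file.path(dir, "mask.json"))
  if (!is.null(ensemble$scaler)) {
    sc <- ensemble$scaler
    out <- list(type = sc$type)
    if (sc$type == "count") out$factor <- sprintf("%.17g", sc$factor)
    if (sc$type == "zscore") {
      out$mean <- sprintf("%.17g", sc$mean)
      out$sd <- sprintf("%.17g", sc$sd)
    }
    jsonlite::write_json(out, file.path(dir, "scaler.json"),
                         auto_unbox = TRUE)
  }
  for (i in seq_along(ensemble$families)) {
    fam <- ensemble$families[i]
    cls <- ensemble$binaries[[fam]]
    members <- if (inherits(cls, "mlp_committee")) cls$members else list(cls)
    for (r in seq_along(members)) {
      save_mlp(members[[r]],
               file.path(dir, sprintf("binary_%03d_m%d_spec.json", i, r)),
               file.path(dir, sprintf("binary_%03d_m%d_weights.txt", i, r)))
    }
  }
  if (!is.null(ensemble$stacker)) {
    save_mlp(ensemble$stacker, file.path(dir, "stacker_spec.json"),
             file.path(dir, "stacker_weights.txt"))
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "kmerTF-bundle")) {
    stop("not an ensemble bundle: ", dir)
  }
  mask <- read_mask(file.path(dir, "mask.json"))
  if (mask$k != man$k) stop("bundle mask k (", mask$k,
                            ") disagrees with manifest k (", man$k, ")")
  fams <- man$families
  binaries <- setNames(vector("list", length(fams)), fams)
  for (i in seq_along(fams)) {
    members <- list()
    r <- 1L
    repeat {
      spec_path <- file.path(dir, sprintf("binary_%03d_m%d_spec.json", i, r))
      if (!file.exists(spec_path)) break
      members[[r]] <- load_mlp(
        spec_path, file.path(dir, sprintf("binary_%03d_m%d_weights.txt", i, r)))
      r <- r + 1L
    }
    if (length(members) == 0L) stop("no classifier files for family ", fams[i])
    binaries[[fams[i]]] <- if (length(members) == 1L) members[[1L]]
                           else mlp_committee(members)
  }
  stacker <- NULL
  if (isTRUE(man$has_stacker)) {
    stacker <- load_mlp(file.path(dir, "stacker_spec.json"),
                        file.path(dir, "stacker_weights.txt"))
    stacker$training_meta$families <- fams
  }
  scaler <- NULL
  scaler_path <- file.path(dir, "scaler.json")
  if (file.exists(scaler_path)) {
    obj <- jsonlite::read_json(scaler_path, simplifyVector = TRUE)
    scaler <- switch(obj$type,
      none = list(type = "none"),
      count = list(type = "count", factor = as.numeric(obj$factor)),
      zscore = list(type = "zscore", mean = as.numeric(obj$mean),
                    sd = as.numeric(obj$sd)))
  }
  structure(list(k = as.integer(man$k), mask = mask, families = fams,
                 binaries = binaries, stacker = stacker, scaler = scaler,
                 split = NULL, meta = man$meta),
            class = "tf_ensemble")
}
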