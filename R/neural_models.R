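#' Classifier architecture specification
#'
#' The per-family binary classifier is a feed-forward network with four fully
#' connected hidden layers of 256, 128, 64 and 32 units, each followed by a
#' ReLU activation and dropout with rate 0.5, and a single sigmoid output
#' trained with binary cross-entropy. The stacking meta-classifier reuses the
#' same hidden architecture, differing only in its input dimension (one
#' probability per family) and its output (a normalized softmax over the
#' family set trained with multi-class cross-entropy).
#'
#' @param input_dim number of input features.
#' @param output_dim 1 for a binary sigmoid head, >= 2 for a softmax head.
#' @param hidden hidden layer widths (strictly decreasing).
#' @param dropout dropout rate applied after every hidden activation.
#' @param output `"sigmoid"` or `"softmax"`.
#' @return an `mlp_spec` list.
#' @export
mlp_spec <- function(input_dim, output_dim = 1L,
                     hidden = c(256L, 128L, 64L, 32L),
                     dropout = 0.5,
                     output = if (output_dim == 1L) "sigmoid" else "softmax") {
  stopifnot(input_dim >= 1, output_dim >= 1, dropout >= 0, dropout < 1,
            all(diff(hidden) < 0), output %in% c("sigmoid", "softmax"))
  if (output == "softmax" && output_dim < 2) stop("softmax head needs >= 2 classes")
  if (output == "sigmoid" && output_dim != 1) {
    stop("a sigmoid head emits a single probability; use softmax for ",
         output_dim, " classes")
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim),
                 dropout = dropout, activation = "relu", output = output),
            class = "mlp_spec")
}

#' Training configuration defaults
#'
#' Hyperparameters not pinned down by the architecture: mini-batch size 64,
#' Adam with learning rate 1e-3 (beta1 0.9, beta2 0.999, eps 1e-8), at most
#' 300 epochs, early stopping with patience 30 on the loss of a 10% held-out
#' validation fold, best-epoch weights restored. The generous epoch cap and
#' patience matter because small balanced subsets see only a handful of
#' gradient steps per epoch and typically traverse an initial loss plateau
#' before converging.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param max_epochs epoch cap.
#' @param patience epochs without validation improvement before stopping.
#' @param val_fraction share of rows held out for early stopping.
#' @param weight_decay decoupled L2 penalty applied at each Adam step.
#'   Regularizes the heavily over-parameterized networks and keeps their
#'   logits from saturating, which matters for open-set rejection: an
#'   overconfident classifier assigns near-1 probabilities to sequences from
#'   no family at all and defeats the confidence threshold.
#' @return a list of training settings.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 1e-3,
                         max_epochs = 300L, patience = 30L,
                         val_fraction = 0.1, weight_decay = 0) {
  list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       val_fraction = val_fraction, weight_decay = weight_decay)
}

# He-normal initialization; biases start at zero
init_params <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden, spec$output_dim)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                     nrow = dims[l], ncol = dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass; with training = TRUE applies inverted dropout and returns
# the caches needed by the backward pass
mlp_forward <- function(params, spec, X, training = FALSE) {
  H <- length(spec$hidden)
  A <- X
  Zs <- vector("list", H); As <- vector("list", H + 1L); Ds <- vector("list", H)
  As[[1L]] <- A
  for (l in seq_len(H)) {
    Z <- A %*% params$W[[l]]
    Z <- sweep(Z, 2L, params$b[[l]], "+")
    A <- pmax(Z, 0)
    if (training && spec$dropout > 0) {
      keep <- 1 - spec$dropout
      D <- matrix((runif(length(A)) < keep) / keep, nrow = nrow(A))
      A <- A * D
      Ds[[l]] <- D
    }
    Zs[[l]] <- Z
    As[[l + 1L]] <- A
  }
  logits <- sweep(A %*% params$W[[H + 1L]], 2L, params$b[[H + 1L]], "+")
  list(logits = logits, Zs = Zs, As = As, Ds = Ds)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# numerically stable mean binary cross-entropy from logits
bce_loss <- function(logits, y) {
  z <- as.numeric(logits)
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

# mean multi-class cross-entropy from logits; Y is a one-hot matrix and w
# an optional per-row weight vector (mean 1)
ce_loss <- function(logits, Y, w = NULL) {
  z <- logits - apply(logits, 1L, max)
  lse <- log(rowSums(exp(z)))
  ll <- rowSums(Y * z) - lse
  if (!is.null(w)) ll <- ll * w
  -mean(ll)
}

mlp_loss <- function(params, spec, X, target, w = NULL) {
  logits <- mlp_forward(params, spec, X, training = FALSE)$logits
  if (spec$output == "sigmoid") bce_loss(logits, target)
  else ce_loss(logits, target, w)
}

# gradients via backpropagation; target is a 0/1 vector (sigmoid) or a
# one-hot matrix (softmax); w weights rows of a softmax loss; dropout caches
# come from the forward pass
mlp_backward <- function(params, spec, fwd, target, w = NULL) {
  H <- length(spec$hidden)
  n <- nrow(fwd$logits)
  if (spec$output == "sigmoid") {
    delta <- (sigmoid(fwd$logits) - matrix(target, ncol = 1L)) / n
  } else {
    delta <- (softmax_rows(fwd$logits) - target) / n
    if (!is.null(w)) delta <- delta * w
  }
  dW <- vector("list", H + 1L); db <- vector("list", H + 1L)
  dW[[H + 1L]] <- crossprod(fwd$As[[H + 1L]], delta)
  db[[H + 1L]] <- colSums(delta)
  dA <- delta %*% t(params$W[[H + 1L]])
  for (l in H:1) {
    if (!is.null(fwd$Ds[[l]])) dA <- dA * fwd$Ds[[l]]
    dZ <- dA * (fwd$Zs[[l]] > 0)
    dW[[l]] <- crossprod(fwd$As[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) dA <- dZ %*% t(params$W[[l]])
  }
  list(W = dW, b = db)
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * ((state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps) +
              weight_decay * params$W[[l]])
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(params = params, state = state)
}

# core training loop shared by the binary classifiers and the stacker
train_mlp <- function(X, target, spec, config = train_config(), seed = 42L,
                      row_weights = NULL) {
  stopifnot(is.matrix(X), nrow(X) >= 2L, ncol(X) == spec$input_dim)
  if (!is.null(row_weights)) stopifnot(length(row_weights) == nrow(X))
  n <- nrow(X)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  params <- init_params(spec)
  state <- adam_init(params)

  n_val <- max(1L, as.integer(floor(config$val_fraction * n)))
  if (n - n_val < 2L) n_val <- max(0L, n - 2L)
  val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  pick <- function(tg, idx) if (is.matrix(tg)) tg[idx, , drop = FALSE] else tg[idx]
  Xtr <- X[tr_idx, , drop = FALSE]; ttr <- pick(target, tr_idx)
  Xva <- X[val_idx, , drop = FALSE]; tva <- pick(target, val_idx)
  wtr <- row_weights[tr_idx]; wva <- row_weights[val_idx]

  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = double(),
                        val_loss = double())
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(length(tr_idx))
    starts <- seq(1L, length(perm), by = config$batch_size)
    for (s in starts) {
      bi <- perm[s:min(s + config$batch_size - 1L, length(perm))]
      fwd <- mlp_forward(params, spec, Xtr[bi, , drop = FALSE], training = TRUE)
      grads <- mlp_backward(params, spec, fwd, pick(ttr, bi), wtr[bi])
      upd <- adam_step(params, grads, state, config$learning_rate,
                       config$weight_decay %||% 0)
      params <- upd$params; state <- upd$state
    }
    tl <- mlp_loss(params, spec, Xtr, ttr, wtr)
    vl <- if (length(val_idx)) mlp_loss(params, spec, Xva, tva, wva) else tl
    if (!is.finite(tl)) {
      stop("training diverged (non-finite loss) at epoch ", epoch,
           "; lower the learning rate or check the inputs")
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                         val_loss = vl))
    if (vl < best$loss - 1e-8) {
      best <- list(loss = vl, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(spec = spec, W = best$params$W, b = best$params$b,
                 training_meta = list(seed = as.integer(seed),
                                      epochs_run = nrow(history),
                                      best_epoch = best$epoch,
                                      best_val_loss = best$loss,
                                      history = history)),
            class = "mlp_model")
}

#' Train one per-family binary classifier
#'
#' @param X masked feature matrix (a `feature_matrix` or plain matrix) of
#'   the balanced binary subset rows.
#' @param y 0/1 labels (1 = member of the target family).
#' @param spec an [mlp_spec()]; default the standard binary architecture.
#' @param config a [train_config()].
#' @param seed integer seed for initialization, fold draw, shuffling and
#'   dropout.
#' @return an `mlp_model` with training history in `training_meta`.
#' @export
train_binary <- function(X, y, spec = NULL, config = train_config(),
                         seed = 42L) {
  Xm <- if (inherits(X, "feature_matrix")) X$values else X
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(Xm), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("binary training needs both classes present")
  if (is.null(spec)) spec <- mlp_spec(ncol(Xm), output_dim = 1L)
  train_mlp(Xm, y, spec, config, seed)
}

#' Train the stacking meta-classifier
#'
#' Takes the matrix of base-classifier probabilities (one column per family,
#' in canonical family order) on the training sequences and learns a softmax
#' model over the family set.
#'
#' The cross-entropy is class-balanced: each row is weighted inversely to
#' its family's frequency (normalized to mean 1), so the long tail of small
#' families cannot be sacrificed by a meta-learner that sees them in only a
#' handful of rows.
#'
#' @param P numeric matrix, n x n_families, of base probabilities.
#' @param labels per-row family labels, all drawn from `families`.
#' @param families canonical ordered family names (must match `colnames(P)`
#'   when present).
#' @param spec,config,seed as in [train_binary()].
#' @param balanced weight rows inversely to class frequency? Default TRUE.
#' @return an `mlp_model` with `training_meta$families` recording the order.
#' @export
train_stacker <- function(P, labels, families, spec = NULL,
                          config = train_config(), seed = 42L,
                          balanced = TRUE) {
  stopifnot(is.matrix(P), ncol(P) == length(families))
  if (!is.null(colnames(P)) && !identical(colnames(P), families)) {
    stop("column order of P does not match the canonical family order")
  }
  cls <- match(as.character(labels), families)
  if (anyNA(cls)) stop("labels outside the family set: ",
                       paste(unique(labels[is.na(cls)]), collapse = ", "))
  Y <- matrix(0, nrow(P), length(families))
  Y[cbind(seq_len(nrow(P)), cls)] <- 1
  if (is.null(spec)) spec <- mlp_spec(length(families),
                                      output_dim = length(families))
  w <- NULL
  if (isTRUE(balanced)) {
    freq <- tabulate(cls, nbins = length(families))
    w <- (1 / freq[cls])
    w <- w / mean(w)
  }
  model <- train_mlp(unname(P), Y, spec, config, seed, row_weights = w)
  model$training_meta$families <- families
  model
}

#' Predict probabilities from a trained model
#'
#' Dropout is disabled at inference, so repeated calls on the same input are
#' identical. A sigmoid model returns a vector of probabilities in \[0, 1\];
#' a softmax model returns a matrix whose rows are non-negative and sum to 1.
#' For a cross-fitted committee (see [mlp_committee()]) the member
#' probabilities are averaged.
#'
#' @param model an `mlp_model` or `mlp_committee`.
#' @param X input matrix with `input_dim` columns.
#' @return numeric vector (sigmoid) or matrix (softmax).
#' @export
predict_proba <- function(model, X) UseMethod("predict_proba")

#' @export
predict_proba.mlp_model <- function(model, X) {
  Xm <- if (inherits(X, "feature_matrix")) X$values else X
  if (!is.matrix(Xm)) Xm <- as.matrix(Xm)
  if (ncol(Xm) != model$spec$input_dim) {
    stop("input has ", ncol(Xm), " columns but the model expects ",
         model$spec$input_dim)
  }
  logits <- mlp_forward(model[c("W", "b")], model$spec, Xm,
                        training = FALSE)$logits
  if (model$spec$output == "sigmoid") as.numeric(sigmoid(logits))
  else softmax_rows(logits)
}

#' Bundle cross-fitted fold models into one committee classifier
#'
#' The committee is the unit that plays the role of "the" binary classifier
#' of a family: each member is the same architecture trained on a different
#' fold complement of the family's balanced subset, and the committee
#' probability is the members' mean. Averaging tames the extrapolation
#' spikes an individual over-parameterized network produces on sequences far
#' from its small training set, which is what the confidence threshold needs
#' to reject non-TF input.
#'
#' @param members list of `mlp_model`s with identical specs.
#' @return an `mlp_committee`.
#' @export
mlp_committee <- function(members) {
  stopifnot(length(members) >= 1L,
            all(vapply(members, inherits, logical(1), "mlp_model")))
  structure(list(members = members, spec = members[[1L]]$spec),
            class = "mlp_committee")
}

#' @export
predict_proba.mlp_committee <- function(model, X) {
  preds <- lapply(model$members, function(m) predict_proba(m, X))
  Reduce(`+`, preds) / length(preds)
}

#' @export
print.mlp_committee <- function(x, ...) {
  cat("mlp_committee of", length(x$members), "members: ")
  print(x$members[[1L]])
  invisible(x)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("mlp_model: ", x$spec$input_dim, " -> [",
      paste(x$spec$hidden, collapse = ", "), "] -> ", x$spec$output_dim,
      " (", x$spec$output, "), trained ", x$training_meta$epochs_run,
      " epochs (best ", x$training_meta$best_epoch, ")\n", sep = "")
  invisible(x)
}

# --- plain-text persistence -------------------------------------------------

# weights are written as one "%.17g" number per line, which round-trips IEEE
# doubles exactly, so a reloaded model reproduces predictions bit for bit
flatten_params <- function(model) {
  unlist(c(lapply(model$W, as.numeric), lapply(model$b, as.numeric)))
}

unflatten_params <- function(spec, flat) {
  dims <- c(spec$input_dim, spec$hidden, spec$output_dim)
  W <- vector("list", length(dims) - 1L); b <- vector("list", length(dims) - 1L)
  pos <- 0L
  for (l in seq_along(W)) {
    len <- dims[l] * dims[l + 1L]
    W[[l]] <- matrix(flat[pos + seq_len(len)], dims[l], dims[l + 1L])
    pos <- pos + len
  }
  for (l in seq_along(b)) {
    b[[l]] <- flat[pos + seq_len(dims[l + 1L])]
    pos <- pos + dims[l + 1L]
  }
  stopifnot(pos == length(flat))
  list(W = W, b = b)
}

save_mlp <- function(model, spec_path, weights_path) {
  meta <- model$training_meta
  meta$history <- NULL   # history is reproducible from seed + data
  jsonlite::write_json(list(spec = unclass(model$spec), training_meta = meta),
                       spec_path, auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("%.17g", flatten_params(model)), weights_path)
  invisible(NULL)
}

load_mlp <- function(spec_path, weights_path) {
  obj <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
  spec <- structure(obj$spec, class = "mlp_spec")
  spec$input_dim <- as.integer(spec$input_dim)
  spec$hidden <- as.integer(spec$hidden)
  spec$output_dim <- as.integer(spec$output_dim)
  flat <- as.numeric(readLines(weights_path))
  params <- unflatten_params(spec, flat)
  structure(list(spec = spec, W = params$W, b = params$b,
                 training_meta = obj$training_meta),
            class = "mlp_model")
}
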