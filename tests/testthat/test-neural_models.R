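test_that("backpropagation gradients match numerical differentiation", {
  num_grad_check <- function(spec, X, target) {
    set.seed(17)
    p <- kmerTF:::init_params(spec)
    fwd <- kmerTF:::mlp_forward(p, spec, X, training = FALSE)
    g <- kmerTF:::mlp_backward(p, spec, fwd, target)
    base <- kmerTF:::mlp_loss(p, spec, X, target)
    eps <- 1e-6
    worst <- 0
    for (l in seq_along(p$W)) {
      for (i in sample(length(p$W[[l]]), 3)) {
        p2 <- p; p2$W[[l]][i] <- p2$W[[l]][i] + eps
        num <- (kmerTF:::mlp_loss(p2, spec, X, target) - base) / eps
        worst <- max(worst, abs(num - g$W[[l]][i]) / max(abs(num), 1e-8))
      }
    }
    worst
  }
  spec_b <- mlp_spec(5, output_dim = 1, hidden = c(7, 4), dropout = 0)
  Xb <- matrix(rnorm(30), 6, 5)
  expect_lt(num_grad_check(spec_b, Xb, c(1, 0, 1, 1, 0, 0)), 1e-4)

  spec_s <- mlp_spec(4, output_dim = 3, hidden = c(6, 5), dropout = 0)
  Xs <- matrix(rnorm(20), 5, 4)
  expect_lt(num_grad_check(spec_s, Xs, diag(3)[c(1, 2, 3, 1, 2), ]), 1e-4)
})

test_that("the specification validates its architecture contract", {
  expect_error(mlp_spec(10, hidden = c(8, 16)), "diff")  # must decrease
  expect_error(mlp_spec(10, output_dim = 3, output = "sigmoid"))
  s <- mlp_spec(50)
  expect_equal(s$hidden, c(256L, 128L, 64L, 32L))
  expect_equal(s$dropout, 0.5)
  expect_equal(s$output, "sigmoid")
})

test_that("training is deterministic in the seed and predictions are probabilities", {
  withr::with_seed(2, {
    X <- matrix(rnorm(60 * 12), 60, 12)
    y <- as.numeric(X[, 1] + X[, 2] > 0)
  })
  spec <- mlp_spec(12, hidden = c(16, 8), dropout = 0.5)
  cfg <- train_config(max_epochs = 15, patience = 15)
  m1 <- train_binary(X, y, spec = spec, config = cfg, seed = 123)
  m2 <- train_binary(X, y, spec = spec, config = cfg, seed = 123)
  expect_identical(m1$W, m2$W)
  m3 <- train_binary(X, y, spec = spec, config = cfg, seed = 124)
  expect_false(identical(m1$W, m3$W))

  p <- predict_proba(m1, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_proba(m1, X))  # dropout off at inference
  expect_length(predict_proba(m1, X[1:3, ]), 3L)
  zero <- predict_proba(m1, matrix(0, 1, 12))
  expect_true(zero >= 0 && zero <= 1)
  expect_error(predict_proba(m1, X[, 1:5]), "expects")
  expect_error(train_binary(X, rep(1, 60), spec = spec, config = cfg),
               "both classes")
})

test_that("training loss decreases monotonically on separable toy data", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(40, mean = 2), 20, 2),
               matrix(rnorm(40, mean = -2), 20, 2))
    y <- rep(c(1, 0), each = 20)
  })
  spec <- mlp_spec(2, hidden = c(8, 4), dropout = 0)
  m <- train_binary(X, y, spec = spec,
                    config = train_config(max_epochs = 5, patience = 5,
                                          batch_size = 8), seed = 1)
  h <- m$training_meta$history
  expect_equal(nrow(h), 5L)
  expect_true(all(diff(h$train_loss) < 0))
})

test_that("a separable motif subset reaches high held-out accuracy", {
  co <- tiny_ensemble()$corpus
  ens <- tiny_ensemble()$ensemble
  test_ids <- ens$split$test_ids
  tc <- corpus_subset(co, test_ids)
  rep <- predict_families(ens, tc, method = "max_vote", threshold = 0)
  truth <- tc$records$family[match(rep$id, tc$records$id)]
  expect_gte(mean(rep$final_label == truth), 0.95)
})

test_that("the stacker consumes family-ordered probabilities and normalizes output", {
  withr::with_seed(3, {
    fams <- c("F1", "F2", "F3")
    n <- 90
    cls <- sample(3, n, replace = TRUE)
    P <- matrix(runif(n * 3) * 0.15, n, 3)
    P[cbind(seq_len(n), cls)] <- runif(n, 0.85, 1)
    colnames(P) <- fams
  })
  stk <- train_stacker(P, fams[cls], fams,
                       config = train_config(max_epochs = 30, patience = 30),
                       seed = 5)
  expect_equal(stk$spec$input_dim, 3L)
  expect_equal(stk$spec$output_dim, 3L)
  S <- predict_proba(stk, P)
  expect_true(all(S >= 0))
  expect_equal(rowSums(S), rep(1, n), tolerance = 1e-9)
  # on clean inputs the stacker argmax matches the max-voting argmax
  agree <- mean(max.col(S, ties.method = "first") ==
                  max.col(P, ties.method = "first"))
  expect_gte(agree, 0.95)
  expect_error(train_stacker(P[, 1:2], fams[cls], fams), "ncol")
  expect_error(train_stacker(P, rep("F9", n), fams), "outside")
  Pbad <- P; colnames(Pbad) <- rev(fams)
  expect_error(train_stacker(Pbad, fams[cls], fams), "order")
})

test_that("models persist to text and reload with bit-identical predictions", {
  withr::with_seed(4, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    y <- as.numeric(X[, 3] > 0)
  })
  m <- train_binary(X, y, spec = mlp_spec(6, hidden = c(8, 4)),
                    config = train_config(max_epochs = 10, patience = 10),
                    seed = 6)
  sp <- tempfile(fileext = ".json"); wp <- tempfile(fileext = ".txt")
  kmerTF:::save_mlp(m, sp, wp)
  back <- kmerTF:::load_mlp(sp, wp)
  expect_identical(back$spec$hidden, m$spec$hidden)
  expect_identical(predict_proba(back, X), predict_proba(m, X))
})

test_that("a committee predicts the mean of its members", {
  withr::with_seed(9, {
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- as.numeric(X[, 1] > 0)
  })
  cfg <- train_config(max_epochs = 8, patience = 8)
  ms <- lapply(1:3, function(s) {
    train_binary(X, y, spec = mlp_spec(5, hidden = c(6, 3)),
                 config = cfg, seed = s)
  })
  com <- mlp_committee(ms)
  expected <- rowMeans(vapply(ms, function(m) predict_proba(m, X),
                              numeric(nrow(X))))
  expect_equal(predict_proba(com, X), expected)
})

test_that("divergent training aborts with a diagnostic", {
  X <- matrix(c(1e8, -1e8, 1e8, -1e8), 4, 1)
  y <- c(1, 0, 1, 0)
  expect_error(
    train_binary(X, y, spec = mlp_spec(1, hidden = c(4, 2), dropout = 0),
                 config = train_config(max_epochs = 5, patience = 5,
                                       learning_rate = 1e300)),
    "diverged")
})
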