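test_that("confusion reproduces the hand-worked one-vs-rest counts", {
  cc <- confusion(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                  classes = c("A", "B"))
  a <- cc[cc$class == "A", ]; b <- cc[cc$class == "B", ]
  expect_equal(c(a$TP, a$FP, a$FN, a$TN), c(1L, 0L, 1L, 2L))
  expect_equal(c(b$TP, b$FP, b$FN, b$TN), c(2L, 1L, 0L, 1L))
  expect_true(all(cc$TP + cc$FP + cc$FN + cc$TN == 4L))
})

test_that("confusion treats unknown as FN for the true class, never TP/FP", {
  cc <- confusion(c("A", "A", "B"), c("unknown", "A", "unknown"),
                  classes = c("A", "B"))
  a <- cc[cc$class == "A", ]; b <- cc[cc$class == "B", ]
  expect_equal(c(a$TP, a$FP, a$FN), c(1L, 0L, 1L))
  expect_equal(c(b$TP, b$FP, b$FN), c(0L, 0L, 1L))

  all_unk <- confusion(c("A", "A", "B"), rep("unknown", 3), c("A", "B"))
  expect_true(all(all_unk$TP == 0L) && all(all_unk$FP == 0L))
  expect_equal(all_unk$FN, c(2L, 1L))

  perfect <- confusion(c("A", "B"), c("A", "B"), c("A", "B"))
  expect_true(all(perfect$FP == 0L) && all(perfect$FN == 0L))

  expect_error(confusion(c("A", "Z"), c("A", "A"), classes = c("A", "B")),
               "outside")
})

test_that("averaged_metrics reproduces the hand-worked example exactly", {
  m <- averaged_metrics(confusion(c("A", "A", "B", "B"),
                                  c("A", "B", "B", "B"), c("A", "B")))
  expect_equal(m$micro$accuracy, 0.75)
  expect_equal(m$macro$precision, 5 / 6)
  expect_equal(m$macro$recall, 0.75)
})

test_that("micro identities hold for single-label predictions without unknowns", {
  withr::with_seed(14, {
    classes <- c("A", "B", "C", "D")
    y_true <- sample(classes, 60, replace = TRUE)
    y_pred <- ifelse(runif(60) < 0.7, y_true, sample(classes, 60, replace = TRUE))
  })
  m <- averaged_metrics(confusion(y_true, y_pred, classes))
  expect_equal(m$micro$precision, m$micro$accuracy)
  expect_equal(m$micro$recall, m$micro$accuracy)
  expect_equal(m$micro$f1, m$micro$accuracy)
  # weighted recall coincides with micro recall in single-label evaluation
  expect_equal(m$weighted$recall, m$micro$recall)
})

test_that("metrics are invariant under joint permutation and handle edge classes", {
  withr::with_seed(15, {
    y_true <- sample(c("A", "B", "C"), 30, replace = TRUE)
    y_pred <- sample(c("A", "B", "C", "unknown"), 30, replace = TRUE)
    perm <- sample(30)
  })
  m1 <- averaged_metrics(confusion(y_true, y_pred, c("A", "B", "C")))
  m2 <- averaged_metrics(confusion(y_true[perm], y_pred[perm], c("A", "B", "C")))
  expect_equal(m1$micro, m2$micro)
  expect_equal(m1$macro, m2$macro)
  # classes absent from y_true are excluded from the macro mean
  m3 <- averaged_metrics(confusion(c("A", "A"), c("A", "A"), c("A", "B")))
  expect_equal(m3$macro$recall, 1)
  # perfect prediction scores 1 everywhere
  mp <- averaged_metrics(confusion(y_true, y_true, c("A", "B", "C")))
  expect_equal(mp$micro$accuracy, 1)
  expect_equal(mp$macro$f1, 1)
  expect_equal(mp$weighted$f1, 1)
})

test_that("threshold_sweep reuses scores and is monotone under unknown-as-error", {
  fix <- tiny_ensemble()
  tc <- corpus_subset(fix$corpus, fix$ensemble$split$test_ids)
  sw <- threshold_sweep(fix$ensemble, tc, method = "two_stage",
                        thresholds = c(0, 0.5, 0.95))
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$threshold, c(0, 0.5, 0.95))
  expect_true(all(diff(sw$n_classified) <= 0))
  expect_true(all(diff(sw$micro_accuracy) <= 1e-12))
  expect_equal(sw$n_classified[1], nrow(tc$records))  # threshold 0: no rejection
  one <- threshold_sweep(fix$ensemble, tc, "max_vote", 0.5)
  expect_equal(nrow(one), 1L)
  expect_error(threshold_sweep(fix$ensemble, tc, "max_vote", c(0.9, 0.1)))
})

test_that("mann_whitney_u matches hand examples and the U identity", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)               # n1 * n2 / 2 under symmetry
  expect_equal(same$p_value, 1)

  disjoint <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(disjoint$U, 0)

  withr::with_seed(16, {
    for (rep in 1:5) {
      a <- runif(sample(3:8, 1)); b <- runif(sample(3:8, 1))
      ua <- mann_whitney_u(a, b)$U
      ub <- mann_whitney_u(b, a)$U
      expect_equal(ua + ub, length(a) * length(b))
    }
  })
})

test_that("exact p-values match brute-force enumeration, with and without ties", {
  cases <- list(
    list(a = c(1, 2), b = c(3, 4)),
    list(a = c(1, 2, 2, 5), b = c(2, 3, 3)),        # ties across samples
    list(a = c(0.1, 0.5, 0.9), b = c(0.2, 0.5)),
    list(a = c(7, 7, 7), b = c(7, 7))               # fully tied
  )
  for (cs in cases) {
    got <- mann_whitney_u(cs$a, cs$b)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, exact_mw_p(cs$a, cs$b))
  }
  # tie-free exact case agrees with R's own exact test
  a <- c(1.1, 2.3, 3.7, 4.2); b <- c(0.5, 2.9, 5.1)
  expect_equal(mann_whitney_u(a, b)$p_value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
  expect_equal(mann_whitney_u(a, b)$U,
               unname(stats::wilcox.test(a, b, exact = TRUE)$statistic))
})

test_that("large samples use the tie-corrected normal approximation", {
  withr::with_seed(17, {
    a <- round(runif(12), 1)   # rounding forces ties
    b <- round(runif(10), 1)
  })
  got <- mann_whitney_u(a, b)
  expect_equal(got$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1))
})
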