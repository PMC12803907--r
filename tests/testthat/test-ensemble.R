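test_that("score_all produces an aligned probability matrix in [0, 1]", {
  fix <- tiny_ensemble()
  co <- fix$corpus; ens <- fix$ensemble
  tc <- corpus_subset(co, ens$split$test_ids)
  P <- score_all(ens, tc)
  expect_equal(dim(P), c(nrow(tc$records), length(ens$families)))
  expect_equal(rownames(P), tc$records$id)
  expect_equal(colnames(P), ens$families)
  expect_true(all(P >= 0 & P <= 1))
  # duplicate sequences score identically
  rec2 <- tc$records[c(1, 1), ]; rec2$id <- c("dup1", "dup2")
  P2 <- score_all(ens, kmerTF:::new_corpus(rec2))
  expect_equal(unname(P2[1, ]), unname(P2[2, ]))
})

test_that("max_vote applies thresholded argmax with deterministic tie-breaks", {
  out <- max_vote(c(0.1, 0.9, 0.3), threshold = 0.5,
                  families = c("A", "B", "C"))
  expect_equal(out$final_label, "B")
  expect_equal(out$confidence, 0.9)

  out2 <- max_vote(c(0.4, 0.3), threshold = 0.5, families = c("A", "B"))
  expect_equal(out2$final_label, "unknown")
  expect_equal(out2$confidence, 0.4)

  # threshold 0 always assigns; exact ties go to the lowest family index
  out3 <- max_vote(c(0.2, 0.7, 0.7), threshold = 0, families = c("A", "B", "C"))
  expect_equal(out3$final_label, "B")
  # a probability exactly equal to the threshold is accepted
  out4 <- max_vote(c(0.5, 0.1), threshold = 0.5, families = c("A", "B"))
  expect_equal(out4$final_label, "A")
})

test_that("two_stage thresholds the stacker scores and checks dimensions", {
  ens <- tiny_ensemble()$ensemble
  fams <- ens$families
  P <- matrix(0.05, 2, length(fams))
  P[1, 2] <- 0.95
  out <- two_stage(P, ens$stacker, threshold = 0)
  expect_equal(nrow(out), 2L)
  S <- attr(out, "stacker_scores")
  expect_equal(rowSums(S), rep(1, 2), tolerance = 1e-9)
  expect_equal(out$confidence, S[cbind(1:2, max.col(S, ties.method = "first"))])
  # threshold 0 never rejects; threshold above the max always rejects
  expect_false(any(out$final_label == "unknown"))
  out_hi <- two_stage(P, ens$stacker, threshold = 1)
  expect_true(all(out_hi$final_label == "unknown" |
                    out_hi$confidence == 1))
  expect_error(two_stage(P[, -1, drop = FALSE], ens$stacker), "expects")
})

test_that("predict_families builds complete reports for both methods", {
  fix <- tiny_ensemble()
  co <- fix$corpus; ens <- fix$ensemble
  tc <- corpus_subset(co, ens$split$test_ids)
  for (meth in c("two_stage", "max_vote")) {
    rep <- predict_families(ens, tc, method = meth, threshold = 0.5)
    expect_equal(nrow(rep), nrow(tc$records))
    expect_equal(rep$id, tc$records$id)
    expect_true(all(paste0("prob_", ens$families) %in% names(rep)))
    expect_true(all(rep$final_label %in% c(ens$families, "unknown")))
    expect_true(all(rep$confidence >= 0 & rep$confidence <= 1))
    expect_equal(unique(rep$method), meth)
    # unknown exactly when the confidence is below the threshold
    expect_equal(rep$final_label == "unknown", rep$confidence < 0.5)
  }
  rep2 <- predict_families(ens, tc, method = "two_stage", threshold = 0.5)
  expect_true(all(paste0("stacker_", ens$families) %in% names(rep2)))

  empty <- kmerTF:::new_corpus(co$records[0, ])
  expect_equal(nrow(predict_families(ens, empty)), 0L)

  no_stack <- ens; no_stack$stacker <- NULL
  expect_error(predict_families(no_stack, tc, method = "two_stage"),
               "stacker")
})

test_that("rejection is monotone in the threshold for both methods", {
  fix <- tiny_ensemble()
  tc <- corpus_subset(fix$corpus, fix$ensemble$split$test_ids)
  for (meth in c("max_vote", "two_stage")) {
    assigned <- lapply(c(0, 0.5, 0.95, 0.99), function(th) {
      rep <- predict_families(fix$ensemble, tc, method = meth, threshold = th)
      rep$id[rep$final_label != "unknown"]
    })
    expect_equal(length(assigned[[1]]), nrow(tc$records))  # threshold-0 totality
    for (i in 2:4) {
      expect_true(all(assigned[[i]] %in% assigned[[i - 1]]))
    }
  }
})

test_that("permuting families and classifiers permutes report labels identically", {
  withr::with_seed(10, {
    P <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  })
  base <- max_vote(P, threshold = 0.4)
  perm <- c(3, 1, 2)
  Pp <- P[, perm]
  permuted <- max_vote(Pp, threshold = 0.4)
  expect_equal(permuted$final_label, base$final_label)
  expect_equal(permuted$confidence, base$confidence)
})

test_that("ensemble bundles round-trip through disk with identical predictions", {
  fix <- tiny_ensemble()
  tc <- corpus_subset(fix$corpus, fix$ensemble$split$test_ids)
  dir <- tempfile("bundle")
  save_ensemble(fix$ensemble, dir)
  back <- load_ensemble(dir)
  expect_equal(back$families, fix$ensemble$families)
  expect_equal(back$mask$indices, fix$ensemble$mask$indices)
  r1 <- predict_families(fix$ensemble, tc, "two_stage", 0.5)
  r2 <- predict_families(back, tc, "two_stage", 0.5)
  expect_identical(r1$confidence, r2$confidence)
  expect_identical(r1$final_label, r2$final_label)
  expect_error(suppressWarnings(load_ensemble(tempdir())))
})

test_that("family_summary counts assignments and above-threshold support", {
  fix <- tiny_ensemble()
  tc <- corpus_subset(fix$corpus, fix$ensemble$split$test_ids)
  rep <- predict_families(fix$ensemble, tc, "max_vote", 0.5)
  fs <- family_summary(rep)
  expect_equal(fs$family, fix$ensemble$families)
  expect_equal(sum(fs$n_assigned), sum(rep$final_label != "unknown"))
  expect_true(all(fs$n_above_threshold >= 0))
})

test_that("reports serialize to TSV and JSON", {
  fix <- tiny_ensemble()
  tc <- corpus_subset(fix$corpus, fix$ensemble$split$test_ids)
  rep <- predict_families(fix$ensemble, tc, "two_stage", 0.5)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_report(rep, tsv, js)
  tab <- read.delim(tsv, colClasses = "character")
  expect_equal(nrow(tab), nrow(rep))
  expect_true(all(c("id", "final_label", "confidence") %in% names(tab)))
  expect_equal(length(jsonlite::read_json(js)), nrow(rep))
})
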