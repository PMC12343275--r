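# Confusion matrices, Wilson intervals, per-class metrics, ROC/AUC.

test_that("confusion matrix counts by enumeration", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(cm, matrix(c(1L, 0L, 1L, 1L), 2,
                              dimnames = list(true = c("A", "B"),
                                              predicted = c("A", "B"))))
  # perfect predictions -> diagonal
  cmd <- confusion_matrix(c("A", "B", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(cmd[1, 2] + cmd[2, 1], 0L)
  expect_identical(sum(diag(cmd)), 3L)
  # empty input -> all zeros
  cm0 <- confusion_matrix(character(), character(), c("A", "B"))
  expect_true(all(cm0 == 0L))
  expect_error(confusion_matrix("A", "C", c("A", "B")), "C")
})

test_that("wilson_interval matches its closed form and rejects bad input", {
  expect_error(wilson_interval(1, 0), "n >= 1")
  expect_error(wilson_interval(7, 5), "0 <= k <= n")
  # k = n: lower bound is 1/(1 + z^2/n)
  z <- qnorm(0.975)
  for (n in c(5, 16, 44)) {
    ci <- wilson_interval(n, n)
    expect_equal(ci[["low"]], 1 / (1 + z^2 / n), tolerance = 1e-12)
    expect_identical(ci[["high"]], 1)
  }
  expect_printed_3dp(wilson_interval(5, 5)[["low"]], 0.566)
  expect_printed_3dp(wilson_interval(25, 27)[["low"]], 0.766)
  expect_printed_3dp(wilson_interval(5, 6)[["high"]], 0.970)
  # symmetric at p = 1/2, and wider at smaller n
  ci10 <- wilson_interval(5, 10)
  expect_equal(ci10[["low"]], 1 - ci10[["high"]], tolerance = 1e-12)
  expect_gt(diff(wilson_interval(5, 10)) , diff(wilson_interval(50, 100)))
})

test_that("wilson interval equals numeric score-test inversion", {
  set.seed(60)
  for (i in 1:50) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    expect_equal(unname(wilson_interval(k, n)), unname(wilson_numeric(k, n)),
                 tolerance = 1e-9)
  }
})

test_that("per-class metrics follow the confusion margins", {
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "A", "B", "B"),
                         c("A", "B"))
  m <- precision_recall_f1(cm)
  expect_true(all(m$precision == 1 & m$recall == 1 & m$f1 == 1))
  # P = R implies F1 = P
  cm2 <- matrix(c(41L, 2L, 2L, 55L), 2,
                dimnames = list(true = c("T", "rest"),
                                predicted = c("T", "rest")))
  m2 <- precision_recall_f1(cm2)
  expect_equal(m2$f1[1], m2$precision[1], tolerance = 1e-12)
  # a class never predicted and never present: flagged, metric 0
  cm3 <- matrix(c(3L, 0L, 0L, 0L), 2,
                dimnames = list(true = c("A", "B"), predicted = c("A", "B")))
  m3 <- precision_recall_f1(cm3)
  expect_true(m3$precision_undefined[2])
  expect_identical(m3$f1[2], 0)
})

test_that("ROC handles separation, chance, and ties like Mann-Whitney", {
  scores <- cbind(pos = c(0.9, 0.8, 0.2, 0.1), neg = c(0.1, 0.2, 0.8, 0.9))
  r <- roc_ovr(c("pos", "pos", "neg", "neg"), scores, "pos")
  expect_identical(r$auc, 1)
  # all scores identical -> chance
  flat <- cbind(pos = rep(0.5, 6), neg = rep(0.5, 6))
  r2 <- roc_ovr(rep(c("pos", "neg"), 3), flat, "pos")
  expect_equal(r2$auc, 0.5, tolerance = 1e-12)
  # positives {0.9, 0.4} vs negatives {0.8, 0.2}
  s3 <- cbind(pos = c(0.9, 0.4, 0.8, 0.2), neg = 1 - c(0.9, 0.4, 0.8, 0.2))
  r3 <- roc_ovr(c("pos", "pos", "neg", "neg"), s3, "pos")
  expect_equal(r3$auc, 0.75, tolerance = 1e-12)
  expect_equal(r3$auc, auc_pairs(c(0.9, 0.4), c(0.8, 0.2)), tolerance = 1e-12)
  # absent class flagged
  r4 <- roc_ovr(rep("neg", 4), s3, "pos")
  expect_true(r4$undefined)
  expect_true(is.na(r4$auc))
})

test_that("trapezoid AUC equals pair counting on random tied instances", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    lab <- sample(c("p", "q"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("p", "q")
    # coarse grid forces ties
    sc <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    scores <- cbind(p = sc, q = 1 - sc)
    got <- roc_ovr(lab, scores, "p")$auc
    want <- auc_pairs(sc[lab == "p"], sc[lab == "q"])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("roc_ovr agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  lab <- sample(c("p", "q"), 40, replace = TRUE)
  sc <- round(runif(40), 2)
  got <- roc_ovr(lab, cbind(p = sc, q = 1 - sc), "p")$auc
  want <- as.numeric(pROC::auc(pROC::roc(lab == "p", sc, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("evaluate_model assembles a coherent, deterministic report", {
  smps <- solid_color_samples(5L, 32L, seed = 6)
  cfg <- arch_config(input_size = c(32, 32), stem_channels = 4L,
                     stage_channels = c(4L, 8L, 8L), num_classes = 2L,
                     class_names = c("a", "b"))
  m <- build_model(cfg, seed = 1)
  m <- train_model(m, smps, config = train_config(epochs = 4L,
                                                  batch_size = 4L, seed = 2L))
  rep1 <- evaluate_model(m, smps)
  rep2 <- evaluate_model(m, smps)
  expect_identical(rep1$confusion, rep2$confusion)
  expect_identical(rep1$probs, rep2$probs)
  # accuracy = trace / total, micro recall = accuracy
  expect_equal(rep1$accuracy$point,
               sum(diag(rep1$confusion)) / sum(rep1$confusion),
               tolerance = 1e-12)
  micro_recall <- sum(diag(rep1$confusion)) / sum(rep1$confusion)
  expect_equal(rep1$accuracy$point, micro_recall, tolerance = 1e-12)
  # all-correct n = 10: CI low is the k = n closed form
  if (rep1$accuracy$point == 1) {
    z <- qnorm(0.975)
    expect_equal(rep1$accuracy$low, 1 / (1 + z^2 / 10), tolerance = 1e-12)
  }
  # report serialization writes the declared artifacts
  dir <- withr::local_tempdir()
  write_eval_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "eval_report.json")))
  expect_true(file.exists(file.path(dir, "confusion_matrix.csv")))
  expect_true(file.exists(file.path(dir, "roc_a.csv")))
  expect_true(file.exists(file.path(dir, "confusion_matrix.png")))
})
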