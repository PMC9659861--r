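# Evaluation statistics: confusion metrics, ROC/AUC, Wilson intervals,
# McNemar tests and the chi-square(1) tail.

test_that("confusion-matrix metrics match hand computations", {
  # perfect classifier
  cm <- diag(c(3L, 4L, 5L))
  m <- classification_metrics(cm)
  expect_true(all(unlist(m) == 1))

  # 2-class hand case
  cm2 <- matrix(c(8L, 2L, 3L, 7L), 2L, 2L, byrow = TRUE)
  m2 <- classification_metrics(cm2)
  expect_equal(m2$Top1Acc, 15 / 20)
  expect_equal(m2$Rec, (0.8 + 0.7) / 2)
  expect_equal(m2$Pre, (8 / 11 + 7 / 9) / 2)
  expect_equal(m2$MAcc, 0.75)   # one-vs-rest accuracy is 15/20 for both classes

  # degenerate: everything predicted as class 1 -> unpredicted class has Pre 0
  cm3 <- matrix(c(5L, 0L, 5L, 0L), 2L, 2L, byrow = TRUE)
  m3 <- classification_metrics(cm3)
  expect_equal(m3$Pre, (0.5 + 0) / 2)
  expect_error(classification_metrics(matrix(0L, 2L, 2L)), "empty")
})

test_that("AUC matches pair counting, boundaries, and the Mann-Whitney identity", {
  # 6-point hand example: 8 of 9 pairs concordant
  scores <- cbind(c(.9, .8, .4, .7, .3, .2))
  scores <- cbind(scores, 1 - scores)
  truths <- c(0L, 0L, 0L, 1L, 1L, 1L)
  expect_equal(roc_auc(scores, truths)$per_class[1L], 8 / 9)

  # perfect separation and uninformative scores
  s2 <- cbind(c(.9, .8, .2, .1), c(.1, .2, .8, .9))
  expect_equal(roc_auc(s2, c(0L, 0L, 1L, 1L))$per_class, c(1, 1))
  s3 <- matrix(0.5, 4L, 2L)
  expect_equal(roc_auc(s3, c(0L, 0L, 1L, 1L))$per_class, c(0.5, 0.5))

  # single-class truth: undefined AUC for the absent class
  expect_true(is.na(roc_auc(s2, c(0L, 0L, 0L, 0L))$per_class[2L]))

  # Mann-Whitney identity on random instances (independent wilcox oracle)
  set.seed(1)
  for (i in 1:5) {
    n <- 40L
    sc <- matrix(stats::runif(2 * n), n, 2L)
    sc <- sc / rowSums(sc)
    y <- sample(0:1, n, replace = TRUE)
    w <- stats::wilcox.test(sc[y == 0L, 1L], sc[y == 1L, 1L], exact = FALSE)
    expect_equal(roc_auc(sc, y)$per_class[1L],
                 unname(w$statistic) / (sum(y == 0L) * sum(y == 1L)))
  }
})

test_that("AUC agrees with pROC on a randomized multiclass instance", {
  skip_if_not_installed("pROC")
  set.seed(2)
  n <- 60L
  sc <- matrix(stats::rgamma(3 * n, 1), n, 3L)
  sc <- sc / rowSums(sc)
  y <- sample(0:2, n, replace = TRUE)
  ours <- roc_auc(sc, y)$per_class
  for (k in 1:3) {
    ref <- pROC::auc(pROC::roc(y == (k - 1L), sc[, k], quiet = TRUE,
                               direction = "<"))
    expect_equal(ours[k], as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("trapezoid area under the ROC points equals the midrank AUC", {
  set.seed(3)
  score <- round(stats::runif(50), 1)   # ties on purpose
  pos <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  pts <- roc_points(score, pos)
  ord <- order(pts$fpr, pts$tpr)
  auc_trap <- sum(diff(pts$fpr[ord]) *
                    (head(pts$tpr[ord], -1) + tail(pts$tpr[ord], -1)) / 2)
  expect_equal(auc_trap,
               roc_auc(cbind(score, 1 - score),
                       ifelse(pos, 0L, 1L))$per_class[1L],
               tolerance = 1e-10)
})

test_that("Wilson intervals hit the closed-form values and boundaries", {
  ci <- binom_ci(8L, 10L)
  expect_equal(unname(ci), c(0.490, 0.943), tolerance = 5e-4)
  expect_equal(unname(binom_ci(0L, 7L)[1L]), 0)
  expect_equal(unname(binom_ci(7L, 7L)[2L]), 1)
  ci2 <- binom_ci(3L, 12L)
  expect_true(ci2[["lo"]] <= 3 / 12 && 3 / 12 <= ci2[["hi"]])
  expect_error(binom_ci(5L, 0L), "n must be")
  expect_error(binom_ci(8L, 5L), "0\\.\\.n")
})

test_that("chi-square(1) tail reproduces the printed statistic-significance pairs", {
  expect_equal(chisq1_pvalue(0), 1)
  expect_equal(round(chisq1_pvalue(2.250), 5), 0.13361)
  expect_equal(round(chisq1_pvalue(0.500), 5), 0.47950)
  expect_equal(round(chisq1_pvalue(7.111), 5), 0.00766)
  # identical to the upper chi-square tail, and monotone decreasing
  s <- seq(0, 10, by = 0.25)
  expect_equal(chisq1_pvalue(s), stats::pchisq(s, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(all(diff(chisq1_pvalue(s)) < 0))
  expect_error(chisq1_pvalue(-1), "non-negative")
})

test_that("McNemar statistic uses the clamped continuity correction", {
  r <- mcnemar_test(0L, 9L)
  expect_equal(r$statistic, 64 / 9, tolerance = 1e-12)
  expect_equal(round(r$p, 5), 0.00766)

  tied <- mcnemar_test(1L, 1L)
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p, 1)

  # symmetric in (b, c)
  expect_equal(mcnemar_test(3L, 11L)$statistic, mcnemar_test(11L, 3L)$statistic)
  expect_equal(mcnemar_test(3L, 11L)$p, mcnemar_test(11L, 3L)$p)

  undef <- mcnemar_test(0L, 0L)
  expect_false(undef$defined)
  expect_true(is.na(undef$statistic))
})

test_that("evaluation reports tie the pieces together", {
  set.seed(4)
  truth <- sample(0:2, 30L, replace = TRUE)
  pred <- ifelse(stats::runif(30) < 0.7, truth, sample(0:2, 30L, replace = TRUE))
  sc <- matrix(stats::runif(90), 30L, 3L); sc <- sc / rowSums(sc)
  rep <- eval_report(truth, pred, sc, c("x", "y", "z"), reference_pred = truth)
  expect_equal(sum(rep$confusion), 30L)
  expect_equal(rep$metrics$Top1Acc, mean(truth == pred))
  expect_length(rep$per_class, 3L)
  expect_s3_class(rep$per_class[[1L]]$mcnemar, "mcnemar_result")
  d <- tempfile()
  write_eval_report(rep, d, sc, truth)
  expect_true(file.exists(file.path(d, "eval_report.json")))
  expect_true(file.exists(file.path(d, "confusion_matrix.csv")))
  expect_true(file.exists(file.path(d, "roc_class2.csv")))
  unlink(d, recursive = TRUE)
})
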