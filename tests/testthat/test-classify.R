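test_that("feature tables assemble in spec order and validate members", {
  auc <- data.frame(Eg = 1:3 / 10, Eloc = 4:6 / 10, Lp = c(1.2, 1.3, 1.4),
                    Cp = 7:9 / 10)
  roi <- data.frame(R_PFC = 1:3, L_PFC = 4:6, R_MC = 7:9, L_MC = 10:12,
                    R_OC = 13:15, L_OC = 16:18)
  x <- build_features(auc, roi, c("Eg", "Lp"))
  expect_equal(colnames(x), c("Eg", "Lp"))
  expect_equal(dim(x), c(3L, 2L))

  h <- build_features(auc, roi, c("Eg", "Lp", "L_OC"))
  expect_equal(colnames(h), c("Eg", "Lp", "L_OC"))

  expect_error(build_features(auc, roi, c("Eg", "Eg")), "duplicate")
  expect_error(build_features(auc, roi, c("Eg", "nope")), "not available")
  auc$Eg[2] <- NA
  expect_error(build_features(auc, roi, c("Eg", "Lp")),
               "subject 2.*'Eg'")

  sets <- default_feature_sets()
  expect_length(sets, 6L)
  expect_equal(sets$hybrid_sig, c("Eg", "Lp", "L_OC"))
  expect_equal(sets$gt_sig, c("Eg", "Lp"))
})

test_that("KNN prediction matches the exhaustive neighbor oracle", {
  # coincident neighbors
  tr <- matrix(c(0, 0, 0, 0, 0, 0), 3, 2)
  expect_equal(knn_predict(tr, c("A", "A", "A"), c(0, 0)), "A")

  # well-separated 1-D clusters
  tr1 <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), 6, 1)
  lab1 <- rep(c("A", "B"), each = 3)
  expect_equal(knn_predict(tr1, lab1, 0.05), "A")
  expect_equal(knn_predict(tr1, lab1, 9.9), "B")

  # 10-point 2-D fixture vs brute force
  set.seed(71)
  tr2 <- matrix(rnorm(20), 10, 2)
  lab2 <- sample(c("A", "B"), 10, replace = TRUE, prob = c(0.6, 0.4))
  for (i in 1:15) {
    z <- rnorm(2)
    expect_equal(knn_predict(tr2, lab2, z, k = 3), bf_knn(tr2, lab2, z, 3))
  }

  # distance tie -> lower training index
  tr3 <- matrix(c(1, -1), 2, 1)
  expect_equal(knn_predict(tr3, c("A", "B"), 0, k = 1), "A")
  expect_error(knn_predict(tr3[0, , drop = FALSE], character(0), 0), "empty")
})

test_that("LDA matches the closed-form discriminant and MASS::lda", {
  # equal-variance 1-D classes, midpoint rule
  set.seed(72)
  x <- matrix(c(rnorm(20, 0), rnorm(20, 10)), ncol = 1)
  lab <- rep(c("lo", "hi"), each = 20)
  expect_equal(lda_fit_predict(x, lab, 4.9), "lo")
  expect_equal(lda_fit_predict(x, lab, 5.1), "hi")

  # well-separated 2-D clusters: zero training errors
  x2 <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  lab2 <- rep(c("A", "B"), each = 20)
  expect_equal(lda_fit_predict(x2, lab2, x2), lab2)

  skip_if_not_installed("MASS")
  set.seed(73)
  x3 <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 1.5), 15, 2))
  lab3 <- rep(c("A", "B"), each = 15)
  test3 <- matrix(rnorm(40, 0.8), 20, 2)
  ref <- as.character(predict(MASS::lda(x3, grouping = lab3), test3)$class)
  expect_equal(lda_fit_predict(x3, lab3, test3), ref)

  # singular covariance: duplicated column needs the ridge fallback
  x4 <- cbind(x3[, 1], x3[, 1])
  expect_error(lda_fit_predict(x4, lab3, c(0, 0), ridge = 0), "singular")
  expect_equal(lda_fit_predict(x4, lab3, c(0, 0)), "A")
})

test_that("confusion metrics reproduce the arithmetic of an 8/10 split", {
  m <- confusion_metrics(tp = 6, fn = 2, tn = 10, fp = 0)
  expect_equal(m$accuracy, 16 / 18)
  expect_equal(round(m$accuracy, 2), 0.89)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 1)

  m2 <- confusion_metrics(tp = 7, fn = 1, tn = 8, fp = 2)
  expect_equal(m2$accuracy, 15 / 18)
  expect_equal(round(m2$accuracy, 2), 0.83)
  expect_equal(round(m2$sensitivity, 2), 0.88)
  expect_equal(m2$specificity, 0.80)

  expect_equal(confusion_metrics(5, 0, 5, 0)$accuracy, 1)
  expect_true(is.na(confusion_metrics(0, 0, 5, 1)$sensitivity))
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("LOOCV is deterministic, leak-free and perfect on separated data", {
  set.seed(74)
  x <- rbind(matrix(rnorm(16, 0), 8, 2), matrix(rnorm(20, 8), 10, 2))
  lab <- rep(c("MCS", "UWS"), c(8, 10))
  for (clf in c("knn", "lda")) {
    res <- loocv(x, lab, classifier = clf, n_repeats = 20)
    expect_equal(res$accuracy, 1)
    expect_equal(res$sensitivity, 1)
    expect_equal(res$specificity, 1)
    # all repeats identical under deterministic tie rules
    expect_equal(var(res$per_repeat$accuracy), 0)
  }

  # leakage probe: the held-out subject's own label must not matter
  res1 <- loocv(x, lab, "knn", n_repeats = 1)
  lab_flip <- lab; lab_flip[1] <- "UWS"
  res2 <- loocv(x, lab_flip, "knn", n_repeats = 1)
  expect_equal(res1$predictions[1], res2$predictions[1])

  expect_error(loocv(x[1:3, ], c("MCS", "MCS", "UWS"), "knn"),
               ">= 2 subjects")
})

test_that("classification table covers every feature set and classifier", {
  set.seed(75)
  n <- 18
  auc <- data.frame(Eg = rnorm(n), Eloc = rnorm(n), Lp = rnorm(n),
                    Cp = rnorm(n))
  roi <- data.frame(R_PFC = rnorm(n), L_PFC = rnorm(n), R_MC = rnorm(n),
                    L_MC = rnorm(n), R_OC = rnorm(n), L_OC = rnorm(n))
  lab <- rep(c("MCS", "UWS"), c(8, 10))
  tab <- classification_table(auc, roi, lab, n_repeats = 2)
  expect_equal(nrow(tab), 12L)
  expect_equal(sort(unique(tab$classifier)), c("knn", "lda"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
})
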