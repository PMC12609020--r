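test_that("confusion-matrix metrics match hand arithmetic", {
  m <- metrics_from_confusion(tp = 9, fn = 1, tn = 8, fp = 2)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$recall, m$sensitivity)
  expect_equal(m$f1, 2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9))
  perfect <- metrics_from_confusion(10, 0, 10, 0)
  expect_true(all(unlist(perfect) == 1))
  deg <- metrics_from_confusion(0, 5, 10, 0)
  expect_true(is.nan(deg$precision))
  expect_error(metrics_from_confusion(-1, 0, 0, 1), "Negative")
})

test_that("trapezoidal AUC equals the pairwise concordance oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c("HC", "HC", "OA", "OA"))$auc, 1)
  set.seed(11)
  for (r in 1:50) {
    n <- sample(10:60, 1)
    labels <- sample(c("HC", "OA"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties sometimes
    got <- roc_auc(scores, labels, positive = "OA")$auc
    want <- auc_concordance(scores, labels, "OA")
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c("OA", "OA", "OA")), "Both classes")
})

test_that("AUC agrees with pROC on a random instance", {
  set.seed(12)
  y <- sample(c("HC", "OA"), 80, replace = TRUE)
  s <- rnorm(80) + (y == "OA")
  got <- roc_auc(s, y, positive = "OA")$auc
  want <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                         levels = c("HC", "OA"),
                                         direction = "<", quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("NCA concentrates weight on a planted informative feature", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    y <- rep(c(0, 1), each = 30)
    X <- matrix(rnorm(60 * 6), 60, 6)
    X[, 3] <- y + rnorm(60, sd = 0.3)
    w <- nca_weights(X, y, seed = s)
    expect_equal(sum(w$weights), 1, tolerance = 1e-9)
    if (which.max(w$weights) == 3 && w$weights[3] > 0.5) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("NCA spreads weight on pure noise and ranks duplicated signal highly", {
  set.seed(13)
  maxw <- replicate(10, {
    X <- matrix(rnorm(60 * 6), 60, 6)
    y <- rep(c(0, 1), each = 30)
    max(nca_weights(X, y)$weights)
  })
  expect_gte(mean(maxw < 0.3), 0.9)
  ok <- replicate(5, {
    X <- matrix(rnorm(60 * 6), 60, 6)
    y <- rep(c(0, 1), each = 30)
    X[, 2] <- y + rnorm(60, sd = 0.3)
    X[, 4] <- y + rnorm(60, sd = 0.3)
    w <- nca_weights(X, y)$weights
    (w[2] + w[4]) > max(w[-c(2, 4)])
  })
  expect_true(all(ok))
})

test_that("weight selection applies the cutoff with a top-3 fallback", {
  fake <- structure(list(weights = c(0.5, 0.3, 0.1, 0.04, 0.03, 0.03)),
                    class = "vag_nca")
  expect_equal(select_by_weight(fake), c(1L, 2L, 3L))
  uni <- structure(list(weights = rep(1 / 12, 12)), class = "vag_nca")
  expect_equal(select_by_weight(uni), 1:12)  # 0.083 sits above the cutoff
  tiny <- structure(list(weights = c(0.04, 0.03, rep(0.93 / 30, 30))),
                    class = "vag_nca")
  expect_warning(sel <- select_by_weight(tiny, threshold = 0.05), "top 3")
  expect_equal(length(sel), 3)
})

test_that("the RBF-SVM CV separates blobs, is deterministic, and chances on noise", {
  set.seed(14)
  X <- rbind(matrix(rnorm(60 * 5), 60, 5), matrix(rnorm(60 * 5, mean = 2), 60, 5))
  y <- rep(c("HC", "OA"), each = 60)
  r <- svm_rbf_cv(X, y, seed = 1)
  expect_gte(r$summary$mean[r$summary$metric == "accuracy"], 0.95)
  expect_equal(r$folds$recall, r$folds$sensitivity)
  f1_check <- 2 * r$folds$precision * r$folds$recall /
    (r$folds$precision + r$folds$recall)
  expect_equal(r$folds$f1, f1_check)
  expect_equal(rowSums(r$confusion[, c("tp", "fn", "tn", "fp")]),
               as.numeric(table(vagdfa:::stratified_folds(y, 5, 1))))
  r2 <- svm_rbf_cv(X, y, seed = 1)
  expect_identical(r$folds, r2$folds)
  expect_error(svm_rbf_cv(X[1:8, ], y[c(1:4, 61:64)], k = 5), "fewer than k")
})

test_that("cv report tidiers and ROC plot work", {
  set.seed(15)
  X <- rbind(matrix(rnorm(40 * 3), 40, 3), matrix(rnorm(40 * 3, 2), 40, 3))
  y <- rep(c("HC", "OA"), each = 40)
  r <- svm_rbf_cv(X, y, seed = 2)
  expect_equal(nrow(tidy(r)), 5)
  gl <- glance(r)
  expect_true("accuracy_mean" %in% names(gl))
  expect_s3_class(autoplot(r), "ggplot")
})
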