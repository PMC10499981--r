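test_that("stratified split preserves class proportions exactly", {
  y <- rep(c("a", "b"), each = 5)
  sp <- split_train_test(y, 0.8, seed = 3)
  expect_equal(sum(y[sp$train] == "a"), 4)
  expect_equal(sum(y[sp$train] == "b"), 4)
  expect_equal(length(sp$test), 2)
  expect_setequal(c(sp$train, sp$test), 1:10)

  expect_identical(split_train_test(y, 0.8, seed = 3),
                   split_train_test(y, 0.8, seed = 3))
  expect_error(split_train_test(c("a", "a", "b"), 0.8), ">= 2 samples")

  # audit: across many random splits the train class proportion never
  # deviates from the global proportion by more than one sample
  y2 <- rep(c("a", "b"), times = c(13, 7))
  for (s in 1:200) {
    sp2 <- split_train_test(y2, 0.8, seed = s)
    n_a <- sum(y2[sp2$train] == "a")
    expect_lte(abs(n_a - 0.8 * 13), 1)
    expect_lte(abs(length(sp2$train) - n_a - 0.8 * 7), 1)
  }
})

test_that("the regularized logistic fit solves its stated objective", {
  # separable 1-D case classifies its training points
  X <- matrix(c(-2, -1, 1, 2), 4, 1, dimnames = list(NULL, "f"))
  y <- factor(c("n", "n", "p", "p"), levels = c("n", "p"))
  m <- fit_margin_logistic(X, y, lambda = 0.1)
  pr <- predict(m, X)
  expect_equal(as.numeric(pr > 0.5), c(0, 0, 1, 1))

  # duplicating every sample leaves the model unchanged (loss is a mean)
  m2 <- fit_margin_logistic(rbind(X, X), factor(rep(y, 2), levels = c("n", "p")),
                            lambda = 0.1)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-7)
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-7)

  # affine rescaling of a feature is absorbed by the training z-scaling
  d <- make_logistic_data(40, 3, seed = 8)
  ma <- fit_margin_logistic(d$X, d$y)
  Xs <- d$X; Xs[, 2] <- Xs[, 2] * 37 + 5
  mb <- fit_margin_logistic(Xs, d$y)
  expect_equal(predict(mb, Xs), predict(ma, d$X), tolerance = 1e-7)

  # monotone margin: moving a feature along the sign of its weight raises
  # the positive-class probability
  j <- which.max(abs(ma$coefficients))
  x0 <- d$X[1, , drop = FALSE]
  x1 <- x0; x1[, j] <- x1[, j] + sign(ma$coefficients[j])
  expect_gt(predict(ma, x1), predict(ma, x0))

  expect_error(fit_margin_logistic(matrix(c(1, NA), 2, 1), factor(c("a", "b"))),
               "non-finite")
  expect_error(fit_margin_logistic(matrix(1:4, 4, 1), factor(rep("a", 4))),
               "two classes")
})

test_that("coefficients match an independent BFGS oracle", {
  for (s in 1:20) {
    d <- make_logistic_data(n = 25 + s, p = sample(2:4, 1), seed = s)
    m <- fit_margin_logistic(d$X, d$y, lambda = 1.0)
    theta <- oracle_logistic_theta(d$X, d$y01, lambda = 1.0)
    expect_equal(unname(c(m$intercept, m$coefficients)), theta,
                 tolerance = 1e-6)
  }
})

test_that("cross-validation is stratified, leak-free, and calibrated", {
  # separable data: CV accuracy 1
  set.seed(19)
  n <- 100
  X <- matrix(c(rnorm(n / 2, -3), rnorm(n / 2, 3), rnorm(n)), n, 2,
              dimnames = list(paste0("s", 1:n), c("f1", "f2")))
  y <- factor(rep(c("a", "b"), each = n / 2), levels = c("a", "b"))
  cv <- cross_validate(X, y, k = 10, seed = 4)
  expect_equal(cv$accuracy, 1)

  # permuted labels: accuracy near chance
  yp <- withr_perm <- y[sample(n)]
  cvp <- cross_validate(X, yp, k = 10, seed = 5)
  expect_gte(cvp$accuracy, 0.35)
  expect_lte(cvp$accuracy, 0.65)

  # leakage audit: each fold's predictions must equal a direct fit on the
  # training folds alone (scaling included)
  cv2 <- cross_validate(X, y, k = 5, seed = 6)
  fold <- cv2$fold
  for (fd in 1:5) {
    m_f <- fit_margin_logistic(X[fold != fd, ], y[fold != fd])
    pr_direct <- predict(m_f, X[fold == fd, , drop = FALSE])
    pred_pooled <- as.numeric(pr_direct > 0.5)
    truth <- as.numeric(y[fold == fd] == "b")
    expect_equal(mean(pred_pooled == truth), cv2$fold_accuracy[fd])
  }

  expect_error(cross_validate(X, y, k = 1), ">= 2")
  expect_warning(cross_validate(X[1:12, ], y[c(1:6, 51:56)], k = 10),
                 "k reduced")
})

test_that("evaluation metrics and Mann-Whitney AUC are correct", {
  d <- make_logistic_data(60, 2, seed = 33)
  m <- fit_margin_logistic(d$X, d$y)
  ev <- evaluate_classifier(m, d$X, d$y)
  expect_equal(ev$accuracy, (ev$confusion["TP"] + ev$confusion["TN"]) / 60,
               ignore_attr = TRUE)
  expect_equal(ev$sensitivity,
               unname(ev$confusion["TP"] /
                        (ev$confusion["TP"] + ev$confusion["FN"])))

  # AUC equals U / (n1 n2) from the rank-sum statistic
  set.seed(44)
  for (i in 1:100) {
    sc <- rnorm(40); lb <- rbinom(40, 1, 0.5)
    if (length(unique(lb)) < 2) next
    u <- unname(wilcox.test(sc[lb == 1], sc[lb == 0])$statistic)
    expect_equal(ucbranch:::.auc_mw(sc, lb), u / (sum(lb) * sum(1 - lb)),
                 tolerance = 1e-12)
  }

  # independent scores give AUC near 0.5 at large n
  set.seed(45)
  sc <- rnorm(2000); lb <- rbinom(2000, 1, 0.5)
  auc <- ucbranch:::.auc_mw(sc, lb)
  expect_gte(auc, 0.45); expect_lte(auc, 0.55)

  # perfect scores give all-1 metrics
  lb2 <- rep(c(0, 1), 20)
  ev2 <- ucbranch:::.eval_metrics(lb2, lb2)
  expect_equal(c(ev2$sensitivity, ev2$specificity, ev2$accuracy, ev2$auc),
               rep(1, 4))
})

test_that("origin assignment applies the documented tie rule and errors", {
  m <- structure(list(features = "f", center = c(f = 0), scale = c(f = 1),
                      intercept = 0, coefficients = c(f = 0), lambda = 1,
                      levels = c("PUC", "CIS")),
                 class = "classifier_model")
  X <- matrix(c(-1, 0, 1), 3, 1,
              dimnames = list(paste0("inv", 1:3), "f"))
  oc <- assign_origin(m, X)
  expect_equal(oc$label, rep("PUC-derived", 3))  # prob exactly 0.5
  expect_true(all(oc$tie))

  m$coefficients <- c(f = 3)
  oc2 <- assign_origin(m, X)
  expect_equal(oc2$label, c("PUC-derived", "PUC-derived", "CIS-derived"))
  expect_false(any(oc2$tie[c(1, 3)]))

  expect_error(assign_origin(m, matrix(1, 1, 1, dimnames = list("s", "g"))),
               "missing panel features: f")
})
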