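# The tumor-origin classifier: stratified splitting, L2-regularized logistic
# regression fitted by Newton-Raphson (the large-margin logistic objective),
# stratified cross-validation without scaling leakage, confusion-matrix
# metrics with Mann-Whitney AUC, and assignment of invasive samples to
# PUC-derived vs CIS-derived.

#' Stratified train/test split
#'
#' Randomly partitions samples into train and test sets preserving class
#' proportions: per class, the train count is `round(train_fraction * n)`,
#' clamped so both sides keep at least one sample.
#'
#' @param labels class label per sample (each class needs >= 2 samples).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(labels, train_fraction = 0.8, seed = 1L) {
  labels <- as.factor(as.character(labels))
  if (any(table(labels) < 2L)) stop("every class needs >= 2 samples")
  idx <- withr_seed(seed, {
    unlist(lapply(levels(labels), function(cl) {
      i <- which(labels == cl)
      n_tr <- min(length(i) - 1L, max(1L, round(train_fraction * length(i))))
      sample(i, n_tr)
    }))
  })
  train <- sort(idx)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# objective pieces of the regularized logistic model; y01 in {0,1},
# Xb includes the intercept column; ridge excludes the intercept
.logistic_obj <- function(theta, X1, y01, lambda) {
  eta <- drop(X1 %*% theta)
  # numerically stable log(1 + exp(-yt * eta))
  yt <- 2 * y01 - 1
  m <- -yt * eta
  loss <- mean(ifelse(m > 30, m, log1p(exp(m))))
  loss + lambda / 2 * sum(theta[-1]^2)
}

.logistic_grad <- function(theta, X1, y01, lambda) {
  eta <- drop(X1 %*% theta)
  p <- plogis(eta)
  g <- drop(crossprod(X1, p - y01)) / nrow(X1)
  g[-1] <- g[-1] + lambda * theta[-1]
  g
}

#' Fit the regularized logistic origin classifier
#'
#' Minimizes mean logistic loss plus `(lambda/2) * ||beta||^2` (intercept
#' unpenalized) by Newton-Raphson to a gradient max-norm below 1e-8. Features
#' are z-scaled with training statistics stored in the model, so predictions
#' are invariant to affine rescaling of the inputs.
#'
#' @param X numeric matrix samples x features (finite values, named columns).
#' @param y two-level factor (or coercible); the fitted probability refers to
#'   the second level (the "positive" class).
#' @param lambda ridge strength on the mean-loss scale. The default `NULL`
#'   uses `1/n` training samples, which reproduces the C = 1 convention of
#'   large-margin solvers (fixed `||w||^2/2` penalty against a summed loss);
#'   a fixed numeric value is honored as given.
#' @return object of class `classifier_model`: `features`, `center`, `scale`,
#'   `intercept`, `coefficients` (on the scaled space), `lambda`, `levels`.
#' @export
fit_margin_logistic <- function(X, y, lambda = NULL) {
  X <- as.matrix(X)
  if (is.null(lambda)) lambda <- 1 / nrow(X)
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes")
  if (any(table(y) < 2L)) stop("each class needs >= 2 samples")
  y01 <- as.numeric(y == levels(y)[2L])
  center <- colMeans(X)
  # population SD, so duplicating the sample set leaves the model unchanged
  scl <- sqrt(colMeans(sweep(X, 2L, center)^2))
  scl[scl == 0] <- 1
  Z <- scale(X, center = center, scale = scl)
  X1 <- cbind(1, Z)
  p_ <- ncol(X1)
  theta <- numeric(p_)
  for (it in seq_len(200L)) {
    g <- .logistic_grad(theta, X1, y01, lambda)
    if (max(abs(g)) < 1e-8) break
    pr <- plogis(drop(X1 %*% theta))
    w <- pmax(pr * (1 - pr), 1e-10)
    H <- crossprod(X1 * w, X1) / nrow(X1)
    diag(H)[-1] <- diag(H)[-1] + lambda
    step <- solve(H, g)
    # halving safeguards the Newton step far from the optimum
    f0 <- .logistic_obj(theta, X1, y01, lambda)
    alpha <- 1
    repeat {
      theta_new <- theta - alpha * step
      if (.logistic_obj(theta_new, X1, y01, lambda) <= f0 + 1e-12 ||
          alpha < 1e-6) break
      alpha <- alpha / 2
    }
    theta <- theta_new
  }
  structure(list(features = colnames(X), center = center, scale = scl,
                 intercept = theta[1L],
                 coefficients = setNames(theta[-1L], colnames(X)),
                 lambda = lambda, levels = levels(y)),
            class = "classifier_model")
}

#' Predict class probabilities from a classifier model
#' @param object a `classifier_model`.
#' @param X samples x features matrix containing the model's features.
#' @param ... unused.
#' @return probability of the positive (second-level) class per sample.
#' @export
predict.classifier_model <- function(object, X, ...) {
  X <- as.matrix(X)
  missing_f <- setdiff(object$features, colnames(X))
  if (length(missing_f))
    stop("missing panel features: ", paste(missing_f, collapse = ", "))
  Z <- scale(X[, object$features, drop = FALSE],
             center = object$center, scale = object$scale)
  plogis(object$intercept + drop(Z %*% object$coefficients))
}

# Mann-Whitney AUC: probability a positive outranks a negative, ties 0.5
.auc_mw <- function(scores, y01) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# confusion-matrix metrics at probability threshold 0.5; positive class is
# the model's second level
.eval_metrics <- function(prob, y01) {
  pred <- as.numeric(prob > 0.5)  # prob exactly 0.5 -> negative class
  tp <- sum(pred == 1 & y01 == 1); fp <- sum(pred == 1 & y01 == 0)
  tn <- sum(pred == 0 & y01 == 0); fn <- sum(pred == 0 & y01 == 1)
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(y01),
       auc = .auc_mw(prob, y01))
}

#' Evaluate a classifier model
#'
#' Confusion matrix at the 0.5 probability threshold plus sensitivity,
#' specificity, accuracy, and Mann-Whitney AUC (ties counted 0.5). The
#' positive class is the model's second level. With a single-class truth the
#' AUC is reported missing.
#'
#' @param model a `classifier_model`.
#' @param X samples x features matrix.
#' @param y true labels.
#' @return list of class `eval_report`.
#' @export
evaluate_classifier <- function(model, X, y) {
  y <- factor(as.character(y), levels = model$levels)
  if (any(is.na(y))) stop("labels outside the model's classes")
  prob <- predict(model, X)
  structure(.eval_metrics(prob, as.numeric(y == model$levels[2L])),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: acc %.3f, sens %.3f, spec %.3f, AUC %s\n",
              x$accuracy, x$sensitivity, x$specificity,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Stratified folds; within each fold, the model (including its feature
#' scaling constants) is fitted on the training folds only, so no test-fold
#' information leaks into the scaling. Metrics are pooled over the
#' out-of-fold predictions.
#'
#' @param X samples x features matrix.
#' @param y two-level labels.
#' @param k number of folds (default 10); reduced with a warning when the
#'   smaller class has fewer than `k` samples.
#' @param lambda ridge strength passed to [fit_margin_logistic()] (default
#'   NULL: 1/n of each training fold).
#' @param seed integer seed for fold assignment.
#' @return `eval_report` with additional `fold_accuracy` and `k`.
#' @export
cross_validate <- function(X, y, k = 10L, lambda = NULL, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes")
  min_class <- min(table(y))
  if (min_class < k) {
    k <- as.integer(min_class)
    warning("k reduced to ", k, " (smallest class size)")
    if (k < 2L) stop("smallest class too small for cross-validation")
  }
  fold <- integer(length(y))
  fold[] <- withr_seed(seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      f[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    f
  })
  prob <- numeric(length(y))
  acc <- numeric(k)
  for (fd in seq_len(k)) {
    tr <- fold != fd
    model <- fit_margin_logistic(X[tr, , drop = FALSE], y[tr], lambda)
    prob[!tr] <- predict(model, X[!tr, , drop = FALSE])
    y01_f <- as.numeric(y[!tr] == levels(y)[2L])
    acc[fd] <- mean(as.numeric(prob[!tr] > 0.5) == y01_f)
  }
  rep_ <- .eval_metrics(prob, as.numeric(y == levels(y)[2L]))
  rep_$fold_accuracy <- acc
  rep_$k <- k
  rep_$fold <- fold
  structure(rep_, class = "eval_report")
}

#' Assign invasive samples to an origin branch
#'
#' Applies a PUC-vs-CIS classifier to invasive samples. The model's first
#' level is the papillary (PUC) class and the second the CIS class; samples
#' with CIS-class probability above 0.5 are called CIS-derived, otherwise
#' PUC-derived (a probability of exactly 0.5 falls to PUC-derived and is
#' flagged).
#'
#' @param model a `classifier_model` trained on PUC vs CIS samples.
#' @param X invasive samples x features matrix (must contain the panel
#'   features; absent features are an error naming them).
#' @return data.frame sample/label/prob_cis/tie.
#' @export
assign_origin <- function(model, X) {
  prob_cis <- predict(model, X)
  data.frame(sample = rownames(X),
             label = ifelse(prob_cis > 0.5, "CIS-derived", "PUC-derived"),
             prob_cis = prob_cis,
             tie = prob_cis == 0.5,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize a classifier model to JSON
#' @param model a `classifier_model`.
#' @param path output path.
#' @export
write_classifier_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
}

#' Read a classifier model from JSON
#' @param path input path.
#' @return a `classifier_model`.
#' @export
read_classifier_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$center <- unlist(m$center); m$scale <- unlist(m$scale)
  m$coefficients <- unlist(m$coefficients)
  structure(m, class = "classifier_model")
}
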