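# Classifier back-ends. Five diverse learners are supported, all with their
# library defaults: linear soft-margin SVM (e1071, C = 1; features
# standardized with training mean/sd), 1-NN and 3-NN with the Euclidean
# metric (class::knn, raw features), Gaussian naive Bayes (e1071, raw
# features) and a pruned CART decision tree (rpart defaults).

LEARNERS <- c("svm", "1nn", "3nn", "nb", "dt")

# Fit on a samples x features matrix and an 0/1 label vector. Returns a
# closure-free list so fits can be compared for equality in leakage tests.
fit_learner <- function(x, y, learner = LEARNERS) {
  learner <- match.arg(learner)
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("at least one feature required")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required in training labels")
  fit <- switch(learner,
    svm = {
      mu <- colMeans(x)
      sdv <- apply(x, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
      list(model = e1071::svm(xs, factor(y, levels = 0:1), kernel = "linear",
                              cost = 1, scale = FALSE),
           mu = mu, sd = sdv)
    },
    `1nn` = ,
    `3nn` = list(train = x, cl = factor(y, levels = 0:1)),
    nb = list(model = e1071::naiveBayes(x, factor(y, levels = 0:1))),
    dt = {
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(x)))
      df$.y <- factor(y, levels = 0:1)
      list(model = rpart::rpart(.y ~ ., data = df, method = "class"),
           vars = names(df)[-ncol(df)])
    })
  structure(list(learner = learner, fit = fit, n_features = ncol(x)),
            class = "setlevel_learner")
}

# Predict 0/1 labels for a samples x features matrix.
predict_learner <- function(object, newx) {
  stopifnot(inherits(object, "setlevel_learner"))
  newx <- as.matrix(newx)
  if (ncol(newx) != object$n_features)
    stop("feature-dimension mismatch between train and test")
  f <- object$fit
  out <- switch(object$learner,
    svm = {
      xs <- sweep(sweep(newx, 2L, f$mu), 2L, f$sd, "/")
      stats::predict(f$model, xs)
    },
    `1nn` = class::knn(f$train, newx, f$cl, k = 1L),
    `3nn` = class::knn(f$train, newx, f$cl, k = min(3L, nrow(f$train))),
    nb = stats::predict(f$model, newx),
    dt = {
      df <- as.data.frame(newx)
      names(df) <- f$vars
      stats::predict(f$model, df, type = "class")
    })
  as.integer(as.character(out))
}

#' Train a classifier and score it on a test fold
#'
#' Fits one of the five supported learners on the training feature matrix and
#' returns the proportion of test samples classified correctly. The SVM
#' back-end standardizes features with training-fold means and standard
#' deviations (applied unchanged to the test features); k-NN and naive Bayes
#' consume raw feature values.
#'
#' @param train_features,test_features samples-by-features numeric matrices
#'   with matching feature dimension.
#' @param train_labels,test_labels 0/1 label vectors; both classes must be
#'   present in training.
#' @param learner one of \code{"svm"}, \code{"1nn"}, \code{"3nn"},
#'   \code{"nb"}, \code{"dt"}.
#' @return Accuracy in [0, 1].
#' @export
learn_and_score <- function(train_features, train_labels,
                            test_features, test_labels, learner = LEARNERS) {
  fit <- fit_learner(train_features, train_labels, learner)
  pred <- predict_learner(fit, test_features)
  mean(pred == as.integer(test_labels))
}
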