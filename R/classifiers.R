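#' @keywords internal
"%||%" <- function(a, b) if (is.null(a)) b else a

#' The six supported classifier families
#' @export
CLASSIFIER_FAMILIES <- c("SVM", "1NN", "3NN", "5NN", "DecisionTree",
                         "NeuralNet")

#' Specify a classifier
#'
#' A lightweight spec naming one of the six supported families plus any
#' hyperparameter overrides and a seed. Defaults follow the underlying
#' packages: SVM is `e1071::svm` with RBF kernel, cost 1,
#' gamma = 1/n_features and its default feature scaling; k-nearest-neighbour
#' is `class::knn` on unscaled Euclidean distance (k = 1, 3 or 5); the
#' decision tree is `rpart::rpart` with its defaults; the neural net is
#' `nnet::nnet` with a 5-unit hidden layer, no weight decay, 100 iterations.
#' All fits run under the spec's seed so stochastic families are
#' reproducible.
#'
#' @param family one of `"SVM"`, `"1NN"`, `"3NN"`, `"5NN"`,
#'   `"DecisionTree"`, `"NeuralNet"`.
#' @param ... hyperparameter overrides (`cost`, `gamma`, `kernel`, `scale`
#'   for SVM; `size`, `decay`, `maxit` for NeuralNet; `cp`, `minsplit` for
#'   DecisionTree; `scale_features` for kNN).
#' @param seed integer RNG seed recorded in the spec.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(family, ..., seed = 1L) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  structure(list(family = family, hyperparameters = list(...),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' All six classifier specs with shared seed
#' @param seed integer seed applied to every spec.
#' @return named list of `classifier_spec`.
#' @export
default_classifier_set <- function(seed = 1L) {
  stats::setNames(lapply(CLASSIFIER_FAMILIES, classifier_spec, seed = seed),
                  CLASSIFIER_FAMILIES)
}

knn_k <- function(family) c("1NN" = 1L, "3NN" = 3L, "5NN" = 5L)[[family]]

is_knn <- function(family) family %in% c("1NN", "3NN", "5NN")

#' Fit on training data and predict hard labels for test data
#'
#' The uniform adapter over the six families. Training data must contain
#' both classes; predictions are hard 0/1 labels, deterministic given the
#' spec's seed (the fit runs inside `withr::with_seed` so the caller's RNG
#' stream is untouched).
#'
#' @param spec a [classifier_spec()].
#' @param train_X numeric matrix, samples x features.
#' @param train_y binary 0/1 labels, one per training row.
#' @param test_X numeric matrix with the same feature count.
#' @return integer vector of 0/1 predictions, one per test row.
#' @export
fit_predict <- function(spec, train_X, train_y, test_X) {
  stopifnot(inherits(spec, "classifier_spec"))
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  if (ncol(train_X) != ncol(test_X))
    stop("train and test feature counts differ")
  train_y <- as.integer(train_y)
  if (length(unique(train_y)) < 2L)
    stop("single-class training set")
  hp <- spec$hyperparameters
  colnames(train_X) <- colnames(test_X) <- paste0("f", seq_len(ncol(train_X)))
  yf <- factor(train_y, levels = c(0L, 1L))
  pred <- withr::with_seed(spec$seed, switch(
    spec$family,
    SVM = {
      fit <- suppressWarnings(e1071::svm(
        x = train_X, y = yf,
        kernel = hp$kernel %||% "radial",
        cost = hp$cost %||% 1,
        gamma = hp$gamma %||% (1 / ncol(train_X)),
        scale = hp$scale %||% TRUE))
      predict(fit, test_X)
    },
    "1NN" = ,
    "3NN" = ,
    "5NN" = {
      if (isTRUE(hp$scale_features)) {
        mu <- colMeans(train_X)
        sg <- apply(train_X, 2L, stats::sd)
        sg[sg == 0] <- 1
        train_X <- sweep(sweep(train_X, 2L, mu), 2L, sg, "/")
        test_X <- sweep(sweep(test_X, 2L, mu), 2L, sg, "/")
      }
      class::knn(train_X, test_X, yf, k = knn_k(spec$family))
    },
    DecisionTree = {
      df <- data.frame(.y = yf, train_X, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            cp = hp$cp %||% 0.01,
                            minsplit = hp$minsplit %||% 20L))
      predict(fit, newdata = data.frame(test_X, check.names = FALSE),
              type = "class")
    },
    NeuralNet = {
      df <- data.frame(.y = yf, train_X, check.names = FALSE)
      fit <- nnet::nnet(.y ~ ., data = df,
                        size = hp$size %||% 5L,
                        decay = hp$decay %||% 0,
                        maxit = hp$maxit %||% 100L,
                        trace = FALSE)
      cls <- predict(fit, newdata = data.frame(test_X, check.names = FALSE),
                     type = "class")
      factor(cls, levels = c("0", "1"))
    }))
  as.integer(as.character(pred))
}
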