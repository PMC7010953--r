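#' Construct a confusion matrix
#'
#' Holds the four counts from which sensitivity, specificity, accuracy and
#' the Matthews correlation coefficient are derived.
#'
#' @param TP,FN,FP,TN non-negative integer counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("confusion matrix counts must be non-negative integers")
  counts <- stats::setNames(as.integer(round(counts)),
                            c("TP", "FN", "FP", "TN"))
  structure(as.list(counts), class = "confusion_matrix")
}

#' Tally predictions against truth into a confusion matrix
#'
#' @param truth,pred binary 0/1 vectors of equal length (1 = positive class).
#' @return a [confusion_matrix()].
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  confusion_matrix(TP = sum(truth == 1L & pred == 1L),
                   FN = sum(truth == 1L & pred == 0L),
                   FP = sum(truth == 0L & pred == 1L),
                   TN = sum(truth == 0L & pred == 0L))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, 2L, byrow = TRUE,
              dimnames = list(c("actual +", "actual -"),
                              c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' Performance metrics from a confusion matrix
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/(TP+TN+FP+FN)` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any
#' factor of the MCC denominator is zero (a degenerate predictor or class),
#' MCC is defined to be 0, the standard convention. Requires at least one
#' actual positive and one actual negative.
#'
#' @param c a [confusion_matrix()].
#' @return object of class `metric_set` with fields `Sn`, `Sp`, `ACC`,
#'   `MCC` and `source` (the input matrix). Values carry full precision;
#'   printing rounds to 3 decimals.
#' @export
metrics <- function(c) {
  stopifnot(inherits(c, "confusion_matrix"))
  TP <- as.numeric(c$TP); FN <- as.numeric(c$FN)
  FP <- as.numeric(c$FP); TN <- as.numeric(c$TN)
  if (TP + FN + FP + TN == 0) stop("all-zero confusion matrix")
  if (TP + FN < 1 || TN + FP < 1)
    stop("need at least one actual positive and one actual negative")
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  structure(list(Sn = TP / (TP + FN),
                 Sp = TN / (TN + FP),
                 ACC = (TP + TN) / (TP + TN + FP + FN),
                 MCC = mcc,
                 source = c),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sn = %.3f  Sp = %.3f  ACC = %.3f  MCC = %.3f\n",
              x$Sn, x$Sp, x$ACC, x$MCC))
  invisible(x)
}

# Majority vote among the k nearest by distance. Like class::knn's default,
# every point tied with the k-th smallest distance participates in the vote;
# a tied vote (possible only with such distance ties) goes to the negative
# class deterministically, where class::knn would sample — on continuous
# data neither tie occurs and the two are prediction-identical.
knn_vote <- function(ds, y, k) {
  thr <- sort.int(ds, partial = k)[k]
  nb <- which(ds <= thr)
  pos <- sum(y[nb] == 1L)
  as.integer(pos * 2L > length(nb))
}

# Fast kNN leave-one-out: one full distance matrix, each sample voted on by
# its k nearest among the others.
knn_loocv_predict <- function(X, y, k) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))
  diag(d2) <- Inf
  vapply(seq_len(n), function(i) knn_vote(d2[i, ], y, k), integer(1L))
}

#' Leave-one-out cross-validation
#'
#' Each of the N samples is predicted by a model trained on the other N-1;
#' the N predictions are tallied against the true labels. A fold whose
#' training set collapses to a single class (possible only when a class has
#' exactly one member) is a hard error naming the fold. For the
#' k-nearest-neighbour families a cached-distance shortcut is used by
#' default (`fast = TRUE`); it is prediction-identical to naive per-fold
#' retraining on continuous data and the identity is asserted in the test
#' suite.
#'
#' @param spec a [classifier_spec()].
#' @param X numeric matrix, samples x features.
#' @param y binary 0/1 labels, one per row of `X`.
#' @param fast use the kNN distance-cache shortcut when applicable.
#' @return a [confusion_matrix()] with the per-sample predictions attached
#'   as attribute `"predictions"`.
#' @export
loocv <- function(spec, X, y, fast = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (n < 2L) stop("LOOCV needs at least 2 samples")
  if (length(y) != n) stop("labels and matrix differ in sample count")
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop("both classes must be present")
  if (any(tab == 1L)) {
    fold <- which(y == as.integer(names(tab)[tab == 1L][1L]))[1L]
    stop("fold ", fold, ": training set would be single-class")
  }
  if (fast && is_knn(spec$family) &&
      !isTRUE(spec$hyperparameters$scale_features)) {
    pred <- knn_loocv_predict(X, y, knn_k(spec$family))
  } else {
    pred <- integer(n)
    for (i in seq_len(n)) {
      pred[i] <- tryCatch(
        fit_predict(spec, X[-i, , drop = FALSE], y[-i],
                    X[i, , drop = FALSE]),
        error = function(e) stop("fold ", i, ": ", conditionMessage(e),
                                 call. = FALSE))
    }
  }
  cm <- confusion_counts(y, pred)
  attr(cm, "predictions") <- pred
  cm
}

#' Write a confusion matrix and its metrics as a small TSV report
#'
#' @param c a [confusion_matrix()].
#' @param path output file.
#' @export
write_metrics_report <- function(c, path) {
  m <- metrics(c)
  df <- data.frame(TP = c$TP, FN = c$FN, FP = c$FP, TN = c$TN,
                   Sn = round(m$Sn, 3), Sp = round(m$Sp, 3),
                   ACC = round(m$ACC, 3), MCC = round(m$MCC, 3))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Metrics from a predictions file
#'
#' Reads a two-column delimited file (truth, prediction; 0/1; header
#' optional) and returns the metric set.
#'
#' @param path predictions file.
#' @return a `metric_set`.
#' @export
evaluate_predictions_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "",
                          colClasses = "character", comment.char = "#")
  if (!df[1L, 1L] %in% c("0", "1")) df <- df[-1L, , drop = FALSE]
  metrics(confusion_counts(as.integer(df[[1L]]), as.integer(df[[2L]])))
}
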