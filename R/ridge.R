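#' Closed-form ridge classifier
#'
#' Fits `W = (D'D + alpha I)^{-1} D' Y` with one-hot labels `Y`. Features
#' can be z-scored with center/scale fitted on the training data; the
#' default is off because GAP and PPV statistics already live on
#' comparable bounded scales, while z-scoring amplifies test-time noise on
#' features whose training variance is near zero (a frequent occurrence in
#' frozen-kernel feature sets at small n). No intercept column is used;
#' when standardizing, the centering supplies the equivalent effect. When
#' `n < d` and
#' `alpha > 0`, the identical solution is computed through the dual form
#' `W = D'(DD' + alpha I)^{-1} Y`. `alpha = 0` with a singular Gram matrix
#' falls back to the pseudoinverse with a warning.
#'
#' @param features n x d numeric matrix.
#' @param labels length-n vector (factor or integer), >= 2 classes.
#' @param alpha regularization coefficient (default 0.039).
#' @param standardize z-score features on training statistics (default
#'   FALSE).
#' @return a `ridge_model` with `W` (d x n_classes), `alpha`, `classes`,
#'   `center`, `scale`.
#' @export
fit_ridge <- function(features, labels, alpha = 0.039, standardize = FALSE) {
  D <- as.matrix(features)
  stopifnot(nrow(D) >= 1, alpha >= 0)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (standardize) {
    center <- colMeans(D)
    scale <- apply(D, 2, sd)
    scale[scale == 0] <- 1
  } else {
    center <- rep(0, ncol(D)); scale <- rep(1, ncol(D))
  }
  Ds <- sweep(sweep(D, 2, center), 2, scale, "/")
  Y <- outer(labels, classes, "==") * 1
  n <- nrow(Ds); d <- ncol(Ds)
  if (alpha > 0 && n < d) {
    K <- tcrossprod(Ds)                            # n x n
    W <- crossprod(Ds, solve(K + diag(alpha, n), Y))
  } else {
    G <- crossprod(Ds) + diag(alpha, d)
    W <- tryCatch(solve(G, crossprod(Ds, Y)), error = function(e) {
      warning("singular normal equations; using pseudoinverse")
      MASS::ginv(G) %*% crossprod(Ds, Y)
    })
  }
  structure(list(W = W, alpha = alpha, classes = classes,
                 center = center, scale = scale),
            class = "ridge_model")
}

#' Predict class labels
#'
#' Scores are the scaled features times `W`; the label is the argmax per
#' row, ties broken toward the lowest class index.
#'
#' @param object a `ridge_model`.
#' @param features m x d matrix (or a single feature vector).
#' @param ... unused.
#' @return length-m vector of predicted labels.
#' @export
predict.ridge_model <- function(object, features, ...) {
  D <- if (is.null(dim(features))) matrix(features, nrow = 1)
       else as.matrix(features)
  if (ncol(D) != nrow(object$W))
    stop("feature dimension ", ncol(D), " does not match model (",
         nrow(object$W), ")")
  Ds <- sweep(sweep(D, 2, object$center), 2, object$scale, "/")
  scores <- Ds %*% object$W
  object$classes[max.col(scores, ties.method = "first")]
}

# Gorodkin multiclass Matthews correlation from a confusion matrix
multiclass_mcc <- function(cm) {
  s <- sum(cm); c0 <- sum(diag(cm))
  t_k <- rowSums(cm); p_k <- colSums(cm)
  num <- c0 * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Multiclass evaluation report
#'
#' Confusion matrix plus global accuracy, macro-averaged one-vs-rest
#' precision, recall and F1, and the multiclass Matthews correlation
#' (Gorodkin generalization), all reported as percentages. A class absent
#' from both truth and prediction contributes precision/recall 0 to the
#' macro averages.
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param classes class set (default: union of both).
#' @return an `eval_report`: `confusion`, `acc`, `pre`, `rec`, `f1`, `mcc`.
#' @export
evaluate <- function(pred, truth, classes = NULL) {
  stopifnot(length(pred) == length(truth))
  if (is.null(classes)) classes <- sort(unique(c(pred, truth)))
  if (!all(pred %in% classes) || !all(truth %in% classes))
    stop("label outside the declared class set")
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  cm <- matrix(as.numeric(cm), nrow = length(classes),
               dimnames = list(truth = classes, pred = classes))
  n <- sum(cm)
  per_class <- t(vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]; fn <- sum(cm[i, -i]); fp <- sum(cm[-i, i])
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
    c(pre = pre, rec = rec, f1 = f1)
  }, numeric(3)))
  structure(list(confusion = cm,
                 acc = 100 * sum(diag(cm)) / n,
                 pre = 100 * mean(per_class[, "pre"]),
                 rec = 100 * mean(per_class[, "rec"]),
                 f1 = 100 * mean(per_class[, "f1"]),
                 mcc = 100 * multiclass_mcc(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("ACC %.2f  PRE %.2f  REC %.2f  F1 %.2f  MCC %.2f  (n = %d)\n",
              x$acc, x$pre, x$rec, x$f1, x$mcc, sum(x$confusion)))
  invisible(x)
}

#' Exact two-sided McNemar test for paired classifiers
#'
#' With discordant counts `b` (A right, B wrong) and `c` (A wrong, B
#' right), the exact two-sided p-value is
#' `min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c, 1/2)`; when
#' `b + c = 0` the p-value is 1.
#'
#' @param pred_a,pred_b predictions of the two classifiers.
#' @param truth true labels (all three the same length).
#' @return list with `b`, `c`, `p_value`.
#' @export
mcnemar_exact <- function(pred_a, pred_b, truth) {
  stopifnot(length(pred_a) == length(truth),
            length(pred_b) == length(truth))
  a_ok <- pred_a == truth; b_ok <- pred_b == truth
  b <- sum(a_ok & !b_ok); cc <- sum(!a_ok & b_ok)
  n <- b + cc
  p <- if (n == 0) 1 else min(1, 2 * pbinom(min(b, cc), n, 0.5))
  list(b = b, c = cc, p_value = p)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values in the input order (monotone, capped at 1).
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}
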