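# Radial-basis max-margin classifier on posterior vectors. The soft-margin
# C-SVC dual
#   max_a  sum(a) - 1/2 sum_ij a_i a_j y_i y_j K_ij
#   s.t.   0 <= a_i <= C,  sum_i a_i y_i = 0
# is a box-constrained QP with one equality constraint, solved with
# quadprog (a small ridge keeps the kernel positive definite). Kernel
# width and cost default to the common heuristics (gamma = 1/J, C = 1);
# they are configurable and make no accuracy claims.

.rbf_kernel <- function(X, Z = X, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train a soft-margin RBF SVM
#'
#' @param X N x J feature matrix.
#' @param y labels coercible to two classes (-1/+1 internally).
#' @param gamma RBF width; default 1/J.
#' @param cost box constraint C; default 1.
#' @param ridge diagonal jitter added to the dual Hessian.
#' @return object of class `rbf_svm` (support coefficients, bias, training
#'   data, levels).
#' @export
svm_train <- function(X, y, gamma = NULL, cost = 1, ridge = 1e-8) {
  X <- as.matrix(X)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) stage_stop("discriminant", "svm needs exactly 2 classes")
  yy <- ifelse(as.character(y) == lev[2], 1, -1)
  gamma <- gamma %||% (1 / ncol(X))
  n <- nrow(X)
  K <- .rbf_kernel(X, gamma = gamma)
  D <- (yy %o% yy) * K + diag(ridge, n)
  # constraints: t(A) a >= b with first row an equality (meq = 1)
  A <- cbind(yy, diag(n), -diag(n))
  b <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A, bvec = b, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-6 * cost
  f0 <- as.vector(K %*% (alpha * yy))
  margin <- sv & alpha < cost * (1 - 1e-6)
  bias <- if (any(margin)) mean(yy[margin] - f0[margin]) else {
    # no free support vectors: place the bias mid-way between class scores
    -(max(f0[yy == -1]) + min(f0[yy == 1])) / 2
  }
  structure(list(X = X[sv, , drop = FALSE], coef = (alpha * yy)[sv],
                 bias = bias, gamma = gamma, cost = cost, levels = lev),
            class = "rbf_svm")
}

#' @export
predict.rbf_svm <- function(object, newdata, ...) {
  K <- .rbf_kernel(as.matrix(newdata), object$X, object$gamma)
  f <- as.vector(K %*% object$coef) + object$bias
  object$levels[(f >= 0) + 1L]
}

#' RBF max-margin classification of posterior vectors under LOO
#'
#' Trains [svm_train()] on the posterior matrix under the given folds
#' (default leave-one-out) and pools the held-out predictions.
#'
#' @param posteriors N x J matrix of per-subject posterior vectors.
#' @param labels true groups (HC/AD; AD subgroups are collapsed).
#' @param folds list of integer index vectors to hold out (default LOO).
#' @param gamma,cost kernel width and box constraint (defaults 1/J and 1).
#' @return list with `accuracy`, `sensitivity`, `specificity`,
#'   `predicted`.
#' @export
svm_classify <- function(posteriors, labels, folds = NULL, gamma = NULL, cost = 1) {
  posteriors <- as.matrix(posteriors)
  lab <- as.character(binary_group(labels))
  n <- nrow(posteriors)
  folds <- folds %||% as.list(seq_len(n))
  predicted <- character(n)
  for (f in folds) {
    train <- setdiff(seq_len(n), f)
    if (length(unique(lab[train])) < 2L) {
      stage_stop("discriminant", "svm fold with single-class training set")
    }
    fit <- svm_train(posteriors[train, , drop = FALSE], lab[train],
                     gamma = gamma, cost = cost)
    predicted[f] <- predict(fit, posteriors[f, , drop = FALSE])
  }
  is_ad <- lab == "AD"
  list(accuracy = mean(predicted == lab),
       sensitivity = mean(predicted[is_ad] == "AD"),
       specificity = mean(predicted[!is_ad] == "HC"),
       predicted = predicted)
}
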