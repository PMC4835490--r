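# Disease-predictive prior: per-voxel weights from ordinary least squares
# on group labels, solved in a PCA-reduced space because the voxel count J
# vastly exceeds the subject count N. The PCA uses the Gram-matrix trick
# for high-dimensional data: eigendecompose the N x N matrix N^-1 X X^T
# (same nonzero spectrum as the J x J covariance) and map its eigenvectors
# back to voxel space.

#' High-dimensional PCA via the Gram matrix
#'
#' Columns of `X` are centered; the eigenpairs (lambda_j, v_j) of
#' `N^-1 X X^T` are computed and mapped to unit-norm voxel-space
#' eigenvectors `u_j = (N lambda_j)^(-1/2) X^T v_j`. Components whose
#' eigenvalue falls below numerical tolerance are dropped with a warning.
#'
#' @param X N x J data matrix (rows = subjects).
#' @param K number of components requested (must be <= N - 1).
#' @param tol relative eigenvalue tolerance for dropping components.
#' @return list with `U` (J x K, unit-norm columns), `lambdas` (descending),
#'   `V` (N x K), `center` (column means), `K` (components kept).
#' @export
pca_highdim <- function(X, K, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (K > n - 1L) stop("K must be <= N - 1", call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  G <- (Xc %*% t(Xc)) / n
  e <- eigen(G, symmetric = TRUE)
  lambdas <- e$values[seq_len(K)]
  ok <- lambdas > tol * max(e$values[1], 0)
  if (!all(ok)) {
    warning("reducing K from ", K, " to ", sum(ok), ": eigenvalues at numerical tolerance")
    K <- sum(ok)
    if (K < 1L) stage_stop("predictive_prior", "no usable principal components")
    lambdas <- lambdas[seq_len(K)]
  }
  V <- e$vectors[, seq_len(K), drop = FALSE]
  U <- crossprod(Xc, V)                    # J x K, columns X^T v_j
  U <- sweep(U, 2L, sqrt(n * lambdas), "/")
  list(U = U, lambdas = lambdas, V = V, center = center, K = K)
}

#' Ordinary least squares in the reduced space
#'
#' Solves `X_reduced beta = y` by the normal equations, falling back to
#' the Moore-Penrose pseudoinverse when the cross-product is singular.
#'
#' @param X_reduced N x K matrix of component scores.
#' @param y length-N response (group codes HC -> -1, AD -> +1).
#' @return length-K coefficient vector.
#' @export
fit_reduced_ols <- function(X_reduced, y) {
  X_reduced <- as.matrix(X_reduced)
  stopifnot(nrow(X_reduced) == length(y))
  xtx <- crossprod(X_reduced)
  xty <- crossprod(X_reduced, y)
  beta <- tryCatch(solve(xtx, xty), error = function(e) pinv(X_reduced) %*% y)
  as.double(beta)
}

#' Regression design from stacked likelihood vectors
#'
#' @param L_matrix N x J matrix whose row n is subject n's likelihood
#'   vector.
#' @param groups length-N HC/AD_EA/AD_LA labels; coded HC -> -1, any
#'   AD -> +1.
#' @param subject_ids optional row ids.
#' @return object of class `regression_design`: `X`, `y`, `subject_ids`.
#' @export
regression_design <- function(L_matrix, groups, subject_ids = NULL) {
  X <- as.matrix(L_matrix)
  y <- ifelse(groups == "HC", -1, 1)
  if (nrow(X) < 3L || length(unique(y)) < 2L) {
    stage_stop("predictive_prior", "design needs N >= 3 with both classes present")
  }
  structure(list(X = X, y = as.double(y),
                 subject_ids = as.character(subject_ids %||% rownames(X) %||% seq_len(nrow(X)))),
            class = "regression_design")
}

#' Build the predictive prior pi_PP
#'
#' PCA-reduce the (centered) likelihood design, fit OLS of the group code
#' on the first K component scores, back-project the coefficients to voxel
#' space (`beta = U beta'`), and rescale to \[0, 1\]. Voxels whose
#' hypo-perfusion predicts disease get weights near 1; voxels that predict
#' health (negative beta) land near 0 under the default min-max rescale.
#'
#' @param design a [regression_design].
#' @param K components to use; default 20, capped at N_train - 1.
#' @param exclude subject ids to drop before fitting (leave-one-out: the
#'   test subject must never inform its own prior).
#' @param rescale `"minmax"` (default), `"abs"` (|beta|/max|beta|) or
#'   `"clip"` (beta clipped to \[0,1\] after dividing by max beta).
#' @return [score_map] of kind `"prior"`, with attributes `beta`
#'   (unscaled voxel coefficients) and `K`.
#' @export
build_predictive_prior <- function(design, K = 20, exclude = NULL,
                                   rescale = c("minmax", "abs", "clip")) {
  rescale <- match.arg(rescale)
  stopifnot(inherits(design, "regression_design"))
  keep <- !(design$subject_ids %in% exclude)
  X <- design$X[keep, , drop = FALSE]
  y <- design$y[keep]
  if (length(unique(y)) < 2L) {
    stage_stop("predictive_prior", "single-class design after exclusion")
  }
  K <- min(K, nrow(X) - 1L)
  p <- pca_highdim(X, K)
  Xc <- sweep(X, 2L, p$center)
  scores <- Xc %*% p$U
  beta_r <- fit_reduced_ols(scores, y)
  beta <- as.double(p$U %*% beta_r)
  vals <- switch(rescale,
    minmax = {
      rng <- range(beta)
      if (rng[2] == rng[1]) rep(0.5, length(beta))
      else (beta - rng[1]) / (rng[2] - rng[1])
    },
    abs = {
      m <- max(abs(beta))
      if (m == 0) rep(0, length(beta)) else abs(beta) / m
    },
    clip = {
      m <- max(beta)
      if (m <= 0) rep(0, length(beta)) else pmin(pmax(beta / m, 0), 1)
    })
  out <- score_map(vals, "prior", "")
  attr(out, "beta") <- beta
  attr(out, "K") <- p$K
  out
}
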