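# Independent oracles and small fixture builders shared across tests.

# Upper-tail Gaussian survival probability by adaptive quadrature of the
# density — independent of the pnorm-based implementation path.
surv_oracle <- function(x, mu, sigma) {
  mapply(function(xi, mi, si) {
    integrate(dnorm, lower = xi, upper = Inf, mean = mi, sd = si,
              rel.tol = 1e-13, abs.tol = 1e-14)$value
  }, x, mu, sigma)
}

# Minimum-norm least-squares solution via SVD pseudoinverse.
pinv_oracle <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# A full mask over a small grid.
full_mask <- function(d) voxel_mask(array(TRUE, dim = d))

# Cohort matrix built directly from a gamma matrix (bypassing volumes).
make_cohort <- function(gamma, groups, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_len(nrow(gamma)))
  cohort_matrix(gamma, ids, groups, full_mask(c(ncol(gamma), 1L, 1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny two-region "brain": first half of the voxels lesion-free, second
# half carrying a planted multiplicative drop for AD rows.
planted_gamma <- function(n_hc, n_ad, J, drop = 0.3, noise = 0.05, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n_hc + n_ad, 0, 0) + 1, n_hc + n_ad, J) +
    matrix(rnorm((n_hc + n_ad) * J, 0, noise), n_hc + n_ad, J)
  lesion <- seq(J %/% 2 + 1L, J)
  base[seq(n_hc + 1L, n_hc + n_ad), lesion] <-
    base[seq(n_hc + 1L, n_hc + n_ad), lesion] * (1 - drop)
  list(gamma = base,
       groups = c(rep("HC", n_hc), rep("AD_LA", n_ad)),
       lesion = lesion)
}
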