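#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a pipeline stage tag
#'
#' All fatal errors raised inside pipeline stages carry the stage name so
#' orchestration failures are attributable to a module.
#' @keywords internal
stage_stop <- function(stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  stop(msg, call. = FALSE)
}

#' FNV-1a content hash of numeric data
#'
#' Library-free 32-bit FNV-1a over the little-endian byte stream of the
#' input, used to fingerprint pipeline inputs in run logs. Not
#' cryptographic; collision resistance is irrelevant here.
#'
#' @param x numeric vector/array (doubles) or raw vector.
#' @return hex string of the 32-bit hash.
#' @keywords internal
fnv1a_hash <- function(x) {
  bytes <- if (is.raw(x)) x else writeBin(as.double(x), raw(), size = 8L, endian = "little")
  h <- 2166136261
  ints <- as.integer(bytes)
  for (b in ints) {
    # xor touches the low byte only (b < 256); keep h as a double to stay
    # within 32 bits without integer overflow
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # exact 32-bit modular multiply by the FNV prime 16777619, split into
    # 16-bit halves so intermediate products stay below 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)), sprintf("%04x", as.integer(h %% 65536)))
}

#' Content fingerprint of a numeric array
#'
#' For large inputs, hashing every byte in an R loop is too slow, so the
#' fingerprint covers the dimensions, global sums, and a deterministic
#' strided subsample (at most 4096 values). Any single-voxel change still
#' perturbs the global sums.
#' @keywords internal
content_hash <- function(x) {
  v <- as.double(x)
  idx <- if (length(v) > 4096L) {
    seq.int(1L, length(v), length.out = 4096L)
  } else {
    seq_along(v)
  }
  fnv1a_hash(c(length(v), sum(v), sum(v * v), v[idx]))
}

#' Moore-Penrose pseudoinverse via SVD
#' @param m numeric matrix.
#' @param tol relative singular-value cutoff.
#' @keywords internal
pinv <- function(m, tol = 1e-12) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
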