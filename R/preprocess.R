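# Post-processing of normalized CBF volumes: Gaussian smoothing against
# ASL noise, then a per-volume feature scale normalization that removes
# global CBF offset/scale differences (cardiovascular state, labeling
# efficiency) before any between-subject comparison.

#' Smoothing configuration
#'
#' @param sigma Gaussian standard deviation in voxel units (default 2;
#'   4 mm at the 2 mm grid).
#' @param kernel_size window edge extent s in voxels (default 6). An even
#'   extent cannot be centered, so the realized window has half-width
#'   `ceiling(s/2)` (7^3 taps for s = 6).
#' @return object of class `smoothing_config`.
#' @export
smoothing_config <- function(sigma = 2, kernel_size = 6) {
  if (!(sigma > 0)) stop("sigma must be > 0", call. = FALSE)
  if (kernel_size < 1) stop("kernel_size must be >= 1", call. = FALSE)
  half <- as.integer(ceiling(kernel_size / 2))
  taps <- dnorm(seq(-half, half), sd = sigma)
  structure(list(sigma = sigma, kernel_size = kernel_size,
                 half = half, taps = taps / sum(taps)),
            class = "smoothing_config")
}

# banded convolution matrix implementing zero-padded 1-D convolution
.conv_matrix <- function(n, taps, half) {
  m <- matrix(0, n, n)
  for (k in seq(-half, half)) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1L & j <= n
    m[cbind(i[ok], j[ok])] <- taps[k + half + 1L]
  }
  m
}

#' Separable 3D Gaussian smoothing
#'
#' Truncated, renormalized (sum 1) Gaussian kernel applied separably along
#' each axis; boundaries are zero-padded, so constants are preserved only
#' in the interior (>= half-width voxels from any face) — in practice the
#' out-of-brain background is zero anyway.
#'
#' @param volume a [volume3d] or 3D array.
#' @param cfg a [smoothing_config].
#' @return smoothed volume, same class as the input.
#' @export
gaussian_smooth <- function(volume, cfg = smoothing_config()) {
  stopifnot(inherits(cfg, "smoothing_config"))
  data <- if (inherits(volume, "volume3d")) volume$data else volume
  d <- dim(data)
  for (ax in 1:3) {
    k <- .conv_matrix(d[ax], cfg$taps, cfg$half)
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(data, perm)
    x <- array(k %*% matrix(x, d[ax]), dim = d[perm])
    data <- aperm(x, order(perm))
  }
  if (inherits(volume, "volume3d")) {
    volume3d(data, voxel_size = volume$voxel_size, subject_id = volume$subject_id)
  } else data
}

#' Per-volume feature scale normalization
#'
#' Removes global CBF scale and offset so subjects are comparable. The
#' default is min-max over masked voxels, v' = (v - min)/(max - min), which
#' maps the mask into \[0, 1\] and is invariant to positive affine
#' transforms of the input; `"global_mean"` instead divides by the mean
#' over masked voxels (scale-only invariance). Unmasked voxels are set
#' to 0.
#'
#' @param volume [volume3d] or 3D array.
#' @param mask [voxel_mask] defining the voxels the statistics are
#'   computed over (typically the coverage mask).
#' @param method `"minmax"` (default) or `"global_mean"`.
#' @return scaled volume, same class as the input.
#' @export
feature_scale <- function(volume, mask, method = c("minmax", "global_mean")) {
  method <- match.arg(method)
  data <- if (inherits(volume, "volume3d")) volume$data else volume
  if (!identical(dim(data), mask$dim)) stage_stop("preprocess", "feature_scale: shape mismatch")
  v <- data[mask$index]
  out <- array(0, dim = dim(data))
  if (method == "minmax") {
    rng <- range(v)
    if (rng[2] == rng[1]) {
      stage_stop("preprocess", "degenerate volume: all masked values equal (",
                 rng[1], ")")
    }
    out[mask$index] <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    m <- mean(v)
    if (m == 0) stage_stop("preprocess", "degenerate volume: zero mean over mask")
    out[mask$index] <- v / m
  }
  if (inherits(volume, "volume3d")) {
    volume3d(out, voxel_size = volume$voxel_size, subject_id = volume$subject_id)
  } else out
}

#' Smooth, scale and linearize a cohort
#'
#' Applies the identical post-processing chain — smooth, feature-scale,
#' mask, linearize — to every subject and stacks the results into a
#' [cohort_matrix].
#'
#' @param volumes list of [volume3d] in clinical order.
#' @param clinical clinical data.frame (ids must match the volumes).
#' @param mask [voxel_mask].
#' @param cfg [smoothing_config].
#' @param scaling scaling method, see [feature_scale()].
#' @return a [cohort_matrix].
#' @export
preprocess_cohort <- function(volumes, clinical, mask,
                              cfg = smoothing_config(),
                              scaling = "minmax") {
  gamma <- t(vapply(volumes, function(v) {
    linearize(feature_scale(gaussian_smooth(v, cfg), mask, scaling), mask)
  }, numeric(mask$J)))
  cohort_matrix(gamma, clinical$id, clinical$group, mask)
}
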