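#' Analysis voxel mask
#'
#' A boolean keep-grid plus the ordered list of kept coordinates that
#' defines position j of every linearized vector. Ordering is R's native
#' array (column-major, x fastest) order — fixed and deterministic; any
#' fixed bijection is equivalent downstream.
#'
#' @param keep logical 3D array.
#' @return object of class `voxel_mask`: `keep`, `index` (linear indices,
#'   ascending), `coords` (J x 3 integer matrix), `dim`, `J`.
#' @export
voxel_mask <- function(keep) {
  if (is.null(dim(keep)) || length(dim(keep)) != 3L) {
    stop("voxel_mask needs a logical 3D array", call. = FALSE)
  }
  keep <- array(as.logical(keep), dim = dim(keep))
  idx <- which(keep)
  if (length(idx) < 1L) stage_stop("volume_io", "empty mask: no voxel survives")
  structure(list(keep = keep, index = idx,
                 coords = arrayInd(idx, dim(keep)),
                 dim = dim(keep), J = length(idx)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask>", x$J, "of", prod(x$dim), "voxels kept on grid",
      paste(x$dim, collapse = "x"), "\n")
  invisible(x)
}

#' Coverage mask from a cohort of volumes
#'
#' A voxel is analyzable only where (almost) every subject has signal: it
#' is kept iff the fraction of subjects with a nonzero value there is
#' strictly greater than `threshold`; voxels with coverage equal or below
#' the threshold are discarded. Computed on raw input volumes, before any
#' smoothing.
#'
#' @param volumes list of [volume3d] on one grid.
#' @param threshold coverage fraction in (0, 1]; default 0.95.
#' @return a [voxel_mask].
#' @export
coverage_mask <- function(volumes, threshold = 0.95) {
  stopifnot(length(volumes) >= 1L)
  if (!(threshold > 0 && threshold <= 1)) {
    stage_stop("volume_io", "coverage threshold must lie in (0, 1]")
  }
  d <- dim(volumes[[1]]$data)
  nz <- array(0L, dim = d)
  for (v in volumes) {
    if (!identical(dim(v$data), d)) stage_stop("volume_io", "coverage_mask: shape mismatch")
    nz <- nz + (v$data != 0)
  }
  voxel_mask(nz / length(volumes) > threshold)
}

#' Linearize a volume over a mask
#'
#' @param volume [volume3d] or 3D array on the mask grid.
#' @param mask [voxel_mask].
#' @return numeric vector of length `mask$J` (element j = value at the
#'   j-th kept coordinate).
#' @export
linearize <- function(volume, mask) {
  data <- if (inherits(volume, "volume3d")) volume$data else volume
  if (!identical(dim(data), mask$dim)) {
    stage_stop("volume_io", "linearize: volume shape ",
               paste(dim(data), collapse = "x"), " does not match mask grid ",
               paste(mask$dim, collapse = "x"))
  }
  as.double(data[mask$index])
}

#' Invert linearization back to a 3D volume
#'
#' @param vec numeric vector of length `mask$J`.
#' @param mask [voxel_mask].
#' @param fill value for voxels outside the mask (default 0; use e.g. -1
#'   to mark out-of-coverage voxels distinctly).
#' @param subject_id id for the returned volume.
#' @param voxel_size voxel edges in mm.
#' @return a [volume3d].
#' @export
delinearize <- function(vec, mask, fill = 0, subject_id = "", voxel_size = c(2, 2, 2)) {
  if (length(vec) != mask$J) {
    stage_stop("volume_io", "delinearize: vector length ", length(vec),
               " != mask size ", mask$J)
  }
  out <- array(as.double(fill), dim = mask$dim)
  out[mask$index] <- as.double(vec)
  volume3d(out, voxel_size = voxel_size, subject_id = subject_id)
}

#' Cohort matrix of linearized volumes
#'
#' Rows are subjects (in clinical-table order), columns the J masked
#' voxels.
#'
#' @param gamma N x J numeric matrix.
#' @param subject_ids length-N ids (become rownames).
#' @param groups length-N labels in HC/AD_EA/AD_LA.
#' @param mask the [voxel_mask] defining column order.
#' @return object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(gamma, subject_ids, groups, mask) {
  gamma <- as.matrix(gamma)
  if (nrow(gamma) < 2L) stop("cohort needs N >= 2 subjects", call. = FALSE)
  if (ncol(gamma) != mask$J) stop("gamma has ", ncol(gamma), " columns; mask has J = ", mask$J, call. = FALSE)
  if (length(subject_ids) != nrow(gamma) || length(groups) != nrow(gamma)) {
    stop("subject_ids/groups length must equal nrow(gamma)", call. = FALSE)
  }
  if (!all(groups %in% c("HC", "AD_EA", "AD_LA"))) {
    stop("groups must be HC, AD_EA or AD_LA", call. = FALSE)
  }
  rownames(gamma) <- as.character(subject_ids)
  structure(list(gamma = gamma, subject_ids = as.character(subject_ids),
                 groups = as.character(groups), mask = mask),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("<cohort_matrix>", nrow(x$gamma), "subjects x", ncol(x$gamma), "voxels (",
      sum(x$groups == "HC"), "HC /", sum(x$groups != "HC"), "AD )\n")
  invisible(x)
}
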