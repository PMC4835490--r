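#' 3D scalar volume
#'
#' The basic container: a 3D grid of CBF (ml/100g/min) or unitless
#' probability/score values on the common analysis grid. NaNs are replaced
#' by 0 at construction and the replacement count is kept (and messaged),
#' since zero is the "no signal" convention the coverage mask relies on.
#'
#' @param data 3D numeric array.
#' @param voxel_size numeric length-3, voxel edges in mm (default 2 mm
#'   isotropic, the grid the normalized CBF maps live on).
#' @param subject_id identifier string.
#' @return object of class `volume3d`: list with `data`, `voxel_size`,
#'   `subject_id`, `n_nan`.
#' @export
volume3d <- function(data, voxel_size = c(2, 2, 2), subject_id = "") {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("volume3d needs a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  data <- array(as.double(data), dim = dim(data))
  nan <- is.na(data)
  n_nan <- sum(nan)
  if (n_nan > 0L) {
    data[nan] <- 0
    message("volume3d: replaced ", n_nan, " NaN/NA voxels with 0",
            if (nzchar(subject_id)) paste0(" [", subject_id, "]"))
  }
  structure(list(data = data, voxel_size = as.double(voxel_size),
                 subject_id = as.character(subject_id), n_nan = n_nan),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d>", x$subject_id, paste(dim(x$data), collapse = "x"),
      "voxels,", paste(x$voxel_size, collapse = "x"), "mm\n")
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Read the clinical covariate table
#'
#' CSV with header `id,group,age,mmse,education,gender`. Groups are
#' `HC`, `AD_EA` (early onset), `AD_LA` (late onset).
#'
#' @param x path to a CSV file, or a data.frame already in memory.
#' @return validated data.frame with those six columns.
#' @export
read_clinical_table <- function(x) {
  tab <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else as.data.frame(x)
  need <- c("id", "group", "age", "mmse", "education", "gender")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clinical table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) stop("clinical table ids are not unique", call. = FALSE)
  if (!all(tab$group %in% c("HC", "AD_EA", "AD_LA"))) {
    stop("group must be one of HC, AD_EA, AD_LA", call. = FALSE)
  }
  if (any(tab$mmse < 0 | tab$mmse > 30, na.rm = TRUE)) stop("mmse must lie in [0, 30]", call. = FALSE)
  if (any(tab$age <= 0, na.rm = TRUE)) stop("age must be positive", call. = FALSE)
  if (!all(tab$gender %in% c("F", "M"))) stop("gender must be F or M", call. = FALSE)
  tab[need]
}

#' Collapse AD subgroups to a two-class label
#' @param group character vector of HC/AD_EA/AD_LA labels.
#' @return factor with levels HC, AD.
#' @export
binary_group <- function(group) {
  factor(ifelse(group == "HC", "HC", "AD"), levels = c("HC", "AD"))
}

#' Load a cohort of volumes plus its clinical table
#'
#' Volumes are returned in clinical-table order; every volume must have a
#' clinical row and all volumes must share one grid shape. Volume subject
#' ids come from `names(paths)` or, unnamed, from the file name stripped
#' of its `.nii`/`.nii.gz` extension.
#'
#' @param paths character vector of NIfTI paths (optionally named by id).
#' @param clinical clinical table path or data.frame (see
#'   [read_clinical_table()]).
#' @return list with `volumes` (list of [volume3d]) and `clinical`.
#' @export
load_cohort <- function(paths, clinical) {
  if (length(paths) < 2L) stage_stop("volume_io", "need at least 2 volumes")
  clinical <- read_clinical_table(clinical)
  ids <- names(paths) %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
  if (anyDuplicated(ids)) stage_stop("volume_io", "duplicate volume ids")
  vols <- lapply(seq_along(paths), function(i) read_nifti(paths[[i]], subject_id = ids[i]))
  names(vols) <- ids
  ref <- dim(vols[[1]]$data)
  for (v in vols) {
    if (!identical(dim(v$data), ref)) {
      stage_stop("volume_io", "shape mismatch for subject '", v$subject_id,
                 "': ", paste(dim(v$data), collapse = "x"),
                 " vs ", paste(ref, collapse = "x"))
    }
  }
  missing <- setdiff(ids, clinical$id)
  if (length(missing)) {
    stage_stop("volume_io", "no clinical row for subject(s): ", paste(missing, collapse = ", "))
  }
  keep <- clinical$id %in% ids
  clinical <- clinical[keep, , drop = FALSE]
  vols <- vols[clinical$id]
  list(volumes = vols, clinical = clinical)
}
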