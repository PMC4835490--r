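# Element-wise Gaussian reference model of the healthy cohort: a normal
# distribution fitted independently at each voxel from the HC rows of the
# cohort matrix, used for T-scores and for the likelihood of deviant
# perfusion.

#' Fit the voxel-wise healthy reference model
#'
#' At each masked voxel, the mean and standard deviation of the healthy
#' controls' (post-processed) CBF. The SD uses divisor N (population form)
#' by default; set `sd_divisor = "n-1"` for the sample form. Zero-variance
#' voxels are floored at `1e-6 * max(sigma)` (or `1e-6` if all sigma are
#' zero) so downstream standardization never divides by zero.
#'
#' For leave-one-out evaluation of an HC subject, pass its id in
#' `exclude` so the reference never contains the subject being scored.
#'
#' @param cohort a [cohort_matrix].
#' @param hc_ids ids to fit on; default all subjects with group `HC`.
#' @param exclude ids to drop (e.g. the held-out subject).
#' @param sd_divisor `"n"` (default) or `"n-1"`.
#' @return object of class `healthy_model`: `mu`, `sigma` (floored),
#'   `sigma_raw`, `n_hc`, `sigma_floor`, `hc_ids`, `excluded`.
#' @export
fit_healthy_model <- function(cohort, hc_ids = NULL, exclude = NULL,
                              sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (is.null(hc_ids)) hc_ids <- cohort$subject_ids[cohort$groups == "HC"]
  bad <- hc_ids[cohort$groups[match(hc_ids, cohort$subject_ids)] != "HC"]
  if (length(bad)) stage_stop("healthy_model", "non-HC ids in hc_ids: ", paste(bad, collapse = ", "))
  hc_ids <- setdiff(hc_ids, exclude)
  n <- length(hc_ids)
  if (n < 2L) stage_stop("healthy_model", "need at least 2 HC subjects, got ", n)
  x <- cohort$gamma[hc_ids, , drop = FALSE]
  mu <- colMeans(x)
  dev2 <- colSums(x * x) - n * mu * mu
  dev2[dev2 < 0] <- 0  # guard tiny negative round-off
  sigma <- sqrt(dev2 / if (sd_divisor == "n") n else n - 1L)
  floor_val <- if (all(sigma == 0)) 1e-6 else 1e-6 * max(sigma)
  structure(list(mu = mu, sigma = pmax(sigma, floor_val), sigma_raw = sigma,
                 n_hc = n, sigma_floor = floor_val, hc_ids = hc_ids,
                 excluded = exclude %||% character(), sd_divisor = sd_divisor),
            class = "healthy_model")
}

#' @export
print.healthy_model <- function(x, ...) {
  cat("<healthy_model> fitted on", x$n_hc, "HC subjects,", length(x$mu),
      "voxels; sigma floor", format(x$sigma_floor), "\n")
  if (length(x$excluded)) cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Single-subject T-score map
#'
#' Voxel-wise standardized deviation (x - mu)/sigma from the healthy
#' model; negative values mean lower-than-normal perfusion.
#'
#' @param subject linearized subject vector (length J).
#' @param model a [healthy_model].
#' @param subject_id id attached to the result.
#' @return [score_map] of kind `"tscore"`.
#' @export
t_score_map <- function(subject, model, subject_id = "") {
  if (length(subject) != length(model$mu)) {
    stage_stop("healthy_model", "subject vector length ", length(subject),
               " != model length ", length(model$mu))
  }
  score_map((subject - model$mu) / model$sigma, "tscore", subject_id)
}

#' Persist / restore a healthy model as NIfTI + JSON sidecar
#'
#' Writes `mu.nii.gz`, `sigma.nii.gz` (via [delinearize()]) and
#' `model.json` (n_hc, sigma_floor, excluded ids) into `dir`.
#'
#' @param model a [healthy_model].
#' @param mask the [voxel_mask] the model was fitted over.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_healthy_model <- function(model, mask, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(delinearize(model$mu, mask), file.path(dir, "mu.nii.gz"))
  write_nifti(delinearize(model$sigma, mask), file.path(dir, "sigma.nii.gz"))
  meta <- list(n_hc = model$n_hc, sigma_floor = model$sigma_floor,
               excluded = model$excluded, sd_divisor = model$sd_divisor,
               hc_ids = model$hc_ids)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
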