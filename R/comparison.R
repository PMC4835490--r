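# Voxel-wise comparison of a subject against the healthy model: the
# likelihood of deviant perfusion (upper-tail survival probability of the
# voxel's healthy Gaussian) and its correction by prior maps into a
# posterior. L near 1 = hypo-perfusion, 0.5 = normal, near 0 =
# hyper-perfusion.

#' Per-subject score map
#'
#' A length-J vector in mask order, tagged with what it is. Likelihood,
#' prior and posterior kinds must lie in \[0, 1\]; T-scores are unbounded.
#'
#' @param values numeric vector.
#' @param kind one of `"tscore"`, `"likelihood"`, `"prior"`, `"posterior"`.
#' @param subject_id id string ("" for subject-independent maps such as
#'   priors).
#' @return object of class `score_map`.
#' @export
score_map <- function(values, kind = c("tscore", "likelihood", "prior", "posterior"),
                      subject_id = "") {
  kind <- match.arg(kind)
  values <- as.double(values)
  if (anyNA(values)) stop("score_map values contain NA", call. = FALSE)
  if (kind != "tscore" && (any(values < 0) || any(values > 1))) {
    stop(kind, " map values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(values = values, kind = kind, subject_id = as.character(subject_id)),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat("<score_map>", x$kind, if (nzchar(x$subject_id)) x$subject_id else NULL,
      "J =", length(x$values),
      sprintf("range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Likelihood of deviant (hypo-) perfusion
#'
#' The complementary cumulative Gaussian at each voxel:
#' `L = 1 - pnorm((x - mu) / sigma)`. CBF far below the healthy mean gives
#' L near 1 (severe hypo-perfusion), CBF at the mean gives exactly 0.5,
#' and CBF far above gives L near 0 (hyper-perfusion).
#'
#' @param subject linearized subject vector (length J).
#' @param model a [healthy_model].
#' @param subject_id id attached to the result.
#' @return [score_map] of kind `"likelihood"`.
#' @export
likelihood_map <- function(subject, model, subject_id = "") {
  if (length(subject) != length(model$mu)) {
    stage_stop("comparison", "subject vector length ", length(subject),
               " != model length ", length(model$mu))
  }
  z <- (subject - model$mu) / model$sigma
  score_map(pnorm(z, lower.tail = FALSE), "likelihood", subject_id)
}

#' Gray-matter prior
#'
#' White-matter ASL signal is unreliable, so the posterior down-weights
#' voxels by their gray-matter probability. The GM probability volume
#' (per subject, or a cohort mean) is linearized over the mask unchanged;
#' values outside \[0, 1\] are clipped with a warning.
#'
#' @param gm_probability [volume3d] (or 3D array) of GM probabilities.
#' @param mask [voxel_mask].
#' @return [score_map] of kind `"prior"`.
#' @export
gm_prior <- function(gm_probability, mask) {
  v <- linearize(gm_probability, mask)
  if (any(v < 0) || any(v > 1)) {
    warning("GM probabilities outside [0, 1]; clipping ",
            sum(v < 0 | v > 1), " voxels")
    v <- pmin(pmax(v, 0), 1)
  }
  score_map(v, "prior", "")
}

#' Bundle prior maps
#'
#' @param ... named [score_map]s of kind `"prior"` (e.g. `gm = ...`,
#'   `pp = ...`).
#' @return object of class `prior_set` (list of priors).
#' @export
prior_set <- function(...) {
  priors <- list(...)
  if (length(priors) == 1L && is.list(priors[[1]]) && !inherits(priors[[1]], "score_map")) {
    priors <- priors[[1]]
  }
  if (length(priors) < 1L) stop("prior_set needs at least one prior", call. = FALSE)
  for (p in priors) {
    if (!inherits(p, "score_map") || p$kind != "prior") {
      stop("all elements must be score_maps of kind 'prior'", call. = FALSE)
    }
  }
  structure(priors, class = "prior_set")
}

#' Prior-corrected posterior map
#'
#' The mean over the M priors of the element-wise product with the
#' likelihood: `P = mean_m(L * pi_m)`. With all priors at 1 this is L
#' itself; a zero prior at a voxel removes that prior's contribution
#' there, suppressing artifactually low perfusion (e.g. non-GM signal).
#' P <= L always holds element-wise.
#'
#' @param L [score_map] of kind `"likelihood"`.
#' @param priors a [prior_set] (or single prior [score_map]).
#' @return [score_map] of kind `"posterior"`.
#' @export
posterior_map <- function(L, priors) {
  stopifnot(inherits(L, "score_map"), L$kind == "likelihood")
  if (inherits(priors, "score_map")) priors <- prior_set(priors)
  stopifnot(inherits(priors, "prior_set"))
  acc <- numeric(length(L$values))
  for (p in priors) {
    if (length(p$values) != length(L$values)) {
      stage_stop("comparison", "prior length ", length(p$values),
                 " != likelihood length ", length(L$values))
    }
    if (any(p$values < 0) || any(p$values > 1)) {
      stage_stop("comparison", "prior values outside [0, 1]")
    }
    acc <- acc + L$values * p$values
  }
  score_map(acc / length(priors), "posterior", L$subject_id)
}

#' Export a score map as a NIfTI volume
#'
#' Convenience wrapper over [delinearize()] + [write_nifti()] for visual
#' QC of CBF / T-score / likelihood / posterior panels.
#'
#' @param map a [score_map].
#' @param mask the [voxel_mask] it lives on.
#' @param path output `.nii`/`.nii.gz` path.
#' @param fill out-of-mask fill value.
#' @return `path`, invisibly.
#' @export
write_score_map <- function(map, mask, path, fill = 0) {
  write_nifti(delinearize(map$values, mask, fill = fill,
                          subject_id = map$subject_id), path)
}
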