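# End-to-end orchestration: post-process a cohort, fit the healthy model,
# build priors and posteriors, run the LOO threshold evaluation and the
# RBF classifier, accumulate regional counts and clinical correlations,
# and write a reproducible JSON report.

#' Pipeline configuration
#'
#' Defaults match the published operating point: smoothing sigma 2 voxels
#' with kernel extent 6, min-max feature scaling within the coverage mask,
#' coverage threshold 0.95, K = 20 predictive-prior components, t_w grid
#' 0.50..1.00 step 0.01 and t_b grid 0..5000 step 50.
#'
#' @param smoothing_sigma,smoothing_kernel see [smoothing_config()].
#' @param scaling `"minmax"` or `"global_mean"`.
#' @param coverage coverage threshold, see [coverage_mask()].
#' @param K predictive-prior components.
#' @param grid a [threshold_grid()].
#' @param gm_source `"subject"` (per-subject GM prior) or `"cohort_mean"`
#'   (mean HC GM map for everyone).
#' @param svm run the RBF classifier too.
#' @param seed RNG seed for any stochastic step.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(smoothing_sigma = 2, smoothing_kernel = 6,
                            scaling = "minmax", coverage = 0.95, K = 20,
                            grid = threshold_grid(), gm_source = "subject",
                            svm = TRUE, seed = 1) {
  stopifnot(gm_source %in% c("subject", "cohort_mean"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Keys mirror the [pipeline_config()] arguments (grid as `tw_min`, ...,
#' `tb_step`); missing keys fall back to the defaults.
#' @param path `.yaml`/`.yml`/`.json` file.
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  gridkeys <- intersect(names(raw), c("tw_min", "tw_max", "tw_step",
                                      "tb_min", "tb_max", "tb_step"))
  grid <- do.call(threshold_grid, raw[gridkeys])
  args <- raw[intersect(names(raw), setdiff(names(formals(pipeline_config)), "grid"))]
  do.call(pipeline_config, c(args, list(grid = grid)))
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("^\\[", msg)) stop(e) else stage_stop(stage, msg)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: coverage masking on raw volumes; smoothing + feature scaling +
#' linearization; healthy-model fit on all HCs (final model, for map
#' export); GM priors; full-data predictive prior (for map export only —
#' the evaluation refits it per fold); LOO threshold evaluation; RBF
#' classification of the held-out posteriors; regional accumulation at
#' the modal thresholds; clinical correlations over correctly classified
#' patients. Deterministic given (inputs, config, seed).
#'
#' @param volumes list of [volume3d] (clinical order) — CBF maps.
#' @param gm list of GM probability [volume3d] aligned with `volumes`.
#' @param clinical clinical table (path or data.frame).
#' @param atlas an [atlas_volume], or NULL to skip regional analysis.
#' @param config a [pipeline_config].
#' @param out_dir optional directory: report.json, surfaces and maps are
#'   written there.
#' @return object of class `perfcad_run`.
#' @export
run_pipeline <- function(volumes, gm, clinical, atlas = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  set.seed(config$seed)
  clinical <- read_clinical_table(clinical)
  .stage("volume_io", {
    if (length(volumes) != nrow(clinical)) stop("one volume per clinical row required")
    d <- dim(volumes[[1]]$data)
    for (v in volumes) if (!identical(dim(v$data), d)) {
      stop("shape mismatch for subject '", v$subject_id, "'")
    }
  })
  mask <- .stage("volume_io", coverage_mask(volumes, config$coverage))
  cohort <- .stage("preprocess", preprocess_cohort(
    volumes, clinical, mask,
    smoothing_config(config$smoothing_sigma, config$smoothing_kernel),
    config$scaling))
  model <- .stage("healthy_model", fit_healthy_model(cohort))
  gm_matrix <- .stage("comparison", {
    m <- t(vapply(gm, function(g) gm_prior(g, mask)$values, numeric(mask$J)))
    if (config$gm_source == "cohort_mean") {
      mu_gm <- colMeans(m[clinical$group == "HC", , drop = FALSE])
      m <- matrix(mu_gm, nrow(m), ncol(m), byrow = TRUE)
    }
    m
  })
  L_all <- .stage("comparison", t(vapply(seq_len(nrow(cohort$gamma)), function(i) {
    likelihood_map(cohort$gamma[i, ], model, cohort$subject_ids[i])$values
  }, numeric(mask$J))))
  pp_full <- .stage("predictive_prior", build_predictive_prior(
    regression_design(L_all, cohort$groups, cohort$subject_ids), K = config$K))
  loo <- .stage("discriminant", loo_evaluate(cohort, gm_matrix,
                                             K = config$K, grid = config$grid))
  svm_res <- if (isTRUE(config$svm)) {
    .stage("discriminant", svm_classify(loo$posteriors, cohort$groups))
  } else NULL
  regional <- correlations <- NULL
  if (!is.null(atlas)) {
    atlas <- .stage("regional", atlas_volume(atlas$labels, atlas$name_map, mask))
    hypo <- loo$posteriors >= loo$modal$tw
    regional <- .stage("regional", regional_report(hypo, atlas, mask, cohort$groups))
    correct_ad <- with(loo$folds, id[group == "AD" & predicted == "AD"])
    correlations <- if (length(correct_ad) >= 3L) {
      .stage("regional", clinical_correlations(
        setNames(loo$at_modal$counts, cohort$subject_ids), clinical,
        subset = correct_ad))
    } else NULL
  }
  run <- structure(list(
    config = config, mask_J = mask$J, mask = mask, model = model,
    predictive_prior = pp_full, loo = loo, svm = svm_res,
    regional = regional, correlations = correlations,
    input_hash = content_hash(vapply(volumes, function(v) sum(v$data), numeric(1)))
  ), class = "perfcad_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.perfcad_run <- function(x, ...) {
  cat("<perfcad_run> J =", x$mask_J, "voxels, input hash", x$input_hash, "\n")
  print(x$loo)
  if (!is.null(x$svm)) {
    cat(sprintf("  svm: accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
                x$svm$accuracy, x$svm$sensitivity, x$svm$specificity))
  }
  if (!is.null(x$correlations)) {
    cat("  correlations (correctly classified patients):\n")
    print(x$correlations, digits = 3)
  }
  invisible(x)
}

#' Serialize a run to a directory
#'
#' Writes `report.json` (config echo, LOO rates, modal thresholds, SVM
#' rates, regional summary, correlations, input hash) and the model maps
#' as NIfTI. The JSON is byte-stable for identical inputs/config/seed.
#'
#' @param run a `perfcad_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- run_report(run)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_healthy_model(run$model, run$mask, file.path(dir, "model"))
  write_score_map(run$predictive_prior, run$mask,
                  file.path(dir, "predictive_prior.nii.gz"))
  write.csv(run$loo$folds, file.path(dir, "loo_folds.csv"), row.names = FALSE)
  invisible(dir)
}

#' Plain-list report of a run (what report.json contains)
#' @param run a `perfcad_run`.
#' @return list ready for JSON serialization.
#' @export
run_report <- function(run) {
  cfg <- run$config
  list(
    config = list(smoothing_sigma = cfg$smoothing_sigma,
                  smoothing_kernel = cfg$smoothing_kernel,
                  scaling = cfg$scaling, coverage = cfg$coverage, K = cfg$K,
                  gm_source = cfg$gm_source, seed = cfg$seed),
    input_hash = run$input_hash,
    n_voxels = run$mask_J,
    loo = list(sensitivity = run$loo$sensitivity,
               specificity = run$loo$specificity,
               misclassification = run$loo$misclassification,
               modal_tw = run$loo$modal$tw, modal_tb = run$loo$modal$tb,
               modal_frequency = run$loo$modal$frequency,
               at_modal_sensitivity = run$loo$at_modal$sensitivity,
               at_modal_specificity = run$loo$at_modal$specificity),
    svm = if (!is.null(run$svm)) run$svm[c("accuracy", "sensitivity", "specificity")],
    regional = if (!is.null(run$regional)) run$regional$summary,
    correlations = run$correlations
  )
}

#' Classify one subject against a fitted model and priors
#'
#' The single-subject entry point: post-process the volume the same way
#' as the training cohort, compute its posterior under the supplied model
#' and priors, count hypo-perfused voxels at `t_w` and classify at `t_b`.
#'
#' @param volume the subject's CBF [volume3d].
#' @param gm the subject's GM probability [volume3d].
#' @param model a [healthy_model].
#' @param pp predictive prior [score_map] (fitted without this subject).
#' @param mask the analysis [voxel_mask].
#' @param t_w,t_b decision thresholds (defaults 0.86 / 200, the published
#'   operating point).
#' @param cfg [smoothing_config()].
#' @param scaling feature scaling method.
#' @param atlas optional [atlas_volume] for a per-region table.
#' @return list: `count`, `label`, `posterior` ([score_map]), optional
#'   `regions`.
#' @export
classify_volume <- function(volume, gm, model, pp, mask,
                            t_w = 0.86, t_b = 200,
                            cfg = smoothing_config(), scaling = "minmax",
                            atlas = NULL) {
  g <- linearize(feature_scale(gaussian_smooth(volume, cfg), mask, scaling), mask)
  L <- likelihood_map(g, model, volume$subject_id)
  P <- posterior_map(L, prior_set(gm = gm_prior(gm, mask), pp = pp))
  count <- count_hypoperfused(P, t_w)
  out <- list(count = count, label = classify_subject(count, t_b), posterior = P)
  if (!is.null(atlas)) {
    out$regions <- regional_counts(P$values >= t_w, atlas, mask)
  }
  out
}
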