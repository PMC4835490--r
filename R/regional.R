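# Atlas-based regional accumulation of hypo-perfused voxels and the
# clinical correlates of the hypo-perfused volume.

#' Labeled atlas volume on the analysis grid
#'
#' Integer labels (0 = background) pre-resampled to the analysis grid,
#' with a name per nonzero label. `coverage_ok` is the set of labels whose
#' voxels all fall inside the coverage mask — regions only partly covered
#' by the ASL signal are flagged and excluded from fraction summaries.
#'
#' @param labels integer 3D array.
#' @param name_map data.frame with columns `label`, `name` (optionally
#'   `lobe`).
#' @param mask optional [voxel_mask] used to compute `coverage_ok`.
#' @return object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, name_map, mask = NULL) {
  if (is.null(dim(labels)) || length(dim(labels)) != 3L) {
    stop("atlas labels must be a 3D array", call. = FALSE)
  }
  labels <- array(as.integer(labels), dim = dim(labels))
  present <- sort(unique(labels[labels != 0L]))
  name_map <- as.data.frame(name_map)
  stopifnot(all(c("label", "name") %in% names(name_map)))
  unnamed <- setdiff(present, name_map$label)
  if (length(unnamed)) stop("atlas labels without names: ", paste(unnamed, collapse = ", "), call. = FALSE)
  coverage_ok <- if (!is.null(mask)) {
    stopifnot(identical(dim(labels), mask$dim))
    present[vapply(present, function(l) all(mask$keep[labels == l]), logical(1))]
  } else present
  structure(list(labels = labels, name_map = name_map,
                 present = present, coverage_ok = coverage_ok),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat("<atlas_volume>", length(x$present), "regions on grid",
      paste(dim(x$labels), collapse = "x"), "(",
      length(x$coverage_ok), "fully covered )\n")
  invisible(x)
}

#' Read/write the atlas name map as TSV
#'
#' Columns `label`, `name`, optional `lobe`.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_atlas_names <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Per-region hypo-perfused voxel counts for one subject
#'
#' @param hypo_mask logical/0-1 vector over the mask (TRUE = voxel called
#'   hypo-perfused).
#' @param atlas an [atlas_volume] on the analysis grid.
#' @param mask the [voxel_mask].
#' @return data.frame: `label`, `name`, `count`, `covered`; plus a row
#'   `label = 0` ("background") holding hypo voxels outside every region,
#'   so counts sum exactly to the total.
#' @export
regional_counts <- function(hypo_mask, atlas, mask) {
  if (!identical(dim(atlas$labels), mask$dim)) {
    stage_stop("regional", "atlas grid does not match the analysis grid")
  }
  hypo_mask <- as.logical(hypo_mask)
  if (length(hypo_mask) != mask$J) {
    stage_stop("regional", "hypo mask length ", length(hypo_mask), " != J = ", mask$J)
  }
  lab_vec <- atlas$labels[mask$index]
  counts <- vapply(atlas$present, function(l) sum(hypo_mask & lab_vec == l), numeric(1))
  bg <- sum(hypo_mask & !(lab_vec %in% atlas$present))
  nm <- atlas$name_map$name[match(atlas$present, atlas$name_map$label)]
  data.frame(label = c(atlas$present, 0L),
             name = c(nm, "background"),
             count = c(counts, bg),
             covered = c(atlas$present %in% atlas$coverage_ok, NA),
             stringsAsFactors = FALSE)
}

#' Cohort-level regional report
#'
#' Accumulates per-subject regional counts, computes group means, region
#' fractions of the total hypo-perfused volume (two readings: mean of
#' per-subject fractions, and pooled voxel fraction), and between-group
#' tests.
#'
#' @param hypo_matrix N x J logical matrix (per-subject hypo calls).
#' @param atlas an [atlas_volume].
#' @param mask the [voxel_mask].
#' @param groups length-N HC/AD labels (AD subgroups collapsed).
#' @param test `"wilcox"` (default) or `"welch"`, see
#'   [group_region_test()].
#' @return object of class `regional_report`: `counts` (N x regions
#'   matrix), `summary` data.frame (per region: group means, fractions,
#'   p-value), `fraction_basis` note.
#' @export
regional_report <- function(hypo_matrix, atlas, mask, groups, test = "wilcox") {
  hypo_matrix <- as.matrix(hypo_matrix)
  counts <- t(apply(hypo_matrix, 1L, function(h) {
    rc <- regional_counts(h, atlas, mask)
    setNames(rc$count, rc$name)
  }))
  lab <- binary_group(groups)
  region <- colnames(counts)
  covered_names <- atlas$name_map$name[match(atlas$coverage_ok, atlas$name_map$label)]
  in_cov <- region %in% covered_names
  tot_per_subj <- rowSums(counts[, in_cov, drop = FALSE])
  frac_subject <- colMeans(counts[, in_cov, drop = FALSE] /
                             pmax(tot_per_subj, 1), na.rm = TRUE)
  frac_pooled <- colSums(counts[, in_cov, drop = FALSE]) /
    max(sum(counts[, in_cov]), 1)
  pvals <- group_region_test(counts, lab, method = test)
  summary <- data.frame(
    name = region,
    covered = in_cov,
    mean_hc = colMeans(counts[lab == "HC", , drop = FALSE]),
    mean_ad = colMeans(counts[lab == "AD", , drop = FALSE]),
    fraction_subject_mean = ifelse(in_cov, frac_subject[match(region, names(frac_subject))], NA),
    fraction_pooled = ifelse(in_cov, frac_pooled[match(region, names(frac_pooled))], NA),
    p_value = pvals[region],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(counts = counts, summary = summary,
                 fraction_basis = "fractions over fully covered regions only"),
            class = "regional_report")
}

#' @export
print.regional_report <- function(x, ...) {
  cat("<regional_report>", nrow(x$counts), "subjects x", ncol(x$counts), "regions\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Between-group test of regional counts
#'
#' Two-sided Mann-Whitney (rank-sum) test per region of HC vs AD counts
#' (robust for skewed counts; Welch t-test by flag). No multiplicity
#' correction by default; `bonferroni = TRUE` multiplies by the region
#' count.
#'
#' @param counts N x R matrix of per-subject regional counts.
#' @param groups length-N HC/AD labels.
#' @param method `"wilcox"` or `"welch"`.
#' @param bonferroni apply Bonferroni correction.
#' @return named vector of p-values.
#' @export
group_region_test <- function(counts, groups, method = c("wilcox", "welch"),
                              bonferroni = FALSE) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  lab <- binary_group(groups)
  if (sum(lab == "HC") < 2L || sum(lab == "AD") < 2L) {
    stage_stop("regional", "group test needs >= 2 subjects per group")
  }
  p <- apply(counts, 2L, function(v) {
    a <- v[lab == "AD"]; h <- v[lab == "HC"]
    if (length(unique(c(a, h))) == 1L) {
      warning("constant counts in both groups; p = 1")
      return(1)
    }
    if (method == "wilcox") {
      suppressWarnings(wilcox.test(a, h, exact = FALSE)$p.value)
    } else {
      t.test(a, h)$p.value
    }
  })
  if (bonferroni) p <- pmin(p * ncol(counts), 1)
  p
}

#' Correlations of the hypo-perfused volume with clinical covariates
#'
#' Spearman rank correlation (Pearson by flag) of per-subject hypo-voxel
#' counts with MMSE, age and education, over a caller-chosen subject
#' subset — conventionally the correctly classified patients.
#'
#' @param hypo_volume named per-subject counts (names = ids) or plain
#'   vector aligned with `clinical`.
#' @param clinical clinical data.frame (see [read_clinical_table()]).
#' @param subset optional ids to restrict to.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame: covariate, rho, p_value, n.
#' @export
clinical_correlations <- function(hypo_volume, clinical,
                                  subset = NULL,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  clinical <- read_clinical_table(clinical)
  if (!is.null(names(hypo_volume))) {
    clinical <- clinical[match(names(hypo_volume), clinical$id), , drop = FALSE]
  } else if (length(hypo_volume) != nrow(clinical)) {
    stage_stop("regional", "hypo_volume length does not match the clinical table")
  }
  if (!is.null(subset)) {
    keep <- clinical$id %in% subset
    clinical <- clinical[keep, , drop = FALSE]
    hypo_volume <- hypo_volume[keep]
  }
  out <- lapply(c("mmse", "age", "education"), function(cv) {
    v <- clinical[[cv]]
    ok <- !is.na(v) & !is.na(hypo_volume)
    if (sum(ok) < 3L) stage_stop("regional", "need >= 3 subjects with non-missing ", cv)
    if (length(unique(v[ok])) == 1L) {
      warning("constant covariate ", cv, "; correlation undefined")
      return(data.frame(covariate = cv, rho = NA_real_, p_value = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(cor.test(hypo_volume[ok], v[ok], method = method))
    data.frame(covariate = cv, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok))
  })
  do.call(rbind, out)
}
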