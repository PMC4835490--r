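# Two-threshold discriminant analysis: a voxel is hypo-perfused when its
# posterior probability reaches the within-subject threshold t_w; a
# subject is classified AD when its hypo-perfused voxel count exceeds the
# between-subjects threshold t_b. Both thresholds are chosen by discrete
# grid search minimizing the misclassification rate, under leave-one-out.
#
# Boundary conventions (declared, the literature gives none): the voxel
# test is inclusive (P >= t_w), the subject test strict (count > t_b).

#' Count hypo-perfused voxels
#'
#' @param P [score_map] of kind `"posterior"` (or a bare numeric vector).
#' @param t_w within-subject probability cutoff (inclusive).
#' @return integer count — the subject's "hypo-perfused volume".
#' @export
count_hypoperfused <- function(P, t_w = 0.86) {
  v <- if (inherits(P, "score_map")) {
    stopifnot(P$kind == "posterior")
    P$values
  } else P
  sum(v >= t_w)
}

#' Classify a subject from its hypo-perfused volume
#'
#' @param count hypo-perfused voxel count.
#' @param t_b between-subjects count cutoff (strict: AD iff count > t_b).
#' @return `"AD"` or `"HC"`.
#' @export
classify_subject <- function(count, t_b = 200) {
  ifelse(count > t_b, "AD", "HC")
}

#' Default threshold grids
#'
#' t_w in 0.50..1.00 step 0.01; t_b in 0..5000 step 50 (the published
#' evaluation ranges). Resolution is configurable.
#'
#' @param tw_min,tw_max,tw_step within-subject grid.
#' @param tb_min,tb_max,tb_step between-subjects grid.
#' @return list with `tw` and `tb` numeric vectors.
#' @export
threshold_grid <- function(tw_min = 0.5, tw_max = 1, tw_step = 0.01,
                           tb_min = 0, tb_max = 5000, tb_step = 50) {
  list(tw = seq(tw_min, tw_max, by = tw_step),
       tb = seq(tb_min, tb_max, by = tb_step))
}

#' Hypo-perfused counts over a t_w grid
#'
#' @param P_matrix N x J matrix of posterior values (rows = subjects).
#' @param tw_grid vector of t_w values.
#' @return N x length(tw_grid) matrix of counts.
#' @export
counts_over_grid <- function(P_matrix, tw_grid) {
  P_matrix <- as.matrix(P_matrix)
  out <- vapply(tw_grid, function(t) rowSums(P_matrix >= t),
                numeric(nrow(P_matrix)))
  matrix(out, nrow = nrow(P_matrix),
         dimnames = list(rownames(P_matrix), NULL))
}

#' Grid search of the two thresholds
#'
#' Evaluates sensitivity (AD called AD), specificity (HC called HC) and
#' misclassification rate ((FP+FN)/N) at every (t_w, t_b) cell, and picks
#' the cell minimizing misclassification. Ties are broken by (1) maximal
#' sensitivity + specificity, (2) smallest t_b, (3) largest t_w.
#'
#' @param counts_by_tw N x length(tw) count matrix from
#'   [counts_over_grid()].
#' @param labels true groups (HC/AD, or HC/AD_EA/AD_LA — collapsed).
#' @param grid a [threshold_grid()].
#' @return object of class `evaluation_surface`: matrices `sensitivity`,
#'   `specificity`, `misclassification` (t_w rows x t_b columns), grids,
#'   and `chosen` (t_w, t_b and its rates).
#' @export
grid_search <- function(counts_by_tw, labels, grid = threshold_grid()) {
  counts_by_tw <- as.matrix(counts_by_tw)
  lab <- binary_group(labels)
  if (length(unique(lab)) < 2L) stage_stop("discriminant", "grid search needs both classes")
  if (ncol(counts_by_tw) != length(grid$tw)) {
    stage_stop("discriminant", "counts_by_tw has ", ncol(counts_by_tw),
               " columns but the t_w grid has ", length(grid$tw))
  }
  is_ad <- lab == "AD"
  n_ad <- sum(is_ad); n_hc <- sum(!is_ad); n <- length(lab)
  ntw <- length(grid$tw); ntb <- length(grid$tb)
  sens <- spec <- misc <- matrix(NA_real_, ntw, ntb)
  for (i in seq_len(ntw)) {
    pred_ad <- outer(counts_by_tw[, i], grid$tb, ">")
    tp <- colSums(pred_ad[is_ad, , drop = FALSE])
    fp <- colSums(pred_ad[!is_ad, , drop = FALSE])
    sens[i, ] <- tp / n_ad
    spec[i, ] <- (n_hc - fp) / n_hc
    misc[i, ] <- (fp + (n_ad - tp)) / n
  }
  # tie-break chain: min misc, max sens+spec, min t_b, max t_w
  tb_idx <- rep(seq_len(ntb), each = ntw)
  tw_idx <- rep(seq_len(ntw), times = ntb)
  ord <- order(as.vector(misc), -(as.vector(sens) + as.vector(spec)),
               grid$tb[tb_idx], -grid$tw[tw_idx])
  best <- ord[1]
  chosen <- list(tw = grid$tw[tw_idx[best]], tb = grid$tb[tb_idx[best]],
                 sensitivity = sens[best], specificity = spec[best],
                 misclassification = misc[best])
  structure(list(sensitivity = sens, specificity = spec,
                 misclassification = misc, tw = grid$tw, tb = grid$tb,
                 chosen = chosen, n = n),
            class = "evaluation_surface")
}

#' @export
print.evaluation_surface <- function(x, ...) {
  cat("<evaluation_surface>", length(x$tw), "x", length(x$tb), "cells;",
      sprintf("chosen t_w = %.2f, t_b = %d: sens %.3f, spec %.3f, misc %.3f\n",
              x$chosen$tw, as.integer(x$chosen$tb), x$chosen$sensitivity,
              x$chosen$specificity, x$chosen$misclassification))
  invisible(x)
}

# shared per-fold computation: model, likelihoods, priors, posteriors
.fold_posteriors <- function(cohort, gm_matrix, holdout, K, pp_rescale = "minmax") {
  ids <- cohort$subject_ids
  model <- fit_healthy_model(cohort, exclude = holdout)
  L <- t(vapply(seq_along(ids), function(i) {
    pnorm((cohort$gamma[i, ] - model$mu) / model$sigma, lower.tail = FALSE)
  }, numeric(ncol(cohort$gamma))))
  rownames(L) <- ids
  train <- setdiff(ids, holdout)
  design <- regression_design(L[train, , drop = FALSE],
                              cohort$groups[match(train, ids)], train)
  pp <- build_predictive_prior(design, K = K, rescale = pp_rescale)
  P <- (L * gm_matrix + sweep(L, 2L, pp$values, "*")) / 2
  list(model = model, L = L, pp = pp, P = P)
}

#' Leave-one-out evaluation of the threshold classifier
#'
#' For each held-out subject: the healthy model is refit without it (if it
#' is an HC), the predictive prior is refit without it, its posterior is
#' computed under that fold's model, thresholds are chosen by
#' [grid_search()] on the remaining subjects' posteriors, and the held-out
#' subject is classified. The pooled confusion matrix over folds gives the
#' reported rates; the modal (t_w, t_b) pair over folds is reported, as
#' are the training-set rates at the modal pair (the two readings of
#' "reported rates" both appear in practice).
#'
#' @param cohort a [cohort_matrix] (post-processed).
#' @param gm_matrix N x J matrix of per-subject GM prior values (rows
#'   aligned with the cohort), or a single length-J vector used for all
#'   subjects.
#' @param K predictive-prior components (default 20, capped per fold).
#' @param grid a [threshold_grid()].
#' @return object of class `loo_result`: `folds` data.frame (id, group,
#'   tw, tb, count, predicted), pooled `sensitivity`, `specificity`,
#'   `misclassification`, `modal` thresholds (+ frequency), training-set
#'   rates at the modal pair, and `posteriors` (N x J held-out posterior
#'   matrix, for downstream classifiers and regional analysis).
#' @export
loo_evaluate <- function(cohort, gm_matrix, K = 20, grid = threshold_grid()) {
  ids <- cohort$subject_ids
  lab <- binary_group(cohort$groups)
  if (sum(lab == "HC") < 2L || sum(lab == "AD") < 2L) {
    stage_stop("discriminant", "LOO needs >= 2 HC and >= 2 AD subjects")
  }
  if (is.vector(gm_matrix) && is.null(dim(gm_matrix))) {
    gm_matrix <- matrix(gm_matrix, nrow = length(ids), ncol = length(gm_matrix), byrow = TRUE)
  }
  gm_matrix <- as.matrix(gm_matrix)
  stopifnot(nrow(gm_matrix) == length(ids), ncol(gm_matrix) == ncol(cohort$gamma))
  folds <- data.frame(id = ids, group = as.character(lab), tw = NA_real_,
                      tb = NA_real_, count = NA_real_, predicted = NA_character_,
                      stringsAsFactors = FALSE)
  posteriors <- matrix(NA_real_, length(ids), ncol(cohort$gamma),
                       dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    hold <- ids[i]
    train <- setdiff(ids, hold)
    train_lab <- lab[match(train, ids)]
    if (length(unique(train_lab)) < 2L) {
      stage_stop("discriminant", "fold ", hold, " has a single-class training set")
    }
    fp <- .fold_posteriors(cohort, gm_matrix, hold, K)
    cnt_train <- counts_over_grid(fp$P[train, , drop = FALSE], grid$tw)
    surf <- grid_search(cnt_train, train_lab, grid)
    posteriors[i, ] <- fp$P[hold, ]
    folds$tw[i] <- surf$chosen$tw
    folds$tb[i] <- surf$chosen$tb
    folds$count[i] <- count_hypoperfused(fp$P[hold, ], surf$chosen$tw)
    folds$predicted[i] <- classify_subject(folds$count[i], surf$chosen$tb)
  }
  is_ad <- folds$group == "AD"
  tp <- sum(is_ad & folds$predicted == "AD")
  tn <- sum(!is_ad & folds$predicted == "HC")
  pair <- paste(folds$tw, folds$tb)
  modal_pair <- names(sort(table(pair), decreasing = TRUE))[1]
  modal <- as.numeric(strsplit(modal_pair, " ")[[1]])
  # second reading of "reported rates": all held-out posteriors thresholded
  # at the modal pair
  cnt_modal <- apply(posteriors, 1L, count_hypoperfused, t_w = modal[1])
  pred_modal <- classify_subject(cnt_modal, modal[2])
  structure(list(
    folds = folds,
    sensitivity = tp / sum(is_ad),
    specificity = tn / sum(!is_ad),
    misclassification = 1 - (tp + tn) / nrow(folds),
    modal = list(tw = modal[1], tb = modal[2],
                 frequency = max(table(pair)) / nrow(folds)),
    at_modal = list(
      sensitivity = mean(pred_modal[is_ad] == "AD"),
      specificity = mean(pred_modal[!is_ad] == "HC"),
      counts = cnt_modal),
    posteriors = posteriors
  ), class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> %d folds: sensitivity %.3f, specificity %.3f, misclassification %.3f\n",
              nrow(x$folds), x$sensitivity, x$specificity, x$misclassification))
  cat(sprintf("  modal thresholds t_w = %.2f, t_b = %d (frequency %.2f)\n",
              x$modal$tw, as.integer(x$modal$tb), x$modal$frequency))
  invisible(x)
}
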