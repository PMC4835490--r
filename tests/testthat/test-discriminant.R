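test_that("voxel and subject threshold conventions are as declared", {
  P <- score_map(c(0.9, 0.86, 0.5, 0.99), "posterior", "s")
  expect_equal(count_hypoperfused(P, 0.86), 3)       # inclusive boundary
  expect_equal(count_hypoperfused(score_map(rep(0, 5), "posterior"), 0.86), 0)
  expect_equal(classify_subject(250, 200), "AD")
  expect_equal(classify_subject(200, 200), "HC")     # strict boundary
  expect_equal(classify_subject(0, 0), "HC")
  # count is non-increasing in t_w
  v <- runif(200)
  tws <- seq(0.5, 1, 0.05)
  cnts <- vapply(tws, function(t) count_hypoperfused(v, t), numeric(1))
  expect_true(all(diff(cnts) <= 0))
})

test_that("grid_search evaluates the surface and applies the tie-break chain", {
  grid <- threshold_grid()
  tw_one <- threshold_grid(tw_min = 0.86, tw_max = 0.86)
  counts <- matrix(c(10, 20, 300, 400), 4, length(tw_one$tw))
  labels <- c("HC", "HC", "AD_LA", "AD_LA")
  surf <- grid_search(counts, labels, tw_one)
  expect_equal(surf$chosen$misclassification, 0)
  # every t_b in [20, 300) separates; smallest grid value above 20 wins
  expect_equal(surf$chosen$tb, 50)
  expect_equal(surf$chosen$sensitivity, 1)
  expect_equal(surf$chosen$specificity, 1)
  # t_b = 0 with all counts > 0: everything called AD
  i0 <- which(surf$tb == 0)
  expect_equal(surf$sensitivity[1, i0], 1)
  expect_equal(surf$specificity[1, i0], 0)
  # t_b above the max count: everything called HC
  iN <- which(surf$tb == 5000)
  expect_equal(surf$sensitivity[1, iN], 0)
  expect_equal(surf$specificity[1, iN], 1)
  # misclassification consistent with the confusion counts
  expect_equal(surf$misclassification[1, i0], 0.5)
  expect_error(grid_search(counts, rep("HC", 4), tw_one), "both classes")
})

test_that("surfaces are monotone in t_b and internally consistent", {
  set.seed(41)
  P <- matrix(runif(30 * 400)^2, 30, 400)
  labels <- rep(c("HC", "AD_LA"), 15)
  grid <- threshold_grid(tb_max = 500, tb_step = 25)
  counts <- counts_over_grid(P, grid$tw)
  surf <- grid_search(counts, labels, grid)
  for (i in seq_along(grid$tw)) {
    expect_true(all(diff(surf$sensitivity[i, ]) <= 0))
    expect_true(all(diff(surf$specificity[i, ]) >= 0))
  }
  n_ad <- 15; n_hc <- 15
  mischeck <- ((1 - surf$sensitivity) * n_ad + (1 - surf$specificity) * n_hc) / 30
  expect_equal(surf$misclassification, mischeck, tolerance = 1e-12)
})

test_that("thresholds are recovered from well-separated planted counts", {
  cnt <- generate_counts(n_hc = 20, n_ad = 20, rate_hc = 50, rate_ad = 500, seed = 7)
  expect_gt(min(cnt$count[cnt$group != "HC"]), max(cnt$count[cnt$group == "HC"]))
  grid <- threshold_grid(tw_min = 0.86, tw_max = 0.86, tb_max = 1000, tb_step = 10)
  counts <- matrix(cnt$count, ncol = 1)
  surf <- grid_search(counts, cnt$group, grid)
  expect_equal(surf$chosen$misclassification, 0)
  expect_gte(surf$chosen$tb, max(cnt$count[cnt$group == "HC"]))
  expect_lt(surf$chosen$tb, min(cnt$count[cnt$group != "HC"]))
})

make_loo_cohort <- function(effect, seed = 42, n_hc = 10, n_ad = 10,
                            grid = c(16, 16, 10)) {
  spec <- synthetic_cohort_spec(grid = grid, n_hc = n_hc, n_ad = n_ad,
                                effect = effect, seed = seed)
  co <- generate_cohort(spec)
  mask <- coverage_mask(co$volumes, 0.95)
  # keep the physical kernel width: sigma 2 voxels on the 24-grid is ~1.33
  # voxels on this downsampled 16-grid
  cohort <- preprocess_cohort(co$volumes, co$clinical, mask,
                              smoothing_config(2 * grid[1] / 24, 6))
  gm <- t(vapply(co$gm, function(g) gm_prior(g, mask)$values, numeric(mask$J)))
  list(cohort = cohort, gm = gm, mask = mask, truth = co$truth, clinical = co$clinical)
}

test_that("LOO evaluation separates a strongly lesioned cohort and not a null one", {
  # t_b resolution matched to this reduced world: a 16x16x10 toy brain has
  # ~1.4e3 analyzable voxels, so counts live well below the clinical-scale
  # 0..5000 grid
  grid <- threshold_grid(tb_max = 800, tb_step = 10)
  planted <- make_loo_cohort(effect = 0.7)
  res <- loo_evaluate(planted$cohort, planted$gm, grid = grid)
  expect_gte(res$sensitivity, 0.9)
  expect_gte(res$specificity, 0.9)
  # per-fold thresholds concentrate on the planted cohort
  expect_gt(res$modal$frequency, 0.5)
  # determinism of the whole evaluation
  res2 <- loo_evaluate(planted$cohort, planted$gm, grid = grid)
  expect_identical(res$folds, res2$folds)
  expect_identical(res$posteriors, res2$posteriors)

  null <- make_loo_cohort(effect = 1.0)
  res0 <- loo_evaluate(null$cohort, null$gm, grid = grid)
  expect_gte(res0$misclassification, 0.2)   # chance-level behaviour
  expect_lte(res0$misclassification, 0.8)
})

test_that("loo_evaluate enforces its preconditions", {
  planted <- make_loo_cohort(effect = 0.7, n_hc = 4, n_ad = 4, grid = c(12, 12, 8))
  co <- planted$cohort
  bad <- cohort_matrix(co$gamma, co$subject_ids,
                       c(rep("HC", 7), "AD_LA"), co$mask)
  expect_error(loo_evaluate(bad, planted$gm), ">= 2 HC and >= 2 AD")
})

test_that("RBF max-margin classifier beats thresholds on separable data, is chance on noise", {
  set.seed(43)
  n <- 20; J <- 40
  X <- matrix(rnorm(n * J, 0.5, 0.05), n, J)
  X[(n / 2 + 1):n, 1:10] <- X[(n / 2 + 1):n, 1:10] + 0.3
  labels <- rep(c("HC", "AD_LA"), each = n / 2)
  res <- svm_classify(X, labels)
  expect_gte(res$accuracy, 0.9)
  # duplicated cohort: identical pooled rates (determinism)
  res2 <- svm_classify(X, labels)
  expect_identical(res$predicted, res2$predicted)

  set.seed(44)
  perm_labels <- sample(labels)
  res0 <- svm_classify(X, perm_labels)
  # no spurious skill on permuted labels; LOO is pessimistic at chance (the
  # held-out subject's class is under-represented in training), so accuracy
  # can fall well below 0.5 — the check is the absence of skill
  expect_lte(res0$accuracy, 0.75)
  expect_error(svm_classify(X, rep("HC", n)), "single-class")
})
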