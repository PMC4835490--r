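test_that("spec validation rejects impossible worlds", {
  expect_error(synthetic_cohort_spec(effect = 0), "effect")
  expect_error(synthetic_cohort_spec(effect = 1.2), "effect")
  expect_error(synthetic_cohort_spec(noise_sd = -1), "SDs")
  expect_error(synthetic_cohort_spec(lesion_extent = 0), "lesion_extent")
  expect_error(synthetic_cohort_spec(n_hc = 1), "n_hc")
})

test_that("the toy atlas has the promised structure", {
  atlas <- toy_atlas()
  expect_s3_class(atlas, "atlas_volume")
  expect_setequal(atlas$present, 1:5)
  dis <- attr(atlas, "disease_labels")
  expect_identical(dis, c(2L, 4L))
  # two disease regions of usable size, GM structures bounded by WM/background
  expect_gt(sum(atlas$labels %in% dis), 600)
  expect_gt(sum(atlas$labels == 2L), sum(atlas$labels == 4L))  # parietal > limbic
  expect_gt(sum(atlas$labels == 5L), 2000)                     # WM matrix
  expect_gt(sum(atlas$labels == 0L), 2000)                     # background
})

test_that("same seed gives bit-identical cohorts; different seeds differ", {
  spec <- synthetic_cohort_spec(grid = c(12, 12, 8), n_hc = 3, n_ad = 3, seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(lapply(a$volumes, `[[`, "data"), lapply(b$volumes, `[[`, "data"))
  expect_identical(a$clinical, b$clinical)
  c3 <- generate_cohort(synthetic_cohort_spec(grid = c(12, 12, 8), n_hc = 3, n_ad = 3, seed = 10))
  expect_false(identical(a$volumes[[1]]$data, c3$volumes[[1]]$data))
})

test_that("generator moments match the spec within Monte-Carlo error", {
  spec <- synthetic_cohort_spec(n_hc = 120, n_ad = 2, seed = 13,
                                grid = c(16, 16, 8))
  co <- generate_cohort(spec)
  atlas <- co$atlas
  gm_idx <- which(atlas$labels %in% 1:4)
  wm_idx <- which(atlas$labels == 5L)
  hc_ids <- co$clinical$id[co$clinical$group == "HC"]
  gm_means <- vapply(hc_ids, function(id) mean(co$volumes[[id]]$data[gm_idx]), numeric(1))
  wm_means <- vapply(hc_ids, function(id) mean(co$volumes[[id]]$data[wm_idx]), numeric(1))
  # region means: GM-like 60, WM-like 20; SE of the cohort mean ~ subject_sd/sqrt(120)
  expect_equal(mean(gm_means), 60, tolerance = 0.05)
  expect_equal(mean(wm_means), 20, tolerance = 0.15)
  # between-subject spread dominated by the global offset (SD 8)
  expect_equal(sd(gm_means), 8, tolerance = 0.25)
  # voxel noise SD ~ 6 after removing the subject offset
  id1 <- hc_ids[1]
  resid <- co$volumes[[id1]]$data[gm_idx] - gm_means[1]
  expect_equal(sd(resid), 6, tolerance = 0.1)
})

test_that("planted lesions reduce disease-region CBF by the stated fraction", {
  co <- generate_cohort(synthetic_cohort_spec())   # defaults: effect .7, 30+30, seed 42
  les <- co$truth$lesion_index
  grp <- co$clinical$group
  mean_in <- vapply(co$clinical$id, function(id) mean(co$volumes[[id]]$data[les]), numeric(1))
  drop <- 1 - mean(mean_in[grp != "HC"]) / mean(mean_in[grp == "HC"])
  expect_equal(drop, 0.3, tolerance = 0.02 / 0.3)  # within +-2 points of 30%
  # effect 1.0 leaves groups exchangeable
  co0 <- generate_cohort(synthetic_cohort_spec(effect = 1.0, effect_sd = 0,
                                               n_hc = 30, n_ad = 30, seed = 42))
  mean_in0 <- vapply(co0$clinical$id, function(id) mean(co0$volumes[[id]]$data[les]), numeric(1))
  expect_lt(abs(mean(mean_in0[grp != "HC"]) - mean(mean_in0[grp == "HC"])), 2 * 8 / sqrt(15))
  expect_true(all(vapply(co0$truth$subjects, function(t) t$burden, numeric(1)) == 0))
})

test_that("ground truth, GM maps and clinical covariates are coherent", {
  co <- generate_cohort(synthetic_cohort_spec(grid = c(16, 16, 8), n_hc = 15,
                                              n_ad = 15, seed = 21))
  grp <- co$clinical$group
  # MMSE inversely coupled to burden: AD clearly below HC
  expect_gt(mean(co$clinical$mmse[grp == "HC"]), 28)
  expect_lt(mean(co$clinical$mmse[grp != "HC"]), 26)
  burdens <- vapply(co$truth$subjects, function(t) t$burden, numeric(1))
  expect_true(all(burdens[grp == "HC"] == 0))
  expect_true(all(burdens[grp != "HC"] > 0))
  # late-onset patients clearly older than controls (early-onset younger),
  # echoing a clinic cohort's age structure
  expect_gt(mean(co$clinical$age[grp == "AD_LA"]),
            mean(co$clinical$age[grp == "HC"]) + 3)
  expect_lt(mean(co$clinical$age[grp == "AD_EA"]),
            mean(co$clinical$age[grp == "HC"]))
  # GM maps near 1 in GM structures, near 0 in WM
  gm1 <- co$gm[[1]]$data
  expect_gt(mean(gm1[co$atlas$labels %in% 1:4]), 0.9)
  expect_lt(mean(gm1[co$atlas$labels == 5L]), 0.1)
  expect_true(all(gm1 >= 0 & gm1 <= 1))
  # lesion extent < 1 subsamples the disease regions
  co2 <- generate_cohort(synthetic_cohort_spec(grid = c(16, 16, 8), n_hc = 3,
                                               n_ad = 3, lesion_extent = 0.5, seed = 3))
  n_les <- vapply(co2$truth$subjects[co2$clinical$group != "HC"],
                  function(t) length(t$lesion), numeric(1))
  expect_equal(unname(n_les), rep(round(0.5 * length(co2$truth$lesion_index)), 3))
})

test_that("generate_counts draws labeled class-specific counts", {
  cnt <- generate_counts(n_hc = 20, n_ad = 20, rate_hc = 50, rate_ad = 500, seed = 5)
  expect_equal(nrow(cnt), 40)
  expect_gt(min(cnt$count[cnt$group != "HC"]), max(cnt$count[cnt$group == "HC"]))
  # equal rates: overlapping distributions
  eq <- generate_counts(rate_hc = 100, rate_ad = 100, seed = 6)
  expect_lt(abs(mean(eq$count[eq$group == "HC"]) - mean(eq$count[eq$group != "HC"])), 15)
  # zero rate -> all zeros
  expect_true(all(generate_counts(rate_hc = 0, seed = 7)$count[1:20] == 0))
  # negative-binomial option overdisperses
  nb <- generate_counts(n_hc = 200, n_ad = 2, rate_hc = 100, size = 2, seed = 8)
  expect_gt(var(nb$count[nb$group == "HC"]), 150)
  expect_identical(generate_counts(seed = 9), generate_counts(seed = 9))
})
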