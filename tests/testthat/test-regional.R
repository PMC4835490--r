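make_atlas <- function(d = c(6, 6, 4), n_regions = 3, seed = 51, mask = NULL) {
  set.seed(seed)
  labels <- array(sample(0:n_regions, prod(d), TRUE), d)
  nm <- data.frame(label = seq_len(n_regions),
                   name = paste0("region", seq_len(n_regions)))
  atlas_volume(labels, nm, mask = mask)
}

test_that("regional_counts accumulates per label with exact conservation", {
  d <- c(6, 6, 4)
  mask <- full_mask(d)
  atlas <- make_atlas(d, mask = mask)
  lab_vec <- atlas$labels[mask$index]

  # hypo mask entirely inside one label
  h <- lab_vec == 2
  rc <- regional_counts(h, atlas, mask)
  expect_equal(rc$count[rc$label == 2], sum(h))
  expect_equal(sum(rc$count[rc$label != 2]), 0)

  # empty mask -> all zeros
  expect_true(all(regional_counts(rep(FALSE, mask$J), atlas, mask)$count == 0))

  # split 60/40 between two labels
  idx1 <- which(lab_vec == 1)[1:12]
  idx3 <- which(lab_vec == 3)[1:8]
  h2 <- rep(FALSE, mask$J); h2[c(idx1, idx3)] <- TRUE
  rc2 <- regional_counts(h2, atlas, mask)
  expect_equal(rc2$count[rc2$label == 1], 12)
  expect_equal(rc2$count[rc2$label == 3], 8)
  expect_error(regional_counts(h2, make_atlas(c(5, 6, 4)), mask), "grid")
})

test_that("region + background counts conserve the total over random cases", {
  set.seed(52)
  for (rep in 1:50) {
    d <- c(sample(4:8, 1), sample(4:8, 1), sample(2:5, 1))
    mask <- voxel_mask(array(runif(prod(d)) > 0.3, d))
    atlas <- make_atlas(d, n_regions = sample(2:5, 1), seed = 52 + rep, mask = mask)
    h <- runif(mask$J) > 0.5
    rc <- regional_counts(h, atlas, mask)
    expect_equal(sum(rc$count), sum(h))
  }
})

test_that("coverage_ok flags regions not fully inside the mask", {
  d <- c(4, 4, 2)
  keep <- array(TRUE, d); keep[1, 1, 1] <- FALSE
  mask <- voxel_mask(keep)
  labels <- array(2L, d); labels[1, 1, 1] <- 1L; labels[1, 2, 1] <- 1L
  atlas <- atlas_volume(labels, data.frame(label = 1:2, name = c("a", "b")), mask)
  expect_identical(atlas$coverage_ok, 2L)
  rc <- regional_counts(rep(TRUE, mask$J), atlas, mask)
  expect_false(rc$covered[rc$label == 1])
  expect_true(rc$covered[rc$label == 2])
})

test_that("group_region_test: rank-sum behaviour, invariance, degenerate cases", {
  set.seed(53)
  n <- 15
  groups <- rep(c("HC", "AD_LA"), each = n)
  counts <- cbind(parietal = c(rpois(n, 30), rpois(n, 300)),
                  frontal = rpois(2 * n, 50))
  p <- group_region_test(counts, groups)
  expect_lt(p[["parietal"]], 0.001)
  expect_gt(p[["frontal"]], 0.01)
  # rank-based: invariant to monotone transforms
  p_t <- group_region_test(sqrt(counts), groups)
  expect_equal(p, p_t, ignore_attr = TRUE)
  # constant counts in both groups -> p = 1 with warning
  expect_warning(p1 <- group_region_test(cbind(z = rep(3, 2 * n)), groups), "constant")
  expect_equal(unname(p1), 1)
  expect_error(group_region_test(counts, c("HC", rep("AD_LA", 2 * n - 1))),
               ">= 2 subjects")
  # Welch flag and Bonferroni behave
  pw <- group_region_test(counts, groups, method = "welch")
  expect_lt(pw[["parietal"]], 0.001)
  pb <- group_region_test(counts, groups, bonferroni = TRUE)
  expect_equal(unname(pb), unname(pmin(p * 2, 1)))
})

test_that("regional_report aggregates counts, fractions and tests", {
  d <- c(6, 6, 4)
  mask <- full_mask(d)
  atlas <- make_atlas(d, mask = mask)
  lab_vec <- atlas$labels[mask$index]
  n <- 12
  groups <- rep(c("HC", "AD_LA"), each = n / 2)
  set.seed(54)
  hypo <- t(vapply(seq_len(n), function(i) {
    if (groups[i] == "HC") rep(FALSE, mask$J)
    else lab_vec == 2 & runif(mask$J) > 0.3
  }, logical(mask$J)))
  # lesion-free regions have constant zero counts in both groups, which
  # regional_report's test stage legitimately warns about
  rep_out <- suppressWarnings(regional_report(hypo, atlas, mask, groups))
  expect_s3_class(rep_out, "regional_report")
  s <- rep_out$summary
  expect_equal(sum(s$fraction_pooled[s$covered], na.rm = TRUE), 1, tolerance = 1e-12)
  expect_gt(s$mean_ad[s$name == "region2"], s$mean_hc[s$name == "region2"])
  expect_lt(s$p_value[s$name == "region2"], 0.01)
})

test_that("clinical correlations: perfect inverse, null, and preconditions", {
  clin <- data.frame(id = sprintf("s%02d", 1:10), group = "AD_LA",
                     age = seq(60, 78, 2), mmse = seq(28, 10, -2),
                     education = rep(12, 10), gender = rep("F", 10))
  counts <- setNames(seq(100, 1000, 100), clin$id)  # strictly increasing
  expect_warning(cc <- clinical_correlations(counts, clin), "constant covariate")
  expect_equal(cc$rho[cc$covariate == "mmse"], -1)
  expect_true(is.na(cc$rho[cc$covariate == "education"]))

  # independent covariate: |rho| small at n = 50
  set.seed(55)
  clin2 <- data.frame(id = sprintf("s%02d", 1:50), group = "AD_LA",
                      age = runif(50, 55, 85), mmse = sample(10:30, 50, TRUE),
                      education = sample(8:20, 50, TRUE),
                      gender = sample(c("F", "M"), 50, TRUE))
  counts2 <- setNames(sample(1:2000, 50), clin2$id)
  cc2 <- clinical_correlations(counts2, clin2)
  expect_lt(abs(cc2$rho[cc2$covariate == "mmse"]), 0.3)

  # subsetting restricts the computation
  cc3 <- clinical_correlations(counts2, clin2, subset = clin2$id[1:20])
  expect_equal(cc3$n[1], 20)
  expect_error(clinical_correlations(counts[1:2], clin[1:2, ]), ">= 3")
})
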