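# Synthetic cohort generator. The phantom emulates the statistical
# structure the pipeline assumes: region-structured baseline perfusion
# (GM-like structures embedded in a WM matrix inside an ellipsoidal
# brain), additive between-subject and voxel noise, disease-specific
# multiplicative hypo-perfusion concentrated in two designated "disease"
# regions (parietal- and limbic-like), GM probability maps, and clinical
# covariates whose MMSE is inversely coupled to lesion burden.

#' Synthetic cohort specification
#'
#' Defaults are the stated world every seeded test runs in: 24 x 24 x 12
#' grid, GM baseline 60 and WM baseline 20 ml/100g/min, between-subject
#' SD 8, voxel noise SD 6, lesion effect 0.70 (a 30% CBF reduction),
#' full lesion extent, 30 + 30 subjects, seed 42. `effect_sd` jitters the
#' per-subject severity so lesion burden varies across AD subjects (and
#' MMSE can couple to it); `mmse_coupling = NULL` auto-calibrates so the
#' default severity costs about 7 MMSE points (healthy ~29.5 vs AD ~22).
#'
#' @param grid integer length-3 grid shape.
#' @param gm_cbf,wm_cbf baseline CBF (ml/100g/min) in GM-like and WM-like
#'   tissue.
#' @param subject_sd SD of the per-subject global offset.
#' @param noise_sd SD of the additive voxel noise.
#' @param effect multiplicative lesion effect in (0, 1]; 1 = no lesion.
#' @param effect_sd per-subject severity jitter SD.
#' @param lesion_extent fraction of disease-region voxels lesioned per AD
#'   subject.
#' @param n_hc,n_ad group sizes.
#' @param mmse_coupling MMSE points lost per unit lesion burden (burden =
#'   sum over lesioned voxels of 1 - effect); NULL = auto.
#' @param seed RNG seed.
#' @return object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(grid = c(24, 24, 12),
                                  gm_cbf = 60, wm_cbf = 20,
                                  subject_sd = 8, noise_sd = 6,
                                  effect = 0.70, effect_sd = 0.06,
                                  lesion_extent = 1.0,
                                  n_hc = 30, n_ad = 30,
                                  mmse_coupling = NULL,
                                  seed = 42) {
  stopifnot(length(grid) == 3L, all(grid >= 8L))
  if (!(subject_sd > 0 && noise_sd > 0)) stop("SDs must be > 0", call. = FALSE)
  if (!(effect > 0 && effect <= 1)) stop("effect must lie in (0, 1]", call. = FALSE)
  if (!(lesion_extent > 0 && lesion_extent <= 1)) stop("lesion_extent must lie in (0, 1]", call. = FALSE)
  if (n_hc < 2L || n_ad < 1L) stop("need n_hc >= 2 and n_ad >= 1", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_cohort_spec")
}

# ellipsoid membership on an integer grid
.ellipsoid <- function(grid, center, radii, power = 2) {
  x <- (seq_len(grid[1]) - center[1]) / radii[1]
  y <- (seq_len(grid[2]) - center[2]) / radii[2]
  z <- (seq_len(grid[3]) - center[3]) / radii[3]
  d <- outer(outer(abs(x)^power, abs(y)^power, "+"), abs(z)^power, "+")
  array(d <= 1, dim = grid)
}

#' Toy brain atlas
#'
#' Four GM-like ellipsoidal structures — frontal (1), parietal (2),
#' temporal (3), limbic (4) — embedded in a WM matrix (5) inside a
#' box-ish superellipsoid brain; 0 = background. Parietal and limbic are
#' the designated disease regions. GM structures are bounded by WM/
#' background, as cortical parcels are, so smoothing bleed from a lesion
#' lands in low-GM-probability tissue.
#'
#' @param grid integer length-3 grid shape (scaled from the 24 x 24 x 12
#'   reference layout).
#' @return an [atlas_volume] with a `disease_labels` attribute (c(2, 4)).
#' @export
toy_atlas <- function(grid = c(24, 24, 12)) {
  s <- grid / c(24, 24, 12)   # scale factors from the reference layout
  ctr <- function(p) p * s
  rad <- function(r) r * s
  labels <- array(0L, dim = grid)
  brain <- .ellipsoid(grid, ctr(c(12.5, 12.5, 6.5)), rad(c(11, 11, 5.3)), power = 4)
  labels[brain] <- 5L
  blobs <- list(
    list(1L, c(12.5, 6.5, 6.5),  c(6.0, 3.6, 3.6)),   # frontal
    list(3L, c(17.5, 16.0, 6.5), c(4.2, 4.2, 3.8)),   # temporal
    list(2L, c(7.0, 16.5, 6.5),  c(5.8, 5.4, 4.6)),   # parietal (disease)
    list(4L, c(13.0, 13.0, 6.5), c(3.8, 3.6, 3.4))    # limbic (disease)
  )
  for (b in blobs) {
    inside <- .ellipsoid(grid, ctr(b[[2]]), rad(b[[3]])) & brain
    labels[inside] <- b[[1]]
  }
  nm <- data.frame(label = 1:5,
                   name = c("frontal", "parietal", "temporal", "limbic", "white_matter"),
                   lobe = c("frontal", "parietal", "temporal", "limbic", "wm"),
                   stringsAsFactors = FALSE)
  out <- atlas_volume(labels, nm)
  attr(out, "disease_labels") <- c(2L, 4L)
  out
}

#' Generate a synthetic cohort
#'
#' Per subject: `volume = baseline + offset + noise` inside the brain
#' (0 outside), with `offset ~ N(0, subject_sd)` shared across voxels and
#' `noise ~ N(0, noise_sd)` per voxel; for AD subjects the composed value
#' at lesioned disease-region voxels is multiplied by that subject's
#' severity (`effect` jittered by `effect_sd`, clamped to \[0.4, 1\]).
#' GM probability maps are ~0.95 in GM structures, ~0.05 in WM, 0 outside.
#' Ages echo a clinic cohort (AD ~5 years older); MMSE is 29.5-ish for HC
#' and drops linearly with lesion burden for AD.
#'
#' @param spec a [synthetic_cohort_spec].
#' @return list: `volumes` (list of [volume3d]), `gm` (list of GM
#'   probability [volume3d]), `atlas` ([toy_atlas()]), `clinical`
#'   (data.frame), `truth` (per-subject lesion indices, severity, burden,
#'   plus `lesion_index` of all disease-region voxels).
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  atlas <- toy_atlas(spec$grid)
  lab <- atlas$labels
  brain <- lab != 0L
  gm_like <- lab %in% 1:4
  baseline <- array(0, dim = spec$grid)
  baseline[lab == 5L] <- spec$wm_cbf
  baseline[gm_like] <- spec$gm_cbf
  lesion_index <- which(array(lab %in% attr(atlas, "disease_labels"), dim = spec$grid))
  coupling <- spec$mmse_coupling %||%
    (7 / ((1 - 0.70) * length(lesion_index)))
  n <- spec$n_hc + spec$n_ad
  group <- c(rep("HC", spec$n_hc),
             rep(c("AD_EA", "AD_LA"), length.out = spec$n_ad))
  ids <- sprintf("%s%02d", ifelse(group == "HC", "hc", "ad"), seq_len(n))
  volumes <- vector("list", n); gm_maps <- vector("list", n)
  truth <- vector("list", n)
  age <- mmse <- numeric(n)
  for (i in seq_len(n)) {
    offset <- rnorm(1, 0, spec$subject_sd)
    noise <- array(rnorm(prod(spec$grid), 0, spec$noise_sd), dim = spec$grid)
    v <- (baseline + offset + noise) * brain
    is_ad <- group[i] != "HC"
    if (is_ad) {
      severity <- min(1, max(0.4, rnorm(1, spec$effect, spec$effect_sd)))
      les <- if (spec$lesion_extent < 1) {
        sort(sample(lesion_index, round(spec$lesion_extent * length(lesion_index))))
      } else lesion_index
      v[les] <- v[les] * severity
      burden <- (1 - severity) * length(les)
      truth[[i]] <- list(lesion = les, severity = severity, burden = burden)
      age[i] <- rnorm(1, if (group[i] == "AD_EA") 60 else 74, 6.5)
      mmse[i] <- round(min(30, max(0, 29 - coupling * burden + rnorm(1, 0, 2))))
    } else {
      truth[[i]] <- list(lesion = integer(), severity = 1, burden = 0)
      age[i] <- rnorm(1, 66, 6)
      mmse[i] <- round(min(30, max(24, 29.5 - abs(rnorm(1, 0, 0.8)))))
    }
    volumes[[i]] <- volume3d(v, subject_id = ids[i])
    g <- array(0, dim = spec$grid)
    g[lab == 5L] <- 0.05
    g[gm_like] <- 0.95
    g <- g + array(rnorm(prod(spec$grid), 0, 0.02), dim = spec$grid) * brain
    gm_maps[[i]] <- volume3d(pmin(pmax(g, 0), 1), subject_id = ids[i])
  }
  clinical <- data.frame(
    id = ids, group = group,
    age = round(pmax(age, 45), 1), mmse = mmse,
    education = round(pmin(pmax(rnorm(n, 13, 4), 5), 22)),
    gender = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  names(volumes) <- names(gm_maps) <- names(truth) <- ids
  list(volumes = volumes, gm = gm_maps, atlas = atlas,
       clinical = clinical,
       truth = list(subjects = truth, lesion_index = lesion_index,
                    coupling = coupling, spec = spec))
}

#' Labeled hypo-count draws for threshold-recovery tests
#'
#' Unit fixture for the discriminant module: per-subject hypo-perfused
#' voxel counts drawn from Poisson (or negative binomial, when `size` is
#' given) distributions with class-specific rates.
#'
#' @param n_hc,n_ad group sizes.
#' @param rate_hc,rate_ad mean counts.
#' @param size negative-binomial dispersion (NULL = Poisson).
#' @param seed RNG seed.
#' @return data.frame with `id`, `group`, `count`.
#' @export
generate_counts <- function(n_hc = 20, n_ad = 20, rate_hc = 50, rate_ad = 500,
                            size = NULL, seed = 1) {
  stopifnot(rate_hc >= 0, rate_ad >= 0, n_hc >= 1, n_ad >= 1)
  set.seed(seed)
  draw <- function(n, rate) {
    if (is.null(size)) rpois(n, rate) else rnbinom(n, size = size, mu = rate)
  }
  data.frame(
    id = c(sprintf("hc%02d", seq_len(n_hc)), sprintf("ad%02d", seq_len(n_ad))),
    group = c(rep("HC", n_hc), rep("AD_LA", n_ad)),
    count = c(draw(n_hc, rate_hc), draw(n_ad, rate_ad)),
    stringsAsFactors = FALSE)
}
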