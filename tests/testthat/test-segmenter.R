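test_that("fuzzy Dice loss matches its closed form and bounds", {
  t <- array(0, c(4, 4, 4)); t[1:8] <- 1
  expect_equal(fuzzy_dsc_loss(t, t, eps = 1e-5), 0, tolerance = 1e-5)
  expect_equal(fuzzy_dsc_loss(t * 0, t, eps = 1e-12), 1, tolerance = 1e-9)
  # pred = 0.5 everywhere, target half-full: 1 - 2*0.5*T / (0.5*N + T)
  N <- 64; Tn <- 8
  p <- array(0.5, c(4, 4, 4))
  expect_equal(fuzzy_dsc_loss(p, t, eps = 0),
               1 - (2 * 0.5 * Tn) / (0.5 * N + Tn))
  expect_error(fuzzy_dsc_loss(array(0, c(2, 2, 2)), t), "shape mismatch")
  # strictly decreasing as pred approaches a binary target pointwise
  set.seed(1)
  tgt <- array(runif(64) < 0.3, c(4, 4, 4))
  prev <- Inf
  for (a in c(0.2, 0.5, 0.8, 1)) {
    cur <- fuzzy_dsc_loss(0.5 + a * (as.numeric(tgt) - 0.5), tgt)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("target strategies resolve per their definitions", {
  d <- c(4, 4, 4)
  m1 <- array(FALSE, d); m1[1:2] <- TRUE                # {a, b}
  m2 <- array(FALSE, d); m2[2:3] <- TRUE                # {b, c}
  rs <- rater_mask_set(list(label_mask(m1, 1), label_mask(m2, 1)))
  expect_identical(resolve_target(target_strategy("single_rater", 2), rs)$values,
                   rs$masks[[2]]$values)
  inter <- resolve_target(target_strategy("intersection"), rs)
  expect_identical(which(inter$values != 0), 2L)        # {b}
  same <- rater_mask_set(list(label_mask(m1, 1), label_mask(m1, 1)))
  for (k in c("single_rater", "intersection", "random_switch"))
    expect_equal(as.logical(resolve_target(target_strategy(k, 1), same,
                                           rng_seed = 3)$values),
                 as.logical(m1))
  expect_error(resolve_target(target_strategy("single_rater", 5), rs),
               "invalid rater")
  disj <- rater_mask_set(list(label_mask(m1, 1),
                              label_mask(array(FALSE, d), 1)))
  expect_warning(resolve_target(target_strategy("intersection"), disj),
                 "empty intersection")
})

test_that("random_switch draws raters uniformly per step", {
  d <- c(2, 2, 2)
  m1 <- array(c(TRUE, rep(FALSE, 7)), d)
  m2 <- array(c(FALSE, TRUE, rep(FALSE, 6)), d)
  rs <- rater_mask_set(list(label_mask(m1, 1), label_mask(m2, 1)))
  picks <- vapply(1:10000, function(s)
    which(resolve_target(target_strategy("random_switch"), rs,
                         rng_seed = s)$values != 0), 0L)
  f1 <- mean(picks == 1L)
  expect_lt(abs(f1 - 0.5), 0.02)
})

test_that("strategy algebra: intersection within raters; n = 1 switch is the rater", {
  smp <- test_phantom(seed = 41)
  rs <- smp$rater_masks
  inter <- resolve_target(target_strategy("intersection"), rs)
  for (m in rs$masks)
    expect_true(all(!inter$values | (m$values != 0)))
  solo <- rater_mask_set(rs$masks[1])
  expect_identical(resolve_target(target_strategy("random_switch"), solo,
                                  rng_seed = 9)$values,
                   rs$masks[[1]]$values)
})

test_that("segment_lc with a truth oracle reproduces the truth mask", {
  smp <- test_phantom(seed = 41)
  res <- segment_lc(oracle_segmenter(smp$true_lc_mask), smp$volume,
                    smp$true_centers,
                    config = segmenter_config(patch_size = 16, roi_size = 32))
  expect_equal(dsc(res$mask, smp$true_lc_mask), 1)
  expect_false(res$empty)
  # constant sub-threshold probabilities give an empty, flagged mask
  const <- function(roi) array(0.4, dim(roi$values))
  expect_warning(
    res0 <- segment_lc(const, smp$volume, smp$true_centers,
                       config = segmenter_config(patch_size = 16,
                                                 roi_size = 32)),
    "empty")
  expect_true(res0$empty)
  expect_equal(sum(res0$mask$values), 0)
})

test_that("both raters' masks fall inside the inference ROI", {
  for (s in c(41, 42)) {
    smp <- test_phantom(seed = s)
    res <- segment_lc(oracle_segmenter(smp$true_lc_mask), smp$volume,
                      smp$true_centers,
                      config = segmenter_config(patch_size = 16, roi_size = 32))
    lo <- res$spec$center_mm - 16 * res$spec$spacing_mm
    hi <- res$spec$center_mm + 16 * res$spec$spacing_mm
    for (m in smp$rater_masks$masks) {
      wc <- lcpipe:::mask_world_coords(m)
      expect_true(all(sweep(wc, 2, lo, ">=")) && all(sweep(wc, 2, hi, "<=")))
    }
  }
})

test_that("largest-component filtering works per side with the stated tie-break", {
  d <- c(12, 12, 12)
  lm <- landmark_set(c(2, 5, 5), c(9, 5, 5))
  m <- array(FALSE, d)
  m[2:3, 5:6, 5:8] <- TRUE          # left: large component (size 16)
  m[2, 10, 2] <- TRUE               # left: singleton -> removed
  m[9:10, 5:6, 5:8] <- TRUE        # right: single component -> kept
  mask <- label_mask(m, 1)
  out <- postprocess_components(mask, lm)
  expect_equal(sum(out$values), 16 + 16)
  expect_false(out$values[2, 10, 2])
  # idempotent on a clean bilateral mask
  out2 <- postprocess_components(out, lm)
  expect_identical(out2$values, out$values)
  # never adds voxels
  expect_true(all(!out$values | m))
  # tie: two equal-size left components; the one nearer the landmark wins
  t2 <- array(FALSE, d)
  t2[2:3, 5, 5] <- TRUE             # 2 voxels at y=5 (near landmark y=5)
  t2[2:3, 10, 5] <- TRUE            # 2 voxels at y=10 (far)
  keep <- postprocess_components(label_mask(t2, 1), lm)
  expect_true(all(keep$values[2:3, 5, 5]))
  expect_false(any(keep$values[2:3, 10, 5]))
})

test_that("substructure training rejects degenerate labels and excludes unlabelled samples", {
  smp <- test_phantom(seed = 41)
  flat <- smp
  flat$substructure_mask <- label_mask(array(0L, dim(smp$volume$values)), 0.75)
  expect_error(
    train_substructure_segmenter(list(flat, flat, flat),
                                 segmenter_config(width = 2, patch_size = 8,
                                                  batch_size = 1, epochs = 1,
                                                  steps_per_epoch = 1)),
    ">= 2 classes")
  missing <- smp
  missing$substructure_mask <- NULL
  expect_message(
    try(train_substructure_segmenter(
      list(missing), segmenter_config(width = 2, patch_size = 8,
                                      batch_size = 1, epochs = 1,
                                      steps_per_epoch = 1)), silent = TRUE),
    "excluded")
})

test_that("substructure class probabilities sum to one per voxel", {
  smp <- test_phantom(seed = 41)
  m <- train_substructure_segmenter(
    list(smp, smp), segmenter_config(width = 2, patch_size = 8,
                                     batch_size = 1, epochs = 0,
                                     steps_per_epoch = 1, patience = 0),
    val_cohort = list(smp))
  out <- segment_substructures(m, smp$volume)
  expect_equal(max(abs(colSums(out$prob) - 1)), 0, tolerance = 1e-9)
  expect_true(all(out$labels$values %in% 0:4))
  expect_true(same_geometry <- identical(dim(out$labels$values),
                                         dim(smp$volume$values)))
})
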