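test_that("Voronoi split partitions the pons with ties to the left", {
  # 2-voxel pons, one voxel nearer each centre
  d <- c(6, 4, 4)
  pm <- array(FALSE, d); pm[2, 2, 2] <- TRUE; pm[5, 2, 2] <- TRUE
  pons <- label_mask(pm, 1)
  lm <- landmark_set(c(1, 1, 1), c(4, 1, 1))
  h <- voronoi_split_pons(pons, lm)
  expect_equal(sum(h$left$values), 1)
  expect_equal(sum(h$right$values), 1)
  expect_true(h$left$values[2, 2, 2])
  expect_true(h$right$values[5, 2, 2])
  expect_error(voronoi_split_pons(pons, landmark_set(c(1, 1, 1), c(1, 1, 1))),
               "coincident")
  expect_error(voronoi_split_pons(label_mask(array(FALSE, d), 1), lm),
               "empty pons")
})

test_that("Voronoi halves are disjoint and cover the pons for random geometries", {
  for (s in 1:100) {
    lcpipe:::with_seed(s, {
      d <- c(12, 10, 10)
      pm <- array(runif(prod(d)) < 0.4, d)
      pm[1, 1, 1] <- TRUE
      pons <- label_mask(pm, 0.5)
      lm <- landmark_set(runif(3, 0, 3), runif(3, 3.2, 5))
      h <- voronoi_split_pons(pons, lm)
      expect_false(any(h$left$values & h$right$values))
      expect_identical(h$left$values | h$right$values, pm)
    })
  }
})

test_that("a symmetric pons splits 50/50 about the bisector plane", {
  d <- c(20, 8, 8)
  pm <- array(FALSE, d); pm[3:18, 2:7, 2:7] <- TRUE
  pons <- label_mask(pm, 1)
  lm <- landmark_set(c(6, 4, 4), c(13, 4, 4))   # mirror-symmetric centres
  h <- voronoi_split_pons(pons, lm)
  expect_equal(sum(h$left$values), sum(h$right$values))
})

test_that("reference cuboids are centred, clipped and flagged as specified", {
  d <- c(30, 30, 30)
  big <- array(FALSE, d); big[4:27, 4:27, 4:27] <- TRUE
  ref <- place_reference_cuboid(label_mask(big, 1), size_vox = 10)
  expect_equal(ref$clipped_fraction, 0)
  expect_equal(sum(ref$mask$values), 1000)
  # centre of mass of a symmetric half is its geometric centre
  expect_equal(ref$cuboid_center_mm, c(15, 15, 15), tolerance = 0.5)
  single <- array(FALSE, d); single[5, 5, 5] <- TRUE
  expect_warning(r1 <- place_reference_cuboid(label_mask(single, 1), 20),
                 "clipped")
  expect_equal(sum(r1$mask$values), 1)
  expect_equal(r1$clipped_fraction, 1 - 1 / 20^3)
  expect_error(place_reference_cuboid(label_mask(array(FALSE, d), 1)),
               "empty half")
})

test_that("contrast ratios follow the relative-difference and ratio forms", {
  d <- c(8, 8, 8)
  v <- array(1, d)
  lc <- array(FALSE, d); lc[1:4] <- TRUE
  ref <- array(FALSE, d); ref[100:140] <- TRUE
  v[lc] <- 2
  vol <- volume_grid(v, 1)
  lm_lc <- label_mask(lc, 1); lm_ref <- label_mask(ref, 1)
  expect_equal(contrast_ratio(vol, lm_lc, lm_ref, "median"), 1)
  expect_equal(contrast_ratio(vol, lm_lc, lm_ref, "median", "ratio"), 2)
  same <- volume_grid(array(3, d), 1)
  expect_equal(contrast_ratio(same, lm_lc, lm_ref, "max"), 0)
  # undefined cases carry reasons
  empty <- label_mask(array(FALSE, d), 1)
  expect_true(is.na(contrast_ratio(vol, empty, lm_ref, "median")))
  zero <- volume_grid(array(0, d), 1)
  cr0 <- contrast_ratio(zero, lm_lc, lm_ref, "median")
  expect_true(is.na(cr0))
  expect_match(attr(cr0, "reason"), "zero reference")
})

test_that("CRs are scale-invariant but not shift-invariant", {
  smp <- test_phantom(seed = 51)
  pons <- label_mask(smp$substructure_mask$values == 2L, 0.75)
  base <- analyze_subject(smp$volume_raw, smp$true_lc_mask, pons,
                          smp$true_centers, size_vox = 10)
  scaled_vol <- volume_grid(smp$volume_raw$values * 7.3, 0.75)
  scaled <- analyze_subject(scaled_vol, smp$true_lc_mask, pons,
                            smp$true_centers, size_vox = 10)
  expect_equal(lcpipe:::cr_vector(scaled), lcpipe:::cr_vector(base),
               tolerance = 1e-9)
  shifted_vol <- volume_grid(smp$volume_raw$values + 5, 0.75)
  shifted <- analyze_subject(shifted_vol, smp$true_lc_mask, pons,
                             smp$true_centers, size_vox = 10)
  expect_gt(max(abs(lcpipe:::cr_vector(shifted) - lcpipe:::cr_vector(base))),
            0.05)
})

test_that("automatic and semi-automatic modes agree when given the same references", {
  smp <- test_phantom(seed = 51)
  pons <- label_mask(smp$substructure_mask$values == 2L, 0.75)
  auto <- analyze_subject(smp$volume_raw, smp$true_lc_mask, pons,
                          smp$true_centers, mode = "automatic", size_vox = 10)
  halves <- voronoi_split_pons(pons, smp$true_centers)
  refs <- list(left = place_reference_cuboid(halves$left, 10, "left")$mask,
               right = place_reference_cuboid(halves$right, 10, "right")$mask)
  semi <- analyze_subject(smp$volume_raw, smp$true_lc_mask, NULL,
                          smp$true_centers, mode = "semi_automatic",
                          ref_masks = refs)
  expect_equal(lcpipe:::cr_vector(semi), lcpipe:::cr_vector(auto))
  expect_error(analyze_subject(smp$volume_raw, smp$true_lc_mask, NULL,
                               smp$true_centers, mode = "semi_automatic"),
               "ref_masks")
})

test_that("an empty side yields undefined CRs there while the other side survives", {
  smp <- test_phantom(seed = 51)
  pons <- label_mask(smp$substructure_mask$values == 2L, 0.75)
  wc <- lcpipe:::mask_world_coords(smp$true_lc_mask)
  mid_x <- (smp$true_centers$left_mm[1] + smp$true_centers$right_mm[1]) / 2
  keep <- which(smp$true_lc_mask$values != 0)[wc[, 1] < mid_x]
  mask1 <- array(FALSE, dim(smp$true_lc_mask$values)); mask1[keep] <- TRUE
  rep <- analyze_subject(smp$volume_raw, label_mask(mask1, 0.75), pons,
                         smp$true_centers, size_vox = 10)
  expect_true(is.na(rep$right$cr_median))
  expect_true(is.finite(rep$left$cr_median))
  expect_match(paste(rep$warnings, collapse = " "), "empty right")
})
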