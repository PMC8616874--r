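# Shared fixtures for the test suite. Phantom cohorts are generated once
# per session and cached, since several files exercise the same
# test-scale cohort (40^3 voxels at 0.75 mm).

.fixture_cache <- new.env(parent = emptyenv())

test_phantom_config <- function(...) {
  phantom_config(shape = c(40, 40, 40), spacing_mm = 0.75, ...)
}

# One cached phantom per seed at the test scale.
test_phantom <- function(seed = 1, noise_sd = 0.05, contrast = c(0.25, 0.35)) {
  key <- sprintf("ph_%d_%g_%s", seed, noise_sd, paste(contrast, collapse = "_"))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_phantom(
      test_phantom_config(noise_sd = noise_sd, contrast = contrast), seed = seed)
  .fixture_cache[[key]]
}

# Cached cohort used by the scaled-down recovery runs (20 train + 4 val +
# 10 test at 0.75 mm).
test_cohort <- function() {
  if (is.null(.fixture_cache$cohort))
    .fixture_cache$cohort <- make_cohort(test_phantom_config(), 34, seed = 11)
  .fixture_cache$cohort
}

# Heatmap oracle: trilinear-weight delta heatmaps at the true centres, so
# the DSNT expectation reproduces the continuous coordinates exactly.
oracle_heatmap_model <- function(truth) {
  function(patch) {
    d <- dim(patch$values)
    H <- matrix(0, 2, prod(d))
    for (k in 1:2) {
      tgt <- if (k == 1) truth$left_mm else truth$right_mm
      idx <- world_to_voxel(patch, tgt)
      f <- floor(idx)
      w <- idx - f
      for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        ii <- f + c(cx, cy, cz)
        if (all(ii >= 0) && all(ii <= d - 1)) {
          wt <- prod(ifelse(c(cx, cy, cz) == 1, w, 1 - w))
          j <- ii[1] + d[1] * (ii[2] + d[2] * ii[3]) + 1
          H[k, j] <- H[k, j] + wt
        }
      }
    }
    H
  }
}

# Segmentation oracle: emits the given mask's values (nearest-sampled onto
# the ROI grid) as probabilities.
oracle_segmenter <- function(mask) {
  function(roi) {
    src <- volume_grid(array(as.numeric(mask$values != 0), dim(mask$values)),
                       mask$spacing_mm, mask$origin_mm)
    pts <- lcpipe:::grid_coords(roi$origin_mm, dim(roi$values), roi$spacing_mm)
    array(sample_world(src, pts, method = "nearest"), dim(roi$values))
  }
}

# Substructure oracle: returns the sample's true label volume.
oracle_substructure <- function(sample) {
  function(volume) sample$substructure_mask$values
}

# Random blob-pair mask on a small grid, for metric fuzz tests.
random_mask <- function(d = c(10, 10, 10), p = 0.2, seed = 1) {
  lcpipe:::with_seed(seed, array(stats::runif(prod(d)) < p, d))
}
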