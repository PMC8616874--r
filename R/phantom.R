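# Synthetic brainstem phantoms with known LC geometry, substructure labels,
# contrast and simulated raters. These stand in for the (private) in-vivo
# cohorts and give every downstream stage a known ground truth.

# Evaluate code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package go
# through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Derive a per-stage child seed from a root seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629)
}

#' Bilateral landmark pair (LC centres) in world mm
#'
#' @param left_mm,right_mm Length-3 world coordinates (mm) of the left and
#'   right LC centre of mass. "Left" is the side with the smaller
#'   first-axis (lateral) coordinate.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(left_mm, right_mm) {
  stopifnot(length(left_mm) == 3, length(right_mm) == 3,
            all(is.finite(left_mm)), all(is.finite(right_mm)))
  structure(list(left_mm = as.numeric(left_mm),
                 right_mm = as.numeric(right_mm)),
            class = "landmark_set")
}

#' Multi-rater mask collection on a common grid
#'
#' @param masks List of binary `label_mask` objects on one geometry.
#' @param rater_ids Character vector of rater identifiers.
#' @return An object of class `rater_mask_set`.
#' @export
rater_mask_set <- function(masks, rater_ids = paste0("R", seq_along(masks))) {
  stopifnot(length(masks) >= 1, length(rater_ids) == length(masks))
  for (m in masks[-1])
    if (!same_geometry(masks[[1]], m)) stop("rater masks on different grids")
  structure(list(masks = masks, rater_ids = rater_ids),
            class = "rater_mask_set")
}

#' Phantom cohort configuration
#'
#' Defines the synthetic study conditions: a brainstem (elliptic cylinder
#' with midbrain / pons / medulla / SCP compartments) containing two
#' slightly curved, quasi-cylindrical hyperintense LCs of ~2 mm diameter and
#' 12-17 mm rostrocaudal extent, with a known LC-vs-pons contrast, additive
#' noise, optional smooth multiplicative bias, and two simulated raters
#' whose boundary jitter is calibrated to a mutual Dice agreement near the
#' inter-expert regime (~0.68).
#'
#' @param shape Grid dimensions (voxels), default `c(64, 64, 64)`.
#' @param spacing_mm Isotropic voxel spacing (mm), default 0.75 (the
#'   acquisition resolution; pass 0.375 for the upsampled working grid).
#' @param lc_length_mm LC rostrocaudal length (mm): scalar or range to draw
#'   from per subject. Default `c(12, 17)`.
#' @param lc_diameter_mm LC diameter (mm), default 2.
#' @param lateral_separation_mm Distance between the two LC centrelines
#'   (mm), default 7.
#' @param contrast True LC-vs-pons contrast c (LC intensity =
#'   (1+c) x pons intensity before normalisation): scalar or range.
#'   Default `c(0.25, 0.35)`.
#' @param noise_sd Additive Gaussian noise sd, in units of the pons
#'   intensity. Default 0.05.
#' @param bias_amplitude Amplitude of an optional smooth multiplicative
#'   bias field. Default 0 (inputs are assumed bias-corrected).
#' @param rater_profiles List of per-rater profiles, each
#'   `list(jitter_sd_vox =, dilation_vox =)`.
#' @param age_ratio Named counts defining the younger:older stratification
#'   ratio, default `c(younger = 25, older = 57)`.
#' @param edge_mm Width of the smooth (partial-volume-like) LC intensity
#'   edge outside the hard core (mm). Default 0.4.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64, 64, 64), spacing_mm = 0.75,
                           lc_length_mm = c(12, 17), lc_diameter_mm = 2,
                           lateral_separation_mm = 7,
                           contrast = c(0.25, 0.35), noise_sd = 0.05,
                           bias_amplitude = 0,
                           rater_profiles = list(
                             R1 = list(jitter_sd_vox = 0.42, dilation_vox = 0),
                             R2 = list(jitter_sd_vox = 0.42, dilation_vox = 0)),
                           age_ratio = c(younger = 25, older = 57),
                           edge_mm = 0.4) {
  stopifnot(length(shape) == 3, all(shape >= 16), spacing_mm > 0,
            lc_diameter_mm > 0, lateral_separation_mm > 0,
            all(lc_length_mm > 0), noise_sd >= 0, bias_amplitude >= 0,
            length(rater_profiles) >= 1)
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 lc_length_mm = lc_length_mm, lc_diameter_mm = lc_diameter_mm,
                 lateral_separation_mm = lateral_separation_mm,
                 contrast = contrast, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 rater_profiles = rater_profiles, age_ratio = age_ratio,
                 edge_mm = edge_mm),
            class = "phantom_config")
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels).
gaussian_smooth3 <- function(values, sigma_vox) {
  if (sigma_vox <= 0) return(values)
  d <- dim(values)
  for (ax in 1:3) {
    n <- d[ax]
    i <- seq_len(n)
    K <- exp(-outer(i, i, "-")^2 / (2 * sigma_vox^2))
    K[abs(outer(i, i, "-")) > ceiling(3 * sigma_vox)] <- 0
    K <- K / rowSums(K)
    values <- apply_axis(values, K, ax)
  }
  values
}

# Smooth cosine ramp: 1 for d <= 0, 0 for d >= w.
cos_ramp <- function(d, w) {
  out <- numeric(length(d))
  out[d <= 0] <- 1
  mid <- d > 0 & d < w
  out[mid] <- 0.5 * (1 + cos(pi * d[mid] / w))
  out
}

# Compartment intensity levels (arbitrary units; pons = 1 so the LC level
# is exactly 1 + c).
phantom_levels <- function() {
  c(background = 0.1, MB = 0.85, P = 1.0, MO = 0.9, SCP = 1.15)
}

#' Substructure label semantics used by the phantom
#' @return Named integer vector mapping labels to compartment names.
#' @export
substructure_labels <- function() {
  c(background = 0L, MB = 1L, P = 2L, MO = 3L, SCP = 4L)
}

#' Generate one synthetic brainstem phantom
#'
#' Builds the label geometry and intensity volume analytically on the
#' configured grid: a hard LC core at exactly (1+c) x pons intensity with a
#' narrow smooth edge (mimicking partial-volume effects, so that sub-voxel
#' localization is meaningful), additive noise, optional bias, and one
#' simulated mask per configured rater. Deterministic given `seed`.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed controlling all per-subject randomness.
#' @param age_group `"younger"` or `"older"` (older subjects draw their
#'   contrast from the lower half of the configured range, mimicking
#'   age/pathology-related signal attenuation).
#' @param id Optional subject identifier stored in the sample.
#' @return An object of class `phantom_sample` with elements `volume`
#'   (z-normalised), `volume_raw`, `true_lc_mask`, `substructure_mask`,
#'   `true_centers`, `true_contrast`, `rater_masks`, `age_group`, `id`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1,
                             age_group = "younger", id = NULL) {
  with_seed(seed, {
    n <- config$shape
    s <- config$spacing_mm
    ext <- (n - 1) * s
    C <- ext / 2                       # world centre (origin at voxel 0 centre)

    draw <- function(rng) if (length(rng) == 2) stats::runif(1, rng[1], rng[2]) else rng
    L <- draw(config$lc_length_mm)
    crng <- config$contrast
    cc <- if (length(crng) == 2) {
      if (identical(age_group, "older"))
        stats::runif(1, crng[1], mean(crng))
      else stats::runif(1, mean(crng), crng[2])
    } else crng
    sep <- config$lateral_separation_mm + stats::runif(1, -0.5, 0.5)
    r0 <- config$lc_diameter_mm / 2
    bow <- stats::runif(1, 0.4, 0.9)   # lateral curvature amplitude (mm)
    zc <- C[3] + 1 + stats::runif(1, -1, 1)
    yc <- C[2] - 6 + stats::runif(1, -0.5, 0.5)
    xoff <- stats::runif(1, -0.75, 0.75)

    if (zc - L / 2 < 2 * s || zc + L / 2 > ext[3] - 2 * s)
      stop("LC geometry does not fit the grid")

    co <- grid_coords(c(0, 0, 0), n, s)
    X <- co[, 1]; Y <- co[, 2]; Z <- co[, 3]

    # brainstem: elliptic cylinder along z
    rx <- min(11, 0.42 * ext[1]); ry <- min(10, 0.38 * ext[2])
    inside_bs <- ((X - C[1]) / rx)^2 + ((Y - C[2]) / ry)^2 <= 1

    lab <- integer(prod(n))
    lab[inside_bs] <- 2L                               # pons by default
    lab[inside_bs & Z < C[3] - 8] <- 3L                # medulla oblongata
    lab[inside_bs & Z > C[3] + 9] <- 1L                # midbrain
    scp <- inside_bs & Z >= C[3] + 2 & Z <= C[3] + 9 &
      (((X - (C[1] - 4.5))^2 + (Y - (C[2] + 6))^2 <= 1.2^2) |
       ((X - (C[1] + 4.5))^2 + (Y - (C[2] + 6))^2 <= 1.2^2))
    lab[scp] <- 4L

    # two slightly curved LC cylinders
    zrel <- (Z - zc) / L
    bowz <- bow * cos(pi * pmin(pmax(zrel, -0.5), 0.5))
    cxl <- C[1] + xoff - sep / 2 - bowz
    cxr <- C[1] + xoff + sep / 2 + bowz
    in_z <- abs(Z - zc) <= L / 2
    cap <- pmax(abs(Z - zc) - L / 2, 0)
    radial_l <- sqrt((X - cxl)^2 + (Y - yc)^2)
    radial_r <- sqrt((X - cxr)^2 + (Y - yc)^2)
    w <- config$edge_mm
    prof <- function(radial) {
      cos_ramp(pmax(radial - r0, 0), w) * cos_ramp(cap, w)
    }
    profile <- pmax(prof(radial_l), prof(radial_r))
    lc_core <- (radial_l <= r0 | radial_r <= r0) & in_z
    if (!any(lc_core & lab == 2L))
      stop("LC geometry does not fit the pons compartment")

    lev <- phantom_levels()
    raw <- lev[["background"]] + numeric(prod(n))
    raw[lab == 1L] <- lev[["MB"]]; raw[lab == 2L] <- lev[["P"]]
    raw[lab == 3L] <- lev[["MO"]]; raw[lab == 4L] <- lev[["SCP"]]
    # LC signal rides on the pons level; core voxels are exactly (1+c)
    raw <- raw * (1 + cc * profile * (lab == 2L))

    if (config$bias_amplitude > 0) {
      b <- array(stats::rnorm(prod(n)), n)
      b <- gaussian_smooth3(b, sigma_vox = max(4, n[1] / 8))
      b <- b / max(abs(b))
      raw <- raw * (1 + config$bias_amplitude * as.numeric(b))
    }
    if (config$noise_sd > 0)
      raw <- raw + stats::rnorm(prod(n), 0, config$noise_sd)

    raw_vol <- volume_grid(array(raw, n), s)
    lc_mask <- label_mask(array(lc_core, n), s,
                          semantics = c(background = 0L, LC = 1L))
    sub_mask <- label_mask(array(lab, n), s, semantics = substructure_labels())

    centers <- mask_side_centers(lc_mask)
    profiles <- config$rater_profiles
    rmasks <- lapply(seq_along(profiles), function(i)
      simulate_rater(lc_mask, profiles[[i]], rng_seed = derive_seed(seed, 1000 + i)))
    structure(list(volume = znormalize(raw_vol), volume_raw = raw_vol,
                   true_lc_mask = lc_mask, substructure_mask = sub_mask,
                   true_centers = centers, true_contrast = cc,
                   rater_masks = rater_mask_set(rmasks, names(profiles)),
                   age_group = age_group, id = id, seed = seed),
              class = "phantom_sample")
  })
}

# Left/right centres of mass of a bilateral binary mask (world mm). Sides
# are split at the overall lateral centre of mass.
mask_side_centers <- function(mask) {
  idx <- which(mask$values != 0)
  if (length(idx) == 0) stop("empty mask")
  d <- vg_dim(mask)
  vox <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  wc <- voxel_to_world(mask, vox)
  mid <- mean(wc[, 1])
  left <- wc[wc[, 1] < mid, , drop = FALSE]
  right <- wc[wc[, 1] >= mid, , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) stop("mask is not bilateral")
  landmark_set(colMeans(left), colMeans(right))
}

#' Simulate an expert rater's manual LC mask
#'
#' Warps the reference mask with a smooth random displacement field
#' (boundary jitter), optionally applies a systematic dilation or erosion,
#' and keeps the largest 26-connected component per side so the result is
#' connected per LC. The expected Dice agreement with the reference
#' decreases monotonically with `jitter_sd_vox`; the package default is
#' calibrated so two independent raters agree at Dice ~0.68.
#'
#' @param true_mask Binary `label_mask` (non-empty).
#' @param profile `list(jitter_sd_vox =, dilation_vox =)`; jitter is the
#'   per-component sd of the displacement field in voxels, dilation the
#'   number of morphological dilation (+) or erosion (-) passes.
#' @param rng_seed Integer seed.
#' @return A binary `label_mask` on the same grid.
#' @export
simulate_rater <- function(true_mask, profile, rng_seed = 1) {
  if (!any(true_mask$values != 0)) stop("empty input mask")
  jit <- profile$jitter_sd_vox %||% 0
  dil <- profile$dilation_vox %||% 0
  d <- vg_dim(true_mask)
  out <- true_mask$values != 0
  if (jit > 0) {
    out <- with_seed(rng_seed, {
      u <- lapply(1:3, function(a) {
        f <- gaussian_smooth3(array(stats::rnorm(prod(d)), d), sigma_vox = 2)
        f <- f / stats::sd(as.numeric(f)) * jit * true_mask$spacing_mm
        as.numeric(f)
      })
      pts <- grid_coords(true_mask$origin_mm, d, true_mask$spacing_mm)
      pts <- pts + cbind(u[[1]], u[[2]], u[[3]])
      soft <- volume_grid(array(as.numeric(true_mask$values != 0), d),
                          true_mask$spacing_mm, true_mask$origin_mm)
      array(sample_world(soft, pts, method = "linear") >= 0.5, d)
    })
  }
  if (dil != 0) {
    for (i in seq_len(abs(dil)))
      out <- if (dil > 0) morph26(out, "dilate") else morph26(out, "erode")
  }
  out <- keep_largest_per_side(out, d)
  label_mask(array(out, d), true_mask$spacing_mm, true_mask$origin_mm,
             semantics = c(background = 0L, LC = 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One pass of 26-neighbourhood binary dilation/erosion.
morph26 <- function(mask, op) {
  d <- dim(mask)
  acc <- if (op == "dilate") array(FALSE, d) else array(TRUE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sh <- shift3(mask, c(dx, dy, dz), fill = (op == "erode"))
    acc <- if (op == "dilate") acc | sh else acc & sh
  }
  acc
}

shift3 <- function(a, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (by[k] >= 0) { src[[k]] <- seq_len(d[k] - by[k]); dst[[k]] <- src[[k]] + by[k] }
    else { src[[k]] <- seq(1 - by[k], d[k]); dst[[k]] <- src[[k]] + by[k] }
    if (length(src[[k]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Keep the largest 26-connected component on each lateral side (split at the
# mask's lateral centre of mass). Empty sides are allowed.
keep_largest_per_side <- function(mask, d) {
  idx <- which(mask)
  if (length(idx) == 0) return(array(FALSE, d))
  lab <- cpp_label26(as.logical(mask), as.integer(d))
  xs <- (which(lab > 0) - 1) %% d[1]
  midx <- mean(((idx - 1) %% d[1]))
  keep <- logical(length(lab))
  comp <- lab[lab > 0]
  cx <- tapply(xs, comp, mean)
  sz <- tapply(xs, comp, length)
  for (side in c("left", "right")) {
    sel <- if (side == "left") cx < midx else cx >= midx
    if (!any(sel)) next
    ids <- as.integer(names(sz)[sel])
    best <- ids[which.max(sz[sel])]
    keep[lab == best] <- TRUE
  }
  array(keep, d)
}

#' Assign age-group labels matching a target ratio
#'
#' Rounds the younger count to the nearest integer (so e.g. the 25:57
#' reference ratio is reproduced exactly at n = 82) and shuffles the
#' labels deterministically.
#'
#' @param n Cohort size.
#' @param age_ratio Named counts, e.g. `c(younger = 25, older = 57)`.
#' @param seed Integer seed.
#' @return Character vector of length `n`.
#' @export
assign_age_groups <- function(n, age_ratio = c(younger = 25, older = 57),
                              seed = 1) {
  frac <- age_ratio[[1]] / sum(age_ratio)
  n_young <- floor(n * frac)
  if (n * frac - n_young >= 0.5) n_young <- n_young + 1
  groups <- c(rep(names(age_ratio)[1], n_young),
              rep(names(age_ratio)[2], n - n_young))
  with_seed(derive_seed(seed, 7), sample(groups))
}

#' Generate a stratified phantom cohort
#'
#' Draws `n` phantoms with per-subject randomized geometry and contrast.
#' Age-group labels are assigned to match the configured younger:older
#' ratio exactly (largest-remainder rounding), supporting stratified fold
#' planning.
#'
#' @param config A [phantom_config()].
#' @param n Cohort size (>= 1).
#' @param seed Integer root seed; per-subject seeds are derived from it.
#' @return List of `phantom_sample` objects.
#' @export
make_cohort <- function(config = phantom_config(), n, seed = 1) {
  stopifnot(n >= 1)
  groups <- assign_age_groups(n, config$age_ratio, seed)
  lapply(seq_len(n), function(i)
    generate_phantom(config, seed = derive_seed(seed, i),
                     age_group = groups[i], id = sprintf("phantom%03d", i)))
}
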