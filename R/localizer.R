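# Coordinate regression of the bilateral LC centres: a 3D U-Net whose two
# output channels are converted to heatmaps (softmax over all patch voxels)
# and reduced to world-mm coordinates by a differentiable
# spatial-to-numerical transform (DSNT). One weight-shared network is
# trained on patches drawn at several resolutions and applied iteratively
# coarse-to-fine at inference (the multi-scale variant); the single-pass
# variant runs one forward pass over the whole volume.

#' Coarse-to-fine resolution schedule
#'
#' @param resolutions_mm Strictly decreasing working resolutions (mm),
#'   coarse to fine. Default `c(3, 1.5, 0.75, 0.375)`.
#' @param patch_size_vox Cubic patch edge length in voxels (default 64).
#' @return An object of class `scale_schedule`.
#' @export
scale_schedule <- function(resolutions_mm = c(3, 1.5, 0.75, 0.375),
                           patch_size_vox = 64) {
  stopifnot(length(resolutions_mm) >= 1, all(resolutions_mm > 0),
            all(diff(resolutions_mm) < 0), patch_size_vox >= 2)
  structure(list(resolutions_mm = as.numeric(resolutions_mm),
                 patch_size_vox = as.integer(patch_size_vox)),
            class = "scale_schedule")
}

#' Heatmap prediction on a patch grid
#'
#' @param heatmaps (n_landmarks x n_voxels) matrix of non-negative values,
#'   each row summing to 1, in the patch's column-major voxel order.
#' @param spec The [patch_spec()] the heatmaps live on.
#' @return An object of class `heatmap_prediction`.
#' @export
heatmap_prediction <- function(heatmaps, spec) {
  if (any(heatmaps < 0)) stop("heatmap values must be non-negative")
  rs <- rowSums(heatmaps)
  if (any(rs == 0)) stop("all-zero heatmap channel (cannot normalize)")
  if (any(abs(rs - 1) > 1e-5)) stop("heatmap channels must sum to 1")
  structure(list(heatmaps = heatmaps, spec = spec),
            class = "heatmap_prediction")
}

# Row-wise softmax, numerically stabilised.
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' DSNT: reduce heatmaps to world coordinates
#'
#' Each landmark coordinate is the probability-weighted mean of the
#' patch's voxel-centre world coordinates — the spatial expectation under
#' the heatmap, which keeps coordinate regression differentiable. Row 1 is
#' taken as the left, row 2 as the right landmark.
#'
#' @param pred A [heatmap_prediction()].
#' @return A [landmark_set()] in world mm.
#' @export
dsnt_coordinates <- function(pred) {
  stopifnot(inherits(pred, "heatmap_prediction"))
  spec <- pred$spec
  X <- grid_coords(patch_origin(spec), rep(spec$size_vox, 3), spec$spacing_mm)
  co <- pred$heatmaps %*% X
  landmark_set(co[1, ], co[min(2, nrow(co)), ])
}

#' Mean per-side Euclidean distance between two landmark sets
#'
#' The localization training loss: the average over the left and right LC
#' of the Euclidean distance (mm) between prediction and target. Zero iff
#' the sets coincide; symmetric.
#'
#' @param pred,target [landmark_set()] objects.
#' @return Non-negative scalar (mm).
#' @export
euclidean_loss <- function(pred, target) {
  (sqrt(sum((pred$left_mm - target$left_mm)^2)) +
     sqrt(sum((pred$right_mm - target$right_mm)^2))) / 2
}

#' Localizer training configuration
#'
#' @param mode `"multiscale"` (patch-based, applied iteratively) or
#'   `"singlepass"` (whole-volume).
#' @param width Base U-Net width.
#' @param batch_size Optimisation batch size; defaults to 32 for the
#'   multi-scale variant and 2 for the whole-volume variant (whose memory
#'   footprint caps the batch).
#' @param epochs,steps_per_epoch,patience Training schedule; early stopping
#'   keeps the weights with the best validation error and `patience` is the
#'   number of non-improving epochs tolerated (0 disables training).
#' @param lr Adam learning rate.
#' @param augment Apply mild random affine augmentation (rotation <=
#'   `rot_deg` degrees, isotropic scale within `1 +- scale_frac`, translation
#'   <= `trans_vox` voxels) consistently to image and target.
#' @param rot_deg,scale_frac,trans_vox Affine augmentation ranges.
#' @param jitter_frac Patch-centre jitter as a fraction of the patch extent.
#' @param seed Integer seed for weight init and sampling.
#' @return An object of class `localizer_config`.
#' @export
localizer_config <- function(mode = c("multiscale", "singlepass"), width = 8,
                             batch_size = NULL, epochs = 10,
                             steps_per_epoch = 20, patience = 3, lr = 2e-3,
                             augment = TRUE, rot_deg = 5, scale_frac = 0.05,
                             trans_vox = 2, jitter_frac = 0.25, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(batch_size)) batch_size <- if (mode == "multiscale") 32L else 2L
  stopifnot(batch_size >= 1, width >= 1)
  structure(list(mode = mode, width = width, batch_size = as.integer(batch_size),
                 epochs = epochs, steps_per_epoch = steps_per_epoch,
                 patience = patience, lr = lr, augment = augment,
                 rot_deg = rot_deg, scale_frac = scale_frac,
                 trans_vox = trans_vox, jitter_frac = jitter_frac, seed = seed),
            class = "localizer_config")
}

# Random mild affine map (rotation about a random axis, isotropic scale,
# translation) about centre `c`. Returns fwd(x): patch coords -> source
# coords, and inv(s): source -> patch.
random_affine <- function(rot_deg, scale_frac, trans_mm, center) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -rot_deg, rot_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sc <- 1 + stats::runif(1, -scale_frac, scale_frac)
  tr <- stats::runif(3, -trans_mm, trans_mm)
  A <- R * sc
  Ai <- solve(A)
  list(fwd = function(x) {
         if (is.matrix(x)) sweep(sweep(x, 2, center) %*% t(A), 2, center + tr, "+")
         else as.numeric(A %*% (x - center)) + center + tr
       },
       inv = function(s) as.numeric(Ai %*% (s - center - tr)) + center)
}

#' Draw one localizer training instance
#'
#' Picks a resolution uniformly from the schedule, centres a patch at the
#' true LC midpoint plus a random offset (small enough that both centres
#' stay inside the patch), optionally applies a mild random affine
#' transformation consistently to the image and the target coordinates, and
#' returns the patch with its target landmark pair.
#'
#' @param sample A `phantom_sample` (or any list with `volume` and
#'   `true_centers`).
#' @param schedule A [scale_schedule()].
#' @param config A [localizer_config()].
#' @param rng_seed Integer seed.
#' @return `list(patch = volume_grid, target = landmark_set, spec = patch_spec)`.
#' @export
sample_training_instance <- function(sample, schedule, config = localizer_config(),
                                     rng_seed = 1) {
  with_seed(rng_seed, {
    res <- schedule$resolutions_mm[sample.int(length(schedule$resolutions_mm), 1)]
    nvox <- schedule$patch_size_vox
    extent <- nvox * res
    truth <- sample$true_centers
    mid <- (truth$left_mm + truth$right_mm) / 2
    half_need <- max(abs(truth$left_mm - mid), abs(truth$right_mm - mid))
    margin <- extent / 2 - half_need - 2 * res
    if (margin <= 0)
      stop("patch cannot contain both targets at the drawn resolution")
    jmax <- min(config$jitter_frac * extent, margin)
    center <- mid + stats::runif(3, -jmax, jmax)
    spec <- patch_spec(center, nvox, res)
    org <- patch_origin(spec)
    pts <- grid_coords(org, rep(nvox, 3), res)
    if (config$augment) {
      aff <- random_affine(config$rot_deg, config$scale_frac,
                           config$trans_vox * res, center)
      tl <- aff$inv(truth$left_mm)
      tr <- aff$inv(truth$right_mm)
      inside <- function(p) all(p > org + res) && all(p < org + (nvox - 2) * res)
      if (inside(tl) && inside(tr)) {
        vals <- sample_world(sample$volume, aff$fwd(pts), method = "linear")
        patch <- volume_grid(array(vals, rep(nvox, 3)), res, org)
        return(list(patch = patch, target = landmark_set(tl, tr), spec = spec))
      }
    }
    patch <- extract_patch(sample$volume, spec, method = "linear")
    list(patch = patch, target = landmark_set(truth$left_mm, truth$right_mm),
         spec = spec)
  })
}

# Loss and logit gradient of the DSNT Euclidean objective for one patch.
# logits: 2 x N; X: N x 3 voxel-centre world coords; targets: 2 x 3.
dsnt_loss_grad <- function(logits, X, targets) {
  p <- softmax_rows(logits)
  pred <- p %*% X
  dif <- pred - targets
  dist <- sqrt(rowSums(dif^2))
  loss <- mean(dist)
  glog <- matrix(0, nrow(logits), ncol(logits))
  for (k in seq_len(nrow(logits))) {
    if (dist[k] < 1e-12) next
    u <- dif[k, ] / dist[k] / nrow(logits)
    gp <- as.numeric(X %*% u)
    glog[k, ] <- p[k, ] * (gp - sum(p[k, ] * gp))
  }
  list(loss = loss, grad = glog)
}

# Whole-volume instance for the single-pass variant (pads to even dims).
fullvol_instance <- function(sample, config, rng_seed) {
  with_seed(rng_seed, {
    vol <- sample$volume
    truth <- sample$true_centers
    if (config$augment) {
      ctr <- volume_center(vol)
      aff <- random_affine(config$rot_deg, config$scale_frac,
                           config$trans_vox * vol$spacing_mm, ctr)
      pts <- grid_coords(vol$origin_mm, vg_dim(vol), vol$spacing_mm)
      vals <- sample_world(vol, aff$fwd(pts), method = "linear")
      vol <- volume_grid(array(vals, vg_dim(vol)), vol$spacing_mm, vol$origin_mm)
      truth <- landmark_set(aff$inv(truth$left_mm), aff$inv(truth$right_mm))
    }
    list(vol = pad_even(vol), target = truth)
  })
}

pad_even <- function(vol) {
  d <- vg_dim(vol)
  dn <- d + d %% 2L
  if (all(dn == d)) return(vol)
  v <- array(0, dn)
  v[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol$values
  volume_grid(v, vol$spacing_mm, vol$origin_mm)
}

#' Train an LC localization network
#'
#' Trains the coordinate-regression U-Net with the DSNT Euclidean loss and
#' Adam. In `"multiscale"` mode, training patches are drawn at resolutions
#' sampled uniformly from the schedule (one weight-shared, scale-agnostic
#' network); in `"singlepass"` mode, whole volumes are used. The validation
#' criterion is the mean Euclidean error on deterministic, unaugmented
#' instances; the best-validation weights are returned (early stopping).
#'
#' @param cohort List of training samples (see [sample_training_instance()]).
#' @param config A [localizer_config()].
#' @param schedule A [scale_schedule()] (ignored in single-pass mode).
#' @param val_cohort Validation samples; defaults to the last 20% of
#'   `cohort` (removed from training).
#' @return An object of class `lc_localizer` with elements `net`, `config`,
#'   `schedule`, `history`, `val`.
#' @export
train_localizer <- function(cohort, config = localizer_config(),
                            schedule = scale_schedule(), val_cohort = NULL) {
  if (length(cohort) == 0) stop("empty training set")
  if (is.null(val_cohort)) {
    nv <- max(1, round(0.2 * length(cohort)))
    val_cohort <- cohort[(length(cohort) - nv + 1):length(cohort)]
    cohort <- cohort[seq_len(length(cohort) - nv)]
    if (length(cohort) == 0) stop("empty training set after validation split")
  }
  ms <- config$mode == "multiscale"
  net <- unet3d_init(1, 2, width = config$width, seed = config$seed)
  opt <- adam_init(net$params)
  counter <- new.env()
  counter$k <- 0L

  step_fun <- function(net) {
    counter$k <- counter$k + 1L
    gacc <- zero_grads(net$params)
    for (b in seq_len(config$batch_size)) {
      sseed <- derive_seed(config$seed, counter$k * 1000L + b)
      si <- with_seed(sseed, sample.int(length(cohort), 1))
      if (ms) {
        inst <- sample_training_instance(cohort[[si]], schedule, config,
                                         rng_seed = derive_seed(sseed, 1))
        vol <- inst$patch
        tgt <- inst$target
      } else {
        inst <- fullvol_instance(cohort[[si]], config, derive_seed(sseed, 1))
        vol <- inst$vol
        tgt <- inst$target
      }
      d <- vg_dim(vol)
      x <- matrix(as.numeric(vol$values), 1)
      fw <- unet3d_forward(net, x, d)
      X <- grid_coords(vol$origin_mm, d, vol$spacing_mm)
      lg <- dsnt_loss_grad(fw$out, X, rbind(tgt$left_mm, tgt$right_mm))
      gacc <- add_grads(gacc, unet3d_backward(net, fw$cache, lg$grad))
    }
    upd <- adam_step(net$params, scale_grads(gacc, 1 / config$batch_size),
                     opt, lr = config$lr)
    net$params <- upd$params
    # persist optimizer state across closure calls
    opt$m <<- upd$state$m; opt$v <<- upd$state$v; opt$t <<- upd$state$t
    net
  }

  val_fun <- function(net) {
    errs <- vapply(val_cohort, function(s) {
      model <- list(net = net, config = config, schedule = schedule)
      class(model) <- "lc_localizer"
      pred <- if (ms) localize_multiscale(model, s$volume, schedule)
              else localize_singlepass(model, s$volume)
      euclidean_loss(pred, s$true_centers)
    }, 0)
    mean(errs)
  }

  res <- train_loop(net, config$epochs, config$steps_per_epoch,
                    config$patience, step_fun, val_fun)
  structure(list(net = res$net, config = config, schedule = schedule,
                 history = res$history, val = res$val),
            class = "lc_localizer")
}

# Heatmaps (rows sum to 1) for a patch, from a trained model or an oracle
# function(patch_grid) returning non-negative 2 x N heatmaps.
predict_heatmap <- function(model, patch) {
  d <- vg_dim(patch)
  if (is.function(model)) {
    h <- model(patch)
    rs <- rowSums(h)
    if (any(rs == 0)) stop("all-zero heatmap channel (cannot normalize)")
    return(h / rs)
  }
  x <- matrix(as.numeric(patch$values), 1)
  fw <- unet3d_forward(model$net, x, d)
  softmax_rows(fw$out)
}

#' Iterative multi-scale LC localization
#'
#' Applies the network consecutively to patches of the input volume at the
#' schedule's increasing resolutions: the first patch is centred at
#' `start_mm` (the volume's world centre by default), and each subsequent
#' patch is centred at the midpoint of the previous left/right prediction.
#'
#' @param model A trained `lc_localizer`, or an oracle function mapping a
#'   patch `volume_grid` to (2 x N) non-negative heatmaps.
#' @param volume Preprocessed (normalised) `volume_grid`.
#' @param schedule A [scale_schedule()]; defaults to the model's.
#' @param start_mm Initial patch centre (world mm).
#' @return A [landmark_set()], with attributes `trace` (list of per-
#'   iteration landmark sets) and `failed` (TRUE if a prediction escaped
#'   the volume by more than one patch extent).
#' @export
localize_multiscale <- function(model, volume, schedule = NULL,
                                start_mm = NULL) {
  if (is.null(schedule)) schedule <- model$schedule
  if (is.null(schedule) || length(schedule$resolutions_mm) == 0)
    stop("empty schedule")
  center <- if (is.null(start_mm)) volume_center(volume) else as.numeric(start_mm)
  trace <- list()
  failed <- FALSE
  pred <- NULL
  for (res in schedule$resolutions_mm) {
    spec <- patch_spec(center, schedule$patch_size_vox, res)
    patch <- extract_patch(volume, spec, method = "linear")
    h <- predict_heatmap(model, patch)
    pred <- dsnt_coordinates(heatmap_prediction(h, spec))
    trace[[length(trace) + 1]] <- pred
    center <- (pred$left_mm + pred$right_mm) / 2
    lo <- volume$origin_mm - schedule$patch_size_vox * res
    hi <- volume$origin_mm + (vg_dim(volume) - 1) * volume$spacing_mm +
      schedule$patch_size_vox * res
    if (any(center < lo) || any(center > hi)) {
      failed <- TRUE
      warning("localization escaped the volume bounds")
      break
    }
  }
  attr(pred, "trace") <- trace
  attr(pred, "failed") <- failed
  pred
}

#' Single-pass whole-volume LC localization
#'
#' One forward pass over the full grid at its native resolution, with the
#' DSNT taken over the whole-volume heatmap (the non-iterative baseline).
#'
#' @param model A trained `lc_localizer` or oracle heatmap function.
#' @param volume Preprocessed `volume_grid`.
#' @param max_voxels Guard against volumes too large for memory; larger
#'   inputs raise an error telling the caller to downscale or tile.
#' @return A [landmark_set()].
#' @export
localize_singlepass <- function(model, volume, max_voxels = 192^3) {
  if (prod(vg_dim(volume)) > max_voxels)
    stop("volume exceeds the memory budget; resample to a coarser grid or tile")
  vol <- pad_even(volume)
  h <- predict_heatmap(model, vol)
  d <- vg_dim(vol)
  X <- grid_coords(vol$origin_mm, d, vol$spacing_mm)
  co <- (h / rowSums(h)) %*% X
  landmark_set(co[1, ], co[2, ])
}
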