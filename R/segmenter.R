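# Patch-based volumetric LC segmentation with a fuzzy Dice loss and four
# multi-rater target strategies (single rater, rater intersection, random
# switching between raters per optimisation step), plus the brainstem
# substructure segmenter whose pons class feeds the contrast-ratio stage.

#' Fuzzy Dice (DSC) loss
#'
#' `1 - (2 * sum(pred*target) + eps) / (sum(pred) + sum(target) + eps)`;
#' 0 iff prediction equals a non-empty binary target, approaching 1 for
#' disjoint masks as `eps -> 0`.
#'
#' @param pred Probability field in \[0,1\] (array or vector).
#' @param target Binary field of the same shape.
#' @param eps Smoothing constant on numerator and denominator.
#' @return Scalar loss in \[0,1\].
#' @export
fuzzy_dsc_loss <- function(pred, target, eps = 1e-5) {
  if (length(pred) != length(target) ||
      (!is.null(dim(pred)) && !is.null(dim(target)) &&
       !identical(dim(pred), dim(target))))
    stop("shape mismatch")
  p <- as.numeric(pred)
  t <- as.numeric(target)
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

#' Multi-rater training-target strategy
#'
#' @param kind `"single_rater"` (use rater `rater`'s mask), `"intersection"`
#'   (voxelwise AND of all raters), or `"random_switch"` (draw one rater
#'   uniformly per optimisation step).
#' @param rater Rater index for `"single_rater"`.
#' @return An object of class `target_strategy`.
#' @export
target_strategy <- function(kind = c("single_rater", "intersection",
                                     "random_switch"), rater = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, rater = as.integer(rater)),
            class = "target_strategy")
}

#' Resolve the training target mask for one optimisation step
#'
#' @param strategy A [target_strategy()].
#' @param raters A [rater_mask_set()].
#' @param rng_seed Seed for the `"random_switch"` draw.
#' @return A binary `label_mask`.
#' @export
resolve_target <- function(strategy, raters, rng_seed = 1) {
  n <- length(raters$masks)
  switch(strategy$kind,
    single_rater = {
      if (strategy$rater < 1 || strategy$rater > n)
        stop("invalid rater index")
      raters$masks[[strategy$rater]]
    },
    intersection = {
      acc <- raters$masks[[1]]$values != 0
      for (m in raters$masks[-1]) acc <- acc & (m$values != 0)
      if (!any(acc)) warning("empty intersection target")
      label_mask(acc, raters$masks[[1]]$spacing_mm,
                 raters$masks[[1]]$origin_mm, raters$masks[[1]]$semantics)
    },
    random_switch = {
      i <- with_seed(rng_seed, sample.int(n, 1))
      raters$masks[[i]]
    })
}

#' Segmenter training configuration
#'
#' @param width Base U-Net width.
#' @param patch_size Training patch edge length in voxels (default 64).
#' @param batch_size Optimisation batch size (default 32).
#' @param trans_vox Range of the random integer-voxel patch translation —
#'   the only augmentation, so neither image nor masks are ever
#'   interpolated.
#' @param threshold Binarization threshold on the predicted probability.
#' @param eps Fuzzy Dice smoothing constant.
#' @param lr,epochs,steps_per_epoch,patience Adam/early-stopping settings.
#' @param roi_size Inference ROI edge length in voxels (default 128, which
#'   comfortably contains both LCs around the localized midpoint).
#' @param seed Integer seed.
#' @return An object of class `segmenter_config`.
#' @export
segmenter_config <- function(width = 8, patch_size = 64, batch_size = 32,
                             trans_vox = 4, threshold = 0.5, eps = 1e-5,
                             lr = 2e-3, epochs = 10, steps_per_epoch = 20,
                             patience = 3, roi_size = 128, seed = 1) {
  stopifnot(threshold > 0, threshold < 1, patch_size %% 2 == 0,
            batch_size >= 1)
  structure(list(width = width, patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size), trans_vox = trans_vox,
                 threshold = threshold, eps = eps, lr = lr, epochs = epochs,
                 steps_per_epoch = steps_per_epoch, patience = patience,
                 roi_size = as.integer(roi_size), seed = seed),
            class = "segmenter_config")
}

sigmoid_ <- function(z) 1 / (1 + exp(-z))

# Gradient of the fuzzy Dice loss w.r.t. pred.
fuzzy_dsc_grad <- function(p, t, eps) {
  den <- sum(p) + sum(t) + eps
  num <- 2 * sum(p * t) + eps
  (num / den^2) - 2 * t / den
}

# Integer-translated patch crop around the sample's LC midpoint: image and
# target are cropped with the same window (nearest sampling = exact crop).
seg_instance <- function(sample, target_mask, config, rng_seed) {
  with_seed(rng_seed, {
    vol <- sample$volume
    s <- vol$spacing_mm
    mid <- (sample$true_centers$left_mm + sample$true_centers$right_mm) / 2
    off <- sample.int(2 * config$trans_vox + 1, 3) - config$trans_vox - 1
    # snap the patch origin to the voxel lattice so the crop needs no
    # interpolation
    half <- (config$patch_size - 1) / 2
    ctr <- voxel_to_world(vol, round(world_to_voxel(vol, mid) - half) +
                            half + off)
    spec <- patch_spec(ctr, config$patch_size, s)
    img <- extract_patch(vol, spec, method = "nearest")
    tgtv <- volume_grid(array(as.numeric(target_mask$values != 0),
                              vg_dim(target_mask)),
                        target_mask$spacing_mm, target_mask$origin_mm)
    tgt <- extract_patch(tgtv, spec, method = "nearest")
    list(img = img, tgt = tgt)
  })
}

#' Train the LC segmentation network
#'
#' Patch-based training (random integer translation as the only
#' augmentation) with the fuzzy Dice loss, against the target mask the
#' chosen multi-rater strategy resolves at every optimisation step. Early
#' stopping on the validation fuzzy Dice loss (for the random-switch
#' strategy the validation target is the voxelwise rater average).
#'
#' @param cohort List of `phantom_sample`-like training subjects (need
#'   `volume`, `true_centers`, `rater_masks`).
#' @param strategy A [target_strategy()].
#' @param config A [segmenter_config()].
#' @param val_cohort Validation subjects (default: last 20% of `cohort`).
#' @return An object of class `lc_segmenter`.
#' @export
train_segmenter <- function(cohort, strategy = target_strategy("random_switch"),
                            config = segmenter_config(), val_cohort = NULL) {
  if (length(cohort) == 0) stop("empty cohort")
  if (is.null(val_cohort)) {
    nv <- max(1, round(0.2 * length(cohort)))
    val_cohort <- cohort[(length(cohort) - nv + 1):length(cohort)]
    cohort <- cohort[seq_len(length(cohort) - nv)]
    if (length(cohort) == 0) stop("empty cohort after validation split")
  }
  net <- unet3d_init(1, 1, width = config$width, seed = config$seed)
  opt <- adam_init(net$params)
  counter <- new.env(); counter$k <- 0L

  step_fun <- function(net) {
    counter$k <- counter$k + 1L
    gacc <- zero_grads(net$params)
    for (b in seq_len(config$batch_size)) {
      sseed <- derive_seed(config$seed, counter$k * 1000L + b)
      si <- with_seed(sseed, sample.int(length(cohort), 1))
      smp <- cohort[[si]]
      tgt_mask <- resolve_target(strategy, smp$rater_masks,
                                 rng_seed = derive_seed(sseed, 11))
      inst <- seg_instance(smp, tgt_mask, config, derive_seed(sseed, 12))
      d <- vg_dim(inst$img)
      fw <- unet3d_forward(net, matrix(as.numeric(inst$img$values), 1), d)
      p <- sigmoid_(fw$out)
      t <- as.numeric(inst$tgt$values)
      gp <- fuzzy_dsc_grad(as.numeric(p), t, config$eps)
      glog <- matrix(gp * as.numeric(p) * (1 - as.numeric(p)), 1)
      gacc <- add_grads(gacc, unet3d_backward(net, fw$cache, glog))
    }
    upd <- adam_step(net$params, scale_grads(gacc, 1 / config$batch_size),
                     opt, lr = config$lr)
    net$params <- upd$params
    opt$m <<- upd$state$m; opt$v <<- upd$state$v; opt$t <<- upd$state$t
    net
  }

  val_target <- function(smp) {
    rm <- smp$rater_masks
    if (strategy$kind == "random_switch") {
      acc <- Reduce(`+`, lapply(rm$masks, function(m) as.numeric(m$values != 0)))
      array(acc / length(rm$masks), vg_dim(rm$masks[[1]]))
    } else {
      resolve_target(strategy, rm)$values != 0
    }
  }

  val_fun <- function(net) {
    mean(vapply(val_cohort, function(smp) {
      tgt <- volume_grid(array(as.numeric(val_target(smp)),
                               vg_dim(smp$volume)),
                         smp$volume$spacing_mm, smp$volume$origin_mm)
      mid <- (smp$true_centers$left_mm + smp$true_centers$right_mm) / 2
      half <- (config$patch_size - 1) / 2
      ctr <- voxel_to_world(smp$volume,
                            round(world_to_voxel(smp$volume, mid) - half) + half)
      spec <- patch_spec(ctr, config$patch_size, smp$volume$spacing_mm)
      img <- extract_patch(smp$volume, spec, method = "nearest")
      tg <- extract_patch(tgt, spec, method = "nearest")
      fw <- unet3d_forward(net, matrix(as.numeric(img$values), 1), vg_dim(img))
      fuzzy_dsc_loss(sigmoid_(fw$out), as.numeric(tg$values), config$eps)
    }, 0))
  }

  res <- train_loop(net, config$epochs, config$steps_per_epoch,
                    config$patience, step_fun, val_fun)
  structure(list(net = res$net, config = config, strategy = strategy,
                 history = res$history, val = res$val),
            class = "lc_segmenter")
}

#' Segment the LC within a landmark-centred ROI
#'
#' Extracts a cubic ROI at the working resolution centred at the landmark
#' midpoint, runs fully-convolutional inference, binarizes at the
#' configured threshold, and maps the mask back onto the source grid.
#'
#' @param model A trained `lc_segmenter`, or an oracle function mapping the
#'   ROI `volume_grid` to a probability array.
#' @param volume Preprocessed `volume_grid`.
#' @param landmarks A [landmark_set()] from the localizer.
#' @param config A [segmenter_config()] (defaults to the model's, if any).
#' @param roi_size,spacing_mm ROI edge length (voxels) and working
#'   resolution (defaults: config `roi_size`, volume spacing).
#' @return List with `mask` (binary `label_mask` on the source grid),
#'   `prob` (probability `volume_grid` on the ROI), `roi_mask` (binary mask
#'   on the ROI), `spec` (the ROI [patch_spec()]), and `empty` flag.
#' @export
segment_lc <- function(model, volume, landmarks, config = NULL,
                       roi_size = NULL, spacing_mm = NULL) {
  if (is.null(config))
    config <- if (!is.function(model)) model$config else segmenter_config()
  if (is.null(roi_size)) roi_size <- config$roi_size
  if (is.null(spacing_mm)) spacing_mm <- volume$spacing_mm
  mid <- (landmarks$left_mm + landmarks$right_mm) / 2
  lo <- volume$origin_mm
  hi <- volume$origin_mm + (vg_dim(volume) - 1) * volume$spacing_mm
  if (any(mid < lo - roi_size * spacing_mm / 2) ||
      any(mid > hi + roi_size * spacing_mm / 2))
    stop("landmark-derived ROI lies outside the volume")
  roi_size <- roi_size + roi_size %% 2L
  if (abs(spacing_mm - volume$spacing_mm) < 1e-9) {
    # snap the ROI to the voxel lattice: the crop is then exact
    half <- (roi_size - 1) / 2
    mid <- voxel_to_world(volume,
                          round(world_to_voxel(volume, mid) - half) + half)
  }
  spec <- patch_spec(mid, roi_size, spacing_mm)
  roi <- extract_patch(volume, spec, method = "linear")
  d <- vg_dim(roi)
  prob_vals <- if (is.function(model)) {
    as.numeric(model(roi))
  } else {
    as.numeric(tiled_infer(model$net, roi, model$config$patch_size, sigmoid_))
  }
  prob <- volume_grid(array(prob_vals, d), spacing_mm, roi$origin_mm)
  roi_mask <- label_mask(array(prob_vals >= config$threshold, d), spacing_mm,
                         roi$origin_mm, c(background = 0L, LC = 1L))
  empty <- !any(roi_mask$values)
  if (empty) warning("empty LC segmentation")
  # map back: nearest-sample the ROI mask at the source voxel centres
  src_pts <- grid_coords(volume$origin_mm, vg_dim(volume), volume$spacing_mm)
  mv <- sample_world(volume_grid(array(as.numeric(roi_mask$values), d),
                                 spacing_mm, roi$origin_mm),
                     src_pts, method = "nearest", fill = 0)
  mask <- label_mask(array(mv >= 0.5, vg_dim(volume)), volume$spacing_mm,
                     volume$origin_mm, c(background = 0L, LC = 1L))
  list(mask = mask, prob = prob, roi_mask = roi_mask, spec = spec,
       empty = empty)
}

#' Keep the largest connected component per LC side
#'
#' Connected-component post-processing against residual false positives.
#' The mask is split at the mid-plane perpendicular to the lateral axis
#' through the landmark midpoint, and within each side only the largest
#' 26-connected component survives (ties broken by centroid distance to
#' that side's landmark). Applying the rule per side preserves the
#' bilateral structure. Never adds voxels; an empty side is allowed.
#'
#' @param mask Binary `label_mask`.
#' @param landmarks A [landmark_set()].
#' @return Filtered binary `label_mask`.
#' @export
postprocess_components <- function(mask, landmarks) {
  d <- vg_dim(mask)
  vals <- mask$values != 0
  if (!any(vals)) return(mask)
  mid_x <- (landmarks$left_mm[1] + landmarks$right_mm[1]) / 2
  lab <- cpp_label26(as.logical(vals), as.integer(d))
  idx <- which(lab > 0)
  vox <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  wc <- voxel_to_world(mask, vox)
  comp <- lab[idx]
  keep <- logical(length(lab))
  for (side in c("left", "right")) {
    lm <- if (side == "left") landmarks$left_mm else landmarks$right_mm
    sel <- if (side == "left") wc[, 1] < mid_x else wc[, 1] >= mid_x
    if (!any(sel)) next
    ids <- unique(comp[sel])
    sizes <- vapply(ids, function(i) sum(comp == i & sel), 0)
    best <- ids[sizes == max(sizes)]
    if (length(best) > 1) {
      cd <- vapply(best, function(i) {
        ctr <- colMeans(wc[comp == i & sel, , drop = FALSE])
        sqrt(sum((ctr - lm)^2))
      }, 0)
      best <- best[which.min(cd)]
    }
    keep[idx[comp == best & sel]] <- TRUE
  }
  label_mask(array(keep, d), mask$spacing_mm, mask$origin_mm, mask$semantics)
}

# Sliding-window inference: cover the grid with lattice-aligned tiles of the
# training patch size (stride = half a tile), run the network on each, and
# blend the per-voxel outputs with a triangular centre weight. This keeps the
# zero-padding context seen at tile borders during patch-based training
# consistent at inference time.
tiled_infer <- function(net, vol, patch_size, activation, input_fun = NULL) {
  d <- vg_dim(vol)
  P <- min(patch_size, min(d))
  P <- P - P %% 2L
  N <- prod(d)
  starts <- lapply(1:3, function(a) {
    if (d[a] <= P) return(0L)
    unique(c(seq(0L, d[a] - P, by = max(1L, P %/% 2L)), d[a] - P))
  })
  w1 <- 1 - 0.9 * abs(seq_len(P) - (P + 1) / 2) / ((P - 1) / 2)
  wt <- as.numeric(outer(outer(w1, w1), w1))
  out_ch <- nrow(net$params$Wh)
  acc <- matrix(0, out_ch, N)
  wacc <- numeric(N)
  for (oz in starts[[3]]) for (oy in starts[[2]]) for (ox in starts[[1]]) {
    sub <- vol$values[ox + seq_len(P), oy + seq_len(P), oz + seq_len(P)]
    x <- if (is.null(input_fun)) matrix(as.numeric(sub), 1)
         else input_fun(volume_grid(array(as.numeric(sub), rep(P, 3L)),
                                    vol$spacing_mm,
                                    vol$origin_mm + c(ox, oy, oz) * vol$spacing_mm))
    fw <- unet3d_forward(net, x, rep(P, 3L))
    p <- activation(fw$out)
    ix <- as.numeric(outer(outer(ox + seq_len(P), d[1] * (oy + seq_len(P) - 1),
                                 "+"),
                           d[1] * d[2] * (oz + seq_len(P) - 1), "+"))
    acc[, ix] <- acc[, ix] + sweep(p, 2, wt, "*")
    wacc[ix] <- wacc[ix] + wt
  }
  sweep(acc, 2, pmax(wacc, 1e-12), "/")
}

# Input builder for the substructure network: intensity plus a normalized
# rostrocaudal coordinate channel. Brainstem compartments are ordered along
# the rostrocaudal axis, so a local patch alone cannot tell midbrain from
# medulla; the coordinate channel (position of each voxel within the
# reference volume's extent, in [-0.5, 0.5]) provides that context.
substructure_input <- function(ref_vol) {
  zc <- volume_center(ref_vol)[3]
  zext <- max((vg_dim(ref_vol)[3] - 1) * ref_vol$spacing_mm, 1e-9)
  function(patch) {
    d <- vg_dim(patch)
    z <- patch$origin_mm[3] + (seq_len(d[3]) - 1) * patch$spacing_mm
    zch <- rep((z - zc) / zext, each = d[1] * d[2])
    rbind(as.numeric(patch$values), zch)
  }
}

# --- brainstem substructure segmentation (5-class) ---------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Train the brainstem substructure segmentation network
#'
#' A 3D U-Net trained analogously to the LC segmenter (translation-only
#' augmentation, per-class fuzzy Dice averaged over the foreground classes)
#' to label background, midbrain, pons, medulla oblongata and superior
#' cerebellar peduncle. Samples without a substructure mask are excluded
#' with a message. Only the pons class is consumed downstream, to derive
#' contrast-ratio reference regions.
#'
#' @param cohort Training subjects (need `volume` and `substructure_mask`).
#' @param config A [segmenter_config()].
#' @param val_cohort Validation subjects (default: last 20%).
#' @return An object of class `substructure_segmenter`.
#' @export
train_substructure_segmenter <- function(cohort, config = segmenter_config(),
                                         val_cohort = NULL) {
  has_lab <- vapply(cohort, function(s) !is.null(s$substructure_mask), TRUE)
  if (any(!has_lab)) {
    message(sum(!has_lab), " sample(s) excluded: missing substructure labels")
    cohort <- cohort[has_lab]
  }
  if (length(cohort) == 0) stop("empty cohort")
  classes <- sort(unique(as.integer(cohort[[1]]$substructure_mask$values)))
  if (length(classes) < 2) stop("needs >= 2 classes")
  K <- max(classes) + 1L
  if (is.null(val_cohort)) {
    nv <- max(1, round(0.2 * length(cohort)))
    val_cohort <- cohort[(length(cohort) - nv + 1):length(cohort)]
    cohort <- cohort[seq_len(length(cohort) - nv)]
    if (length(cohort) == 0) stop("empty cohort after validation split")
  }
  net <- unet3d_init(2, K, width = config$width, seed = config$seed)
  opt <- adam_init(net$params)
  counter <- new.env(); counter$k <- 0L

  inst_fun <- function(smp, rng_seed, jitter = TRUE) {
    with_seed(rng_seed, {
      vol <- smp$volume
      d <- vg_dim(vol)
      half <- (config$patch_size - 1) / 2
      ctrv <- if (jitter) {
        # patch centre uniform over the lattice positions that keep the
        # patch inside the volume, so every region is seen in training
        vapply(1:3, function(a)
          sample.int(max(1L, d[a] - config$patch_size + 1L), 1) - 1L + half, 0)
      } else {
        round(world_to_voxel(vol, volume_center(vol)) - half) + half
      }
      spec <- patch_spec(voxel_to_world(vol, ctrv), config$patch_size,
                         vol$spacing_mm)
      img <- extract_patch(vol, spec, method = "nearest")
      labv <- volume_grid(array(as.numeric(smp$substructure_mask$values),
                                vg_dim(vol)), vol$spacing_mm, vol$origin_mm)
      lab <- extract_patch(labv, spec, method = "nearest")
      list(img = img, lab = round(as.numeric(lab$values)))
    })
  }

  # Fuzzy Dice averaged over the foreground classes, plus a voxelwise
  # cross-entropy term. The Dice part alone has vanishing gradients for
  # classes absent from a patch (and none at all for background), which at
  # small patch sizes lets background drift into rare classes; the CE term
  # supplies a uniform per-voxel gradient for every class.
  multiclass_loss_grad <- function(logits, lab, K, eps) {
    n <- length(lab)
    p <- softmax_cols(logits)
    onehot <- matrix(0, K, n)
    onehot[cbind(lab + 1L, seq_len(n))] <- 1
    fg <- 2:K
    losses <- numeric(length(fg))
    gp <- matrix(0, K, n)
    for (i in seq_along(fg)) {
      k <- fg[i]
      losses[i] <- fuzzy_dsc_loss(p[k, ], onehot[k, ], eps)
      gp[k, ] <- fuzzy_dsc_grad(p[k, ], onehot[k, ], eps) / length(fg)
    }
    # softmax backward for the Dice part, plus the CE gradient (p - onehot)
    glog <- p * (gp - matrix(colSums(p * gp), K, n, byrow = TRUE)) +
      (p - onehot) / n
    ptrue <- pmax(p[cbind(lab + 1L, seq_len(n))], 1e-12)
    list(loss = mean(losses) + mean(-log(ptrue)), grad = glog)
  }

  step_fun <- function(net) {
    counter$k <- counter$k + 1L
    gacc <- zero_grads(net$params)
    for (b in seq_len(config$batch_size)) {
      sseed <- derive_seed(config$seed, counter$k * 1000L + b)
      si <- with_seed(sseed, sample.int(length(cohort), 1))
      smp <- cohort[[si]]
      inst <- inst_fun(smp, derive_seed(sseed, 21))
      d <- vg_dim(inst$img)
      fw <- unet3d_forward(net, substructure_input(smp$volume)(inst$img), d)
      lg <- multiclass_loss_grad(fw$out, inst$lab, K, config$eps)
      gacc <- add_grads(gacc, unet3d_backward(net, fw$cache, lg$grad))
    }
    upd <- adam_step(net$params, scale_grads(gacc, 1 / config$batch_size),
                     opt, lr = config$lr)
    net$params <- upd$params
    opt$m <<- upd$state$m; opt$v <<- upd$state$v; opt$t <<- upd$state$t
    net
  }

  val_fun <- function(net) {
    mean(vapply(val_cohort, function(smp) {
      inst <- inst_fun(smp, 1, jitter = FALSE)
      d <- vg_dim(inst$img)
      fw <- unet3d_forward(net, substructure_input(smp$volume)(inst$img), d)
      multiclass_loss_grad(fw$out, inst$lab, K, config$eps)$loss
    }, 0))
  }

  res <- train_loop(net, config$epochs, config$steps_per_epoch,
                    config$patience, step_fun, val_fun)
  structure(list(net = res$net, config = config, n_classes = K,
                 history = res$history, val = res$val,
                 semantics = cohort[[1]]$substructure_mask$semantics),
            class = "substructure_segmenter")
}

#' Predict brainstem substructure labels for a volume
#'
#' Full-volume convolutional inference; per-voxel class probabilities are
#' softmax-normalised and the argmax label is returned.
#'
#' @param model A trained `substructure_segmenter`, or an oracle function
#'   mapping the volume to a label array.
#' @param volume Preprocessed `volume_grid`.
#' @return List with `labels` (a `label_mask`) and `prob` (K x n_voxels
#'   matrix of class probabilities).
#' @export
segment_substructures <- function(model, volume) {
  if (is.function(model)) {
    lab <- model(volume)
    return(list(labels = label_mask(array(as.integer(lab), vg_dim(volume)),
                                    volume$spacing_mm, volume$origin_mm,
                                    substructure_labels()),
                prob = NULL))
  }
  p <- tiled_infer(model$net, volume, model$config$patch_size, softmax_cols,
                   input_fun = substructure_input(volume))
  lab <- array(max.col(t(p)) - 1L, vg_dim(volume))
  list(labels = label_mask(lab, volume$spacing_mm, volume$origin_mm,
                           model$semantics),
       prob = p)
}
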