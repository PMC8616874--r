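# Automated contrast-ratio (CR) extraction: the pons mask is split between
# the two LC centres in Voronoi fashion, a fixed-size cuboid reference
# region is placed at each half's centre of mass, and per-side median and
# maximum CRs are computed on the raw (pre-normalisation) intensity scale.

mask_world_coords <- function(mask, idx = which(mask$values != 0)) {
  d <- vg_dim(mask)
  vox <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  voxel_to_world(mask, vox)
}

#' Split a pons mask between the two LC centres
#'
#' Every pons voxel is assigned to the LC centre with the shortest
#' Euclidean distance (world mm); exact ties go to the left. The two
#' halves partition the input exactly.
#'
#' @param pons_mask Non-empty binary `label_mask` of the pons.
#' @param landmarks A [landmark_set()] with two distinct centres.
#' @return `list(left, right)` of binary `label_mask` halves.
#' @export
voronoi_split_pons <- function(pons_mask, landmarks) {
  idx <- which(pons_mask$values != 0)
  if (length(idx) == 0) stop("empty pons mask")
  if (all(abs(landmarks$left_mm - landmarks$right_mm) < 1e-9))
    stop("coincident landmarks")
  wc <- mask_world_coords(pons_mask, idx)
  dl <- rowSums(sweep(wc, 2, landmarks$left_mm)^2)
  dr <- rowSums(sweep(wc, 2, landmarks$right_mm)^2)
  d <- vg_dim(pons_mask)
  left <- array(FALSE, d); right <- array(FALSE, d)
  to_left <- dl <= dr
  left[idx[to_left]] <- TRUE
  right[idx[!to_left]] <- TRUE
  list(left = label_mask(left, pons_mask$spacing_mm, pons_mask$origin_mm),
       right = label_mask(right, pons_mask$spacing_mm, pons_mask$origin_mm))
}

#' Place a fixed-size cuboid reference region in a pons half
#'
#' The cuboid (default 20^3 voxels) is centred at the half's centre of
#' mass, rounded to the nearest voxel; the region is the cuboid clipped to
#' the pons half, with the clipped fraction recorded (warning above 0.5).
#'
#' @param half_mask Non-empty binary `label_mask` (one Voronoi half).
#' @param size_vox Cuboid edge length in voxels (default 20).
#' @param side Label stored for provenance (`"left"`/`"right"`).
#' @return An object of class `reference_region` with elements `mask`,
#'   `cuboid_center_mm`, `size_vox`, `clipped_fraction`, `side`.
#' @export
place_reference_cuboid <- function(half_mask, size_vox = 20, side = "unknown") {
  idx <- which(half_mask$values != 0)
  if (length(idx) == 0) stop("empty half")
  wc <- mask_world_coords(half_mask, idx)
  com_vox <- round(world_to_voxel(half_mask, colMeans(wc)))
  d <- vg_dim(half_mask)
  lo <- com_vox - floor((size_vox - 1) / 2)
  hi <- lo + size_vox - 1
  sel <- array(FALSE, d)
  rng <- lapply(1:3, function(a) max(lo[a], 0):min(hi[a], d[a] - 1))
  if (all(vapply(rng, length, 1L) > 0))
    sel[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1] <- TRUE
  region <- sel & (half_mask$values != 0)
  clipped <- 1 - sum(region) / size_vox^3
  if (clipped > 0.5)
    warning(sprintf("reference cuboid clipped by %.0f%%", 100 * clipped))
  structure(list(mask = label_mask(region, half_mask$spacing_mm,
                                   half_mask$origin_mm),
                 cuboid_center_mm = voxel_to_world(half_mask, com_vox),
                 size_vox = as.integer(size_vox),
                 clipped_fraction = clipped, side = side),
            class = "reference_region")
}

#' Contrast ratio of LC intensity against a reference region
#'
#' The statistic (`median` or `max`) is applied identically to the LC and
#' reference intensities. The default formula is the relative difference
#' `(stat(LC) - stat(ref)) / stat(ref)`; `formula = "ratio"` gives the pure
#' ratio `stat(LC) / stat(ref)`. CRs are intended to be computed on the
#' raw intensity scale: they are invariant under positive rescaling but
#' not under the additive shift of z-normalisation.
#'
#' @param volume Intensity `volume_grid` (raw scale).
#' @param lc_mask Non-empty binary `label_mask` of the LC (one side).
#' @param ref_region A [place_reference_cuboid()] result or a binary
#'   `label_mask`.
#' @param stat `"median"` or `"max"`.
#' @param formula `"relative_difference"` (default) or `"ratio"`.
#' @return Scalar CR, or `NA` with attribute `reason` if undefined.
#' @export
contrast_ratio <- function(volume, lc_mask, ref_region,
                           stat = c("median", "max"),
                           formula = c("relative_difference", "ratio")) {
  stat <- match.arg(stat)
  formula <- match.arg(formula)
  ref_mask <- if (inherits(ref_region, "reference_region")) ref_region$mask
              else ref_region
  lc_idx <- which(lc_mask$values != 0)
  ref_idx <- which(ref_mask$values != 0)
  if (length(lc_idx) == 0)
    return(structure(NA_real_, reason = "empty LC mask"))
  if (length(ref_idx) == 0)
    return(structure(NA_real_, reason = "empty reference region"))
  f <- if (stat == "median") stats::median else max
  v <- as.numeric(volume$values)
  s_lc <- f(v[lc_idx])
  s_ref <- f(v[ref_idx])
  if (abs(s_ref) < 1e-12)
    return(structure(NA_real_, reason = "zero reference statistic"))
  if (formula == "ratio") s_lc / s_ref else (s_lc - s_ref) / s_ref
}

# Split a bilateral LC mask at the mid-plane through the landmark midpoint.
split_lc_sides <- function(lc_mask, landmarks) {
  idx <- which(lc_mask$values != 0)
  d <- vg_dim(lc_mask)
  left <- array(FALSE, d); right <- array(FALSE, d)
  if (length(idx) > 0) {
    wc <- mask_world_coords(lc_mask, idx)
    mid_x <- (landmarks$left_mm[1] + landmarks$right_mm[1]) / 2
    left[idx[wc[, 1] < mid_x]] <- TRUE
    right[idx[wc[, 1] >= mid_x]] <- TRUE
  }
  list(left = label_mask(left, lc_mask$spacing_mm, lc_mask$origin_mm),
       right = label_mask(right, lc_mask$spacing_mm, lc_mask$origin_mm))
}

#' Full per-subject contrast-ratio analysis
#'
#' In `"automatic"` mode the reference regions are derived by
#' [voronoi_split_pons()] and [place_reference_cuboid()]; in
#' `"semi_automatic"` mode externally supplied reference masks are used
#' (emulating template-propagated cuboids). Emits the four CRs in the
#' conventional order: median left, median right, maximum left, maximum
#' right. Failures are recorded per field (`NA` + warning) rather than
#' aborting.
#'
#' @param volume Raw-intensity `volume_grid`.
#' @param lc_mask Binary bilateral LC `label_mask`.
#' @param pons_mask Binary pons `label_mask` (automatic mode).
#' @param landmarks A [landmark_set()].
#' @param mode `"automatic"` or `"semi_automatic"`.
#' @param ref_masks For semi-automatic mode: `list(left =, right =)` binary
#'   `label_mask` reference regions.
#' @param size_vox Reference cuboid edge length (voxels).
#' @param formula CR formula, see [contrast_ratio()].
#' @return An object of class `cr_report`: per side `cr_median`, `cr_max`,
#'   `lc_voxel_count`, plus reference provenance and warnings.
#' @export
analyze_subject <- function(volume, lc_mask, pons_mask = NULL, landmarks,
                            mode = c("automatic", "semi_automatic"),
                            ref_masks = NULL, size_vox = 20,
                            formula = "relative_difference") {
  mode <- match.arg(mode)
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)
  refs <- list(left = NULL, right = NULL)
  if (mode == "automatic") {
    if (is.null(pons_mask)) stop("automatic mode requires a pons mask")
    halves <- tryCatch(voronoi_split_pons(pons_mask, landmarks),
                       error = function(e) { note(conditionMessage(e)); NULL })
    if (!is.null(halves)) {
      for (side in c("left", "right")) {
        refs[[side]] <- tryCatch(
          withCallingHandlers(
            place_reference_cuboid(halves[[side]], size_vox, side = side),
            warning = function(w) {
              note(conditionMessage(w)); invokeRestart("muffleWarning")
            }),
          error = function(e) { note(conditionMessage(e)); NULL })
      }
    }
  } else {
    if (is.null(ref_masks) || is.null(ref_masks$left) || is.null(ref_masks$right))
      stop("semi_automatic mode requires ref_masks$left and ref_masks$right")
    refs <- ref_masks
  }
  sides <- split_lc_sides(lc_mask, landmarks)
  out <- list(mode = mode, warnings = warnings)
  for (side in c("left", "right")) {
    lc_side <- sides[[side]]
    nvox <- sum(lc_side$values != 0)
    crs <- list(median = NA_real_, max = NA_real_)
    if (is.null(refs[[side]])) {
      note(sprintf("%s reference region unavailable", side))
    } else if (nvox == 0) {
      note(sprintf("empty %s LC mask; CRs undefined", side))
    } else {
      for (st in c("median", "max")) {
        cr <- contrast_ratio(volume, lc_side, refs[[side]], stat = st,
                             formula = formula)
        if (is.na(cr)) note(sprintf("%s %s CR undefined: %s", side, st,
                                    attr(cr, "reason")))
        crs[[st]] <- as.numeric(cr)
      }
    }
    out[[side]] <- list(cr_median = crs$median, cr_max = crs$max,
                        lc_voxel_count = nvox,
                        reference = if (!is.null(refs[[side]]) &&
                                        inherits(refs[[side]], "reference_region"))
                          list(center_mm = refs[[side]]$cuboid_center_mm,
                               clipped_fraction = refs[[side]]$clipped_fraction)
                        else NULL)
  }
  out$warnings <- warnings
  structure(out, class = "cr_report")
}

#' @export
print.cr_report <- function(x, ...) {
  cat(sprintf("<cr_report> mode=%s\n", x$mode))
  for (side in c("left", "right"))
    cat(sprintf("  %-5s cr_median=%.4f cr_max=%.4f (n=%d)\n", side,
                x[[side]]$cr_median, x[[side]]$cr_max,
                x[[side]]$lc_voxel_count))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# The four CRs in conventional reporting order.
cr_vector <- function(report) {
  c(cr_med_L = report$left$cr_median, cr_med_R = report$right$cr_median,
    cr_max_L = report$left$cr_max, cr_max_R = report$right$cr_max)
}
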