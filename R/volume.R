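#' @useDynLib lcpipe, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd
NULL

#' Isotropic 3D scalar volume with world geometry
#'
#' The image carrier used by every stage of the pipeline. A `volume_grid`
#' couples a 3D array of voxel values with an isotropic voxel spacing (mm)
#' and the world position of the centre of voxel (0,0,0). Voxel indices are
#' 0-based and refer to voxel centres; world coordinates are in mm along
#' axis-aligned, right-handed axes (axis 1 = lateral/left-right, axis 2 =
#' anterior-posterior, axis 3 = rostrocaudal).
#'
#' @param values 3D numeric array of voxel values.
#' @param spacing_mm Positive scalar isotropic voxel spacing in mm.
#' @param origin_mm Length-3 world coordinate (mm) of the centre of voxel
#'   (0,0,0). Defaults to the origin.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("non-3D image")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("spacing_mm must be a positive scalar")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be a finite 3-vector")
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "volume_grid")
}

#' Integer label volume on a `volume_grid` geometry
#'
#' @param values 3D array of non-negative integer labels (or logical for a
#'   binary mask).
#' @param spacing_mm,origin_mm Geometry, as for [volume_grid()].
#' @param semantics Optional named integer vector mapping label values to
#'   names, e.g. `c(background = 0, LC = 1)`.
#' @return An object of class `label_mask` (inherits `volume_grid`).
#' @export
label_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                       semantics = NULL) {
  storage.mode(values) <- if (is.logical(values)) "logical" else "integer"
  v <- volume_grid(if (is.logical(values)) values else values, spacing_mm, origin_mm)
  v$semantics <- semantics
  class(v) <- c("label_mask", "volume_grid")
  v
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels @ %.4g mm, origin (%.3g, %.3g, %.3g) mm\n",
              class(x)[1], d[1], d[2], d[3], x$spacing_mm,
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

vg_dim <- function(vol) dim(vol$values)

#' World extent centre of a volume
#' @param vol A `volume_grid`.
#' @return Length-3 world coordinate (mm) of the geometric centre.
#' @export
volume_center <- function(vol) {
  vol$origin_mm + (vg_dim(vol) - 1) / 2 * vol$spacing_mm
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(vg_dim(a), vg_dim(b)) &&
    abs(a$spacing_mm - b$spacing_mm) < tol &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

#' Convert world coordinates to continuous voxel indices (and back)
#'
#' Voxel indices are 0-based and refer to voxel centres, so
#' `voxel_to_world(vol, c(0,0,0))` is the volume's `origin_mm` and the two
#' transforms are exact inverses.
#'
#' @param vol A `volume_grid`.
#' @param point_mm World coordinate(s) in mm: a length-3 vector or an n x 3
#'   matrix.
#' @return Continuous 0-based voxel index/indices of the same shape.
#' @export
world_to_voxel <- function(vol, point_mm) {
  if (is.matrix(point_mm))
    sweep(point_mm, 2, vol$origin_mm) / vol$spacing_mm
  else
    (point_mm - vol$origin_mm) / vol$spacing_mm
}

#' @rdname world_to_voxel
#' @param index_vox Continuous 0-based voxel index/indices (length-3 vector or
#'   n x 3 matrix).
#' @export
voxel_to_world <- function(vol, index_vox) {
  if (is.matrix(index_vox))
    sweep(index_vox * vol$spacing_mm, 2, vol$origin_mm, "+")
  else
    index_vox * vol$spacing_mm + vol$origin_mm
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI file into a [volume_grid()]. The voxel spacing must be
#' isotropic; the world origin is taken from the translation part of the
#' file's affine. Anisotropic input is rejected unless `resample_to` is
#' given, in which case the volume is resampled to that isotropic spacing.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param resample_to Optional isotropic target spacing (mm) used when the
#'   file is anisotropic.
#' @param label If `TRUE`, read as a [label_mask()] (values coerced to
#'   integer; any resampling uses nearest-neighbour).
#' @return A `volume_grid` (or `label_mask`).
#' @export
read_volume <- function(path, resample_to = NULL, label = FALSE) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("non-3D image")
  pd <- attr(img, "pixdim")[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  iso <- max(pd) - min(pd) < 1e-4 * max(pd)
  vals <- array(as.numeric(img), dim = dim(img))
  if (!iso) {
    if (is.null(resample_to))
      stop("non-isotropic spacing without resample_to")
    stop("anisotropic resampling is not supported; provide isotropic input")
  }
  out <- if (label)
    label_mask(round(vals), mean(pd), origin)
  else
    volume_grid(vals, mean(pd), origin)
  if (!is.null(resample_to))
    out <- resample_volume(out, resample_to,
                           method = if (label) "nearest" else "windowed_sinc")
  out
}

#' Write a volume to NIfTI
#'
#' Values are stored as float64 so that a read-back round trip is
#' bit-exact; the affine encodes the isotropic spacing and world origin.
#'
#' @param vol A `volume_grid` or `label_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vals <- vol$values
  storage.mode(vals) <- "double"
  aff <- diag(c(rep(vol$spacing_mm, 3), 1))
  aff[1:3, 4] <- vol$origin_mm
  attr(vals, "pixdim") <- rep(vol$spacing_mm, 3)
  img <- RNifti::asNifti(vals, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# Lanczos-3 windowed-sinc kernel.
lanczos3 <- function(u) {
  out <- numeric(length(u))
  inside <- abs(u) < 3
  uu <- u[inside]
  s <- function(v) ifelse(v == 0, 1, sin(pi * v) / (pi * v))
  out[inside] <- s(uu) * s(uu / 3)
  out
}

# 1D resampling matrix mapping n_in samples to positions t (in input index
# units, 0-based). Rows are normalised to sum 1 so constants are preserved.
interp_matrix <- function(n_in, t, method) {
  M <- matrix(0, length(t), n_in)
  if (method == "nearest") {
    idx <- pmin(pmax(floor(t + 0.5), 0), n_in - 1)
    M[cbind(seq_along(t), idx + 1)] <- 1
    return(M)
  }
  half <- if (method == "windowed_sinc") 3 else 1
  for (k in seq_along(t)) {
    lo <- max(0, ceiling(t[k] - half))
    hi <- min(n_in - 1, floor(t[k] + half))
    if (hi < lo) { lo <- hi <- pmin(pmax(round(t[k]), 0), n_in - 1) }
    j <- lo:hi
    w <- if (method == "windowed_sinc") lanczos3(t[k] - j) else pmax(0, 1 - abs(t[k] - j))
    if (sum(w) == 0) { j <- pmin(pmax(round(t[k]), 0), n_in - 1); w <- 1 }
    M[k, j + 1] <- w / sum(w)
  }
  M
}

apply_axis <- function(values, M, axis) {
  d <- dim(values)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  v <- aperm(values, perm)
  dv <- dim(v)
  out <- M %*% matrix(v, nrow = dv[1])
  out <- array(out, dim = c(nrow(M), dv[2], dv[3]))
  aperm(out, order(perm))
}

#' Resample a volume to a new isotropic spacing
#'
#' Separable resampling along each axis. `windowed_sinc` (Lanczos-3) is the
#' default for intensity volumes and mirrors the sinc upsampling used to
#' bring 0.75 mm acquisitions to the 0.375 mm working grid; `nearest` must be
#' used for label volumes. The world origin is kept at the first voxel
#' centre, so any feature keeps its world coordinate (within one output
#' voxel at the far boundary).
#'
#' @param vol A `volume_grid` or `label_mask`.
#' @param target_spacing_mm Positive target spacing (mm).
#' @param method One of `"windowed_sinc"`, `"linear"`, `"nearest"`.
#' @return A resampled volume of the same class.
#' @export
resample_volume <- function(vol, target_spacing_mm,
                            method = c("windowed_sinc", "linear", "nearest")) {
  method <- match.arg(method)
  if (!is.numeric(target_spacing_mm) || target_spacing_mm <= 0)
    stop("non-positive spacing")
  if (inherits(vol, "label_mask") && method != "nearest")
    stop("label volumes must use method = \"nearest\"")
  d <- vg_dim(vol)
  ratio <- vol$spacing_mm / target_spacing_mm
  vals <- vol$values
  storage.mode(vals) <- "double"
  n_out <- pmax(1L, as.integer(floor((d - 1) * ratio + 1e-9)) + 1L)
  for (ax in 1:3) {
    t <- (seq_len(n_out[ax]) - 1) / ratio
    M <- interp_matrix(d[ax], t, method)
    vals <- apply_axis(vals, M, ax)
  }
  if (inherits(vol, "label_mask"))
    label_mask(round(vals), target_spacing_mm, vol$origin_mm, vol$semantics)
  else
    volume_grid(vals, target_spacing_mm, vol$origin_mm)
}

#' Z-score normalise a volume
#'
#' Affinely rescales intensities to mean 0, standard deviation 1 —
#' the normalisation applied to every acquisition before the networks see
#' it.
#'
#' @param vol A `volume_grid`.
#' @return A `volume_grid` with normalised values.
#' @export
znormalize <- function(vol) {
  v <- as.numeric(vol$values)
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) stop("constant-valued input (zero variance)")
  volume_grid(array((vol$values - mean(v)) / s, vg_dim(vol)),
              vol$spacing_mm, vol$origin_mm)
}

#' Sample a volume at arbitrary world coordinates
#'
#' Trilinear (or nearest) interpolation; points outside the volume return
#' `fill` (0 by default, the background mean of a z-normalised volume).
#'
#' @param vol A `volume_grid`.
#' @param points_mm n x 3 matrix of world coordinates (mm).
#' @param method `"linear"` or `"nearest"`.
#' @param fill Value for out-of-bounds points.
#' @return Numeric vector of n sampled values.
#' @export
sample_world <- function(vol, points_mm, method = c("linear", "nearest"),
                         fill = 0) {
  method <- match.arg(method)
  d <- vg_dim(vol)
  idx <- world_to_voxel(vol, points_mm)
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = 3)
  # snap near-integer indices so aligned crops are exact
  snap <- abs(idx - round(idx)) < 1e-9
  idx[snap] <- round(idx[snap])
  if (method == "nearest") {
    ii <- floor(idx + 0.5)
    ok <- ii[, 1] >= 0 & ii[, 1] <= d[1] - 1 &
          ii[, 2] >= 0 & ii[, 2] <= d[2] - 1 &
          ii[, 3] >= 0 & ii[, 3] <= d[3] - 1
    out <- rep(fill, nrow(ii))
    if (any(ok)) {
      lin <- ii[ok, 1] + d[1] * (ii[ok, 2] + d[2] * ii[ok, 3]) + 1
      out[ok] <- as.numeric(vol$values)[lin]
    }
    return(out)
  }
  f <- floor(idx)
  w <- idx - f
  out <- rep(as.numeric(fill), nrow(idx))
  vals <- as.numeric(vol$values)
  acc <- numeric(nrow(idx))
  inb <- rep(TRUE, nrow(idx))
  # accumulate the 8 corner contributions; corners outside contribute fill
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 1) w[, 1] else 1 - w[, 1]
    wy <- if (cy == 1) w[, 2] else 1 - w[, 2]
    wz <- if (cz == 1) w[, 3] else 1 - w[, 3]
    wt <- wx * wy * wz
    ii <- cbind(f[, 1] + cx, f[, 2] + cy, f[, 3] + cz)
    ok <- ii[, 1] >= 0 & ii[, 1] <= d[1] - 1 &
          ii[, 2] >= 0 & ii[, 2] <= d[2] - 1 &
          ii[, 3] >= 0 & ii[, 3] <= d[3] - 1
    contrib <- rep(as.numeric(fill), nrow(idx))
    if (any(ok & wt > 0)) {
      sel <- ok & wt > 0
      lin <- ii[sel, 1] + d[1] * (ii[sel, 2] + d[2] * ii[sel, 3]) + 1
      contrib[sel] <- vals[lin]
    }
    acc <- acc + wt * contrib
  }
  acc
}

#' Patch specification
#'
#' A cubic patch defined in world coordinates: its centre (mm), edge length
#' in voxels, and voxel spacing (mm).
#'
#' @param center_mm Length-3 world coordinate of the patch centre.
#' @param size_vox Positive integer edge length in voxels (scalar).
#' @param spacing_mm Positive voxel spacing (mm).
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(center_mm, size_vox, spacing_mm) {
  stopifnot(length(center_mm) == 3, size_vox >= 1, spacing_mm > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 size_vox = as.integer(size_vox),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "patch_spec")
}

# World coordinates (n^3 x 3) of all voxel centres of a patch/volume grid,
# x fastest (R linear order).
grid_coords <- function(origin_mm, n, spacing_mm) {
  ax <- lapply(1:3, function(a) origin_mm[a] + (0:(n[a] - 1)) * spacing_mm)
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}

patch_origin <- function(spec) {
  spec$center_mm - (spec$size_vox - 1) / 2 * spec$spacing_mm
}

#' Extract a resampled cubic patch from a volume
#'
#' The returned patch is a `volume_grid` of `spec$size_vox`^3 voxels at
#' `spec$spacing_mm`, centred (in world coordinates) at `spec$center_mm`.
#' Regions outside the source volume are filled with 0, the background mean
#' after z-normalisation. World coordinates are preserved: the same
#' anatomical point has the same mm coordinate whether addressed through the
#' source or the patch.
#'
#' @param vol Source `volume_grid`.
#' @param spec A [patch_spec()].
#' @param method Interpolation method passed to [sample_world()].
#' @return A `volume_grid` patch.
#' @export
extract_patch <- function(vol, spec, method = c("linear", "nearest")) {
  method <- match.arg(method)
  n <- rep(spec$size_vox, 3)
  org <- patch_origin(spec)
  pts <- grid_coords(org, n, spec$spacing_mm)
  vals <- sample_world(vol, pts, method = method, fill = 0)
  volume_grid(array(vals, dim = n), spec$spacing_mm, org)
}
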