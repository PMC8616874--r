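# Evaluation mathematics: Dice, multi-rater Dice, false discovery rate,
# localization errors, ICC(2,1), Welch t test, and the stratified nested
# cross-validation planner/runner.

as_mask_logical <- function(m) {
  if (inherits(m, "label_mask") || inherits(m, "volume_grid")) m$values != 0
  else m != 0
}

check_geometry_pair <- function(a, b) {
  if (inherits(a, "volume_grid") && inherits(b, "volume_grid") &&
      !same_geometry(a, b)) stop("geometry mismatch")
  av <- as_mask_logical(a); bv <- as_mask_logical(b)
  if (length(av) != length(bv)) stop("geometry mismatch")
  list(a = av, b = bv)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined to agree
#' perfectly (DSC = 1).
#'
#' @param a,b Binary masks (`label_mask` or logical/numeric arrays) on a
#'   common geometry.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(a, b) {
  m <- check_geometry_pair(a, b)
  denom <- sum(m$a) + sum(m$b)
  if (denom == 0) return(1)
  2 * sum(m$a & m$b) / denom
}

#' Multi-rater Dice similarity coefficient
#'
#' Joint agreement of a prediction P with n rater masks:
#' `MRDSC = 2 * sum_i |P n R_i| / (n |P| + sum_i |R_i|)`.
#' Reduces exactly to [dsc()] for a single rater.
#'
#' @param p Predicted binary mask.
#' @param raters A [rater_mask_set()] or list of binary masks.
#' @return Scalar in \[0, 1\].
#' @export
mrdsc <- function(p, raters) {
  masks <- if (inherits(raters, "rater_mask_set")) raters$masks else raters
  n <- length(masks)
  stopifnot(n >= 1)
  pv <- as_mask_logical(p)
  inter <- 0
  rsum <- 0
  for (m in masks) {
    mv <- as_mask_logical(m)
    if (length(mv) != length(pv)) stop("geometry mismatch")
    inter <- inter + sum(pv & mv)
    rsum <- rsum + sum(mv)
  }
  denom <- n * sum(pv) + rsum
  if (denom == 0) return(1)
  2 * inter / denom
}

#' False discovery rate of a predicted mask
#'
#' Fraction of predicted voxels outside the reference:
#' `|pred \\ ref| / |pred|` (equivalently 1 - precision). An empty
#' prediction has FDR 0 by convention.
#'
#' @param pred,ref Binary masks on a common geometry.
#' @return Scalar in \[0, 1\].
#' @export
fdr <- function(pred, ref) {
  m <- check_geometry_pair(pred, ref)
  np <- sum(m$a)
  if (np == 0) return(0)
  sum(m$a & !m$b) / np
}

#' Per-side localization errors
#'
#' Euclidean distance per side (mm) plus dimension-wise absolute errors,
#' with the third axis reported as the axial (rostrocaudal) direction and
#' the first two as in-plane.
#'
#' @param pred,truth [landmark_set()] objects.
#' @return List with `euclidean` (named left/right, mm), `per_axis`
#'   (2 x 3 matrix of |error| per axis), `axial`, `inplane`.
#' @export
localization_error <- function(pred, truth) {
  dl <- pred$left_mm - truth$left_mm
  dr <- pred$right_mm - truth$right_mm
  per_axis <- rbind(left = abs(dl), right = abs(dr))
  colnames(per_axis) <- c("x", "y", "z")
  list(euclidean = c(left = sqrt(sum(dl^2)), right = sqrt(sum(dr^2))),
       per_axis = per_axis,
       axial = per_axis[, 3],
       inplane = per_axis[, 1:2])
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement —
#' computed from the two-way ANOVA mean squares. Used to compare
#' automatically and manually derived contrast ratios across subjects.
#'
#' @param x n x k matrix: n subjects measured by k methods/raters.
#' @return Scalar ICC(2,1).
#' @export
icc_agreement <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 methods")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value.
#'
#' @param a,b Numeric samples (each >= 2 values).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Deal the indices of one stratum into nf folds with largest-remainder
# target sizes, after a seeded shuffle.
allocate_stratum <- function(idx, nf, offset = 0L) {
  n <- length(idx)
  base <- n %/% nf
  extra <- n %% nf
  # rotate which folds get the remainder so strata don't pile up in fold 1
  sizes <- rep(base, nf)
  if (extra > 0) sizes[((offset + seq_len(extra) - 1L) %% nf) + 1L] <- base + 1L
  split(idx, factor(rep(seq_len(nf), times = sizes), levels = seq_len(nf)))
}

#' Plan a stratified nested cross-validation
#'
#' Partitions the cohort into `outer` test folds; for each, the remaining
#' subjects are partitioned into `inner` folds used as validation sets
#' (the rest training). Every subset preserves the cohort's strata ratio
#' within one subject (largest-remainder allocation). Deterministic given
#' `seed`.
#'
#' @param strata Character/factor vector of per-subject stratum labels
#'   (e.g. age group), or a cohort list of `phantom_sample`s whose
#'   `age_group` is used.
#' @param outer,inner Fold counts (defaults 3 and 5).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: `outer_folds` (list of index
#'   vectors) and `inner_folds[[o]]` (list of `inner` index vectors over
#'   the non-test subjects), plus `strata` and `seed`.
#' @export
nested_cv_plan <- function(strata, outer = 3, inner = 5, seed = 1) {
  if (is.list(strata))
    strata <- vapply(strata, function(s) s$age_group, "")
  n <- length(strata)
  if (n < outer * inner) stop("cohort too small for the requested folds")
  strata <- as.character(strata)
  plan_split <- function(idx, labs, nf, sd, offset) {
    shuffled <- with_seed(sd, idx[order(labs, stats::runif(length(idx)))])
    labs_s <- labs[match(shuffled, idx)]
    folds <- vector("list", nf)
    off <- offset
    for (g in unique(labs_s)) {
      al <- allocate_stratum(shuffled[labs_s == g], nf, offset = off)
      for (f in seq_len(nf))
        folds[[f]] <- c(folds[[f]], al[[f]] %||% integer(0))
      off <- off + length(shuffled[labs_s == g]) %% nf
    }
    lapply(folds, sort)
  }
  outer_folds <- plan_split(seq_len(n), strata, outer, derive_seed(seed, 1), 0L)
  inner_folds <- lapply(seq_len(outer), function(o) {
    rest <- sort(setdiff(seq_len(n), outer_folds[[o]]))
    plan_split(rest, strata[rest], inner, derive_seed(seed, 100 + o), o)
  })
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 strata = strata, outer = outer, inner = inner, seed = seed),
            class = "fold_plan")
}

#' Run a nested cross-validated evaluation
#'
#' Enumerates the (outer, inner) combinations of a [nested_cv_plan()]. For
#' each, `trainer(train_idx, val_idx)` must return a predictor
#' `function(sample)` yielding `list(lc_mask =, landmarks =)`; the
#' predictor is scored on the outer test fold: DSC/FDR against each rater
#' and their intersection, MRDSC, and per-side localization error.
#' Per-combination failures are isolated and reported.
#'
#' @param cohort List of `phantom_sample`-like subjects.
#' @param plan A [nested_cv_plan()].
#' @param trainer Function `(train_idx, val_idx) -> function(sample)`.
#' @param max_runs Optional cap on the number of (outer, inner)
#'   combinations (for budgeted runs).
#' @return List with `per_subject` (data.frame, one row per subject x
#'   combination) and `summary` (mean/sd per combination), `failures`.
#' @export
run_evaluation <- function(cohort, plan, trainer, max_runs = Inf) {
  rows <- list()
  failures <- character()
  run <- 0
  for (o in seq_len(plan$outer)) {
    test_idx <- plan$outer_folds[[o]]
    rest <- sort(setdiff(seq_along(cohort), test_idx))
    for (i in seq_len(plan$inner)) {
      run <- run + 1
      if (run > max_runs) break
      val_idx <- plan$inner_folds[[o]][[i]]
      train_idx <- setdiff(rest, val_idx)
      pred_fun <- tryCatch(trainer(train_idx, val_idx), error = function(e) {
        failures <<- c(failures, sprintf("outer %d inner %d: %s", o, i,
                                         conditionMessage(e)))
        NULL
      })
      if (is.null(pred_fun)) next
      for (s in test_idx) {
        smp <- cohort[[s]]
        res <- tryCatch(pred_fun(smp), error = function(e) {
          failures <<- c(failures, sprintf("outer %d inner %d subject %d: %s",
                                           o, i, s, conditionMessage(e)))
          NULL
        })
        if (is.null(res)) next
        rm <- smp$rater_masks
        inter <- resolve_target(target_strategy("intersection"), rm)
        le <- localization_error(res$landmarks, smp$true_centers)
        row <- data.frame(outer = o, inner = i, subject = s,
                          dsc_truth = dsc(res$lc_mask, smp$true_lc_mask),
                          mrdsc = mrdsc(res$lc_mask, rm),
                          dsc_int = dsc(res$lc_mask, inter),
                          loc_err_left = le$euclidean[["left"]],
                          loc_err_right = le$euclidean[["right"]])
        for (r in seq_along(rm$masks)) {
          row[[paste0("dsc_", rm$rater_ids[r])]] <- dsc(res$lc_mask, rm$masks[[r]])
          row[[paste0("fdr_", rm$rater_ids[r])]] <- fdr(res$lc_mask, rm$masks[[r]])
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  per_subject <- do.call(rbind, rows)
  summary <- NULL
  if (!is.null(per_subject)) {
    mcols <- setdiff(names(per_subject), c("outer", "inner", "subject"))
    agg_m <- stats::aggregate(per_subject[mcols],
                              per_subject[c("outer", "inner")], mean)
    agg_s <- stats::aggregate(per_subject[mcols],
                              per_subject[c("outer", "inner")], stats::sd)
    names(agg_s)[-(1:2)] <- paste0(mcols, "_sd")
    summary <- merge(agg_m, agg_s, by = c("outer", "inner"))
  }
  list(per_subject = per_subject, summary = summary, failures = failures)
}
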