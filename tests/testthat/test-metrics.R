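test_that("dsc matches hand counts, conventions and brute force", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2] <- TRUE            # |a| = 2
  b[1:3] <- TRUE            # |b| = 3, overlap 2
  expect_equal(dsc(a, b), 0.8)
  expect_equal(dsc(b, b), 1)
  expect_equal(dsc(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1)
  disj <- array(FALSE, c(4, 4, 4)); disj[10:12] <- TRUE
  expect_equal(dsc(a, disj), 0)
  for (s in 1:25) {
    x <- random_mask(seed = s); y <- random_mask(seed = s + 100)
    brute <- 2 * sum(x & y) / (sum(x) + sum(y))
    expect_equal(dsc(x, y), brute)
    expect_equal(dsc(x, y), dsc(y, x))
  }
})

test_that("fdr is 1 - precision with the empty-prediction convention", {
  p <- array(FALSE, c(4, 4, 4)); r <- p
  p[1:4] <- TRUE; r[2:8] <- TRUE          # 1 of 4 predicted outside ref
  expect_equal(fdr(p, r), 0.25)
  expect_equal(fdr(r, r), 0)
  expect_equal(fdr(array(FALSE, c(4, 4, 4)), r), 0)
  out <- array(FALSE, c(4, 4, 4)); out[20:25] <- TRUE
  expect_equal(fdr(out, r), 1)
  for (s in 1:25) {
    x <- random_mask(seed = s); y <- random_mask(seed = s + 200)
    prec <- if (sum(x) == 0) 1 else sum(x & y) / sum(x)
    expect_equal(fdr(x, y), 1 - prec)
  }
})

test_that("mrdsc matches its definition and reduces to dsc for one rater", {
  # hand count: P={a,b,c}, R1={a,b}, R2={b,c,d} -> 2*(2+2)/(2*3+2+3) = 8/11
  d <- c(3, 3, 3)
  P <- array(FALSE, d); P[1:3] <- TRUE
  R1 <- array(FALSE, d); R1[1:2] <- TRUE
  R2 <- array(FALSE, d); R2[2:4] <- TRUE
  expect_equal(mrdsc(P, list(R1, R2)), 8 / 11)
  expect_equal(mrdsc(R1, list(R1, R1)), 1)
  for (s in 1:50) {
    x <- random_mask(seed = s); y <- random_mask(seed = s + 300)
    expect_identical(mrdsc(x, list(y)), dsc(x, y))
  }
})

test_that("mrdsc stays in [0,1] and is 1 iff all masks coincide", {
  for (s in 1:50) {
    p <- random_mask(seed = s)
    rs <- lapply(1:3, function(k) random_mask(seed = s + 400 + k))
    v <- mrdsc(p, rs)
    expect_gte(v, 0); expect_lte(v, 1)
    if (v == 1) for (r in rs) expect_identical(p, r)
  }
})

test_that("localization errors decompose into axial and in-plane parts", {
  t0 <- landmark_set(c(0, 0, 0), c(5, 0, 0))
  expect_equal(localization_error(t0, t0)$euclidean,
               c(left = 0, right = 0))
  ax <- landmark_set(c(0, 0, 1.2), c(5, 0, 0))
  le <- localization_error(ax, t0)
  expect_equal(le$euclidean[["left"]], 1.2)
  expect_equal(le$axial[["left"]], 1.2)
  expect_equal(unname(le$inplane["left", ]), c(0, 0))
  off <- landmark_set(c(0.3, 0.4, 1.2), c(5, 0, 0))
  expect_equal(localization_error(off, t0)$euclidean[["left"]], 1.3)
})

test_that("ICC(2,1) matches an aov-based oracle to 1e-10", {
  icc_oracle <- function(x) {
    n <- nrow(x); k <- ncol(x)
    df <- data.frame(y = as.numeric(x),
                     subj = factor(rep(seq_len(n), k)),
                     meth = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + meth, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  x <- matrix(c(9, 2, 5, 8, 6, 7,
                2, 1, 4, 6, 2, 8), ncol = 2)
  expect_equal(icc_agreement(x), icc_oracle(x), tolerance = 1e-10)
  set.seed(42)
  for (i in 1:5) {
    y <- matrix(rnorm(24, 10), ncol = 3)
    expect_equal(icc_agreement(y), icc_oracle(y), tolerance = 1e-10)
  }
  same <- cbind(1:6, 1:6)
  expect_equal(icc_agreement(same), 1)
  set.seed(1)
  base <- rnorm(40)
  noisy <- icc_agreement(cbind(base, base + rnorm(40, sd = 100)))
  expect_lt(abs(noisy), 0.3)
  expect_error(icc_agreement(matrix(1:2, 1)), ">= 2 subjects")
})

test_that("welch_t matches stats::t.test to 1e-10 and its edge cases", {
  set.seed(5)
  a <- rnorm(12); b <- rnorm(9, 0.7, 2)
  w <- welch_t(a, b)
  tt <- stats::t.test(a, b)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # equal n and variance: reduces to Student's t
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(welch_t(x, y)$t,
               unname(stats::t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 1e-10)
  expect_error(welch_t(1, c(1, 2)), ">= 2 values")
})

test_that("nested fold plans partition and stratify for many seeds", {
  strata <- assign_age_groups(82, c(younger = 25, older = 57), seed = 1)
  expect_equal(sum(strata == "younger"), 25)
  frac <- 25 / 82
  for (sd in 1:30) {
    plan <- nested_cv_plan(strata, outer = 3, inner = 5, seed = sd)
    expect_setequal(unlist(plan$outer_folds), 1:82)
    expect_equal(sum(lengths(plan$outer_folds)), 82)
    for (o in 1:3) {
      of <- plan$outer_folds[[o]]
      expect_lte(abs(sum(strata[of] == "younger") - frac * length(of)), 1)
      rest <- setdiff(1:82, of)
      expect_setequal(unlist(plan$inner_folds[[o]]), rest)
      for (f in plan$inner_folds[[o]])
        expect_lte(abs(sum(strata[f] == "younger") - frac * length(f)), 1)
    }
  }
  expect_identical(nested_cv_plan(strata, seed = 3),
                   nested_cv_plan(strata, seed = 3))
  expect_false(identical(nested_cv_plan(strata, seed = 3)$outer_folds,
                         nested_cv_plan(strata, seed = 4)$outer_folds))
  expect_error(nested_cv_plan(strata[1:10], outer = 3, inner = 5), "too small")
})

test_that("run_evaluation with an oracle segmenter scores perfect R1 agreement", {
  cohort <- lapply(1:6, function(s) test_phantom(seed = 500 + s))
  plan <- nested_cv_plan(vapply(cohort, function(s) s$age_group, ""),
                         outer = 2, inner = 2, seed = 9)
  trainer <- function(train_idx, val_idx) {
    function(smp) list(lc_mask = smp$rater_masks$masks[[1]],
                       landmarks = smp$true_centers)
  }
  ev <- run_evaluation(cohort, plan, trainer)
  expect_length(ev$failures, 0)
  expect_true(all(ev$per_subject$dsc_R1 == 1))
  expect_true(all(ev$per_subject$fdr_R1 == 0))
  expect_true(all(ev$per_subject$loc_err_left == 0))
  # MRDSC of R1 against {R1, R2} equals its definition on those masks
  i <- ev$per_subject$subject[1]
  rm <- cohort[[i]]$rater_masks
  expect_equal(ev$per_subject$mrdsc[ev$per_subject$subject == i][1],
               mrdsc(rm$masks[[1]], rm))
  # metric columns bounded in [0, 1]
  for (cl in c("dsc_truth", "mrdsc", "dsc_int", "dsc_R1", "fdr_R1")) {
    expect_true(all(ev$per_subject[[cl]] >= 0 & ev$per_subject[[cl]] <= 1))
  }
})
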