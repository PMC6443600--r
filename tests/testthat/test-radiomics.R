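test_that("quantization follows the equal-width rule and its degenerate cases", {
  m <- array(TRUE, c(4, 1, 1))
  q <- quantize(array(5, c(4, 1, 1)), m, 8)
  expect_true(all(q$grid[m] == 1L))

  v <- array(c(0, 100, 128, 255), c(4, 1, 1))
  q2 <- quantize(v, m, 2)
  expect_equal(q2$grid[m], c(1L, 1L, 2L, 2L))

  for (s in 1:5) {
    q3 <- random_quantized(s, G = 6)
    expect_true(all(q3$grid[q3$mask] >= 1L & q3$grid[q3$mask] <= 6L))
  }
  expect_error(quantize(v, array(FALSE, c(4, 1, 1)), 2), "empty")
})

test_that("first-order features match hand arithmetic and are shift invariant", {
  m <- array(TRUE, c(4, 1, 1))
  f <- first_order_features(array(1:4, c(4, 1, 1)), m)
  expect_equal(unname(f["variance"]), 1.25)
  expect_equal(unname(f["mean"]), 2.5)
  f0 <- first_order_features(array(7, c(4, 1, 1)), m)
  expect_equal(unname(f0["variance"]), 0)
  expect_true(is.na(f0["skewness"]) && is.na(f0["kurtosis"]))

  set.seed(1)
  v <- array(rnorm(64), c(4, 4, 4)); mk <- array(TRUE, c(4, 4, 4))
  fa <- first_order_features(v, mk)
  fb <- first_order_features(v + 100, mk)
  for (nm in c("variance", "sd", "skewness", "kurtosis", "range"))
    expect_equal(unname(fa[nm]), unname(fb[nm]), tolerance = 1e-8)
})

test_that("co-occurrence matches the hand-worked micro-example", {
  v <- array(c(1, 1, 1, 2), c(4, 1, 1)); m <- array(TRUE, c(4, 1, 1))
  q <- quantize(v, m, 2)
  gm <- glcm_matrix(q, c(1, 0, 0))
  expect_equal(gm$P, matrix(c(2/3, 1/6, 1/6, 0), 2, 2))
  f <- glcm_features(q, c(1, 0, 0))
  expect_equal(unname(f["cluster_shade"]), 2 / 27, tolerance = 1e-12)
})

test_that("run-length matches the hand-worked micro-example and the constant case", {
  v <- array(c(2, 2, 1), c(3, 1, 1)); m <- array(TRUE, c(3, 1, 1))
  q <- quantize(v, m, 2)
  f <- glrlm_features(q, c(1, 0, 0))
  expect_equal(unname(f["lgre"]), 0.625)
  rm_ <- glrlm_matrix(q, c(1, 0, 0))
  expect_equal(rm_$N_r, 2)

  qc <- quantize(array(3, c(5, 1, 1)), array(TRUE, c(5, 1, 1)), 4)
  fc <- glrlm_features(qc, c(1, 0, 0))
  expect_equal(unname(fc["lgre"]), 1)   # single run at level 1
})

test_that("co-occurrence and run-length agree with brute-force enumeration on random grids", {
  dirs <- glcm_directions_3d()
  for (s in 1:100) {
    q <- random_quantized(s, max_dim = 8, G = 4)
    d <- dirs[1 + (s %% nrow(dirs)), ]
    P_impl <- glcm_matrix(q, d)
    P_orac <- oracle_glcm(q$grid, q$mask, q$G, d)
    if (is.null(P_orac)) {
      expect_null(P_impl)
    } else {
      expect_equal(P_impl$P, P_orac, tolerance = 1e-12)
      f <- glcm_features(q, d)
      expect_equal(unname(f["cluster_shade"]), oracle_cluster_shade(P_orac),
                   tolerance = 1e-9)
    }
    runs_o <- oracle_runs(q$grid, q$mask, d)
    f_impl <- glrlm_features(q, d)
    expect_equal(unname(f_impl["lgre"]), oracle_lgre(runs_o), tolerance = 1e-12)
    rm_ <- glrlm_matrix(q, d)
    expect_equal(rm_$N_r, length(runs_o$level))
  }
})

test_that("no valid pair at an offset yields missing features, not zeros", {
  v <- array(1:2, c(2, 1, 1)); m <- array(c(TRUE, FALSE), c(2, 1, 1))
  q <- quantize(v, m, 2)
  f <- glcm_features(q, c(1, 0, 0))
  expect_true(all(is.na(f)))
})

test_that("gabor responses behave as matched filters with zero DC", {
  mk <- matrix(TRUE, 32, 32)
  fc <- gabor_features(matrix(5, 32, 32), mk, 0.2, 0)
  expect_lt(unname(fc["variance"]), 1e-6 * 25)
  expect_equal(unname(fc["entropy"]), 0)

  X <- matrix(rep(1:32, each = 32), 32)  # column coordinate
  s <- sin(2 * pi * 0.2 * X)
  aligned <- gabor_features(s, mk, 0.2, 0)
  orth <- gabor_features(s, mk, 0.2, pi / 2)
  expect_gt(unname(aligned["variance"]), unname(orth["variance"]))

  expect_error(gabor_kernel(0.7, 0), "frequency")
  expect_warning(gabor_features(matrix(rnorm(36), 6, 6), matrix(TRUE, 6, 6),
                                0.05, 0), "kernel larger")
})

test_that("the default feature bank has the documented cardinality and key set", {
  man <- feature_manifest()
  expect_equal(nrow(man), 592)
  expect_equal(sum(man$dim == "3D"), 356)
  expect_equal(sum(man$dim == "2D"), 236)
  expect_false(any(duplicated(man$id)))

  p <- generate_tumor_phantom(texture_params(), shape = c(14, 14, 14), seed = 5)
  fv <- extract_feature_bank(p)
  expect_identical(names(fv), man$id)

  # identical volume/mask => identical features; id set independent of data
  p2 <- list(volume = p$volume, mask = p$mask)
  expect_identical(extract_feature_bank(p2), fv)
})

test_that("direction-averaged texture features are invariant to 90-degree in-plane rotation", {
  p <- generate_tumor_phantom(texture_params(), shape = c(12, 12, 12), seed = 8)
  rot <- function(a) {
    b <- aperm(a, c(2, 1, 3))
    b[dim(b)[1]:1, , , drop = FALSE]
  }
  q1 <- quantize(p$volume, p$mask, 8)
  q2 <- quantize(rot(p$volume), rot(p$mask), 8)
  dirs <- glcm_directions_3d()
  f1 <- lsccpim:::glcm_features_avg(q1, dirs, 1)
  f2 <- lsccpim:::glcm_features_avg(q2, dirs, 1)
  expect_equal(f1, f2, tolerance = 1e-9)
  r1 <- lsccpim:::glrlm_features_avg(q1, dirs)
  r2 <- lsccpim:::glrlm_features_avg(q2, dirs)
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("features are invariant to a global intensity shift after quantization", {
  p <- generate_tumor_phantom(texture_params(), shape = c(12, 12, 12), seed = 9)
  q1 <- quantize(p$volume, p$mask, 8)
  q2 <- quantize(p$volume + 250, p$mask, 8)
  expect_identical(q1$grid[q1$mask], q2$grid[q2$mask])
})

test_that("texture classes at contrast ratio 2 are separable by a co-occurrence feature", {
  lo <- texture_params(correlation_length = 2, contrast = 1)
  hi <- texture_params(correlation_length = 4, contrast = 2)
  val <- function(par, seed) {
    p <- generate_tumor_phantom(par, shape = c(14, 14, 14), seed = seed)
    q <- quantize(p$volume, p$mask, 16)
    unname(lsccpim:::glcm_features_avg(q, glcm_directions_3d(), 1)["contrast"])
  }
  a <- vapply(1:12, function(s) val(lo, s), numeric(1))
  b <- vapply(1:12, function(s) val(hi, 100 + s), numeric(1))
  # two-class AUC from the rank-sum statistic
  auc <- mean(outer(b, a, ">") + 0.5 * outer(b, a, "=="))
  auc <- max(auc, 1 - auc)
  expect_gt(auc, 0.9)
})

test_that("NIfTI extraction path matches in-memory extraction", {
  p <- generate_tumor_phantom(texture_params(), shape = c(12, 12, 12), seed = 3)
  vp <- tempfile(fileext = ".nii.gz"); mp <- tempfile(fileext = ".nii.gz")
  write_phantom_nifti(p, vp, mp)
  cfg <- feature_bank_config(quantization_levels = c(8),
                             glcm_distances_3d = 1, glcm_distances_2d = 1,
                             gabor_frequencies = 0.2, gabor_orientations = 0)
  expect_equal(extract_from_nifti(vp, mp, cfg),
               extract_feature_bank(p, cfg), tolerance = 1e-6)
})
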