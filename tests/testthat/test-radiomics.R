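const_volume <- function(dm, value = 5) image_volume(array(value, dm))

test_that("fixed-bin-width discretization follows the floor rule", {
  dm <- c(3, 1, 1)
  mask <- seg_mask(array(1L, dm))
  v <- image_volume(array(c(0, 64, 128), dm))
  expect_equal(sort(unique(discretize(v, mask)$labels[mask$voxels == 1])),
               c(1L, 2L, 3L))
  v2 <- image_volume(array(c(0, 63.9, 0), dm))
  expect_equal(unique(discretize(v2, mask)$labels[mask$voxels == 1]), 1L)
  vc <- const_volume(dm)
  d <- discretize(vc, mask)
  expect_equal(d$n_bins, 1)
  expect_error(discretize(v, seg_mask(array(0L, dm))), "empty")
  expect_error(discretize(v, mask, bin_width = 0), "bin_width")
})

test_that("first-order features match hand computations", {
  dm <- c(4, 1, 1)
  mask <- seg_mask(array(1L, dm))
  v <- image_volume(array(c(1, 2, 3, 4), dm))
  fo <- first_order_features(v, mask)
  expect_equal(unname(fo["Mean"]), 2.5)
  expect_equal(unname(fo["Variance"]), 1.25)       # population variance
  expect_equal(unname(fo["Energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(fo["RootMeanSquared"]), sqrt(30 / 4))
  expect_equal(unname(fo["Range"]), 3)
  expect_equal(unname(fo["Median"]), 2.5)

  cm <- first_order_features(const_volume(c(3, 3, 1)), seg_mask(array(1L, c(3, 3, 1))))
  expect_equal(unname(cm["Mean"]), 5)
  expect_equal(unname(cm["Variance"]), 0)
  expect_equal(unname(cm["Skewness"]), 0)          # zero-variance convention
  expect_equal(unname(cm["Kurtosis"]), 0)
  expect_equal(unname(cm["Entropy"]), 0)           # single bin
  expect_equal(unname(cm["Uniformity"]), 1)
})

test_that("adding a constant shifts the mean but not discretized texture", {
  p <- generate_phantom(small_phantom_spec(seed = 61))
  part <- region_partition(p$mask)
  roi <- restrict_region(p$mask, "apex", part)
  shifted <- image_volume(p$image$intensities + 500, p$image$spacing)
  f1 <- first_order_features(p$image, roi)
  f2 <- first_order_features(shifted, roi)
  expect_equal(unname(f2["Mean"] - f1["Mean"]), 500)
  t1 <- texture_features(texture_matrices(discretize(p$image, roi)))
  t2 <- texture_features(texture_matrices(discretize(shifted, roi)))
  expect_equal(t1, t2)
})

test_that("shape features are physically sensible on a cube", {
  cube <- block_mask(c(14, 14, 14), 3:12, 3:12, 3:12)   # 10^3 voxels, 1 mm
  sf <- shape_features(cube)
  expect_equal(unname(sf["VoxelVolume"]), 1000)
  expect_lt(abs(sf["MeshVolume"] - 1000) / 1000, 0.05)
  expect_lt(abs(sf["SurfaceArea"] - 600) / 600, 0.10)
  # max 3D diameter equals the brute-force max pairwise surface distance
  pts <- bf_surface_points(cube)
  bf <- max(dist(pts))
  expect_equal(unname(sf["Maximum3DDiameter"]), bf, tolerance = 1e-12)
  expect_equal(unname(sf["Maximum2DDiameterSlice"]), sqrt(81 + 81))
})

test_that("equal-radii phantoms are more spherical than elongated ones", {
  round_sp <- phantom_spec(grid_shape = c(28, 28, 28),
                           ellipsoid_radii = c(9, 9, 9), seed = 1)
  long_sp <- phantom_spec(grid_shape = c(40, 22, 22),
                          ellipsoid_radii = c(16, 6, 6), seed = 1)
  s_round <- shape_features(generate_phantom(round_sp)$mask)
  s_long <- shape_features(generate_phantom(long_sp)$mask)
  expect_gt(s_round["Sphericity"], s_long["Sphericity"])
  expect_lte(s_round["Sphericity"], 1 + 1e-6)
  expect_gt(s_round["Elongation"], s_long["Elongation"])
})

test_that("shape degenerates gracefully for a single voxel", {
  single <- block_mask(c(5, 5, 5), 3, 3, 3)
  sf <- shape_features(single)
  expect_true(all(is.finite(sf)))
  expect_equal(unname(sf[c("MajorAxisLength", "Elongation", "Flatness")]),
               c(0, 0, 0))
})

test_that("leaking a blob strictly increases surface area", {
  p <- generate_phantom(small_phantom_spec(seed = 62))
  leaked <- perturb_mask(p$mask, perturbation_spec("leak_blob", 2, seed = 5))
  expect_gt(shape_features(leaked)["SurfaceArea"],
            shape_features(p$mask)["SurfaceArea"])
})

test_that("the in-plane GLCM of a 2x2 ROI matches pair counting", {
  L <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  C <- segqc:::glcm_direction(L, c(1L, 0L, 0L), c(1L, 2L))
  # pairs along axis 1: (1,1) and (1,2); symmetric counts
  expect_equal(unname(C), matrix(c(2, 1, 1, 0), 2, 2))
})

test_that("a constant ROI has one zone, zero contrast and trivial matrices", {
  dm <- c(4, 3, 2)
  mask <- seg_mask(array(1L, dm))
  disc <- discretize(const_volume(dm), mask)
  mats <- texture_matrices(disc)
  expect_equal(sum(mats$glszm), 1)                 # one zone of size |mask|
  expect_equal(unname(mats$glszm[1, 24]), 1)
  tf <- texture_features(mats)
  expect_equal(unname(tf["glcm_Contrast"]), 0)
  expect_equal(unname(tf["ngtdm_Contrast"]), 0)
  expect_equal(sum(mats$ngtdm$s), 0)
})

test_that("texture matrices match brute-force enumeration on random ROIs", {
  set.seed(63)
  dirs <- as.matrix(half_directions_13())
  for (i in 1:25) {
    dm <- c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1))
    L <- random_label_roi(dm, n_levels = sample(2:4, 1))
    roi <- roi_from_labels(L)
    mats <- texture_matrices(roi)
    lev <- roi$levels
    d_idx <- sample(13, 3)  # three random directions per case
    pkg_dirs <- segqc:::directions_13()
    for (d in d_idx) {
      dd <- pkg_dirs[[d]]
      got <- mats$glcm[[d]]
      want <- bf_glcm(L, dd, lev)
      if (is.null(got)) expect_equal(sum(want), 0)
      else expect_equal(unname(got), unname(want))
      expect_equal(unname(mats$glrlm[[d]]), unname(bf_glrlm(L, dd, lev)))
    }
    expect_equal(unname(mats$glszm), unname(bf_glszm(L, lev)))
    expect_equal(unname(mats$gldm), unname(bf_gldm(L, lev)))
    ng <- bf_ngtdm(L, lev)
    expect_equal(mats$ngtdm$n, ng$n)
    expect_equal(mats$ngtdm$s, ng$s, tolerance = 1e-12)
  }
})

test_that("GLCM features are per-direction averages, not merged-matrix features", {
  set.seed(64)
  L <- random_label_roi(c(5, 5, 4), n_levels = 4)
  roi <- roi_from_labels(L)
  mats <- texture_matrices(roi)
  tf <- texture_features(mats)
  per_dir <- vapply(Filter(Negate(is.null), mats$glcm), function(C)
    segqc:::glcm_features_one(C, roi$levels)["Contrast"], numeric(1))
  expect_equal(unname(tf["glcm_Contrast"]), mean(per_dir))
  merged <- Reduce(`+`, Filter(Negate(is.null), mats$glcm))
  merged_contrast <- segqc:::glcm_features_one(merged, roi$levels)["Contrast"]
  expect_false(isTRUE(all.equal(unname(tf["glcm_Contrast"]),
                                unname(merged_contrast))))
})

test_that("GLRLM short-run emphasis matches a run-enumeration oracle", {
  set.seed(65)
  L <- random_label_roi(c(3, 3, 1), n_levels = 2, p_in = 1)
  roi <- roi_from_labels(L)
  mats <- texture_matrices(roi)
  d1 <- segqc:::directions_13()[[1]]
  P <- bf_glrlm(L, d1, roi$levels)
  sre_oracle <- sum(sweep(P, 2, as.numeric(colnames(P))^2, `/`)) / sum(P)
  got <- segqc:::glrlm_features_one(mats$glrlm[[1]], roi$levels,
                                    roi$n_voxels)["ShortRunEmphasis"]
  expect_equal(unname(got), sre_oracle)
})

test_that("extraction yields exactly 321 finite features with frozen names", {
  p <- generate_phantom(small_phantom_spec(seed = 66))
  fv <- extract_case(p$image, p$mask)
  expect_length(fv, 321)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_names())
  classes <- vapply(strsplit(names(fv), "_"), `[`, character(1), 2)
  expect_equal(unname(table(classes)["firstorder"]), 54L)  # 18 x 3 regions
  # whole-region mean equals the direct in-mask mean
  expect_equal(unname(fv["whole_firstorder_Mean"]),
               mean(p$image$intensities[p$mask$voxels == 1]))
  # determinism
  fv2 <- extract_case(p$image, p$mask)
  expect_identical(unclass(fv), unclass(fv2))
})

test_that("degenerate regions still emit 321 entries, flagged", {
  # mask spanning 2 slices: apex/base partitions are empty
  m <- block_mask(c(8, 8, 6), 3:6, 3:6, 3:4)
  v <- image_volume(array(rnorm(8 * 8 * 6, 100, 20), c(8, 8, 6)))
  fv <- extract_case(v, m)
  expect_length(fv, 321)
  expect_true(all(is.finite(fv)))
  valid <- attr(fv, "valid_regions")
  expect_true(valid["whole"])
  expect_false(valid["apex"])
  expect_false(valid["base"])
  expect_equal(unname(fv["apex_firstorder_Mean"]), 0)
})
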