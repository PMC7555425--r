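test_that("phantom mask volume matches the analytic ellipsoid volume", {
  p <- generate_phantom(phantom_spec(seed = 3))
  analytic <- 4 / 3 * pi * 20 * 25 * 22
  expect_lt(abs(mask_volume_mm3(p$mask) - analytic) / analytic, 0.05)
})

test_that("phantom generation is a pure function of its seed", {
  sp <- phantom_spec(grid_shape = c(24, 24, 24), ellipsoid_radii = c(7, 8, 6),
                     seed = 11)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$mask$voxels, b$mask$voxels)
  sp2 <- sp; sp2$seed <- 12L
  expect_false(identical(generate_phantom(sp2)$image$intensities,
                         a$image$intensities))
})

test_that("an ellipsoid exceeding the grid is rejected", {
  expect_error(phantom_spec(grid_shape = c(24, 24, 24),
                            ellipsoid_radii = c(20, 25, 22)),
               "exceeds grid bounds")
})

test_that("phantom image contrasts gland against background", {
  p <- generate_phantom(small_phantom_spec(seed = 2))
  inside <- mean(p$image$intensities[p$mask$voxels == 1])
  outside <- mean(p$image$intensities[p$mask$voxels == 0])
  expect_gt(inside, outside + 50)
})

test_that("identity and zero-magnitude perturbations return the mask unchanged", {
  p <- generate_phantom(small_phantom_spec(seed = 4))
  expect_identical(perturb_mask(p$mask, perturbation_spec("none"))$voxels,
                   p$mask$voxels)
  for (kind in c("erode", "dilate", "boundary_jitter", "translate"))
    expect_identical(
      perturb_mask(p$mask, perturbation_spec(kind, magnitude = 0))$voxels,
      p$mask$voxels)
})

test_that("erosion shrinks, dilation grows, and quality degrades monotonically", {
  p <- generate_phantom(small_phantom_spec(seed = 5))
  e1 <- perturb_mask(p$mask, perturbation_spec("erode", 1))
  e2 <- perturb_mask(p$mask, perturbation_spec("erode", 2))
  d1 <- perturb_mask(p$mask, perturbation_spec("dilate", 1))
  expect_lt(mask_volume_voxels(e1), mask_volume_voxels(p$mask))
  expect_gt(mask_volume_voxels(d1), mask_volume_voxels(p$mask))
  expect_gt(dice(p$mask, e1), dice(p$mask, e2))
  # grid and spacing always preserved
  expect_identical(dim(e2$voxels), dim(p$mask$voxels))
  expect_identical(e2$spacing, p$mask$spacing)
})

test_that("dropping apex slices removes exactly that many mask slices", {
  m <- block_mask(c(6, 6, 16), 2:5, 2:5, 3:14)  # spans 12 slices
  spans <- function(x) sum(apply(x$voxels, 3, sum) > 0)
  expect_equal(spans(m), 12)
  dropped <- perturb_mask(m, perturbation_spec("drop_apex_slices", 3))
  expect_equal(spans(dropped), 9)
  # apex = inferior (lowest) slices go first
  expect_equal(min(which(apply(dropped$voxels, 3, sum) > 0)), 6)
  base_dropped <- perturb_mask(m, perturbation_spec("drop_base_slices", 3))
  expect_equal(max(which(apply(base_dropped$voxels, 3, sum) > 0)), 11)
})

test_that("a perturbation that empties the mask warns and flags, not errors", {
  m <- block_mask(c(8, 8, 8), 4:5, 4:5, 4:5)
  expect_warning(out <- perturb_mask(m, perturbation_spec("erode", 3)),
                 "emptied")
  expect_equal(sum(out$voxels), 0)
  expect_true(out$emptied)
})

test_that("leak blob adds volume outside but adjacent to the mask", {
  p <- generate_phantom(small_phantom_spec(seed = 6))
  leaked <- perturb_mask(p$mask, perturbation_spec("leak_blob", 2, seed = 3))
  expect_gt(mask_volume_voxels(leaked), mask_volume_voxels(p$mask))
  expect_true(all(leaked$voxels[p$mask$voxels == 1] == 1))
})

test_that("observer cohort is mild, deterministic, and validates n", {
  expect_error(generate_observer_cohort(1, small_phantom_spec()), "n >= 2")
  quiet <- generate_observer_cohort(
    2, small_phantom_spec(),
    observer_noise = perturbation_spec("boundary_jitter", 0), seed = 8)
  for (cs in quiet) expect_identical(cs$observer$voxels, cs$gold$voxels)
  cohort <- generate_observer_cohort(5, small_phantom_spec(), seed = 9)
  dscs <- vapply(cohort, function(cs) dice(cs$observer, cs$gold), numeric(1))
  expect_true(all(dscs > 0.8 & dscs < 1))
  cohort2 <- generate_observer_cohort(5, small_phantom_spec(), seed = 9)
  expect_identical(lapply(cohort, function(c) c$observer$voxels),
                   lapply(cohort2, function(c) c$observer$voxels))
})
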