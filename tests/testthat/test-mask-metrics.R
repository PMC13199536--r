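test_that("median smoothing matches the brute-force filter", {
  # solid cube much larger than the kernel: interior and face centres are
  # untouched (edges and corners round off, as a median filter does)
  cube <- array(FALSE, c(15, 15, 15))
  cube[4:12, 4:12, 4:12] <- TRUE
  sm <- median_smooth_mask(cube, spacing = 0.6, kernel_mm = 3)
  expect_identical(sm, bf_median_filter(cube, half = 2))
  expect_true(all(sm[6:10, 6:10, 6:10]))       # interior
  expect_true(sm[8, 8, 12] && sm[8, 8, 4])     # face centres
  expect_true(sm[4, 8, 8] && sm[12, 8, 8])
  expect_false(any(sm & !cube))                # no dilation beyond the cube
  # isolated voxel removed
  spk <- array(FALSE, c(9, 9, 9)); spk[5, 5, 5] <- TRUE
  expect_false(any(median_smooth_mask(spk, 0.6, 3)))
  # 1-voxel pit on a flat face is filled; full brute-force comparison
  pit <- cube; pit[8, 8, 12] <- FALSE
  sm2 <- median_smooth_mask(pit, 0.6, 3)
  expect_true(sm2[8, 8, 12])
  expect_identical(sm2, bf_median_filter(pit, half = 2))
  # sub-voxel kernel returns input with a warning
  expect_warning(out <- median_smooth_mask(cube, spacing = 4, kernel_mm = 3),
                 "kernel")
  expect_identical(out, cube)
})

test_that("volume and overlap metrics follow their definitions", {
  A <- array(FALSE, c(15, 12, 12)); A[1:11, 1:10, 1:10] <- TRUE # 1100
  B <- array(FALSE, c(15, 12, 12)); B[1:10, 1:10, 1:10] <- TRUE # 1000
  expect_equal(relative_volume_difference(A, B), 0.10)
  expect_equal(relative_volume_difference(B, A), 100 / 1100)
  expect_equal(relative_volume_difference(A, A), 0)
  expect_error(relative_volume_difference(A, array(FALSE, dim(A))), "empty")

  expect_equal(dice_coefficient(A, A), 1)
  D <- array(FALSE, dim(A)); D[13:15, , ] <- TRUE
  expect_equal(dice_coefficient(A, D), 0)
  # two 10^3 cubes overlapping in half
  C1 <- array(FALSE, c(20, 12, 12)); C1[1:10, 1:10, 1:10] <- TRUE
  C2 <- array(FALSE, c(20, 12, 12)); C2[6:15, 1:10, 1:10] <- TRUE
  expect_equal(dice_coefficient(C1, C2), 0.5)
  # nested masks: DC = 2|A| / (|A| + |B|) by counting
  expect_equal(dice_coefficient(B, A), 2 * 1000 / (1000 + 1100))
  expect_error(dice_coefficient(array(FALSE, c(2, 2, 2)),
                                array(FALSE, c(2, 2, 2))), "empty")
})

test_that("surface extraction lists exactly the boundary voxels", {
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  sp <- surface_points(cube, 1)
  expect_equal(nrow(sp), 26)  # 3^3 minus hollow centre
  # the centre voxel is interior, never listed
  expect_false(any(sp[, 1] == 2.5 & sp[, 2] == 2.5 & sp[, 3] == 2.5))
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(nrow(surface_points(single, 1)), 1)
  # border-of-volume voxels count as surface; the centre of a full 3^3
  # volume is interior (all 6 face neighbours in-mask)
  full <- array(TRUE, c(3, 3, 3))
  expect_equal(nrow(surface_points(full, 1)), 26)
  expect_equal(nrow(surface_points(array(TRUE, c(2, 2, 2)), 1)), 8)
  expect_error(surface_points(array(FALSE, c(2, 2, 2)), 1), "empty")
})

test_that("surface distances equal the O(n^2) brute-force oracle", {
  set.seed(7)
  sp <- 0.6
  for (rep in 1:6) {
    A <- random_mask(c(14, 13, 12))
    B <- random_mask(c(14, 13, 12))
    bf <- bf_surface_distances(A, B, sp)
    expect_equal(mean_surface_distance(A, B, sp), bf$msd, tolerance = 1e-9)
    expect_equal(hausdorff_distance(A, B, sp), bf$hd, tolerance = 1e-9)
  }
  # dilated-cube example with explicit reference
  cube <- array(FALSE, c(12, 12, 12)); cube[4:8, 4:8, 4:8] <- TRUE
  dil <- array(FALSE, c(12, 12, 12)); dil[3:9, 3:9, 3:9] <- TRUE
  bf <- bf_surface_distances(cube, dil, sp)
  expect_equal(mean_surface_distance(cube, dil, sp), bf$msd, tolerance = 1e-12)
  expect_equal(mean_surface_distance(dil, cube, sp),
               mean_surface_distance(cube, dil, sp))
  # protruding spike of k voxels sets the Hausdorff distance
  spike <- cube; spike[9:11, 6, 6] <- TRUE
  expect_equal(hausdorff_distance(cube, spike, sp), 3 * sp, tolerance = 1e-12)
  expect_equal(hausdorff_distance(cube, cube, sp), 0)
})

test_that("Hausdorff dominates mean surface distance on random pairs", {
  set.seed(11)
  for (rep in 1:50) {
    A <- random_mask(c(10, 10, 10), n_seeds = 2)
    B <- random_mask(c(10, 10, 10), n_seeds = 2)
    expect_gte(hausdorff_distance(A, B, 1) + 1e-12,
               mean_surface_distance(A, B, 1))
  }
})

test_that("cross-sectional area handles cuboids, cylinders and bands", {
  # axis-aligned 10 x 10 mm section is exact
  cub <- array(FALSE, c(14, 14, 12)); cub[3:12, 3:12, 2:11] <- TRUE
  expect_equal(cross_sectional_area(cub, 1), 100)
  # endplate-band exclusion does not change a uniform section
  expect_equal(cross_sectional_area(cub, 1, endplate_fraction = 0.2), 100)
  expect_equal(cross_sectional_area(cub, 1, endplate_fraction = 0), 100)
  # elliptic cylinder approaches pi a b
  ph <- make_vertebra_phantom(a = 20, b = 15, height = 30, waist = 0,
                              spacing = 0.6)
  expect_equal(cross_sectional_area(ph$body_mask, 0.6), pi * 20 * 15,
               tolerance = 0.02)
  expect_error(cross_sectional_area(array(FALSE, c(3, 3, 3)), 1), "slices")
})

test_that("pairwise summaries average exactly three comparisons", {
  ph <- tiny_phantom()
  m <- ph$mask
  rep3 <- list(m, m, m)
  g <- pairwise_geometric_summary(rep3, ph$spacing, mode = "intra",
                                  smooth = FALSE)
  expect_equal(nrow(g$table), 3)
  expect_equal(unname(g$mean["dice"]), 1)
  expect_equal(unname(g$mean["rvd"]), 0)
  expect_equal(unname(g$sd["hd_mm"]), 0)
  # mean/SD equal recomputation from the per-pair table
  masks <- lapply(1:3, function(s) {
    simulate_operator_mask(ph, operator_preset("inter"), seed = s)
  })
  g2 <- pairwise_geometric_summary(masks, ph$spacing, mode = "inter",
                                   smooth = FALSE)
  for (metric in c("rvd", "dice", "msd_mm", "hd_mm")) {
    expect_equal(unname(g2$mean[metric]), mean(g2$table[[metric]]))
    expect_equal(unname(g2$sd[metric]), sd(g2$table[[metric]]))
  }
  # voxel-unit distances use the scan spacing
  expect_equal(g2$table$hd_vox, g2$table$hd_mm / ph$spacing)
  expect_error(pairwise_geometric_summary(masks[1:2], ph$spacing), "3 masks")
})
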