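test_that("phantom geometry matches its analytic description", {
  ph <- make_vertebra_phantom(a = 20, b = 15, height = 30, waist = 0,
                              spacing = 0.6)
  expect_equal(ph$Hm, 30)
  # voxel-count CSA converges to the analytic ellipse area
  expect_equal(ph$csa, pi * 20 * 15, tolerance = 1e-10)
  expect_equal(cross_sectional_area(ph$body_mask, 0.6), pi * 20 * 15,
               tolerance = 0.02)
  # mask equals the analytic solid sampled at voxel centres: spot-check the
  # centre voxel and a far corner
  expect_true(ph$mask[round(ph$dim[1] / 2), round(ph$dim[2] / 2),
                      round(ph$dim[3] / 2)])
  expect_false(ph$mask[1, 1, 1])
  expect_true(all(ph$density >= 0))
})

test_that("lesions carve the density field and are validated", {
  les <- list(centre = c(3, 0, 2), radius = 4, multiplier = 0)
  ph <- make_vertebra_phantom(a = 15, b = 12, height = 24, spacing = 0.6,
                              lesions = list(les))
  g <- list(x = (seq_len(ph$dim[1]) - 0.5) * 0.6,
            y = (seq_len(ph$dim[2]) - 0.5) * 0.6,
            z = (seq_len(ph$dim[3]) - 0.5) * 0.6)
  # voxel at the lesion centre has density 0; far-away bone keeps base value
  ic <- round((ph$centre + les$centre) / 0.6)
  expect_identical(ph$density[ic[1], ic[2], ic[3]], 0)
  io <- round((ph$centre + c(-8, 0, -6)) / 0.6)
  expect_equal(ph$density[io[1], io[2], io[3]], ph$base_density)
  # BMC accounts for the lesion deficit
  ph0 <- make_vertebra_phantom(a = 15, b = 12, height = 24, spacing = 0.6)
  expect_lt(ph$bmc, ph0$bmc)
  expect_error(make_vertebra_phantom(lesions = list(
    list(centre = c(19, 0, 0), radius = 5, multiplier = 0.1))),
    "inside the body")
  expect_error(make_vertebra_phantom(lesions = list(
    list(centre = c(0, 0, 0), radius = 2, multiplier = 1.2))),
    "multiplier")
  expect_error(make_vertebra_phantom(a = 2, b = 2, height = 30, spacing = 0.6),
               "coarse")
})

test_that("QCT rendering obeys the scanner's affine response", {
  ph <- tiny_phantom(base_density = 0.15)
  sc <- noise_free_scanner(slope_hu = 1000, intercept_hu = 0)
  q <- render_qct(ph, sc, seed = 1)
  # densest rod core reads slope * 0.20 HU
  means <- extract_rod_means(q)
  expect_equal(means, c(0, 50, 100, 150, 200), tolerance = 1e-12)
  # empty field reads the intercept
  sc2 <- noise_free_scanner(slope_hu = 800, intercept_hu = -25)
  q2 <- render_qct(ph, sc2, seed = 1, include_rods = FALSE)
  expect_equal(q2$data[1, 1, 1], -25)
  # determinism: same seed, bit-identical volumes
  sc3 <- scanner_model(noise_sd = 12, blur_sd = 0.3, voxel_mm = 1)
  expect_identical(render_qct(ph, sc3, seed = 7)$data,
                   render_qct(ph, sc3, seed = 7)$data)
  expect_false(identical(render_qct(ph, sc3, seed = 7)$data,
                         render_qct(ph, sc3, seed = 8)$data))
  expect_error(scanner_model(noise_sd = -1), "noise")
  expect_error(scanner_model(rod_bmd = c(0, 0.05, 0.1, 0.15)), "5 rods")
})

test_that("rendered rod means are affine in rod density with R^2 = 1", {
  ph <- tiny_phantom()
  sc <- noise_free_scanner(slope_hu = 1234, intercept_hu = -40)
  q <- render_qct(ph, sc, seed = 1)
  means <- extract_rod_means(q)
  fit <- lm(means ~ sc$rod_bmd)
  expect_equal(unname(coef(fit)), c(-40, 1234), tolerance = 1e-9)
  r2 <- 1 - sum(fit$residuals^2) / sum((means - mean(means))^2)
  expect_equal(r2, 1, tolerance = 1e-12)
})

test_that("zero-amplitude operator reproduces the true mask exactly", {
  ph <- tiny_phantom()
  p0 <- operator_profile(0, 0, 0, 0, 0)
  m <- simulate_operator_mask(ph, p0, seed = 3)
  expect_identical(m, ph$mask)
  expect_equal(dice_coefficient(m, ph$mask), 1)
  expect_equal(relative_volume_difference(m, ph$mask), 0)
  expect_equal(mean_surface_distance(m, ph$mask, ph$spacing), 0)
  expect_equal(hausdorff_distance(m, ph$mask, ph$spacing), 0)
})

test_that("operator masks are seed-deterministic and single-component", {
  ph <- tiny_phantom()
  prof <- operator_preset("inter")
  m1 <- simulate_operator_mask(ph, prof, seed = 11)
  m2 <- simulate_operator_mask(ph, prof, seed = 11)
  expect_identical(m1, m2)
  # single connected component: largest component is the mask itself
  expect_identical(m1, vertebraFE:::largest_component(m1))
})

test_that("intra preset agrees with truth more than inter preset", {
  ph <- tiny_phantom()
  seeds <- 1:20
  dice_for <- function(preset) {
    vapply(seeds, function(s) {
      dice_coefficient(simulate_operator_mask(ph, preset, seed = s), ph$mask)
    }, numeric(1))
  }
  d_intra <- dice_for(operator_preset("intra"))
  d_inter <- dice_for(operator_preset("inter"))
  expect_gt(mean(d_intra), mean(d_inter))
})

test_that("volume error grows with the boundary-offset amplitude", {
  ph <- tiny_phantom()
  seeds <- 1:20
  mean_rvd <- function(offset_sd) {
    mean(vapply(seeds, function(s) {
      m <- simulate_operator_mask(ph, operator_profile(offset_sd, 0, 0, 0, 0),
                                  seed = s)
      relative_volume_difference(m, ph$mask)
    }, numeric(1)))
  }
  r <- vapply(c(0.1, 0.3, 0.6), mean_rvd, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("study sets have the 3 intra + 2 inter masks per vertebra", {
  pargs <- list(a = 9, b = 7, height = 14, spacing = 1, margin = 2)
  sc <- scanner_model(voxel_mm = 1)
  st <- make_study(n_control = 2, n_lytic = 1, seed = 5, phantom_args = pargs,
                   scanner = sc)
  expect_length(st$vertebrae, 3)
  expect_true(all(vapply(st$vertebrae, function(v) length(v$masks), integer(1)) == 5L))
  expect_equal(vapply(st$vertebrae, function(v) v$condition, character(1)),
               c("C", "C", "L"))
  st1 <- make_study(n_control = 1, n_lytic = 0, seed = 5, phantom_args = pargs,
                    scanner = sc)
  expect_length(st1$vertebrae[[1]]$masks, 5)
  # same master seed reproduces identical per-mask seeds and masks
  st2 <- make_study(n_control = 1, n_lytic = 0, seed = 5, phantom_args = pargs,
                    scanner = sc)
  expect_identical(st1$vertebrae[[1]]$seeds, st2$vertebrae[[1]]$seeds)
  expect_identical(st1$vertebrae[[1]]$masks, st2$vertebrae[[1]]$masks)
  expect_error(make_study(0, 0), "at least one")
})

test_that("study manifests round-trip to disk as NIfTI + JSON", {
  dir <- withr::local_tempdir()
  st <- make_study(n_control = 1, n_lytic = 0, seed = 2,
                   phantom_args = list(a = 9, b = 7, height = 14, spacing = 1,
                                       margin = 2),
                   scanner = scanner_model(voxel_mm = 1), out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 2)
  expect_length(man$vertebrae$V01$masks, 5)
  m <- read_nifti_volume(file.path(dir, "V01_op1_rep1.nii.gz"))
  expect_equal(m$spacing, 1)
  expect_identical(array(m$data > 0.5, dim(m$data)),
                   st$vertebrae[[1]]$masks$op1_rep1)
})
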