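test_that("structured TET10 meshing splits cubes into six tets", {
  mask <- array(TRUE, c(4, 4, 4))  # 4 mm cube at 1 mm voxels
  mesh <- mask_to_tet10_mesh(mask, spacing = 1, elem_size = 2)
  expect_equal(mesh$n_cubes, 8)
  expect_equal(nrow(mesh$conn), 48)
  expect_s3_class(mesh, "tet10_mesh")
  # volume conservation: union of kept cubes
  expect_equal(nrow(mesh$conn) * mesh$h^3 / 6, 8 * 2^3)
  expect_true(all(element_jacobians(mesh) > 0))
  expect_error(mask_to_tet10_mesh(array(FALSE, c(3, 3, 3)), 1), "empty")
  expect_error(mask_to_tet10_mesh(mask, spacing = 2, elem_size = 1), ">=")
})

test_that("meshes of random phantoms keep positive Jacobians and volume", {
  set.seed(21)
  for (rep in 1:5) {
    ph <- make_vertebra_phantom(a = runif(1, 8, 11), b = runif(1, 6, 9),
                                height = runif(1, 12, 16), spacing = 1,
                                margin = 2, waist = runif(1, 0, 0.2))
    mesh <- mask_to_tet10_mesh(ph$mask, 1, elem_size = 2)
    expect_true(all(element_jacobians(mesh) > 0))
    expect_equal(nrow(mesh$conn), 6 * mesh$n_cubes)
  }
})

test_that("landmarks sit on the surface and recover applied tilt", {
  ph <- small_phantom()
  lm <- place_landmarks(ph$mask, ph$spacing)
  surf <- surface_points(ph$mask, ph$spacing)
  for (pt in list(lm$superior[1, ], lm$inferior[3, ])) {
    d <- sqrt((surf[, 1] - pt[1])^2 + (surf[, 2] - pt[2])^2 +
                (surf[, 3] - pt[3])^2)
    expect_lt(min(d), 1.5 * ph$spacing)
  }
  # untilted body: landmark planes horizontal, bisector at mid-height
  al <- align_to_anatomical_frame(NULL, lm)
  expect_lt(al$frame$tilt_deg, 0.5)
  # 5 degree tilt about x recovered within 0.5 degrees (0.6 mm voxels)
  ph5 <- make_vertebra_phantom(tilt_deg = 5)
  lm5 <- place_landmarks(ph5$mask, ph5$spacing)
  al5 <- align_to_anatomical_frame(NULL, lm5)
  expect_lt(abs(al5$frame$tilt_deg - 5), 0.5)
  # analytic landmarks recover it exactly
  al5a <- align_to_anatomical_frame(NULL, ph5$landmarks)
  expect_lt(abs(al5a$frame$tilt_deg - 5), 1e-9)
})

test_that("anatomical alignment is rigid and idempotent", {
  ph <- small_phantom()
  mesh <- mask_to_tet10_mesh(ph$mask, ph$spacing, elem_size = 2)
  al <- align_to_anatomical_frame(mesh, ph$landmarks)
  # already-aligned phantom: rotation is the identity
  expect_lt(max(abs(al$frame$R - diag(3))), 1e-10)
  # rigid transform preserves pairwise distances
  idx <- seq(1, nrow(mesh$nodes), length.out = 20)
  d0 <- dist(mesh$nodes[idx, ])
  d1 <- dist(al$mesh$nodes[idx, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
  # collinear landmarks rejected
  bad <- ph$landmarks
  bad$superior[2, ] <- bad$superior[1, ] + c(1, 0, 0)
  bad$superior[3, ] <- bad$superior[1, ] + c(2, 0, 0)
  expect_error(align_to_anatomical_frame(mesh, bad), "collinear")
})

test_that("endplate bands capture the end faces of a flat cylinder", {
  mask <- array(TRUE, c(6, 6, 10))  # 6x6x10 mm bar at 1 mm voxels
  mesh <- mask_to_tet10_mesh(mask, 1, elem_size = 2)
  ep <- identify_endplate_nodes(mesh, delta = 0.1)
  # exactly the top/bottom face nodes (half-step lattice: 7x7 per face)
  expect_equal(sort(ep$cranial), sort(which(mesh$nodes[, 3] > 10 - 1e-9)))
  expect_equal(sort(ep$caudal), sort(which(mesh$nodes[, 3] < 1e-9)))
  expect_length(intersect(ep$cranial, ep$caudal), 0)
  # band nesting: larger delta grabs at least as many nodes
  n_prev <- 0
  for (delta in c(0.1, 1, 2.1)) {
    n_now <- length(identify_endplate_nodes(mesh, delta)$cranial)
    expect_gte(n_now, n_prev)
    n_prev <- n_now
  }
  # height between endplate centroids
  expect_equal(vertebral_height(mesh, ep), 10)
  # in-plane translation leaves Hm unchanged
  mesh2 <- mesh
  mesh2$nodes[, 1] <- mesh2$nodes[, 1] + 12.3
  expect_equal(vertebral_height(mesh2, ep), 10)
})

test_that("element densities average the calibrated field", {
  mask <- array(TRUE, c(6, 6, 6))
  mesh <- mask_to_tet10_mesh(mask, 1, elem_size = 2)
  # constant field
  img <- vertebraFE:::new_qct_image(array(0.17, c(6, 6, 6)), 1, "g/cm3")
  expect_equal(element_density(mesh, img), rep(0.17, nrow(mesh$conn)))
  # linear ramp: element mean equals the value at the element centroid
  ramp <- vertebraFE:::new_qct_image(
    array(rep((seq_len(6) - 0.5) * 0.01, each = 36), c(6, 6, 6)), 1, "g/cm3")
  rho <- element_density(mesh, ramp)
  centz <- vapply(seq_len(nrow(mesh$conn)), function(e) {
    mean(mesh$nodes[mesh$conn[e, 1:4], 3])
  }, numeric(1))
  # exact away from the volume border (trilinear extrapolation clamps there)
  interior <- centz > 2 & centz < 4
  expect_true(any(interior))
  expect_equal(rho[interior], centz[interior] * 0.01, tolerance = 1e-12)
  expect_error(element_density(mesh, vertebraFE:::new_qct_image(
    array(1, c(3, 3, 3)), 1, "g/cm3")), "outside")
})

test_that("density-elasticity laws return the published constants", {
  m1 <- material_from_density(rho_app = 1)
  expect_equal(m1$E, 4730)
  expect_equal(m1$sigma_y1, 21.7)
  expect_equal(m1$E_py / m1$E, 0.05)
  # ash-to-apparent conversion: rho_app = rho_QCT / 0.6
  m2 <- material_from_density(rho_qct = 0.6)
  expect_equal(m2$rho_app, 1)
  expect_equal(m2$E, 4730)
  m3 <- material_from_density(rho_app = 0.5)
  expect_equal(m3$E, 4730 * 0.5^1.56, tolerance = 1e-12)
  expect_equal(m3$E, 1.60e3, tolerance = 0.01)
  # strictly increasing in density; E_py/E constant
  rr <- seq(0.05, 1.5, by = 0.05)
  mm <- material_from_density(rho_app = rr)
  expect_true(all(diff(mm$E) > 0))
  expect_true(all(diff(mm$sigma_y1) > 0))
  expect_equal(mm$E_py / mm$E, rep(0.05, length(rr)))
  # floor material for lytic elements
  mf <- material_from_density(rho_qct = 0)
  expect_equal(mf$rho_app, 0.01)
  expect_gt(mf$E, 0)
  expect_error(material_from_density(rho_qct = -0.1), "negative")
})

test_that("model BMC matches the analytic phantom within 3%", {
  # protocol scale: 0.6 mm voxels, 1 mm elements on the full-size body
  ph <- make_vertebra_phantom()
  sc <- noise_free_scanner(voxel_mm = 0.6)
  cal <- calibrate_from_rods(render_qct(ph, sc, 1))
  model <- build_fe_model(ph$mask, ph$spacing, bmd = cal$image, elem_size = 1,
                          landmarks = ph$landmarks)
  expect_lt(abs(model$bmc - ph$bmc) / ph$bmc, 0.03)
  # uniform density: BMC = rho * V exactly
  mask <- array(TRUE, c(6, 6, 6))
  mu <- build_fe_model(mask, 1, elem_size = 2, uniform_density = 0.15,
                       align = FALSE)
  expect_equal(mu$bmc, 0.15 * 216 / 1000, tolerance = 1e-12)
  # BMC invariant under mesh refinement on a uniform field
  mu2 <- build_fe_model(mask, 1, elem_size = 1, uniform_density = 0.15,
                        align = FALSE)
  expect_equal(mu2$bmc, mu$bmc, tolerance = 1e-12)
  sm <- model_summary(mu)
  expect_equal(sum(sm$modulus_histogram$count), sm$n_elements)
  # phantom height recovered within one element size
  expect_lt(abs(model$Hm - ph$Hm), 1)
})
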