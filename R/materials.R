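#' Density-driven elasto-plastic material mapping for trabecular bone
#'
#' Maps QCT-equivalent density to the heterogeneous material of each
#' element: `rho_QCT` is taken as the ash density, converted to apparent
#' density by `rho_app = rho_QCT / 0.6`; the elastic modulus follows the
#' vertebral trabecular power law `E = 4730 * rho_app^1.56` MPa; the von
#' Mises yield stress follows the density-strength law
#' `sigma_y1 = 21.7 * rho_app^1.52` MPa; and the post-yield modulus is
#' `E_py = 0.05 * E` (a 95% reduction, realised as linear isotropic
#' hardening).
#'
#' Apparent densities below `floor_app` are mapped to the floor material so
#' that fully lytic elements keep a small positive stiffness.
#'
#' @param rho_qct QCT-equivalent (ash) density, g/cm^3 (vectorised).
#' @param rho_app apparent density, g/cm^3; supply instead of `rho_qct` to
#'   skip the ash-to-apparent conversion.
#' @param floor_app lower clamp on apparent density, g/cm^3.
#' @return data.frame with columns `rho_app`, `E` (MPa), `sigma_y1` (MPa),
#'   `E_py` (MPa).
#' @export
material_from_density <- function(rho_qct = NULL, rho_app = NULL,
                                  floor_app = 0.01) {
  stop_if_not(xor(is.null(rho_qct), is.null(rho_app)),
              "supply exactly one of rho_qct, rho_app")
  if (is.null(rho_app)) {
    stop_if_not(all(rho_qct >= 0), "negative density")
    rho_app <- rho_qct / 0.6
  } else {
    stop_if_not(all(rho_app >= 0), "negative density")
  }
  rho_app <- pmax(rho_app, floor_app)
  E <- 4730 * rho_app^1.56
  data.frame(rho_app = rho_app,
             E = E,
             sigma_y1 = 21.7 * rho_app^1.52,
             E_py = 0.05 * E)
}

#' Mean element density from a calibrated image
#'
#' Samples the calibrated density field at a fixed barycentric lattice of
#' interior points per element (trilinear interpolation) and averages.
#'
#' @param mesh a `tet10_mesh` in the image world frame (i.e. before
#'   anatomical alignment, or pass `world_nodes`).
#' @param bmd a `qct_image` in g/cm^3.
#' @param world_nodes optional N x 3 node coordinates in image world frame
#'   (if the mesh was aligned).
#' @return numeric(E) of per-element mean rho_QCT.
#' @export
element_density <- function(mesh, bmd, world_nodes = NULL) {
  stop_if_not(bmd$units == "g/cm3", "image must be calibrated (g/cm3)")
  nodes <- world_nodes %||% mesh$nodes
  # interior barycentric lattice: strictly positive integer compositions
  s <- 6L
  comp <- expand.grid(i = 1:(s - 3), j = 1:(s - 3), k = 1:(s - 3))
  comp <- comp[comp$i + comp$j + comp$k <= s - 1, , drop = FALSE]
  bary <- cbind(s - comp$i - comp$j - comp$k, comp$i, comp$j, comp$k) / s
  E <- nrow(mesh$conn)
  acc <- numeric(E)
  for (p in seq_len(nrow(bary))) {
    # affine map: x = sum L_i * corner_i
    pts <- bary[p, 1] * nodes[mesh$conn[, 1], , drop = FALSE] +
      bary[p, 2] * nodes[mesh$conn[, 2], , drop = FALSE] +
      bary[p, 3] * nodes[mesh$conn[, 3], , drop = FALSE] +
      bary[p, 4] * nodes[mesh$conn[, 4], , drop = FALSE]
    acc <- acc + sample_image_trilinear(bmd, pts)
  }
  acc / nrow(bary)
}

# trilinear interpolation of a qct_image at world points (N x 3)
sample_image_trilinear <- function(img, pts) {
  sp <- img$spacing
  dims <- img$dim
  # continuous voxel coordinate: voxel centre i at (i - 0.5) * sp + origin
  u <- sweep(pts, 2, img$origin) / sp + 0.5
  stop_if_not(all(u >= 0.5 - 1e-6) &&
                all(sweep(u, 2, dims) <= 0.5 + 1e-6),
              "sample point outside image volume")
  i0 <- pmin(pmax(floor(u), 1), matrix(rep(dims, each = nrow(u)), ncol = 3) - 1)
  f <- u - i0
  f <- pmin(pmax(f, 0), 1)
  g000 <- img$data[cbind(i0[, 1], i0[, 2], i0[, 3])]
  g100 <- img$data[cbind(i0[, 1] + 1, i0[, 2], i0[, 3])]
  g010 <- img$data[cbind(i0[, 1], i0[, 2] + 1, i0[, 3])]
  g110 <- img$data[cbind(i0[, 1] + 1, i0[, 2] + 1, i0[, 3])]
  g001 <- img$data[cbind(i0[, 1], i0[, 2], i0[, 3] + 1)]
  g101 <- img$data[cbind(i0[, 1] + 1, i0[, 2], i0[, 3] + 1)]
  g011 <- img$data[cbind(i0[, 1], i0[, 2] + 1, i0[, 3] + 1)]
  g111 <- img$data[cbind(i0[, 1] + 1, i0[, 2] + 1, i0[, 3] + 1)]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  (g000 * (1 - fx) + g100 * fx) * (1 - fy) * (1 - fz) +
    (g010 * (1 - fx) + g110 * fx) * fy * (1 - fz) +
    (g001 * (1 - fx) + g101 * fx) * (1 - fy) * fz +
    (g011 * (1 - fx) + g111 * fx) * fy * fz
}

#' Build a subject-specific FE model from a mask and calibrated image
#'
#' Runs the model-build stage end to end: structured TET10 meshing,
#' landmark placement, anatomical alignment, endplate identification,
#' body height and mean CSA, per-element density sampling and material
#' mapping.
#'
#' @param mask 3D logical segmentation (vertebral body), already smoothed
#'   if desired.
#' @param spacing mask voxel size, mm.
#' @param bmd calibrated `qct_image` (g/cm^3); NULL for a uniform density.
#' @param elem_size element size, mm.
#' @param uniform_density used when `bmd` is NULL, g/cm^3 (rho_QCT).
#' @param align apply the landmark-based anatomical alignment (default);
#'   without it the grid frame is used directly.
#' @param floor_app apparent-density floor passed to
#'   [material_from_density()].
#' @param endplate_delta band width for endplate node identification, mm.
#' @param landmarks optional precomputed landmarks (e.g. phantom ground
#'   truth).
#' @return object of class `fe_model`.
#' @export
build_fe_model <- function(mask, spacing, bmd = NULL, elem_size = 1,
                           uniform_density = NULL, align = TRUE,
                           floor_app = 0.01, endplate_delta = NULL,
                           landmarks = NULL) {
  mesh <- mask_to_tet10_mesh(mask, spacing, elem_size)
  world_nodes <- mesh$nodes
  frame <- NULL
  levels <- NULL
  if (align) {
    lm <- landmarks %||% place_landmarks(mask, spacing)
    al <- align_to_anatomical_frame(mesh, lm)
    mesh <- al$mesh
    frame <- al$frame
    # anatomical endplate levels in frame coordinates: superior plane at
    # z = 0 (frame origin), inferior at the landmark-centroid distance
    hm_lm <- sum((colMeans(lm$superior) - colMeans(lm$inferior)) * frame$R[, 3])
    levels <- c(-abs(hm_lm), 0)
  }
  endplates <- identify_endplate_nodes(mesh, endplate_delta %||% (0.3 * mesh$h),
                                       levels = levels)
  Hm <- vertebral_height(mesh, endplates)
  csa <- cross_sectional_area(mask, spacing)
  if (!is.null(bmd)) {
    rho <- element_density(mesh, bmd, world_nodes = world_nodes)
  } else {
    rho <- rep(uniform_density %||% 0.18, nrow(mesh$conn))
  }
  mat <- material_from_density(rho_qct = rho, floor_app = floor_app)
  vol_e <- mesh$h^3 / 6
  structure(list(mesh = mesh, world_nodes = world_nodes, frame = frame,
                 endplates = endplates, Hm = Hm, csa = csa,
                 rho_qct = rho, material = mat,
                 bmc = sum(rho * vol_e) / 1000,
                 elem_volume = vol_e),
            class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("FE model: %d nodes, %d TET10 elements @ %g mm\n",
              nrow(x$mesh$nodes), nrow(x$mesh$conn), x$mesh$h))
  cat(sprintf("  Hm %.2f mm, CSA %.1f mm2, BMC %.3f g\n", x$Hm, x$csa, x$bmc))
  cat(sprintf("  E range %.3g .. %.3g MPa (median %.3g)\n",
              min(x$material$E), max(x$material$E), stats::median(x$material$E)))
  invisible(x)
}

#' Model summary: bone mineral content and element-modulus histogram
#'
#' @param model an `fe_model`.
#' @param breaks histogram bin edges for E, MPa.
#' @return list with `bmc` (g), `modulus_histogram` (data.frame of bin
#'   edges and counts), `n_elements`.
#' @export
model_summary <- function(model, breaks = seq(0, 6000, by = 250)) {
  E <- model$material$E
  breaks[length(breaks)] <- max(breaks[length(breaks)], max(E) + 1)
  h <- hist(E, breaks = breaks, plot = FALSE)
  list(bmc = model$bmc,
       modulus_histogram = data.frame(lower = h$breaks[-length(h$breaks)],
                                      upper = h$breaks[-1],
                                      count = h$counts),
       n_elements = length(E))
}
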