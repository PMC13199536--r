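#' Operator segmentation-variability profile
#'
#' Parameterises a simulated human operator contouring a vertebra on QCT
#' slices. The perturbation acts additively in signed-distance space on the
#' true mask, which guarantees topologically valid masks and gives one
#' interpretable amplitude per variability source:
#' a global erode/dilate bias drawn once per segmentation, a smooth
#' correlated surface displacement, an independent per-slice contour offset
#' (emulating slice-by-slice contouring), and a Bernoulli inclusion of an
#' ambiguous surface feature (an osteophyte-like bump, the mechanism behind
#' worst-case inter-operator surface distances).
#'
#' @param offset_sd SD of the global signed-distance offset, mm.
#' @param jitter_amp amplitude (SD) of the correlated surface jitter, mm.
#' @param jitter_corr_mm correlation length of the surface jitter, mm.
#' @param slice_amp SD of the per-slice contour offset, mm.
#' @param p_ambiguous probability that the ambiguous feature is included.
#' @return an object of class `operator_profile`.
#' @export
operator_profile <- function(offset_sd = 0.15, jitter_amp = 0.25,
                             jitter_corr_mm = 5, slice_amp = 0.15,
                             p_ambiguous = 0.1) {
  stop_if_not(offset_sd >= 0 && jitter_amp >= 0 && slice_amp >= 0 &&
                jitter_corr_mm >= 0, "all amplitudes must be non-negative")
  stop_if_not(p_ambiguous >= 0 && p_ambiguous <= 1,
              "inclusion probability must be in [0, 1]")
  structure(list(offset_sd = offset_sd, jitter_amp = jitter_amp,
                 jitter_corr_mm = jitter_corr_mm, slice_amp = slice_amp,
                 p_ambiguous = p_ambiguous),
            class = "operator_profile")
}

#' Preset operator profiles
#'
#' `intra` emulates repeat segmentations by one operator; `inter` emulates
#' different operators and is noisier in every component. The amplitudes are
#' calibration knobs of the generator, not measured quantities.
#' @param which `"intra"` or `"inter"`.
#' @export
operator_preset <- function(which = c("intra", "inter")) {
  which <- match.arg(which)
  if (which == "intra") {
    operator_profile(offset_sd = 0.12, jitter_amp = 0.2, jitter_corr_mm = 5,
                     slice_amp = 0.12, p_ambiguous = 0.05)
  } else {
    operator_profile(offset_sd = 0.3, jitter_amp = 0.45, jitter_corr_mm = 8,
                     slice_amp = 0.25, p_ambiguous = 0.3)
  }
}

#' Exact Euclidean distance transform of a 3D mask
#'
#' Distance (mm) from every voxel centre to the nearest `TRUE` voxel centre.
#' @param mask 3D logical array.
#' @param spacing voxel spacing, mm (scalar or length 3).
#' @export
distance_transform <- function(mask, spacing) {
  stop_if_not(length(dim(mask)) == 3, "mask must be a 3D array")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  d <- edt3d_cpp(as.logical(mask), dim(mask), as.numeric(spacing))
  array(d, dim(mask))
}

# Signed distance to the mask boundary: negative inside, positive outside.
# Voxel-centre distances are corrected by half a voxel so that voxels
# adjacent to the boundary sit at +/- spacing/2 rather than +/- spacing;
# sub-voxel boundary displacements then act on the boundary layer.
signed_distance <- function(mask, spacing) {
  dout <- distance_transform(mask, spacing)   # 0 inside, >0 outside
  din <- distance_transform(!mask, spacing)   # 0 outside, >0 inside
  d <- dout - din
  d - 0.5 * spacing * sign(d)
}

largest_component <- function(mask) {
  out <- largest_component_cpp(as.logical(mask), dim(mask))
  array(out, dim(mask))
}

#' Simulate one operator segmentation of a phantom
#'
#' Perturbs the phantom's true mask in signed-distance space according to an
#' [operator_profile()], then keeps the largest connected component. With
#' all amplitudes zero and inclusion probability zero the true mask is
#' returned exactly.
#'
#' @param phantom a [make_vertebra_phantom()].
#' @param profile an [operator_profile()].
#' @param seed integer seed; the same seed reproduces the same mask.
#' @return 3D logical array on the phantom grid.
#' @export
simulate_operator_mask <- function(phantom, profile, seed = 1) {
  stop_if_not(inherits(profile, "operator_profile"), "profile must be an operator_profile")
  mask <- phantom$mask
  sp <- phantom$spacing
  if (profile$p_ambiguous > 0 || profile$offset_sd > 0 ||
      profile$jitter_amp > 0 || profile$slice_amp > 0) {
    with_seed(split_seed(seed, 23L), {
      if (profile$p_ambiguous > 0 && runif(1) < profile$p_ambiguous) {
        mask <- mask | osteophyte_mask(phantom)
      }
      if (profile$offset_sd > 0 || profile$jitter_amp > 0 || profile$slice_amp > 0) {
        sd_field <- signed_distance(mask, sp)
        field <- 0
        if (profile$offset_sd > 0) field <- field + rnorm(1, 0, profile$offset_sd)
        if (profile$jitter_amp > 0) {
          noise <- array(rnorm(prod(dim(mask))), dim(mask))
          smooth <- gaussian_blur3d(noise, profile$jitter_corr_mm / sp)
          smooth <- smooth / sd(smooth)
          field <- field + profile$jitter_amp * smooth
        }
        if (profile$slice_amp > 0) {
          zoff <- rnorm(dim(mask)[3], 0, profile$slice_amp)
          field <- field + array(rep(zoff, each = prod(dim(mask)[1:2])), dim(mask))
        }
        mask <- sd_field <= field
      }
    })
  }
  if (!any(mask)) stop("perturbation removed the whole mask", call. = FALSE)
  largest_component(mask)
}

# half-ellipsoid bump on the anterior equator of the body: the ambiguous
# feature operators may or may not include
osteophyte_mask <- function(phantom, radii = c(5, 4, 4)) {
  g <- grid_coords(phantom$dim, phantom$spacing)
  f <- waist_scale(0.5, phantom$waist)
  centre_body <- c(0, phantom$b * f, 0)
  th <- phantom$tilt_deg * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  c_world <- as.numeric(R %*% centre_body + phantom$centre)
  m <- array(FALSE, phantom$dim)
  dx2 <- ((g$x - c_world[1]) / radii[1])^2
  for (k in seq_along(g$z)) {
    dz2 <- ((g$z[k] - c_world[3]) / radii[3])^2
    iny <- which(((g$y - c_world[2]) / radii[2])^2 + dz2 <= 1 & g$y >= c_world[2] - 1e-9)
    for (j in iny) {
      lim <- 1 - ((g$y[j] - c_world[2]) / radii[2])^2 - dz2
      m[dx2 <= lim, j, k] <- TRUE
    }
  }
  m
}

#' Generate a reproducibility study set
#'
#' For each vertebra: one QCT rendering and five simulated segmentations
#' (three repeats by Operator-1 under the intra profile; one each by
#' Operator-2 and Operator-3 under the inter profile), mirroring a
#' three-operator reproducibility design. Control vertebrae have no
#' lesions; lytic vertebrae carry one low-density lesion.
#'
#' @param n_control,n_lytic number of control / lytic vertebrae.
#' @param presets list with elements `intra` and `inter`
#'   ([operator_profile()] objects).
#' @param seed master seed; per-mask seeds are derived from it.
#' @param phantom_args arguments passed to [make_vertebra_phantom()].
#' @param scanner a [scanner_model()].
#' @param lesion lesion specification applied to lytic vertebrae.
#' @param out_dir optional directory: QCT volumes and masks are written as
#'   NIfTI-1 `.nii.gz` plus a JSON manifest.
#' @return an object of class `vfe_study`: list of vertebrae, each with
#'   `phantom`, `qct`, `masks` (named list of 5), `seeds`, `condition`.
#' @export
make_study <- function(n_control = 3, n_lytic = 3,
                       presets = list(intra = operator_preset("intra"),
                                      inter = operator_preset("inter")),
                       seed = 1, phantom_args = list(),
                       scanner = scanner_model(), lesion = NULL,
                       out_dir = NULL) {
  stop_if_not(n_control + n_lytic >= 1, "at least one vertebra required")
  conditions <- c(rep("C", n_control), rep("L", n_lytic))
  vertebrae <- list()
  for (v in seq_along(conditions)) {
    cond <- conditions[v]
    pargs <- phantom_args
    if (cond == "L") {
      # default lytic lesion scaled to the body: off-centre sphere at a
      # quarter of the smaller semi-axis, near-zero residual density
      a0 <- pargs$a %||% formals(make_vertebra_phantom)$a
      b0 <- pargs$b %||% formals(make_vertebra_phantom)$b
      h0 <- pargs$height %||% formals(make_vertebra_phantom)$height
      les <- lesion %||% list(centre = c(0.15 * a0, 0, 0.08 * h0),
                              radius = 0.28 * min(a0, b0), multiplier = 0.05)
      pargs$lesions <- list(les)
    }
    phantom <- do.call(make_vertebra_phantom, pargs)
    qct_seed <- split_seed(seed, v, 0L)
    qct <- render_qct(phantom, scanner, seed = qct_seed)
    masks <- list(); seeds <- list(qct = qct_seed)
    # operator 1, repeats 1..3 (intra); operators 2..3, repeat 1 (inter)
    plan <- list(op1_rep1 = c(1L, 1L), op1_rep2 = c(1L, 2L), op1_rep3 = c(1L, 3L),
                 op2_rep1 = c(2L, 1L), op3_rep1 = c(3L, 1L))
    for (nm in names(plan)) {
      op <- plan[[nm]][1]
      prof <- if (op == 1L) presets$intra else presets$inter
      s <- split_seed(seed, v, op, plan[[nm]][2])
      masks[[nm]] <- simulate_operator_mask(phantom, prof, seed = s)
      seeds[[nm]] <- s
    }
    vertebrae[[v]] <- list(id = sprintf("V%02d", v), condition = cond,
                           phantom = phantom, qct = qct, masks = masks,
                           seeds = seeds)
  }
  study <- structure(list(vertebrae = vertebrae, seed = seed,
                          presets = presets, scanner = scanner),
                     class = "vfe_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.vfe_study <- function(x, ...) {
  nC <- sum(vapply(x$vertebrae, function(v) v$condition == "C", logical(1)))
  nL <- length(x$vertebrae) - nC
  cat(sprintf("Reproducibility study: %d vertebrae (%d control, %d lytic), %d masks, master seed %d\n",
              length(x$vertebrae), nC, nL, 5 * length(x$vertebrae), x$seed))
  invisible(x)
}
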