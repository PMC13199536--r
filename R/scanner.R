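#' Scanner model for synthetic QCT rendering
#'
#' Describes the affine HU-to-density response of the simulated scanner, its
#' noise and point-spread blur, and the geometry of the in-line five-rod
#' calibration phantom (15 mm diameter rods at equivalent densities
#' 0.00-0.20 g/cm^3, the clinical QCT protocol emulated here).
#'
#' @param slope_hu HU per g/cm^3 (must be positive).
#' @param intercept_hu HU offset of the scanner response.
#' @param noise_sd Gaussian noise standard deviation, HU.
#' @param blur_sd point-spread Gaussian blur standard deviation, mm.
#' @param voxel_mm isotropic voxel size, mm.
#' @param rod_bmd equivalent densities of the five rods, g/cm^3, strictly
#'   increasing.
#' @param rod_diameter_mm rod diameter, mm.
#' @param rod_gap_mm in-plane gap between adjacent rods, mm.
#' @return an object of class `scanner_model`.
#' @export
scanner_model <- function(slope_hu = 1000, intercept_hu = -20,
                          noise_sd = 15, blur_sd = 0.3, voxel_mm = 0.6,
                          rod_bmd = c(0, 0.05, 0.10, 0.15, 0.20),
                          rod_diameter_mm = 15, rod_gap_mm = 4) {
  stop_if_not(slope_hu > 0, "HU slope must be positive")
  stop_if_not(voxel_mm > 0, "voxel size must be positive")
  stop_if_not(noise_sd >= 0, "noise SD must be non-negative")
  stop_if_not(blur_sd >= 0, "blur SD must be non-negative")
  stop_if_not(length(rod_bmd) == 5 && all(diff(rod_bmd) > 0),
              "exactly 5 rods with strictly increasing BMD required")
  structure(list(slope_hu = slope_hu, intercept_hu = intercept_hu,
                 noise_sd = noise_sd, blur_sd = blur_sd, voxel_mm = voxel_mm,
                 rod_bmd = rod_bmd, rod_diameter_mm = rod_diameter_mm,
                 rod_gap_mm = rod_gap_mm),
            class = "scanner_model")
}

new_qct_image <- function(data, spacing, units, origin = c(0, 0, 0),
                          rods = NULL) {
  structure(list(data = data, spacing = spacing, units = units,
                 origin = origin, rods = rods, dim = dim(data)),
            class = "qct_image")
}

#' @export
print.qct_image <- function(x, ...) {
  cat(sprintf("QCT image: %d x %d x %d voxels @ %g mm [%s]\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, x$units))
  cat(sprintf("  intensity range %.3g .. %.3g\n", min(x$data), max(x$data)))
  if (!is.null(x$rods)) cat(sprintf("  calibration rods: %d\n", nrow(x$rods$centres)))
  invisible(x)
}

#' Render a synthetic QCT volume from a phantom
#'
#' Maps the phantom's true density field through the scanner's affine
#' HU response, renders the five-rod calibration phantom beneath the
#' vertebra, applies Gaussian point-spread blur and additive Gaussian
#' noise. The output volume extends the phantom grid in -y (and x, if
#' needed) to make room for the rods; the origin records the offset so
#' that world coordinates agree between mask and scan.
#'
#' @param phantom a [make_vertebra_phantom()] object.
#' @param scanner a [scanner_model()].
#' @param seed integer seed controlling the noise field.
#' @param include_rods render the calibration rods (default TRUE).
#' @return a `qct_image` in HU, with rod geometry attached.
#' @export
render_qct <- function(phantom, scanner = scanner_model(), seed = 1,
                       include_rods = TRUE) {
  sp <- scanner$voxel_mm
  stop_if_not(abs(sp - phantom$spacing) < 1e-9,
              "scanner voxel size must match the phantom grid")
  dims <- phantom$dim
  origin <- c(0, 0, 0)
  rods <- NULL
  if (include_rods) {
    dia <- scanner$rod_diameter_mm
    pitch <- dia + scanner$rod_gap_mm
    row_width <- 5 * pitch - scanner$rod_gap_mm + 2 * sp
    ext_x <- dims[1] * sp
    pad_x <- max(0, ceiling((row_width - ext_x) / 2 / sp))
    pad_y <- ceiling((dia + 6) / sp)
    dims <- c(dims[1] + 2 * pad_x, dims[2] + pad_y, dims[3])
    origin <- c(-pad_x * sp, -pad_y * sp, 0)
    cx <- origin[1] + dims[1] * sp / 2
    centres_x <- cx + (seq_len(5) - 3) * pitch
    rods <- list(centres = cbind(x = centres_x,
                                 y = origin[2] + (dia / 2 + 2)),
                 diameter = dia, bmd = scanner$rod_bmd)
  }

  g <- grid_coords(dims, sp, origin)
  bmd <- array(0, dims)
  # paste phantom density field into the padded volume
  off <- round(-origin / sp)
  ix <- off[1] + seq_len(phantom$dim[1])
  iy <- off[2] + seq_len(phantom$dim[2])
  iz <- off[3] + seq_len(phantom$dim[3])
  bmd[ix, iy, iz] <- phantom$density
  if (include_rods) {
    r <- rods$diameter / 2
    for (q in seq_len(5)) {
      inx <- which((g$x - rods$centres[q, 1])^2 <= r^2)
      for (i in inx) {
        dy2 <- r^2 - (g$x[i] - rods$centres[q, 1])^2
        iny <- which((g$y - rods$centres[q, 2])^2 <= dy2)
        if (rods$bmd[q] > 0) bmd[i, iny, ] <- rods$bmd[q]
        # zero-density rod is water-equivalent: leave field at 0
      }
    }
  }

  hu <- scanner$slope_hu * bmd + scanner$intercept_hu
  if (scanner$blur_sd > 0) hu <- gaussian_blur3d(hu, scanner$blur_sd / sp)
  if (scanner$noise_sd > 0) {
    noise <- with_seed(split_seed(seed, 11L),
                       array(rnorm(prod(dims), 0, scanner$noise_sd), dims))
    hu <- hu + noise
  }
  new_qct_image(hu, sp, "HU", origin, rods)
}

# separable Gaussian blur, sigma in voxels, kernel truncated at 3 sigma,
# edges renormalised against a blurred all-ones field
gaussian_blur3d <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  half <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  w <- exp(-0.5 * ((-half:half) / sigma_vox)^2)
  w <- w / sum(w)
  norm <- array(1, dim(x))
  for (d in 1:3) {
    x <- shift_convolve(x, w, d)
    norm <- shift_convolve(norm, w, d)
  }
  x / norm
}

# convolve along dimension d by shift-and-add with zero padding
shift_convolve <- function(x, w, d) {
  half <- (length(w) - 1L) / 2L
  dims <- dim(x)
  out <- array(0, dims)
  n <- dims[d]
  idx_full <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  for (s in -half:half) {
    src <- idx_full; dst <- idx_full
    lo <- max(1L, 1L - s); hi <- min(n, n - s)
    if (lo > hi) next
    dst[[d]] <- lo:hi
    src[[d]] <- (lo:hi) + s
    out[dst[[1]], dst[[2]], dst[[3]]] <- out[dst[[1]], dst[[2]], dst[[3]]] +
      w[s + half + 1L] * x[src[[1]], src[[2]], src[[3]]]
  }
  out
}
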