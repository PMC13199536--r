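#' Mean HU inside the calibration-rod ROIs
#'
#' Extracts the mean intensity over a prismatic region of interest centred
#' on each rod axis: square cross-section with side equal to half the rod
#' diameter (7.5 mm for the 15 mm protocol rods), extended along the full
#' rod length within the field of view.
#'
#' @param qct a `qct_image` in HU.
#' @param rods rod geometry (`list(centres = matrix[5, c(x, y)], diameter,
#'   bmd)`); defaults to the geometry attached by [render_qct()].
#' @return numeric(5), mean HU per rod in increasing-BMD order.
#' @export
extract_rod_means <- function(qct, rods = qct$rods) {
  stop_if_not(!is.null(rods), "no rod geometry available")
  half <- rods$diameter / 4  # ROI side = diameter / 2
  g <- grid_coords(qct$dim, qct$spacing, qct$origin)
  means <- numeric(nrow(rods$centres))
  ord <- order(rods$bmd)
  for (q in seq_along(means)) {
    cx <- rods$centres[ord[q], 1]; cy <- rods$centres[ord[q], 2]
    ix <- which(abs(g$x - cx) <= half)
    iy <- which(abs(g$y - cy) <= half)
    stop_if_not(length(ix) > 0 && length(iy) > 0 &&
                  cx - half >= qct$origin[1] && cy - half >= qct$origin[2] &&
                  cx + half <= qct$origin[1] + qct$dim[1] * qct$spacing &&
                  cy + half <= qct$origin[2] + qct$dim[2] * qct$spacing,
                "rod ROI exits the image volume")
    means[q] <- mean(qct$data[ix, iy, ])
  }
  means
}

#' Fit the densitometric calibration
#'
#' Ordinary least squares of the known rod equivalent densities on the
#' measured mean HU: the direction used to convert HU volumes to BMD.
#'
#' @param mean_hu numeric(5), mean HU per rod.
#' @param rod_bmd numeric(5), known equivalent densities, g/cm^3.
#' @return an object of class `calibration_model` with `slope`
#'   (g/cm^3 per HU), `intercept` (g/cm^3) and `r_squared`.
#' @export
fit_densitometric_calibration <- function(mean_hu,
                                          rod_bmd = c(0, 0.05, 0.10, 0.15, 0.20)) {
  stop_if_not(length(mean_hu) == 5 && length(rod_bmd) == 5,
              "exactly 5 paired observations required")
  stop_if_not(sd(mean_hu) > 0, "degenerate calibration: zero HU variance")
  fit <- lm(rod_bmd ~ mean_hu)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((rod_bmd - mean(rod_bmd))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 mean_hu = mean_hu, rod_bmd = rod_bmd),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Densitometric calibration: BMD = %.6g * HU + %.6g  (R2 = %.6f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Apply a densitometric calibration to a QCT image
#'
#' Voxelwise affine map from HU to BMD (g/cm^3). Calibrated densities below
#' `floor` are clamped there: the density-elasticity laws are undefined for
#' negative density and lytic tissue is modelled as near-zero density.
#'
#' @param qct a `qct_image` in HU.
#' @param model a `calibration_model`.
#' @param floor lower clamp for calibrated densities, g/cm^3.
#' @return a `qct_image` in g/cm^3.
#' @export
calibrate_image <- function(qct, model, floor = 0) {
  stop_if_not(inherits(model, "calibration_model"), "model must be a calibration_model")
  stop_if_not(qct$units == "HU", "image already calibrated (units g/cm3)")
  bmd <- model$slope * qct$data + model$intercept
  bmd[bmd < floor] <- floor
  new_qct_image(bmd, qct$spacing, "g/cm3", qct$origin, qct$rods)
}

#' One-call calibration from the attached rod geometry
#' @param qct a `qct_image` in HU with rod geometry attached.
#' @param rod_bmd known rod densities, g/cm^3.
#' @inheritParams calibrate_image
#' @return list with `image` (calibrated `qct_image`) and `model`.
#' @export
calibrate_from_rods <- function(qct, rod_bmd = qct$rods$bmd, floor = 0) {
  means <- extract_rod_means(qct)
  model <- fit_densitometric_calibration(means, sort(rod_bmd))
  list(image = calibrate_image(qct, model, floor), model = model)
}
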