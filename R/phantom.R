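#' Vertebra-like phantom with known geometry and density
#'
#' Builds a ground-truth digital phantom of a vertebral body: an elliptic
#' cylinder (semi-axes `a`, `b` in mm, height `height` mm) with an optional
#' cosine waist concavity, optional posterior elements, and optional
#' spherical lytic lesions where the density is multiplied by a factor in
#' `[0, 1)`. The phantom carries an analytic description (landmarks, height,
#' mean cross-sectional area, bone mineral content) alongside its voxelised
#' true mask and density field, so every downstream stage of the pipeline
#' can be verified against closed-form ground truth.
#'
#' The true mask is the analytic solid sampled at voxel centres. The density
#' field is the QCT-equivalent density rho_QCT in g/cm^3, uniform at
#' `base_density` inside the body apart from the lesions.
#'
#' @param a,b in-plane semi-axes of the body ellipse, mm.
#' @param height body height, mm.
#' @param waist waist-concavity amplitude as a fraction of the semi-axes;
#'   the in-plane scale along the height is `1 - waist * sin(pi * t)` with
#'   `t` in `[0, 1]`, so the body narrows at mid-height and has full section
#'   at the endplates.
#' @param tilt_deg rigid tilt of the body about the x axis, degrees.
#' @param lesions list of lesions, each `list(centre = c(x, y, z), radius,
#'   multiplier)` with `centre` in mm in the body frame (origin at body
#'   centre) and `multiplier` in `[0, 1)`.
#' @param base_density rho_QCT of intact bone, g/cm^3.
#' @param posterior logical; add schematic posterior elements (two pedicle
#'   cylinders and a spinous block). Off by default: the mechanical analysis
#'   keys on the vertebral body.
#' @param spacing isotropic voxel size, mm.
#' @param margin empty margin around the body, mm.
#' @param endplate_fraction fraction of slices at each body end treated as
#'   endplate bands and excluded from the analytic mean CSA.
#' @return an object of class `vertebra_phantom`.
#' @export
make_vertebra_phantom <- function(a = 20, b = 15, height = 30, waist = 0.15,
                                  tilt_deg = 0, lesions = list(),
                                  base_density = 0.18, posterior = FALSE,
                                  spacing = 0.6, margin = 3,
                                  endplate_fraction = 0.1) {
  stop_if_not(a > 0 && b > 0 && height > 0, "body semi-axes and height must be positive")
  stop_if_not(waist >= 0 && waist < 1, "waist must be in [0, 1)")
  stop_if_not(spacing > 0, "spacing must be positive")
  stop_if_not(min(2 * a, 2 * b, height) / spacing >= 10,
              "grid too coarse to resolve the body (< 10 voxels across)")
  for (les in lesions) {
    stop_if_not(is.numeric(les$multiplier) && les$multiplier >= 0 && les$multiplier < 1,
                "lesion multiplier must be in [0, 1)")
    stop_if_not(lesion_inside_body(les, a, b, height, waist),
                "lesion does not lie strictly inside the body")
  }

  post_depth <- if (posterior) 1.6 * b else 0
  ext_x <- 2 * (a + margin)
  ext_y <- 2 * (b + margin) + post_depth
  ext_z <- height + 2 * margin + 2 * abs(sin(tilt_deg * pi / 180)) * b
  dim <- as.integer(ceiling(c(ext_x, ext_y, ext_z) / spacing))
  # body centre placed so the body (plus optional posterior elements) fits
  centre <- c(ext_x / 2, b + margin, ext_z / 2)

  g <- grid_coords(dim, spacing)
  solid <- phantom_solid_mask(g, centre, a, b, height, waist, tilt_deg, posterior)
  density <- array(0, dim)
  density[solid$body | solid$posterior] <- base_density
  for (les in lesions) {
    inles <- lesion_mask(g, centre, tilt_deg, les)
    density[inles & solid$body] <- base_density * les$multiplier
  }

  mask <- solid$body | solid$posterior

  # analytic quantities (all in mm / g/cm^3), on the untilted body
  f2_int <- integrate(function(t) (1 - waist * sin(pi * t))^2, 0, 1)$value
  q <- endplate_fraction
  f2_mid <- integrate(function(t) (1 - waist * sin(pi * t))^2, q, 1 - q)$value / (1 - 2 * q)
  body_volume <- pi * a * b * height * f2_int
  lesion_deficit <- sum(vapply(lesions, function(l) {
    (1 - l$multiplier) * 4 / 3 * pi * l$radius^3
  }, numeric(1)))
  bmc <- (base_density * body_volume - base_density * lesion_deficit) / 1000 # mm^3 * g/cm^3 -> g

  structure(list(
    a = a, b = b, height = height, waist = waist, tilt_deg = tilt_deg,
    lesions = lesions, base_density = base_density, posterior = posterior,
    spacing = spacing, dim = dim, centre = centre,
    mask = mask, body_mask = solid$body, density = density,
    landmarks = phantom_landmarks(a, b, height, waist, tilt_deg, centre),
    Hm = height,
    csa = pi * a * b * f2_mid,
    csa_full = pi * a * b * f2_int,
    bmc = bmc,
    endplate_fraction = endplate_fraction
  ), class = "vertebra_phantom")
}

# in-plane scale factor of the waisted ellipse at relative height t in [0,1]
waist_scale <- function(t, waist) 1 - waist * sin(pi * pmin(pmax(t, 0), 1))

# rotate world coords into the (possibly tilted) body frame
body_frame_coords <- function(g, centre, tilt_deg) {
  th <- tilt_deg * pi / 180
  nx <- length(g$x); ny <- length(g$y); nz <- length(g$z)
  X <- g$x - centre[1]
  Y <- g$y - centre[2]
  Z <- g$z - centre[3]
  # R_x(-th) applied to (x, y, z): body q = R^T p
  Ym <- outer(Y, Z, function(y, z) cos(th) * y + sin(th) * z)
  Zm <- outer(Y, Z, function(y, z) -sin(th) * y + cos(th) * z)
  list(X = X, Ym = Ym, Zm = Zm, nx = nx, ny = ny, nz = nz)
}

phantom_solid_mask <- function(g, centre, a, b, height, waist, tilt_deg, posterior) {
  bf <- body_frame_coords(g, centre, tilt_deg)
  nx <- bf$nx; ny <- bf$ny; nz <- bf$nz
  body <- array(FALSE, c(nx, ny, nz))
  post <- array(FALSE, c(nx, ny, nz))
  X2 <- bf$X^2
  ped_r <- 0.15 * b
  ped_x <- c(-0.55, 0.55) * a
  for (k in seq_len(nz)) {
    qy <- bf$Ym[, k]; qz <- bf$Zm[, k]
    t <- (qz + height / 2) / height
    f <- waist_scale(t, waist)
    for (j in which(abs(qz) <= height / 2)) {
      fj <- f[j]
      r2 <- 1 - (qy[j] / (b * fj))^2
      if (r2 > 0) body[X2 <= (a * fj)^2 * r2, j, k] <- TRUE
    }
    if (posterior) {
      # pedicles: cylinders along y behind the body; spinous block further back
      jped <- which(qy < -0.55 * b & qy >= -1.4 * b & abs(qz) <= 0.2 * height)
      for (j in jped) {
        post[(bf$X - ped_x[1])^2 <= ped_r^2, j, k] <- TRUE
        post[(bf$X - ped_x[2])^2 <= ped_r^2, j, k] <- TRUE
      }
      jsp <- which(qy < -1.4 * b & qy >= -1.8 * b & abs(qz) <= 0.15 * height)
      for (j in jsp) post[abs(bf$X) <= 0.2 * a, j, k] <- TRUE
    }
  }
  list(body = body, posterior = post)
}

lesion_mask <- function(g, centre, tilt_deg, les) {
  bf <- body_frame_coords(g, centre, tilt_deg)
  nx <- bf$nx; ny <- bf$ny; nz <- bf$nz
  m <- array(FALSE, c(nx, ny, nz))
  c0 <- les$centre; r <- les$radius
  dx2 <- (bf$X - c0[1])^2
  for (k in seq_len(nz)) {
    dy <- bf$Ym[, k] - c0[2]
    dz <- bf$Zm[, k] - c0[3]
    d2 <- dy^2 + dz^2
    keep <- which(d2 <= r^2)
    for (j in keep) m[dx2 <= r^2 - d2[j], j, k] <- TRUE
  }
  m
}

lesion_inside_body <- function(les, a, b, height, waist) {
  c0 <- les$centre; r <- les$radius
  if (abs(c0[3]) + r >= height / 2) return(FALSE)
  t <- (c0[3] + height / 2) / height
  f <- waist_scale(t, waist) # conservative: use scale at lesion centre height
  rad <- sqrt((c0[1] / (a * f))^2 + (c0[2] / (b * f))^2)
  margin <- r / (f * min(a, b))
  rad + margin < 1
}

# 6 landmarks: most anterior point and the two posterior corners on each
# endplate; anterior is the +y direction of the body frame.
phantom_landmarks <- function(a, b, height, waist, tilt_deg, centre) {
  th <- tilt_deg * pi / 180
  R <- matrix(c(1, 0, 0,
                0, cos(th), -sin(th),
                0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  pts_body <- rbind(
    c(0, b, height / 2),                              # superior anterior
    c(-a * cos(pi / 6), -b * sin(pi / 6), height / 2), # superior posterior-left
    c(a * cos(pi / 6), -b * sin(pi / 6), height / 2),  # superior posterior-right
    c(0, b, -height / 2),
    c(-a * cos(pi / 6), -b * sin(pi / 6), -height / 2),
    c(a * cos(pi / 6), -b * sin(pi / 6), -height / 2)
  )
  world <- t(R %*% t(pts_body)) + matrix(centre, 6, 3, byrow = TRUE)
  list(superior = world[1:3, , drop = FALSE], inferior = world[4:6, , drop = FALSE])
}

#' @export
print.vertebra_phantom <- function(x, ...) {
  cat("Vertebra phantom\n")
  cat(sprintf("  body: %g x %g mm semi-axes, height %g mm, waist %g, tilt %g deg\n",
              x$a, x$b, x$height, x$waist, x$tilt_deg))
  cat(sprintf("  grid: %d x %d x %d voxels @ %g mm\n", x$dim[1], x$dim[2], x$dim[3], x$spacing))
  cat(sprintf("  density %g g/cm3, %d lesion(s), posterior elements: %s\n",
              x$base_density, length(x$lesions), x$posterior))
  cat(sprintf("  analytic Hm %.1f mm, mean CSA %.1f mm2, BMC %.2f g\n",
              x$Hm, x$csa, x$bmc))
  invisible(x)
}
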