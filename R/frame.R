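# Anatomical frame: six virtual landmarks (most anterior point and the two
# posterior corners of each endplate) define a cranial and a caudal plane;
# their bisector plane becomes the model transverse plane, and the origin is
# placed at the centroid of the superior endplate.

#' Place the six anatomical landmarks on a mask or phantom
#'
#' For a [make_vertebra_phantom()] the analytic landmarks are returned.
#' For a mask, landmarks are located on the outer surface: within an
#' angular sector about each target azimuth (anterior, posterior-left,
#' posterior-right, seen from the body centroid), the surface voxels at the
#' extreme axial level are selected and their sub-voxel mean position is
#' used.
#'
#' @param x a `vertebra_phantom` or a 3D logical mask.
#' @param spacing voxel size (required for masks), mm.
#' @param sector_deg half-width of the azimuth sector, degrees.
#' @return list with `superior` and `inferior` 3 x 3 matrices (rows =
#'   anterior, posterior-left, posterior-right; mm).
#' @export
place_landmarks <- function(x, spacing = NULL, sector_deg = 25) {
  if (inherits(x, "vertebra_phantom")) return(x$landmarks)
  mask <- x
  stop_if_not(!is.null(spacing), "spacing required for mask input")
  sp <- surface_points(mask, spacing)
  ctr <- colMeans(sp)
  ang <- atan2(sp[, 2] - ctr[2], sp[, 1] - ctr[1]) # azimuth, anterior = +y = pi/2
  targets <- c(anterior = pi / 2, post_left = -pi + pi / 6, post_right = -pi / 6)
  half <- sector_deg * pi / 180
  pick <- function(target, superior) {
    dd <- atan2(sin(ang - target), cos(ang - target))
    in_sector <- abs(dd) <= half
    stop_if_not(sum(in_sector) > 3, "degenerate landmark sector (<= 3 voxels)")
    z <- sp[in_sector, 3]
    zext <- if (superior) max(z) else min(z)
    near <- abs(z - zext) <= 0.75 * spacing
    colMeans(sp[in_sector, , drop = FALSE][near, , drop = FALSE])
  }
  sup <- t(vapply(targets, pick, numeric(3), superior = TRUE))
  inf <- t(vapply(targets, pick, numeric(3), superior = FALSE))
  rownames(sup) <- rownames(inf) <- names(targets)
  list(superior = sup, inferior = inf)
}

plane_from_points <- function(p) {
  stop_if_not(nrow(p) == 3, "plane needs 3 points")
  n <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
  nn <- sqrt(sum(n^2))
  stop_if_not(nn > 1e-12, "collinear landmark triple")
  list(normal = n / nn, point = colMeans(p))
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Build the anatomical frame and align a mesh to it
#'
#' Fits the cranial and caudal planes to the superior and inferior landmark
#' triples, computes the bisector plane, and rotates the mesh so the
#' bisector normal becomes the z axis (the model transverse plane), with
#' the anterior landmark direction defining +y. The origin is the centroid
#' of the superior landmarks (the superior endplate centroid).
#'
#' @param mesh a `tet10_mesh` (or NULL to return the frame only).
#' @param landmarks output of [place_landmarks()].
#' @return list with `frame` (origin, rotation `R` with frame axes as
#'   columns, bisector angle diagnostics) and `mesh` (nodes transformed
#'   into frame coordinates).
#' @export
align_to_anatomical_frame <- function(mesh, landmarks) {
  sup <- plane_from_points(landmarks$superior)
  inf <- plane_from_points(landmarks$inferior)
  up <- landmarks$superior[1, ] - landmarks$inferior[1, ]
  n1 <- sup$normal * sign(sum(sup$normal * up))
  n2 <- inf$normal * sign(sum(inf$normal * up))
  nz <- n1 + n2
  nz <- nz / sqrt(sum(nz^2))
  # anterior direction: from the posterior-corner midpoint to the anterior
  # landmark, averaged over the two endplates, projected on the plane
  ant <- 0.5 * (landmarks$superior[1, ] - colMeans(landmarks$superior[2:3, , drop = FALSE])) +
    0.5 * (landmarks$inferior[1, ] - colMeans(landmarks$inferior[2:3, , drop = FALSE]))
  ny <- ant - sum(ant * nz) * nz
  ny <- ny / sqrt(sum(ny^2))
  nx <- cross3(ny, nz)
  R <- cbind(nx, ny, nz) # columns are frame axes in world coords
  origin <- colMeans(landmarks$superior)
  frame <- list(origin = origin, R = R,
                tilt_deg = acos(min(1, abs(nz[3]))) * 180 / pi)
  out_mesh <- mesh
  if (!is.null(mesh)) {
    out_mesh$nodes <- t(t(mesh$nodes) - origin) %*% R
    colnames(out_mesh$nodes) <- c("x", "y", "z")
  }
  list(frame = frame, mesh = out_mesh)
}

#' Identify cranial and caudal endplate node sets
#'
#' Nodes within a band `delta` of the endplate levels of the aligned mesh.
#' The endplate level is the median over mesh columns (x, y positions on
#' the node lattice) of the column's extreme z — robust to small caps or
#' pits that a perturbed segmentation can leave above or below the plate,
#' which a plain global-extreme band would latch onto. Nodes above the
#' cranial level (local caps) are included in the cranial set. For a
#' flat-ended aligned body this reduces to exactly the end-face nodes.
#'
#' When the anatomical endplate levels are known (from the landmark-based
#' frame: superior plane at z = 0, inferior at z = -Hm), pass them as
#' `levels`; the bands then anchor on the anatomy rather than on the mesh
#' extremes, so over-segmented caps of surrounding (near-zero-density)
#' tissue hang outside the load path instead of carrying it in series.
#'
#' @param mesh aligned `tet10_mesh`.
#' @param delta band width, mm (default `0.3 h`).
#' @param levels optional `c(z_inferior, z_superior)` anatomical endplate
#'   levels, mm (frame coordinates).
#' @return list with `cranial` and `caudal` node index vectors.
#' @export
identify_endplate_nodes <- function(mesh, delta = 0.3 * mesh$h,
                                    levels = NULL) {
  z <- mesh$nodes[, 3]
  if (is.null(levels)) {
    col <- paste(round(2 * mesh$nodes[, 1] / mesh$h),
                 round(2 * mesh$nodes[, 2] / mesh$h))
    z_top <- stats::median(tapply(z, col, max))
    z_bot <- stats::median(tapply(z, col, min))
  } else {
    # clamp to the mesh when a mask under-reaches the anatomical plane
    z_top <- min(levels[2], max(z))
    z_bot <- max(levels[1], min(z))
  }
  cranial <- which(z >= z_top - delta)
  caudal <- which(z <= z_bot + delta)
  stop_if_not(length(cranial) > 0 && length(caudal) > 0, "empty endplate band")
  stop_if_not(length(intersect(cranial, caudal)) == 0,
              "endplate bands overlap; reduce delta")
  list(cranial = cranial, caudal = caudal)
}

#' Vertebral body height Hm (mm)
#'
#' Distance between the centroids of the cranial and caudal endplate node
#' sets along the axial (z) axis.
#' @param mesh aligned `tet10_mesh`.
#' @param endplates output of [identify_endplate_nodes()].
#' @export
vertebral_height <- function(mesh, endplates) {
  stop_if_not(length(endplates$cranial) > 0 && length(endplates$caudal) > 0,
              "empty endplate set")
  abs(mean(mesh$nodes[endplates$cranial, 3]) - mean(mesh$nodes[endplates$caudal, 3]))
}
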