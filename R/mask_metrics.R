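#' Median smoothing of a binary mask
#'
#' 3D median filter with a cubic window whose width is `kernel_mm` converted
#' to voxels and forced odd, applied to a binary mask (the majority vote over
#' the window). This is the 3 mm smoothing applied to manual segmentations
#' before meshing to remove slice-contouring irregularities.
#'
#' @param mask 3D logical array.
#' @param spacing isotropic voxel size, mm.
#' @param kernel_mm window width, mm (default 3).
#' @return smoothed 3D logical array.
#' @export
median_smooth_mask <- function(mask, spacing, kernel_mm = 3) {
  w <- round(kernel_mm / spacing)
  if (w < 2) {
    warning("smoothing kernel smaller than one voxel; mask returned unchanged")
    return(mask)
  }
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) / 2L
  counts <- box_sum3d(array(as.double(mask), dim(mask)), half)
  # window is clipped at the volume border; majority over the clipped window
  win <- box_sum3d(array(1, dim(mask)), half)
  counts > win / 2
}

# sliding cubic box sum via cumulative sums along each axis (zero-padded)
box_sum3d <- function(x, half) {
  for (d in 1:3) x <- run_sum_axis(x, half, d)
  x
}

run_sum_axis <- function(x, half, d) {
  dims <- dim(x)
  n <- dims[d]
  perm <- c(d, setdiff(1:3, d))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = n)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(n, seq_len(n) + half) + 1L
  lo <- pmax(0L, seq_len(n) - half - 1L) + 1L
  out <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  out <- array(out, dims[perm])
  aperm(out, order(perm))
}

#' Relative volume difference between two masks
#'
#' `|V(A) - V(B)| / V(B)` with `B` the reference; a fraction (multiply by
#' 100 for percent). Note the asymmetry: the reference volume is the
#' denominator.
#' @param A,B 3D logical arrays on the same grid.
#' @export
relative_volume_difference <- function(A, B) {
  check_same_grid(A, B)
  vb <- sum(B)
  stop_if_not(vb > 0, "reference mask B is empty")
  abs(sum(A) - vb) / vb
}

#' Dice coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: 0 means no overlap, 1 perfect overlap.
#' @param A,B 3D logical arrays on the same grid.
#' @export
dice_coefficient <- function(A, B) {
  check_same_grid(A, B)
  denom <- sum(A) + sum(B)
  stop_if_not(denom > 0, "both masks are empty")
  2 * sum(A & B) / denom
}

check_same_grid <- function(A, B) {
  stop_if_not(identical(dim(A), dim(B)), "masks must share a grid")
}

#' Surface voxel centres of a mask
#'
#' Centres (mm) of mask voxels with at least one face-adjacent background
#' neighbour; voxels on the volume border count as surface.
#' @param mask 3D logical array.
#' @param spacing voxel size, mm.
#' @return matrix with columns x, y, z (mm) and attribute `index`.
#' @export
surface_points <- function(mask, spacing) {
  stop_if_not(any(mask), "mask is empty")
  surf <- surface_mask(mask)
  idx <- which(surf, arr.ind = TRUE)
  cbind(x = (idx[, 1] - 0.5) * spacing,
        y = (idx[, 2] - 0.5) * spacing,
        z = (idx[, 3] - 0.5) * spacing)
}

surface_mask <- function(mask) {
  dims <- dim(mask)
  pad <- array(FALSE, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
  core <- pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)]
  nb <- pad[1:dims[1], 2:(dims[2] + 1), 2:(dims[3] + 1)] &
    pad[3:(dims[1] + 2), 2:(dims[2] + 1), 2:(dims[3] + 1)] &
    pad[2:(dims[1] + 1), 1:dims[2], 2:(dims[3] + 1)] &
    pad[2:(dims[1] + 1), 3:(dims[2] + 2), 2:(dims[3] + 1)] &
    pad[2:(dims[1] + 1), 2:(dims[2] + 1), 1:dims[3]] &
    pad[2:(dims[1] + 1), 2:(dims[2] + 1), 3:(dims[3] + 2)]
  core & !nb
}

# directed nearest-surface distances from every surface voxel of `from` to
# the surface of `to`, via the exact distance transform of the target surface
directed_surface_distances <- function(from, to, spacing) {
  dt <- distance_transform(surface_mask(to), spacing)
  dt[surface_mask(from)]
}

#' Mean surface distance between two masks (mm)
#'
#' Symmetric average of the two directed mean nearest-neighbour distances
#' between boundary voxel centres.
#' @param A,B 3D logical arrays on the same grid.
#' @param spacing voxel size, mm.
#' @export
mean_surface_distance <- function(A, B, spacing) {
  check_same_grid(A, B)
  stop_if_not(any(A) && any(B), "masks must be nonempty")
  0.5 * (mean(directed_surface_distances(A, B, spacing)) +
           mean(directed_surface_distances(B, A, spacing)))
}

#' Hausdorff distance between two masks (mm)
#'
#' Exact (maximum, not percentile) symmetric Hausdorff distance between
#' boundary voxel centres.
#' @inheritParams mean_surface_distance
#' @export
hausdorff_distance <- function(A, B, spacing) {
  check_same_grid(A, B)
  stop_if_not(any(A) && any(B), "masks must be nonempty")
  max(max(directed_surface_distances(A, B, spacing)),
      max(directed_surface_distances(B, A, spacing)))
}

#' Mean cross-sectional area of a vertebral body mask (mm^2)
#'
#' Mean over transverse (z) slices of voxel count times in-plane voxel
#' area, after dropping the endplate bands: the top and bottom
#' `endplate_fraction` of occupied slices.
#'
#' @param body_mask 3D logical array restricted to the vertebral body.
#' @param spacing voxel size, mm.
#' @param endplate_fraction fraction of occupied slices dropped at each end.
#' @export
cross_sectional_area <- function(body_mask, spacing, endplate_fraction = 0.1) {
  counts <- apply(body_mask, 3, sum)
  occ <- which(counts > 0)
  stop_if_not(length(occ) >= 3, "fewer than 3 usable slices")
  drop <- floor(length(occ) * endplate_fraction)
  keep <- occ[seq(1 + drop, length(occ) - drop)]
  stop_if_not(length(keep) >= 3, "fewer than 3 usable slices after endplate exclusion")
  mean(counts[keep]) * spacing^2
}

#' Pairwise geometric agreement summary for three masks
#'
#' Computes RVD, Dice, mean surface distance and Hausdorff distance for the
#' three unordered pairs of three masks (reproducibility convention: for
#' pair (i, j) with i < j, mask j is the RVD reference) and returns the
#' per-pair values with mean and SD per metric. For intra mode the three
#' masks are repeats 1-3 of one operator; for inter mode one mask per
#' operator.
#'
#' @param masks list of exactly 3 logical arrays on one grid.
#' @param spacing voxel size, mm.
#' @param mode `"intra"` or `"inter"` (annotation only).
#' @param smooth apply the 3 mm median smoothing before comparing
#'   (pipeline default).
#' @param scope annotation: `"body"` or `"whole"`.
#' @return object of class `geometric_report`: per-pair table plus
#'   `mean` and `sd` named vectors (rvd, dice, msd_mm, hd_mm, and voxel
#'   versions of the distances).
#' @export
pairwise_geometric_summary <- function(masks, spacing, mode = c("intra", "inter"),
                                       smooth = TRUE, scope = "body") {
  mode <- match.arg(mode)
  stop_if_not(length(masks) == 3, "exactly 3 masks required")
  if (smooth) masks <- lapply(masks, median_smooth_mask, spacing = spacing)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  rows <- lapply(pairs, function(p) {
    A <- masks[[p[1]]]; B <- masks[[p[2]]]
    data.frame(pair = sprintf("%d-vs-%d", p[1], p[2]),
               rvd = relative_volume_difference(A, B),
               dice = dice_coefficient(A, B),
               msd_mm = mean_surface_distance(A, B, spacing),
               hd_mm = hausdorff_distance(A, B, spacing))
  })
  tab <- do.call(rbind, rows)
  tab$msd_vox <- tab$msd_mm / spacing
  tab$hd_vox <- tab$hd_mm / spacing
  metrics <- c("rvd", "dice", "msd_mm", "hd_mm", "msd_vox", "hd_vox")
  structure(list(table = tab,
                 mean = vapply(tab[metrics], mean, numeric(1)),
                 sd = vapply(tab[metrics], sd, numeric(1)),
                 mode = mode, scope = scope, spacing = spacing),
            class = "geometric_report")
}

#' @export
print.geometric_report <- function(x, ...) {
  cat(sprintf("Geometric agreement (%s-operator, %s scope): mean over 3 comparisons\n",
              x$mode, x$scope))
  m <- x$mean; s <- x$sd
  cat(sprintf("  RVD %.3f +/- %.3f | Dice %.3f +/- %.3f | MSD %.2f +/- %.2f mm | HD %.2f +/- %.2f mm\n",
              m["rvd"], s["rvd"], m["dice"], s["dice"],
              m["msd_mm"], s["msd_mm"], m["hd_mm"], s["hd_mm"]))
  invisible(x)
}
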