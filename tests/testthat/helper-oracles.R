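# Shared fixtures and independent brute-force oracles for the test suite.

# small, fast phantom used throughout mechanical tests (1 mm voxels)
small_phantom <- function(...) {
  make_vertebra_phantom(a = 10, b = 8, height = 16, spacing = 1, margin = 2, ...)
}

tiny_phantom <- function(...) {
  make_vertebra_phantom(a = 9, b = 7, height = 14, spacing = 1, margin = 2, ...)
}

noise_free_scanner <- function(voxel_mm = 1, ...) {
  scanner_model(noise_sd = 0, blur_sd = 0, voxel_mm = voxel_mm, ...)
}

# O(n^2) brute-force surface-distance oracle on voxel-centre point sets;
# distances via coordinate differences (numerically stable near zero)
bf_surface_distances <- function(A, B, spacing) {
  pa <- surface_points(A, spacing)
  pb <- surface_points(B, spacing)
  nn_dist <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i) {
      sqrt(min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2 +
                 (q[, 3] - p[i, 3])^2))
    }, numeric(1))
  }
  dab <- nn_dist(pa, pb)
  dba <- nn_dist(pb, pa)
  list(msd = 0.5 * (mean(dab) + mean(dba)), hd = max(max(dab), max(dba)))
}

# brute-force binary median filter with window half-width `half`,
# window clipped at the volume border (majority over existing voxels)
bf_median_filter <- function(mask, half) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    xs <- max(1, i - half):min(dims[1], i + half)
    ys <- max(1, j - half):min(dims[2], j + half)
    zs <- max(1, k - half):min(dims[3], k + half)
    win <- mask[xs, ys, zs]
    out[i, j, k] <- sum(win) > length(win) / 2
  }
  out
}

# random blobby mask for metric property tests (always nonempty)
random_mask <- function(dims = c(12, 12, 12), n_seeds = 3, r_max = 4) {
  m <- array(FALSE, dims)
  ctr <- cbind(runif(n_seeds, 2, dims[1] - 1), runif(n_seeds, 2, dims[2] - 1),
               runif(n_seeds, 2, dims[3] - 1))
  rad <- runif(n_seeds, 1.5, r_max)
  for (s in seq_len(n_seeds)) {
    for (k in seq_len(dims[3])) {
      dz2 <- (k - ctr[s, 3])^2
      if (dz2 > rad[s]^2) next
      for (j in seq_len(dims[2])) {
        dy2 <- (j - ctr[s, 2])^2
        lim <- rad[s]^2 - dz2 - dy2
        if (lim < 0) next
        i <- which((seq_len(dims[1]) - ctr[s, 1])^2 <= lim)
        m[i, j, k] <- TRUE
      }
    }
  }
  if (!any(m)) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)] <- TRUE
  m
}

# homogeneous-bar model: cuboid mask with uniform elastic material
bar_model <- function(nx = 10, ny = 10, nz = 20, E = 1000, sy = Inf,
                      Epy = 50, elem = 2) {
  mask <- array(TRUE, c(nx, ny, nz))
  model <- build_fe_model(mask, 1, elem_size = elem, uniform_density = 0.3,
                          align = FALSE)
  model$material$E[] <- E
  model$material$sigma_y1[] <- sy
  model$material$E_py[] <- Epy
  model
}
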