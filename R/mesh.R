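# Structured TET10 meshing: the mask is resampled to cubes of side
# `elem_size` (cube kept if its centre falls inside the mask), each cube is
# split into the 6 Kuhn tetrahedra around the main diagonal, and elements
# are promoted to quadratic via shared edge midpoints. All tetrahedra of a
# given position in the split ("type" 1..6) are translates of each other,
# which the FE kernel exploits.

# local cube vertices, coords in {0,1}
.cube_verts <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0,
                        0,0,1, 1,0,1, 1,1,1, 0,1,1),
                      ncol = 3, byrow = TRUE)
# 6-tet Kuhn split around diagonal v1-v7 (1-based vertex ids), all
# positively oriented
.tet_split <- matrix(c(1,2,3,7, 1,3,4,7, 1,4,8,7,
                       1,8,5,7, 1,5,6,7, 1,6,2,7),
                     ncol = 4, byrow = TRUE)

# TET10 node offsets on the half-step lattice (units of elem_size / 2):
# corners then midside nodes 5:(1,2) 6:(2,3) 7:(3,1) 8:(1,4) 9:(2,4) 10:(3,4)
tet10_offsets <- function() {
  out <- array(0L, c(6, 10, 3))
  mid_pairs <- rbind(c(1,2), c(2,3), c(3,1), c(1,4), c(2,4), c(3,4))
  for (t in 1:6) {
    corners <- 2L * .cube_verts[.tet_split[t, ], , drop = FALSE]
    out[t, 1:4, ] <- corners
    for (m in 1:6) {
      out[t, 4 + m, ] <- (corners[mid_pairs[m, 1], ] + corners[mid_pairs[m, 2], ]) / 2L
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Mesh a binary mask with quadratic tetrahedra
#'
#' Structured voxel-derived TET10 meshing: deterministic, with a maximum
#' element size of `elem_size` mm. The mesh volume equals the union of the
#' kept cubes exactly.
#'
#' @param mask 3D logical array.
#' @param spacing voxel size of the mask grid, mm.
#' @param elem_size cube edge length, mm (>= spacing).
#' @return object of class `tet10_mesh`: `nodes` (N x 3, mm), `conn`
#'   (E x 10, 1-based), `etype` (E, 1..6), `h` (elem_size), `n_cubes`.
#' @export
mask_to_tet10_mesh <- function(mask, spacing, elem_size = 1) {
  stop_if_not(any(mask), "mask is empty")
  stop_if_not(elem_size >= spacing - 1e-9, "elem_size must be >= voxel spacing")
  idx <- which(mask, arr.ind = TRUE)
  h <- elem_size
  # world bounding box of mask voxels
  lo <- (apply(idx, 2, min) - 1) * spacing
  hi <- apply(idx, 2, max) * spacing
  c_lo <- floor(lo / h); c_hi <- ceiling(hi / h)
  nc <- as.integer(c_hi - c_lo)
  # cube centres in world coords; kept if the containing voxel is in-mask
  cx <- (c_lo[1] + seq_len(nc[1]) - 0.5) * h
  cy <- (c_lo[2] + seq_len(nc[2]) - 0.5) * h
  cz <- (c_lo[3] + seq_len(nc[3]) - 0.5) * h
  vi <- pmin(pmax(floor(cx / spacing) + 1L, 1L), dim(mask)[1])
  vj <- pmin(pmax(floor(cy / spacing) + 1L, 1L), dim(mask)[2])
  vk <- pmin(pmax(floor(cz / spacing) + 1L, 1L), dim(mask)[3])
  keep <- which(mask[cbind(rep(vi, times = nc[2] * nc[3]),
                           rep(rep(vj, each = nc[1]), times = nc[3]),
                           rep(vk, each = nc[1] * nc[2]))])
  stop_if_not(length(keep) > 0, "no cube centre falls inside the mask")
  k3 <- arrayInd(keep, nc)
  # half-step lattice coords of cube corner (vertex 1) per kept cube
  base <- 2L * (k3 - 1L)
  m <- nrow(base)
  off <- tet10_offsets()
  # lattice dims (in half steps)
  L <- 2L * nc + 1L
  conn_keys <- matrix(0, m * 6L, 10L)
  etype <- rep(1:6, each = m)
  for (t in 1:6) {
    rows <- (t - 1L) * m + seq_len(m)
    for (a in 1:10) {
      kx <- base[, 1] + off[t, a, 1]
      ky <- base[, 2] + off[t, a, 2]
      kz <- base[, 3] + off[t, a, 3]
      conn_keys[rows, a] <- kx + as.double(L[1]) * (ky + as.double(L[2]) * kz)
    }
  }
  ukeys <- sort(unique(as.vector(conn_keys)))
  conn <- matrix(match(as.vector(conn_keys), ukeys), nrow = m * 6L, ncol = 10L)
  kz <- floor(ukeys / (as.double(L[1]) * L[2]))
  rem <- ukeys - kz * as.double(L[1]) * L[2]
  ky <- floor(rem / L[1])
  kx <- rem - ky * L[1]
  nodes <- cbind(x = (c_lo[1] + kx / 2) * h,
                 y = (c_lo[2] + ky / 2) * h,
                 z = (c_lo[3] + kz / 2) * h)
  structure(list(nodes = nodes, conn = conn, etype = etype, h = h,
                 n_cubes = m),
            class = "tet10_mesh")
}

#' @export
print.tet10_mesh <- function(x, ...) {
  cat(sprintf("TET10 mesh: %d nodes, %d elements (%d cubes @ %g mm)\n",
              nrow(x$nodes), nrow(x$conn), x$n_cubes, x$h))
  invisible(x)
}

# quadratic tetrahedron shape-function derivatives wrt natural coords
# xi = (L2, L3, L4), L1 = 1 - sum(xi); returns 10 x 3 matrix dN/dxi
tet10_dNdxi <- function(xi) {
  L2 <- xi[1]; L3 <- xi[2]; L4 <- xi[3]; L1 <- 1 - L2 - L3 - L4
  d <- matrix(0, 10, 3)
  # corners: N1 = L1(2L1-1) etc.; dL1/dxi = (-1,-1,-1)
  d[1, ] <- (4 * L1 - 1) * c(-1, -1, -1)
  d[2, ] <- c(4 * L2 - 1, 0, 0)
  d[3, ] <- c(0, 4 * L3 - 1, 0)
  d[4, ] <- c(0, 0, 4 * L4 - 1)
  # midside: 5:(1,2) 6:(2,3) 7:(3,1) 8:(1,4) 9:(2,4) 10:(3,4)
  d[5, ] <- 4 * c(L1 - L2, -L2, -L2)
  d[6, ] <- 4 * c(L3, L2, 0)
  d[7, ] <- 4 * c(-L3, L1 - L3, -L3)
  d[8, ] <- 4 * c(-L4, -L4, L1 - L4)
  d[9, ] <- 4 * c(L4, 0, L2)
  d[10, ] <- 4 * c(0, L4, L3)
  d
}

tet10_N <- function(xi) {
  L2 <- xi[1]; L3 <- xi[2]; L4 <- xi[3]; L1 <- 1 - L2 - L3 - L4
  c(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1), L4 * (2 * L4 - 1),
    4 * L1 * L2, 4 * L2 * L3, 4 * L3 * L1, 4 * L1 * L4, 4 * L2 * L4, 4 * L3 * L4)
}

# B matrix (6 x 30, engineering Voigt) for an affine TET10 at natural point xi
tet10_B <- function(corners, xi) {
  J <- t(corners[2:4, , drop = FALSE] - matrix(corners[1, ], 3, 3, byrow = TRUE)) # 3x3, columns = edges
  detJ <- det(J)
  stop_if_not(detJ > 0, "element Jacobian not positive")
  dN <- tet10_dNdxi(xi) %*% solve(J)  # 10 x 3 = dN/dx
  B <- matrix(0, 6, 30)
  for (a in 1:10) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[a, 1]
    B[2, c0 + 2] <- dN[a, 2]
    B[3, c0 + 3] <- dN[a, 3]
    B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
    B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
    B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
  }
  list(B = B, detJ = detJ)
}

.gauss_tet4 <- local({
  a <- 0.5854101966249685; b <- 0.1381966011250105
  rbind(c(b, b, b), c(a, b, b), c(b, a, b), c(b, b, a)) # xi = (L2, L3, L4)
})

.node_xi <- local({
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mids <- rbind((corners[1, ] + corners[2, ]) / 2, (corners[2, ] + corners[3, ]) / 2,
                (corners[3, ] + corners[1, ]) / 2, (corners[1, ] + corners[4, ]) / 2,
                (corners[2, ] + corners[4, ]) / 2, (corners[3, ] + corners[4, ]) / 2)
  rbind(corners, mids)
})

# per-type B matrices at Gauss points and nodes for the (possibly rotated)
# structured mesh; all elements of a type share them
mesh_type_matrices <- function(mesh) {
  Bg <- array(0, c(6, 30, 4 * 6))
  Bn <- array(0, c(6, 30, 10 * 6))
  detJ <- NA_real_
  for (t in 1:6) {
    e <- match(t, mesh$etype)
    stop_if_not(!is.na(e), "mesh missing an element type")
    corners <- mesh$nodes[mesh$conn[e, 1:4], , drop = FALSE]
    for (g in 1:4) {
      bb <- tet10_B(corners, .gauss_tet4[g, ])
      Bg[, , (t - 1) * 4 + g] <- bb$B
      detJ <- bb$detJ
    }
    for (a in 1:10) Bn[, , (t - 1) * 10 + a] <- tet10_B(corners, .node_xi[a, ])$B
  }
  list(Bg = Bg, Bn = Bn, wg = detJ / 24) # gauss weight x detJ = V/4
}

#' Per-element Jacobian check
#' @param mesh a `tet10_mesh`.
#' @return numeric(E) of corner-tet Jacobian determinants (all positive for
#'   a valid mesh).
#' @export
element_jacobians <- function(mesh) {
  vapply(seq_len(nrow(mesh$conn)), function(e) {
    corners <- mesh$nodes[mesh$conn[e, 1:4], , drop = FALSE]
    det(t(corners[2:4, ] - matrix(corners[1, ], 3, 3, byrow = TRUE)))
  }, numeric(1))
}
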