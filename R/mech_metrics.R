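#' Ultimate force from a compression result (N)
#'
#' The resultant axial reaction at the final (1.9% apparent strain)
#' increment — by protocol, not the maximum of the curve — reported
#' positive in compression.
#' @param result an `fe_result`.
#' @export
ultimate_force <- function(result) {
  inc <- result$increments
  last <- nrow(inc)
  stop_if_not(abs(inc$displacement[last] - result$total_disp) < 1e-9,
              "solve stopped before the imposed apparent strain")
  abs(inc$force[last])
}

#' Apparent stiffness K from the force-displacement curve (N/mm)
#'
#' Least-squares slope of force against displacement over the linear range,
#' operationalised as every increment (from zero) with no plastic activity.
#' If yielding starts in the first increment, the first-increment secant is
#' used with a warning.
#' @param result an `fe_result`.
#' @export
apparent_stiffness <- function(result) {
  inc <- result$increments
  linear <- cumsum(inc$n_yield) == 0  # includes the zero row
  if (sum(linear) < 2) {
    warning("yielding within the first increment; using first-increment secant")
    return(inc$force[2] / inc$displacement[2])
  }
  d <- inc$displacement[linear]; f <- inc$force[linear]
  unname(coef(lm(f ~ d))[2])
}

#' Mechanical outcome summary
#'
#' Applies the outcome normalisations: ultimate stress
#' `sigma_U = F_U / CSA`, and normalised apparent modulus
#' `E_APP = K * Hm / CSA`.
#' @param result an `fe_result`.
#' @param model the `fe_model` that produced it.
#' @return object of class `mechanical_summary` (data.frame row with F_U,
#'   sigma_U, K, E_APP, Hm, CSA, final displacement).
#' @export
mechanical_summary <- function(result, model) {
  stop_if_not(model$csa > 0, "CSA must be positive")
  F_U <- ultimate_force(result)
  K <- apparent_stiffness(result)
  out <- data.frame(F_U = F_U,
                    sigma_U = F_U / model$csa,
                    K = K,
                    E_APP = K * model$Hm / model$csa,
                    Hm = model$Hm, CSA = model$csa,
                    delta_l = result$total_disp)
  class(out) <- c("mechanical_summary", "data.frame")
  out
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat(sprintf("F_U = %.1f N | sigma_U = %.3f MPa | K = %.1f N/mm | E_APP = %.1f MPa\n",
              x$F_U, x$sigma_U, x$K, x$E_APP))
  cat(sprintf("  (Hm = %.2f mm, CSA = %.1f mm2, delta_l = %.3f mm)\n",
              x$Hm, x$CSA, x$delta_l))
  invisible(x)
}

#' Strain frequency tables over the mid-50% of the body height
#'
#' Selects nodes with axial coordinate in the central 50% of the
#' caudal-to-cranial span and bins their principal strains with fixed
#' edges, returning normalised frequencies (histogram range cut at
#' `|strain| = 0.04`, the region of interest for vertebral strain
#' distributions).
#'
#' @param result an `fe_result`.
#' @param model the matching `fe_model`.
#' @param n_bins number of bins.
#' @param strain_range signed bin range.
#' @return list of two data.frames (`eps_p1`, `eps_p3`) with bin centres
#'   and frequencies summing to 1, plus the selected node count.
#' @export
strain_histogram <- function(result, model, n_bins = 40,
                             strain_range = c(-0.04, 0.04)) {
  z <- model$mesh$nodes[, 3]
  zc <- mean(model$mesh$nodes[model$endplates$cranial, 3])
  za <- mean(model$mesh$nodes[model$endplates$caudal, 3])
  lo <- min(za, zc); hi <- max(za, zc)
  band <- z >= lo + 0.25 * (hi - lo) & z <= hi - 0.25 * (hi - lo)
  stop_if_not(any(band), "empty mid-height band")
  edges <- seq(strain_range[1], strain_range[2], length.out = n_bins + 1)
  bin_table <- function(v) {
    v <- pmin(pmax(v, strain_range[1]), strain_range[2])
    counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                       nbins = n_bins)
    data.frame(centre = (edges[-1] + edges[-(n_bins + 1)]) / 2,
               frequency = counts / sum(counts))
  }
  list(eps_p1 = bin_table(result$eps_p1[band]),
       eps_p3 = bin_table(result$eps_p3[band]),
       n_nodes = sum(band))
}

#' Spherical probe grid in the anatomical frame
#'
#' A 3 x 3 x 3 lattice of 27 spherical probes of `radius_mm` radius,
#' symmetric about the body centre, with per-axis offsets at
#' `offset_fraction` of the body semi-extents — fixed relative placement so
#' probes are comparable across segmentations of one vertebra.
#'
#' @param model an `fe_model` (aligned).
#' @param radius_mm probe radius, mm.
#' @param offset_fraction per-axis offsets as a fraction of the body
#'   semi-extent.
#' @return object of class `probe_set`: data.frame of 27 centres (mm),
#'   radius, and an `outside` flag for probes protruding beyond the mesh
#'   bounding extents (flagged, never dropped).
#' @export
probe_grid <- function(model, radius_mm = 2, offset_fraction = 0.25) {
  stop_if_not(radius_mm > 0, "radius must be positive")
  nodes <- model$mesh$nodes
  lims <- apply(nodes, 2, range)
  centre <- colMeans(lims)
  semi <- (lims[2, ] - lims[1, ]) / 2
  offs <- expand.grid(ix = -1:1, iy = -1:1, iz = -1:1)
  centres <- cbind(centre[1] + offs$ix * offset_fraction * semi[1],
                   centre[2] + offs$iy * offset_fraction * semi[2],
                   centre[3] + offs$iz * offset_fraction * semi[3])
  colnames(centres) <- c("x", "y", "z")
  outside <- logical(27)
  for (p in 1:27) {
    outside[p] <- any(centres[p, ] - radius_mm < lims[1, ] |
                        centres[p, ] + radius_mm > lims[2, ])
  }
  structure(list(centres = as.data.frame(centres), radius = radius_mm,
                 outside = outside),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("Probe set: %d spherical probes, radius %g mm (%d protruding)\n",
              nrow(x$centres), x$radius, sum(x$outside)))
  invisible(x)
}

#' Mean principal strains inside each probe
#'
#' Averages the nodal principal strains over the mesh nodes inside each
#' probe sphere (equal nodal weights on the uniform structured mesh). The
#' lesion flag is true when any sampled node lies inside a lesion of the
#' generating phantom (synthetic ground truth).
#'
#' @param result an `fe_result`.
#' @param model the matching `fe_model`.
#' @param probes a [probe_grid()] result.
#' @param phantom optional `vertebra_phantom` for lesion flags.
#' @return data.frame: probe id, centre, mean eps_p1, mean eps_p3, node
#'   count, lesion flag.
#' @export
probe_mean_strains <- function(result, model, probes, phantom = NULL) {
  nodes <- model$mesh$nodes
  out <- probes$centres
  out$probe <- seq_len(nrow(out))
  out$eps_p1 <- out$eps_p3 <- NA_real_
  out$n_nodes <- 0L
  out$lesion <- FALSE
  for (p in seq_len(nrow(out))) {
    c0 <- as.numeric(probes$centres[p, ])
    d2 <- (nodes[, 1] - c0[1])^2 + (nodes[, 2] - c0[2])^2 + (nodes[, 3] - c0[3])^2
    inside <- d2 <= probes$radius^2
    stop_if_not(any(inside), sprintf("probe %d samples no nodes", p))
    out$eps_p1[p] <- mean(result$eps_p1[inside])
    out$eps_p3[p] <- mean(result$eps_p3[inside])
    out$n_nodes[p] <- sum(inside)
    if (!is.null(phantom) && length(phantom$lesions) > 0) {
      # probe centres are in the anatomical frame; map back to world
      pw <- if (!is.null(model$frame)) {
        as.numeric(model$frame$R %*% c0 + model$frame$origin)
      } else c0
      th <- phantom$tilt_deg * pi / 180
      Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
                   3, 3, byrow = TRUE)
      pb <- as.numeric(t(Rx) %*% (pw - phantom$centre))
      for (les in phantom$lesions) {
        if (sum((pb - les$centre)^2) <= (les$radius + probes$radius)^2) {
          out$lesion[p] <- TRUE
        }
      }
    }
  }
  out[, c("probe", "x", "y", "z", "eps_p1", "eps_p3", "n_nodes", "lesion")]
}
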