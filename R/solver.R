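# Displacement-controlled quasi-static compression of an fe_model:
# small-strain TET10 elements (4-point Gauss), J2 von Mises plasticity with
# linear isotropic hardening calibrated so the uniaxial post-yield tangent
# equals E_py, Newton-Raphson per increment with automatic bisection, and
# direct sparse Cholesky factorisation (CHOLMOD via Matrix).

#' Point-level J2 radial-return update
#'
#' Reference implementation of the stress update used at every Gauss point:
#' given a total engineering-Voigt strain, the committed plastic state and
#' the material, returns the stress, the algorithmically consistent tangent
#' and the new state. The hardening modulus is `H = E * E_py / (E - E_py)`
#' so the uniaxial elasto-plastic tangent modulus equals `E_py`.
#'
#' @param eps total strain, engineering Voigt
#'   `(exx, eyy, ezz, gxy, gyz, gzx)`.
#' @param state list with `ep` (plastic strain, tensor components, 6) and
#'   `alpha` (equivalent plastic strain).
#' @param material list with `E`, `sigma_y1`, `E_py` (MPa).
#' @param nu Poisson's ratio.
#' @return list with `stress` (Voigt, MPa), `tangent` (6 x 6, engineering
#'   Voigt), `state` (updated), `dgamma` (plastic multiplier increment).
#' @export
j2_update <- function(eps, state = list(ep = numeric(6), alpha = 0),
                      material, nu = 0.3) {
  E <- material$E; sy <- material$sigma_y1; Epy <- material$E_py
  stop_if_not(Epy < E, "post-yield modulus must be below E")
  H <- hardening_modulus(E, Epy)
  mu <- E / (2 * (1 + nu)); kappa <- E / (3 * (1 - 2 * nu))
  et <- c(eps[1:3], eps[4:6] / 2)
  evol <- sum(et[1:3])
  ed <- et - c(rep(evol / 3, 3), 0, 0, 0)
  str <- 2 * mu * (ed - state$ep)
  ss <- sum(str[1:3]^2) + 2 * sum(str[4:6]^2)
  qtr <- sqrt(1.5 * ss)
  ycur <- sy + H * state$alpha
  m <- c(1, 1, 1, 0, 0, 0)
  if (qtr <= ycur || !is.finite(sy)) {
    s <- str; ep_new <- state$ep; alpha_new <- state$alpha
    dg <- 0; theta <- 1; thetabar <- 0
  } else {
    dg <- (qtr - ycur) / (3 * mu + H)
    theta <- 1 - 3 * mu * dg / qtr
    thetabar <- 3 * mu / (3 * mu + H) - (1 - theta)
    s <- theta * str
    ep_new <- state$ep + dg * 1.5 * str / qtr
    alpha_new <- state$alpha + dg
  }
  stress <- s + kappa * evol * m
  nvec <- if (dg > 0) str / sqrt(ss) else numeric(6)
  Idev <- diag(c(1, 1, 1, 0.5, 0.5, 0.5)) - outer(m, m) / 3
  D <- kappa * outer(m, m) + 2 * mu * theta * Idev -
    2 * mu * thetabar * outer(nvec, nvec)
  list(stress = stress, tangent = D,
       state = list(ep = ep_new, alpha = alpha_new), dgamma = dg)
}

hardening_modulus <- function(E, Epy) {
  stop_if_not(all(Epy < E), "E_py must be strictly below E")
  ifelse(Epy <= 0, 0, E * Epy / (E - Epy))
}

#' Solve displacement-controlled compression of an FE model
#'
#' Applies a compressive axial displacement equivalent to
#' `apparent_strain * Hm` to the cranial endplate nodes, with the caudal
#' endplate fixed, in equal increments with Newton-Raphson iteration and
#' automatic step bisection on non-convergence.
#'
#' Boundary conditions (`bc`):
#' \describe{
#'   \item{default}{caudal nodes fixed in x, y, z; cranial nodes: z
#'     prescribed, transverse free (axial-only reading of uniaxial
#'     compression).}
#'   \item{tied}{both endplates fully bonded to rigid platens (cranial
#'     transverse fixed too).}
#'   \item{frictionless}{z-only constraints on both endplates plus minimal
#'     in-plane rigid-body restraints.}
#' }
#'
#' @param model an `fe_model`.
#' @param apparent_strain imposed apparent compressive strain (default
#'   0.019, i.e. 1.9%).
#' @param n_increments number of equal displacement increments.
#' @param nu Poisson's ratio (not density-dependent).
#' @param bc boundary-condition variant.
#' @param elastic override plasticity: solve with unbounded yield stress.
#' @param tol relative Newton tolerance on the residual norm.
#' @param max_iter Newton iterations per increment before bisection.
#' @param max_bisect maximum number of step bisections.
#' @return object of class `fe_result`: `increments` data.frame
#'   (displacement mm, force N, n_yield, dissipation), displacement field
#'   `u` (N x 3, mm), nodal strain tensors and principal strains, solver
#'   log.
#' @export
solve_compression <- function(model, apparent_strain = 0.019,
                              n_increments = 10, nu = 0.3,
                              bc = c("default", "tied", "frictionless"),
                              elastic = FALSE,
                              tol = 1e-8, max_iter = 25, max_bisect = 4) {
  bc <- match.arg(bc)
  mesh <- model$mesh
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  total_disp <- apparent_strain * model$Hm
  tm <- mesh_type_matrices(mesh)
  conn <- mesh$conn; storage.mode(conn) <- "integer"
  etype <- as.integer(mesh$etype)
  Emod <- model$material$E
  sy <- if (elastic) rep(Inf, nrow(conn)) else model$material$sigma_y1
  Hmod <- ifelse(is.finite(sy), hardening_modulus(Emod, model$material$E_py), 0)

  cr <- model$endplates$cranial
  ca <- model$endplates$caudal
  zdir <- 3L
  dof_of <- function(nodes, comp) 3L * (nodes - 1L) + comp
  presc <- dof_of(cr, zdir)         # cranial axial, driven
  fixed0 <- switch(bc,
    default = c(dof_of(ca, 1L), dof_of(ca, 2L), dof_of(ca, 3L)),
    tied = c(dof_of(ca, 1L), dof_of(ca, 2L), dof_of(ca, 3L),
             dof_of(cr, 1L), dof_of(cr, 2L)),
    frictionless = {
      cz <- dof_of(ca, 3L)
      ctr <- colMeans(mesh$nodes[ca, 1:2, drop = FALSE])
      d2 <- (mesh$nodes[ca, 1] - ctr[1])^2 + (mesh$nodes[ca, 2] - ctr[2])^2
      pin <- ca[which.min(d2)]
      far <- ca[which.max(abs(mesh$nodes[ca, 1] - ctr[1]))]
      c(cz, dof_of(pin, 1L), dof_of(pin, 2L), dof_of(far, 2L))
    })
  fixed0 <- setdiff(unique(fixed0), presc)
  constrained <- c(presc, fixed0)
  free <- setdiff(seq_len(ndof), constrained)

  u <- numeric(ndof)
  ep <- matrix(0, nrow(conn) * 4L, 6L)
  alpha <- numeric(nrow(conn) * 4L)
  sign_z <- -1 # compression: cranial moves down

  increments <- data.frame(displacement = 0, force = 0, n_yield = 0L,
                           dissipation = 0)
  log <- character(0)
  Kfact <- NULL        # cached Cholesky factor, valid while fully elastic
  any_plastic <- FALSE

  assemble <- function(u, want_tangent) {
    fe_assemble_cpp(conn, etype, tm$Bg, tm$wg, Emod, sy, Hmod, nu,
                    u, ep, alpha, want_tangent)
  }
  dofmap <- integer(ndof)
  dofmap[free] <- seq_along(free)
  nfree <- length(free)
  factorise <- function(asm) {
    # assemble the tangent directly on the free dofs; reuse the symbolic
    # Cholesky factorisation (structure is constant) across iterations
    ii <- dofmap[asm$Ki]; jj <- dofmap[asm$Kj]
    sel <- ii > 0L & jj > 0L
    # kernel emits the lower triangle of the symmetric tangent; the dof ->
    # free-index map is monotone, so the triangle property is preserved
    Kff <- Matrix::sparseMatrix(i = ii[sel], j = jj[sel], x = asm$Kx[sel],
                                dims = c(nfree, nfree), symmetric = TRUE)
    if (is.null(Kfact)) {
      Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
    } else {
      Matrix::update(Kfact, Kff)
    }
  }

  pending <- seq_len(n_increments) / n_increments * total_disp
  cur_disp <- 0
  n_bisect_used <- 0

  while (length(pending) > 0) {
    target <- pending[1]
    u_try <- u
    u_try[presc] <- sign_z * target
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      want_K <- any_plastic || is.null(Kfact)
      asm <- assemble(u_try, want_tangent = want_K)
      if (!want_K && asm$n_yield > 0) {
        # first yield inside this increment: refresh the tangent
        any_plastic <- TRUE
        asm <- assemble(u_try, want_tangent = TRUE)
      }
      r <- -asm$fint
      react <- sqrt(sum(asm$fint[constrained]^2))
      if (sqrt(sum(r[free]^2)) <= tol * max(react, 1)) {
        converged <- TRUE
        break
      }
      if (any_plastic || is.null(Kfact)) Kfact <- factorise(asm)
      du <- as.numeric(Matrix::solve(Kfact, r[free]))
      # backtracking line search: the plastic active set can chatter under
      # full Newton steps; damp until the residual norm decreases
      step <- 1
      rn <- sqrt(sum(r[free]^2))
      repeat {
        u_cand <- u_try
        u_cand[free] <- u_try[free] + step * du
        rn2 <- sqrt(sum(assemble(u_cand, want_tangent = FALSE)$fint[free]^2))
        if (rn2 < rn || step <= 1 / 64) break
        step <- step / 2
      }
      u_try <- u_cand
    }
    if (!converged) {
      n_bisect_used <- n_bisect_used + 1
      stop_if_not(n_bisect_used <= max_bisect,
                  "FE solve failed to converge after maximum bisections")
      mid <- (cur_disp + target) / 2
      pending <- c(mid, pending)
      log <- c(log, sprintf("bisect: inserting sub-step at %.4g mm", mid))
      next
    }
    final <- assemble(u_try, want_tangent = FALSE)  # commit plastic state
    ep[, ] <- final$ep
    alpha[] <- final$alpha
    if (final$n_yield > 0) any_plastic <- TRUE
    u <- u_try
    cur_disp <- target
    force <- -sum(final$fint[dof_of(cr, zdir)])  # positive in compression
    increments <- rbind(increments,
                        data.frame(displacement = target, force = force,
                                   n_yield = final$n_yield,
                                   dissipation = final$dissipation))
    pending <- pending[-1]
  }

  strains <- nodal_strain_tensors(mesh, tm, u)
  pr <- principal_strains(strains)
  structure(list(increments = increments,
                 u = matrix(u, ncol = 3, byrow = TRUE),
                 strain = strains,
                 eps_p1 = pr$e1, eps_p2 = pr$e2, eps_p3 = pr$e3,
                 apparent_strain = apparent_strain,
                 total_disp = total_disp, nu = nu, bc = bc,
                 converged = TRUE, log = log,
                 plastic_alpha = alpha,
                 fint_final = final$fint),
            class = "fe_result")
}

# axial reactions over the endplate sets at the final converged state
# (global-equilibrium diagnostic: they must cancel)
reaction_balance <- function(model, result) {
  crz <- 3L * (model$endplates$cranial - 1L) + 3L
  caz <- 3L * (model$endplates$caudal - 1L) + 3L
  list(cranial = sum(result$fint_final[crz]),
       caudal = sum(result$fint_final[caz]))
}

nodal_strain_tensors <- function(mesh, tm, u) {
  conn <- mesh$conn; storage.mode(conn) <- "integer"
  fe_nodal_strains_cpp(conn, as.integer(mesh$etype), tm$Bn, u,
                       nrow(mesh$nodes))
}

#' Nodal principal strains from an FE result
#'
#' Strain tensors are evaluated at element nodes from the shape-function
#' gradients, averaged over adjacent elements (equal element volumes), and
#' eigen-decomposed in closed form. `eps_p1 >= eps_p2 >= eps_p3` at every
#' node.
#'
#' @param result an `fe_result`.
#' @return data.frame with columns `eps_p1`, `eps_p2`, `eps_p3`.
#' @export
nodal_principal_strains <- function(result) {
  data.frame(eps_p1 = result$eps_p1, eps_p2 = result$eps_p2,
             eps_p3 = result$eps_p3)
}

# closed-form (Cardano) eigenvalues of symmetric 3x3 tensors, vectorised;
# input engineering Voigt (shears are gamma): tensor shear = gamma / 2
principal_strains <- function(voigt) {
  a11 <- voigt[, 1]; a22 <- voigt[, 2]; a33 <- voigt[, 3]
  a12 <- voigt[, 4] / 2; a23 <- voigt[, 5] / 2; a13 <- voigt[, 6] / 2
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  e1 <- e2 <- e3 <- q
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b23 <- a23[nz] / p[nz]; b13 <- a13[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    e3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2[nz] <- 3 * q[nz] - e1[nz] - e3[nz]
  }
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' @export
print.fe_result <- function(x, ...) {
  inc <- x$increments
  cat(sprintf("FE compression result: %d increments to %.3g mm (%.2f%% apparent strain)\n",
              nrow(inc) - 1, x$total_disp, 100 * x$apparent_strain))
  cat(sprintf("  final force %.1f N; yielded Gauss points at final increment: %d\n",
              inc$force[nrow(inc)], inc$n_yield[nrow(inc)]))
  invisible(x)
}

#' @export
summary.fe_result <- function(object, ...) {
  inc <- object$increments
  cat("Force-displacement history:\n")
  print(inc, row.names = FALSE)
  cat(sprintf("principal strain range: eps_p1 [%.4g, %.4g], eps_p3 [%.4g, %.4g]\n",
              min(object$eps_p1), max(object$eps_p1),
              min(object$eps_p3), max(object$eps_p3)))
  invisible(inc)
}
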