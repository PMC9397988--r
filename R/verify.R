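## Analytic verification problems for the plane-strain solver: patch test,
## slender cantilever vs beam theory, rigid-cylinder indentation vs Hertz
## line contact, dense-solver equivalence, and energy balance.

#' Patch test: linear displacement field reproduced exactly
#'
#' A linear displacement field prescribed on the whole boundary of a
#' homogeneous square must be reproduced exactly in the interior, with
#' spatially constant stress, for any conforming element; straight-sided T6
#' with 3-point quadrature passes to machine precision.
#'
#' @return list with `disp_error`, `stress_error` (absolute, machine-scale).
#' @export
verify_patch <- function() {
  rm <- mesh_rectangle(10, 10, 2.5)
  A <- matrix(c(1e-3, 2e-4, 3e-4, -5e-4), 2, 2)
  bn <- unique(c(rm$boundary$bottom, rm$boundary$top, rm$boundary$left,
                 rm$boundary$right))
  ub <- rm$nodes[bn, , drop = FALSE] %*% t(A)
  pres <- c(rbind(ub[, 1], ub[, 2]))
  names(pres) <- c(rbind(2L * bn - 1L, 2L * bn))
  sol <- solve_elastic(rm, E = 2, nu = 0.3, prescribed = pres)
  uex <- as.vector(t(rm$nodes %*% t(A)))
  D <- plane_strain_matrix(2, 0.3)
  sex <- as.vector(D %*% c(A[1, 1], A[2, 2], A[1, 2] + A[2, 1]))
  list(disp_error = max(abs(sol$u - uex)),
       stress_error = max(abs(sweep(sol$fields$stress[, 1:3], 2, sex))))
}

#' Slender cantilever vs Euler-Bernoulli beam theory
#'
#' Tip-loaded cantilever (L/h = 20, nu = 0 so plane strain coincides with
#' beam theory), tip deflection compared with `PL^3/(3EI)`.
#'
#' @return list with `fem`, `beam`, `rel_error`.
#' @export
verify_cantilever <- function() {
  L <- 100; h <- 5; E <- 1000; P <- -1
  rm <- mesh_rectangle(L, h, 1.25)
  fixed <- unique(rm$boundary$left)
  fixed_dofs <- sort(c(2L * fixed - 1L, 2L * fixed))
  tip <- rm$boundary$right
  f <- numeric(2L * nrow(rm$nodes))
  f[2L * tip] <- P / length(tip)
  sol <- solve_elastic(rm, E = E, nu = 0, fixed_dofs = fixed_dofs, f_ext = f)
  tipdef <- mean(sol$u[2L * tip])
  beam <- P * L^3 / (3 * E * h^3 / 12)
  list(fem = tipdef, beam = beam, rel_error = abs(tipdef - beam) / abs(beam))
}

#' Rigid-cylinder indentation vs Hertz line contact
#'
#' A rigid cylinder (R = 50 mm) is pressed 3 mm into a deep homogeneous
#' block; the measured contact half-width and peak pressure are compared with
#' the Hertz line-contact closed forms evaluated at the measured total load:
#' `a = sqrt(4 P R / (pi E*))`, `p0 = 2P/(pi a)` with `E* = E/(1-nu^2)`.
#'
#' @return list with measured and predicted `a`, `p0`, load `P`, and relative
#'   errors.
#' @export
verify_hertz <- function() {
  E <- 100; nu <- 0.3; R <- 50; depth <- 3
  W <- 200; H <- 100
  x_lines <- sort(unique(c(seq(0, 75, by = 5), seq(75, 125, by = 1),
                           seq(125, W, by = 5))))
  y_lines <- sort(unique(c(seq(0, 80, by = 5), seq(80, 94, by = 2),
                           seq(94, H, by = 1))))
  rm <- mesh_rectangle(W, H, 1, x_lines = x_lines, y_lines = y_lines)
  m <- nrow(rm$tri)
  K <- assemble_stiffness(rm, list(E_elem = rep(E, m), nu_elem = rep(nu, m)))
  fixed <- unique(rm$boundary$bottom)
  fixed_dofs <- sort(c(2L * fixed - 1L, 2L * fixed))
  free <- setdiff(seq_len(2L * nrow(rm$nodes)), fixed_dofs)
  top <- rm$boundary$top
  trib <- chain_trib_lengths(rm$nodes, top)
  kpen <- 2000                        # MPa/mm; penetration ~ p0/kpen << a
  scene <- list(mode = "none", skin_slaves = top, radius_extra = 0,
                kpen_cushion = kpen * trib, kpen_hard = kpen * trib,
                eps_reg = 5e-3, stab = 0,
                rollers = list(centers = cbind(W / 2, H + R - depth), R = R))
  ctrl <- solver_control(kinematics = "linear", rtol = 1e-8, max_iter = 60L)
  sol <- newton_increment(K, free, rm$nodes, scene,
                          numeric(2L * nrow(rm$nodes)), ctrl, "hertz")
  if (!sol$converged) stop("Hertz verification solve did not converge")
  ct <- sol$contact
  P <- abs(sol$contact$roller_force_y)
  act <- which(ct$force > 0)
  xs <- rm$nodes[top[act], 1]
  spacing <- mean(diff(sort(rm$nodes[top, 1])))
  a_meas <- (max(xs) - min(xs)) / 2 + spacing / 2
  ## nodal force -> pressure with the consistent load weights of quadratic
  ## boundary elements: midside nodes carry 2/3 of an element edge, corners
  ## 1/6 each side (force/trib alone oscillates +-33% between node types)
  w_cons <- trib * ifelse(seq_along(top) %% 2L == 1L, 2 / 3, 4 / 3)
  p0_meas <- max(ct$force / w_cons)
  Estar <- E / (1 - nu^2)
  a_pred <- sqrt(4 * P * R / (pi * Estar))
  p0_pred <- 2 * P / (pi * a_pred)
  list(P = P, a = a_meas, a_hertz = a_pred,
       p0 = p0_meas, p0_hertz = p0_pred,
       a_rel_error = abs(a_meas - a_pred) / a_pred,
       p0_rel_error = abs(p0_meas - p0_pred) / p0_pred)
}

#' Sparse vs dense solver equivalence on a small mesh
#'
#' On a mesh below 200 degrees of freedom, the sparse factorization must
#' reproduce a dense base-R solve of the same system to 1e-10 relative.
#'
#' @param seed RNG seed for the random load.
#' @return list with `rel_error`, `ndof`.
#' @export
verify_dense_oracle <- function(seed = 1L) {
  rm <- mesh_rectangle(10, 10, 5)      # 2 x 2 cells -> 25 nodes, 50 dof
  m <- nrow(rm$tri)
  K <- assemble_stiffness(rm, list(E_elem = rep(3, m),
                                   nu_elem = rep(0.45, m)))
  fixed <- unique(rm$boundary$bottom)
  fixed_dofs <- sort(c(2L * fixed - 1L, 2L * fixed))
  n2 <- 2L * nrow(rm$nodes)
  free <- setdiff(seq_len(n2), fixed_dofs)
  set.seed(seed)
  f <- stats::rnorm(length(free))
  u_sparse <- as.numeric(Matrix::solve(Matrix::forceSymmetric(K[free, free]),
                                       f))
  u_dense <- base::solve(as.matrix(K[free, free]), f)
  list(rel_error = max(abs(u_sparse - u_dense)) / max(abs(u_dense)),
       ndof = n2)
}

#' Energy balance of a frictionless traction solve
#'
#' On a coarse phantom in strict small-strain mode, the external work done by
#' the contact forces (trapezoidal accumulation over increments) must equal
#' the stored strain energy; the model has no dissipation.
#'
#' @param tl traction level for the check.
#' @return list with `work`, `strain_energy`, `rel_error`.
#' @export
verify_energy <- function(tl = 6L) {
  geom <- build_phantom(phantom_spec(mesh_target_edge_mm = 8,
                                     csf_mm = 0, cord_mm = 0,
                                     epidural_fat_mm = 0))
  mesh <- mesh_geometry(geom)
  sol <- solve_traction(mesh, material_table(), traction_protocol(), geom,
                        tl = tl,
                        control = solver_control(kinematics = "linear"))
  W <- sol$levels[[tl]]$external_work
  U <- strain_energy(sol, tl)
  list(work = W, strain_energy = U, rel_error = abs(W - U) / abs(U))
}

#' Run the analytic verification suite
#'
#' Patch test (machine precision), cantilever vs beam theory (5%), Hertz
#' line contact (10%), dense-solver equivalence (1e-10) and energy balance
#' (1%).
#'
#' @return data.frame with columns `check`, `value`, `tolerance`, `pass`.
#' @export
verify_suite <- function() {
  pt <- verify_patch()
  cb <- verify_cantilever()
  hz <- verify_hertz()
  de <- verify_dense_oracle()
  en <- verify_energy()
  out <- data.frame(
    check = c("patch_disp_error", "patch_stress_error",
              "cantilever_rel_error", "hertz_halfwidth_rel_error",
              "hertz_pressure_rel_error", "dense_oracle_rel_error",
              "energy_balance_rel_error"),
    value = c(pt$disp_error, pt$stress_error, cb$rel_error, hz$a_rel_error,
              hz$p0_rel_error, de$rel_error, en$rel_error),
    tolerance = c(1e-9, 1e-9, 0.05, 0.10, 0.10, 1e-10, 0.01)
  )
  out$pass <- out$value <= out$tolerance
  out
}
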