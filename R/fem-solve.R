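#' Solver control parameters
#'
#' @param rtol relative out-of-balance force tolerance (default 1e-6, against
#'   the total contact force norm).
#' @param atol absolute force tolerance floor (N).
#' @param max_iter maximum Newton iterations per sub-increment.
#' @param max_halvings maximum bisections of a traction-level increment on
#'   non-convergence.
#' @param penalty_factor contact penalty scale; the surface penalty stiffness
#'   is `penalty_factor * E_soft / target_edge` (MPa/mm), holding penetration
#'   near `gap_tol`.
#' @param gap_tol admissible non-physical (penalty) penetration budget (mm,
#'   default 0.02; the cushion-layer compression is a physical deflection
#'   and is not counted).
#' @param comp_tol complementarity tolerance |gap x force| (N mm).
#' @param kinematics `"updated"` (updated-Lagrangian: geometry advanced each
#'   increment, small-strain kinematics per increment) or `"linear"` (strict
#'   small-strain on the original geometry, for verification against linear
#'   closed forms).
#' @param stabilization optional stiffness-proportional stabilization: each
#'   free dof carries a spring `stabilization * diag(K)` against the
#'   increment's start configuration.  Off by default: it regularizes
#'   quasi-static limit points but lets the solver ride through local
#'   tissue-crush snaps whose post-snap states the small-strain kinematics
#'   cannot represent; prefer it only for exploratory runs that stall.
#' @param nu_cap Poisson-ratio cap for conditioning (CSF).
#' @param verbose print per-iteration convergence lines.
#' @return list of class `solver_control`.
#' @export
solver_control <- function(rtol = 1e-6, atol = 1e-8, max_iter = 40L,
                           max_halvings = 5L, increments_per_level = 2L,
                           penalty_factor = 200,
                           gap_tol = 0.02, comp_tol = 0.01,
                           kinematics = c("updated", "linear"),
                           mat_model = c("cushion", "deformable", "none"),
                           stabilization = 0,
                           nu_cap = 0.495, verbose = FALSE) {
  kinematics <- match.arg(kinematics)
  mat_model <- match.arg(mat_model)
  structure(list(rtol = rtol, atol = atol, max_iter = as.integer(max_iter),
                 max_halvings = as.integer(max_halvings),
                 increments_per_level = as.integer(increments_per_level),
                 penalty_factor = penalty_factor, gap_tol = gap_tol,
                 comp_tol = comp_tol, kinematics = kinematics,
                 mat_model = mat_model, stabilization = stabilization,
                 nu_cap = nu_cap, verbose = verbose),
            class = "solver_control")
}

## assemble the traction contact scene for a mesh at roller level state.
## Three mat models:
##   "cushion"    -- the mat acts as a compliant (Winkler) layer carried by
##                   the rigid rollers: effective roller radius grows by the
##                   mat thickness (+ rest clearance) and the contact law
##                   stiffness is the series combination of the penalty and
##                   the mat's through-thickness constrained stiffness.  The
##                   meshed mat body is a spectator.  Robust default: the
##                   deformable frictionless mat sandwiched between rigid
##                   rollers and the back has nearly neutral tangential modes
##                   (membrane tension ~ T/R against load ~ F/R) that a
##                   quasi-static solver cannot stabilize without friction.
##   "deformable" -- the mat is a meshed elastic strip with two contact
##                   pairs (roller/mat underside, mat top/skin), mirroring
##                   the reference setup; may need many sub-increments.
##   "none"       -- bare rigid rollers against the skin (fast tests).
build_scene <- function(mesh, geometry, protocol, materials, bnd, control) {
  fixed <- bnd$fixed_nodes
  E_mat <- material_lookup(materials, "mat")$E
  nu_mat <- material_lookup(materials, "mat")$nu
  kpen_surf <- control$penalty_factor * E_mat / mesh$target_edge
  trib_skin <- chain_trib_lengths(mesh$nodes, mesh$boundary$posterior_skin)
  sc <- list(mode = control$mat_model,
             skin_chain = mesh$boundary$posterior_skin,
             skin_slaves = setdiff(mesh$boundary$posterior_skin, fixed),
             eps_reg = min(control$gap_tol, 0.01) / 2,
             stab = 0,
             rollers = NULL)
  names(trib_skin) <- mesh$boundary$posterior_skin
  if (control$mat_model == "cushion") {
    Ec_mat <- E_mat * (1 - nu_mat) / ((1 + nu_mat) * (1 - 2 * nu_mat))
    k_winkler <- Ec_mat / geometry$spec$mat_thickness_mm
    k_int <- 1 / (1 / kpen_surf + 1 / k_winkler)
    sc$radius_extra <- geometry$spec$mat_thickness_mm +
      geometry$spec$mat_clearance_mm
    sc$kpen_cushion <- k_int * trib_skin[as.character(sc$skin_slaves)]
    sc$kpen_hard <- kpen_surf * trib_skin[as.character(sc$skin_slaves)]
  } else if (control$mat_model == "none") {
    sc$radius_extra <- geometry$spec$mat_thickness_mm +
      geometry$spec$mat_clearance_mm
    sc$kpen_cushion <- kpen_surf * trib_skin[as.character(sc$skin_slaves)]
    sc$kpen_hard <- sc$kpen_cushion
  } else {
    trib_mat <- chain_trib_lengths(mesh$nodes, mesh$boundary$mat_bottom)
    names(trib_mat) <- mesh$boundary$mat_bottom
    sc$mat_top_chain <- mesh$boundary$mat_top
    sc$mat_bottom_slaves <- setdiff(mesh$boundary$mat_bottom, fixed)
    sc$kpen_skin <- kpen_surf * trib_skin
    sc$kpen_mat <- kpen_surf * trib_mat[as.character(sc$mat_bottom_slaves)]
  }
  sc
}

## one displacement-driven sub-increment: Newton iteration over the contact
## state.  K assembled on X; contact evaluated at X + du; incremental
## equilibrium K du = f_c(X + du) - f_c_prev.
newton_increment <- function(K, free, X, scene, f_c_prev, control,
                             label = "", du0 = NULL) {
  n2 <- 2L * nrow(X)
  du <- if (is.null(du0)) numeric(n2) else du0
  du[-free] <- 0
  iter <- 0L
  res_hist <- numeric(0)
  Kff <- Matrix::forceSymmetric(K[free, free])
  ## stiffness-proportional stabilization springs (per-dof, against the
  ## increment's start configuration); regularizes local limit points
  k_stab <- control$stabilization * Matrix::diag(K)
  resid_norm <- function(du_try) {
    xcur <- X + matrix(du_try, ncol = 2, byrow = TRUE)
    ct <- scene_contact(xcur, scene)
    r <- as.numeric(K %*% du_try) + k_stab * du_try - (ct$f - f_c_prev)
    list(ct = ct, r = r, rn = sqrt(sum(r[free]^2)))
  }
  cur <- resid_norm(du)
  repeat {
    iter <- iter + 1L
    ref <- max(sqrt(sum(cur$ct$f[free]^2)), sqrt(sum(f_c_prev[free]^2)),
               control$atol)
    res_hist <- c(res_hist, cur$rn)
    if (control$verbose)
      message(sprintf("  %s it %02d  |r| = %.3e  ref = %.3e  active = %d",
                      label, iter, cur$rn, ref, sum(cur$ct$active)))
    if (cur$rn <= control$rtol * ref) {
      return(list(converged = TRUE, du = du, contact = cur$ct, iters = iter,
                  residuals = res_hist,
                  stab_force = sqrt(sum((k_stab * du)[free]^2))))
    }
    if (iter > control$max_iter ||
        (iter >= 12L && cur$rn > 0.5 * res_hist[iter - 8L])) {
      ## stalled or cycling: bail out and let the caller bisect
      return(list(converged = FALSE, du = du, contact = cur$ct, iters = iter,
                  residuals = res_hist))
    }
    A <- Matrix::forceSymmetric(Kff + cur$ct$Kc[free, free] +
                                Matrix::Diagonal(x = k_stab[free]))
    delta <- numeric(n2)
    delta[free] <- tryCatch(
      as.numeric(Matrix::solve(A, cur$r[free])),
      error = function(e)   # indefinite tangent: fall back to sparse LU
        as.numeric(Matrix::solve(as(A, "generalMatrix"), cur$r[free])))
    ## backtracking line search on the out-of-balance norm (contact
    ## re-evaluation is cheap; no extra factorizations)
    best <- NULL; best_fac <- 1
    for (fac in c(1, 0.5, 0.25, 0.125, 0.0625, 0.03125)) {
      trial <- resid_norm(du - fac * delta)
      if (is.null(best) || trial$rn < best$rn) {
        best <- trial; best_fac <- fac
      }
      if (best$rn < 0.5 * cur$rn) break
    }
    du <- du - best_fac * delta
    cur <- best
  }
}

#' Solve the traction problem up to a traction level
#'
#' Quasi-static incremental solve of plane-strain linear elasticity with
#' frictionless penalty contact: the rigid rollers are raised one traction
#' level per increment (bisected adaptively on non-convergence) and a Newton
#' iteration resolves the contact state at each increment.  With
#' `kinematics = "updated"` the nodal geometry is advanced after every
#' increment (first-order geometric nonlinearity); stress and strain are
#' accumulated incrementally.
#'
#' @param mesh a `labeled_mesh` of the phantom (body + mat).
#' @param materials a [material_table()].
#' @param protocol a [traction_protocol()].
#' @param geometry the `phantom_geometry` the mesh came from (roller
#'   placement and clearances).
#' @param boundary a [boundary_spec()]; default `boundary_spec(mesh)`.
#' @param tl target traction level (0..9).
#' @param control a [solver_control()].
#' @return object of class `traction_solution`: per-level displacement,
#'   accumulated quadrature-point stress/strain, contact diagnostics and
#'   convergence history.
#' @export
solve_traction <- function(mesh, materials, protocol, geometry,
                           boundary = NULL, tl = 9L,
                           control = solver_control()) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  if (is.null(boundary)) boundary <- boundary_spec(mesh)
  if (tl < 0 || tl > protocol$n_levels)
    stop("tl must be in 0..", protocol$n_levels, call. = FALSE)
  resolved <- resolve_materials(mesh, materials, control$nu_cap)
  fixed_dofs <- boundary$fixed_dofs
  n2 <- 2L * nrow(mesh$nodes)
  free <- setdiff(seq_len(n2), fixed_dofs)

  scene0 <- build_scene(mesh, geometry, protocol, materials, boundary,
                        control)
  st0 <- roller_state(protocol, geometry, 0)
  m <- nrow(mesh$tri)

  X <- mesh$nodes
  u_total <- numeric(n2)
  sig <- array(0, c(m, 3, 4))   # sxx, syy, txy, szz at qps
  eps <- array(0, c(m, 3, 3))   # exx, eyy, gxy
  f_c_prev <- numeric(n2)
  levels_out <- vector("list", tl)
  K <- assemble_stiffness(mesh, resolved)

  mesh_cur <- mesh
  disp_done <- 0
  total_work <- 0
  du_pred <- NULL
  step_pred <- NA_real_
  for (lev in seq_len(tl)) {
    disp_target <- tl_to_displacement(lev, protocol)
    remaining <- disp_target - disp_done
    halvings <- 0L
    iters_lev <- 0L
    res_lev <- numeric(0)
    successes <- 0L
    base_div <- max(1L, control$increments_per_level)
    while (remaining > 1e-12) {
      step <- min(remaining,
                  (disp_target - tl_to_displacement(lev - 1L, protocol)) /
                    base_div) / 2^halvings
      scene <- scene0
      scene$rollers <- list(
        centers = cbind(st0$cx, st0$cy + disp_done + step),
        R = st0$R)
      if (control$mat_model == "deformable") {
        ## freeze the master vertex normals at the increment's reference
        ## configuration: the gap is then nearly linear in the increment and
        ## the Newton linearization stays consistent (normals are refreshed
        ## between increments along with the geometry)
        scene$nts_normals <- chain_vertex_normals(X[scene$mat_top_chain, ,
                                                    drop = FALSE])
      }
      du0 <- if (!is.null(du_pred)) du_pred * (step / step_pred) else NULL
      sol <- newton_increment(K, free, X, scene, f_c_prev, control,
                              label = sprintf("TL step @%.2f mm",
                                              disp_done + step),
                              du0 = du0)
      iters_lev <- iters_lev + sol$iters
      res_lev <- c(res_lev, sol$residuals)
      inverted <- FALSE
      if (sol$converged && control$kinematics == "updated") {
        a_new <- tri_signed_area(X + matrix(sol$du, ncol = 2, byrow = TRUE),
                                 mesh_cur$tri[, 1:3, drop = FALSE])
        inverted <- any(a_new <= 0)
      }
      if (!sol$converged || inverted) {
        halvings <- halvings + 1L
        successes <- 0L
        du_pred <- NULL
        if (inverted && halvings > control$max_halvings)
          stop("solve_traction: mesh inversion detected at displacement ",
               signif(disp_done + step, 5),
               " mm even at the smallest sub-increment; the local material ",
               "strain exceeds what the small-strain incremental kinematics ",
               "can represent", call. = FALSE)
        if (halvings > control$max_halvings)
          stop("solve_traction: no convergence at actuator displacement ",
               signif(disp_done + step, 5), " mm after ",
               control$max_halvings, " bisections (last residuals: ",
               paste(signif(utils::tail(sol$residuals, 3), 3),
                     collapse = ", "), ")", call. = FALSE)
        next
      }
      ## accept sub-increment
      de <- qp_strains(mesh_cur, sol$du)
      eps <- eps + de
      Dl <- resolved
      c1 <- Dl$E_elem / ((1 + Dl$nu_elem) * (1 - 2 * Dl$nu_elem))
      D11 <- c1 * (1 - Dl$nu_elem); D12 <- c1 * Dl$nu_elem
      D33 <- Dl$E_elem / (2 * (1 + Dl$nu_elem))
      for (k in 1:3) {
        dsxx <- D11 * de[, k, 1] + D12 * de[, k, 2]
        dsyy <- D12 * de[, k, 1] + D11 * de[, k, 2]
        sig[, k, 1] <- sig[, k, 1] + dsxx
        sig[, k, 2] <- sig[, k, 2] + dsyy
        sig[, k, 3] <- sig[, k, 3] + D33 * de[, k, 3]
        sig[, k, 4] <- sig[, k, 4] + Dl$nu_elem * (dsxx + dsyy)
      }
      total_work <- total_work +
        sum((sol$contact$f + f_c_prev) / 2 * sol$du)
      u_total <- u_total + sol$du
      f_c_prev <- sol$contact$f
      disp_done <- disp_done + step
      remaining <- disp_target - disp_done
      du_pred <- sol$du
      step_pred <- step
      successes <- successes + 1L
      if (halvings > 0L && successes >= 2L) {
        halvings <- halvings - 1L
        successes <- 0L
      }
      if (control$kinematics == "updated") {
        X <- X + matrix(sol$du, ncol = 2, byrow = TRUE)
        mesh_cur$nodes <- X
        ## material + initial-stress stiffness on the updated geometry
        K <- assemble_stiffness(mesh_cur, resolved) +
          assemble_geometric_stiffness(mesh_cur, sig)
        scene0 <- build_scene(mesh_cur, geometry, protocol, materials,
                              boundary, control)
      }
      last_contact <- sol$contact
    }
    levels_out[[lev]] <- list(
      tl = lev,
      displacement_mm = disp_target,
      u = u_total,
      sig_qp = sig,
      eps_qp = eps,
      iterations = iters_lev,
      residuals = res_lev,
      n_active = sum(last_contact$active),
      max_penetration = last_contact$hard_penetration,
      max_comp = max(abs(last_contact$gap * last_contact$force)),
      roller_force_y = last_contact$roller_force_y,
      external_work = total_work
    )
  }

  structure(list(mesh = mesh, geometry = geometry, protocol = protocol,
                 boundary = boundary, control = control,
                 materials = materials, tl = tl,
                 levels = levels_out,
                 nodes_final = X, u = u_total),
            class = "traction_solution")
}

#' Recover nodal stress/strain fields from a solution increment
#'
#' Quadrature-point tensors are extrapolated linearly to the element nodes
#' and averaged across adjacent elements (area-weighted).  The von Mises
#' stress uses the full plane-strain tensor including
#' `szz = nu (sxx + syy)`; the equivalent strain is the von-Mises-equivalent
#' (deviatoric) strain `sqrt(2/3 e:e)`.
#'
#' @param solution a `traction_solution`.
#' @param level traction level to recover (defaults to the solved level).
#' @param region_restrict optional region label: average only over elements
#'   of that region (avoids smearing across material interfaces; used for
#'   disc ROI summaries).
#' @return list with nodal `stress` (N x 4), `strain` (N x 3), `von_mises`
#'   (N), `eq_strain` (N), and `nodes` (indices with support).
#' @export
recover_fields <- function(solution, level = solution$tl,
                           region_restrict = NULL) {
  stopifnot(inherits(solution, "traction_solution"))
  if (level < 1 || level > solution$tl)
    stop("level must be in 1..", solution$tl, call. = FALSE)
  lv <- solution$levels[[level]]
  nodal_from_qp(solution$mesh, lv$sig_qp, lv$eps_qp, region_restrict)
}

## shared recovery: qp arrays -> nodal fields
nodal_from_qp <- function(mesh, sig_qp, eps_qp, region_restrict = NULL) {
  m <- nrow(mesh$tri)
  sel <- seq_len(m)
  if (!is.null(region_restrict)) {
    id <- mesh$labels$region_id[mesh$labels$label == region_restrict]
    if (!length(id)) stop("unknown region '", region_restrict, "'",
                          call. = FALSE)
    sel <- which(mesh$region_id == id)
    if (!length(sel)) stop("region '", region_restrict, "' has no elements",
                           call. = FALSE)
  }
  Eext <- qp_to_node_matrix()
  tri <- mesh$tri[sel, , drop = FALSE]
  area <- abs(tri_signed_area(mesh$nodes, tri[, 1:3, drop = FALSE]))
  N <- nrow(mesh$nodes)
  acc_s <- matrix(0, N, 4)
  acc_e <- matrix(0, N, 3)
  idx <- as.vector(tri)
  warr <- rep(area, 6)
  wacc <- rowsum(warr, idx)
  wtot <- numeric(N); wtot[as.integer(rownames(wacc))] <- wacc[, 1]
  for (c_i in 1:4) {
    nodal_el <- sig_qp[sel, , c_i, drop = FALSE][, , 1] %*% t(Eext) # me x 6
    acc <- rowsum(as.vector(nodal_el) * warr, idx)
    acc_s[as.integer(rownames(acc)), c_i] <- acc[, 1]
  }
  for (c_i in 1:3) {
    nodal_el <- eps_qp[sel, , c_i, drop = FALSE][, , 1] %*% t(Eext)
    acc <- rowsum(as.vector(nodal_el) * warr, idx)
    acc_e[as.integer(rownames(acc)), c_i] <- acc[, 1]
  }
  support <- which(wtot > 0)
  acc_s[support, ] <- acc_s[support, , drop = FALSE] / wtot[support]
  acc_e[support, ] <- acc_e[support, , drop = FALSE] / wtot[support]
  vm <- von_mises_stress(acc_s)
  eq <- equivalent_strain(acc_e)
  list(stress = acc_s, strain = acc_e, von_mises = vm, eq_strain = eq,
       nodes = support)
}

#' von Mises stress from plane-strain tensor components
#' @param s matrix / vector of components `(sxx, syy, txy, szz)`.
#' @return numeric vector of von Mises stresses.
#' @export
von_mises_stress <- function(s) {
  if (is.null(dim(s))) s <- matrix(s, 1)
  sxx <- s[, 1]; syy <- s[, 2]; txy <- s[, 3]; szz <- s[, 4]
  sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) + 3 * txy^2)
}

#' von-Mises-equivalent (deviatoric) strain under plane strain
#' @param e matrix / vector of components `(exx, eyy, gxy)`; `ezz = 0`.
#' @return numeric vector of equivalent strains `sqrt(2/3 e_dev : e_dev)`.
#' @export
equivalent_strain <- function(e) {
  if (is.null(dim(e))) e <- matrix(e, 1)
  exx <- e[, 1]; eyy <- e[, 2]; exy <- e[, 3] / 2
  tr3 <- (exx + eyy) / 3
  dxx <- exx - tr3; dyy <- eyy - tr3; dzz <- -tr3
  sqrt(pmax(0, 2 / 3 * (dxx^2 + dyy^2 + dzz^2 + 2 * exy^2)))
}

#' Strain energy of a solution increment
#'
#' Integrates `1/2 sigma : eps` over the mesh from the accumulated
#' quadrature-point fields (the plane-strain `szz` does no work since
#' `ezz = 0`).
#'
#' @param solution a `traction_solution`.
#' @param level traction level.
#' @return energy in N mm (per mm of out-of-plane thickness).
#' @export
strain_energy <- function(solution, level = solution$tl) {
  lv <- solution$levels[[level]]
  w <- qp_weights(solution$mesh)
  en <- 0
  for (k in 1:3)
    en <- en + sum(w[, k] * 0.5 *
                     (lv$sig_qp[, k, 1] * lv$eps_qp[, k, 1] +
                        lv$sig_qp[, k, 2] * lv$eps_qp[, k, 2] +
                        lv$sig_qp[, k, 3] * lv$eps_qp[, k, 3]))
  en
}

#' Linear elastic solve (no contact) for verification problems
#'
#' Direct sparse solve of `K u = f` with fixed and prescribed displacement
#' boundary conditions on a labeled mesh with a single material; used by the
#' analytic verification suite (patch test, cantilever, dense-oracle
#' comparison).
#'
#' @param mesh a `labeled_mesh`.
#' @param E,nu material constants.
#' @param fixed_dofs dofs constrained to zero.
#' @param f_ext external nodal force vector (length 2N).
#' @param prescribed optional named numeric vector: dof index -> prescribed
#'   displacement.
#' @return list with `u`, stiffness `K`, and recovered fields.
#' @export
solve_elastic <- function(mesh, E, nu, fixed_dofs = integer(0),
                          f_ext = NULL, prescribed = NULL) {
  m <- nrow(mesh$tri)
  mats <- list(E_elem = rep(E, m), nu_elem = rep(nu, m))
  K <- assemble_stiffness(mesh, mats)
  n2 <- 2L * nrow(mesh$nodes)
  if (is.null(f_ext)) f_ext <- numeric(n2)
  u <- numeric(n2)
  pres_dofs <- integer(0)
  if (!is.null(prescribed)) {
    pres_dofs <- as.integer(names(prescribed))
    u[pres_dofs] <- as.numeric(prescribed)
  }
  fixed_all <- union(fixed_dofs, pres_dofs)
  free <- setdiff(seq_len(n2), fixed_all)
  rhs <- f_ext[free] - as.numeric(K[free, fixed_all, drop = FALSE] %*%
                                    u[fixed_all])
  u[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  de <- qp_strains(mesh, u)
  sig <- array(0, c(m, 3, 4))
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  for (k in 1:3) {
    sig[, k, 1] <- c1 * (1 - nu) * de[, k, 1] + c1 * nu * de[, k, 2]
    sig[, k, 2] <- c1 * nu * de[, k, 1] + c1 * (1 - nu) * de[, k, 2]
    sig[, k, 3] <- E / (2 * (1 + nu)) * de[, k, 3]
    sig[, k, 4] <- nu * (sig[, k, 1] + sig[, k, 2])
  }
  list(u = u, K = K, sig_qp = sig, eps_qp = de,
       fields = nodal_from_qp(mesh, sig, de))
}

#' @export
print.traction_solution <- function(x, ...) {
  cat(sprintf("Traction solution to TL%d (%s kinematics): %d nodes, %d elements\n",
              x$tl, x$control$kinematics, nrow(x$mesh$nodes), nrow(x$mesh$tri)))
  if (x$tl >= 1) {
    lv <- x$levels[[x$tl]]
    cat(sprintf("  final level: %d Newton iterations, %d active contact nodes, max penetration %.2e mm\n",
                lv$iterations, lv$n_active, lv$max_penetration))
  }
  invisible(x)
}
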