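test_that("assembled stiffness matches an independent element oracle", {
  rm <- mesh_rectangle(1.3, 0.9, 2, x_lines = c(0, 1.3), y_lines = c(0, 0.9))
  E <- 7; nu <- 0.35
  K <- assemble_stiffness(rm, list(E_elem = rep(E, nrow(rm$tri)),
                                   nu_elem = rep(nu, nrow(rm$tri))))
  D <- plane_strain_matrix(E, nu)
  n2 <- 2L * nrow(rm$nodes)
  Ko <- matrix(0, n2, n2)
  for (e in seq_len(nrow(rm$tri))) {
    nd <- rm$tri[e, ]
    Ke <- oracle_t6_stiffness(rm$nodes[nd, ], D)
    dofs <- as.vector(rbind(2L * nd - 1L, 2L * nd))
    Ko[dofs, dofs] <- Ko[dofs, dofs] + Ke
  }
  expect_equal(as.matrix(K), Ko, tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("stiffness is symmetric with an exact rigid-body nullspace", {
  rm <- mesh_rectangle(10, 10, 2.5)
  K <- assemble_stiffness(rm, list(E_elem = rep(2, nrow(rm$tri)),
                                   nu_elem = rep(0.3, nrow(rm$tri))))
  expect_lt(max(abs(K - Matrix::t(K))), 1e-12 * max(abs(K)))
  tx <- rep(c(1, 0), nrow(rm$nodes))
  ty <- rep(c(0, 1), nrow(rm$nodes))
  rot <- as.vector(t(cbind(-rm$nodes[, 2], rm$nodes[, 1])))
  nrmK <- max(abs(K))
  expect_lt(max(abs(K %*% tx)), 1e-9 * nrmK)
  expect_lt(max(abs(K %*% ty)), 1e-9 * nrmK)
  expect_lt(max(abs(K %*% rot)), 1e-9 * nrmK * max(abs(rm$nodes)))
})

test_that("patch test is exact to machine precision", {
  pt <- verify_patch()
  expect_lt(pt$disp_error, 1e-12)
  expect_lt(pt$stress_error, 1e-12)
})

test_that("von Mises stress handles canonical states", {
  expect_equal(von_mises_stress(c(3, 0, 0, 0)), 3)          # uniaxial
  expect_equal(von_mises_stress(c(2, 2, 0, 2)), 0)          # hydrostatic
  expect_equal(von_mises_stress(c(0, 0, 1.5, 0)), sqrt(3) * 1.5)  # shear
})

test_that("equivalent strain is the deviatoric von Mises measure", {
  ## pure engineering shear g: eq strain = g / sqrt(3)
  g <- 0.02
  expect_equal(equivalent_strain(c(0, 0, g)), g / sqrt(3))
  ## equibiaxial in-plane stretch a (ezz = 0): eq strain = 2a/3
  a <- 0.01
  expect_equal(equivalent_strain(c(a, a, 0)), 2 * a / 3)
  ## in-plane hydrostatic has no deviatoric shear only when ezz matches;
  ## under plane strain it does not vanish
  expect_gt(equivalent_strain(c(a, a, 0)), 0)
})

test_that("stress and strain measures are proportional through 3G", {
  ## for an isotropic material both measures are deviatoric:
  ## vm(sigma) = 3G * eq(eps) for any plane-strain state
  E <- 17; nu <- 0.49
  D <- plane_strain_matrix(E, nu)
  G <- E / (2 * (1 + nu))
  set.seed(7)
  for (k in 1:10) {
    eps <- rnorm(3) * 0.01
    sig <- as.vector(D %*% eps)
    szz <- nu * (sig[1] + sig[2])
    vm <- von_mises_stress(c(sig, szz))
    eq <- equivalent_strain(eps)
    expect_equal(vm, 3 * G * eq, tolerance = 1e-10)
  }
})

test_that("contact solve is deterministic and satisfies contact bounds", {
  sol <- coarse_solution()
  sc <- coarse_scene()
  sol2 <- solve_traction(sc$mesh, material_table(), traction_protocol(),
                         sc$geom, tl = 5)
  expect_identical(sol$u, sol2$u)
  expect_identical(sol$levels[[5]]$sig_qp, sol2$levels[[5]]$sig_qp)
  lv <- sol$levels[[5]]
  ctrl <- solver_control()
  expect_lte(lv$max_penetration, ctrl$gap_tol)
  expect_gt(lv$n_active, 0)
  expect_gt(lv$roller_force_y, 0)
})

test_that("displacements vanish below the contact onset level", {
  sol <- coarse_solution()
  ## TL1-3: the rollers are clear of the chain, no contact at all
  for (lv in 1:3) {
    expect_lt(max(abs(sol$levels[[lv]]$u)), 1e-8)
    expect_equal(sol$levels[[lv]]$n_active, 0L)
  }
  ## TL4 is the exact-touch level: micrometre-scale grazing contact is
  ## possible at the calibration sampling resolution, but carries no load
  expect_lt(max(abs(sol$levels[[4]]$u)), 1e-4)
  expect_lt(sol$levels[[4]]$roller_force_y, 1e-3)
  expect_gt(max(abs(sol$levels[[5]]$u)), 1)
})

test_that("total roller force is non-decreasing in traction level", {
  sw <- default_study_sweep()   # harvested from the full solves
  ## use the coarse solution for the direct force diagnostic
  sol <- coarse_solution()
  fy <- vapply(seq_len(5), function(l) sol$levels[[l]]$roller_force_y,
               numeric(1))
  expect_true(all(diff(fy) >= -1e-9))
})

test_that("recovered fields are consistent with elastic energy storage", {
  en <- verification_results()
  e <- en$value[en$check == "energy_balance_rel_error"]
  expect_lt(e, 0.01)
})

test_that("boundary spec fixes anterior end nodes away from contact surfaces", {
  sc <- coarse_scene()
  bnd <- boundary_spec(sc$mesh)
  expect_gt(length(bnd$fixed_nodes), 0)
  skin <- sc$mesh$boundary$posterior_skin
  slaves <- setdiff(skin, bnd$fixed_nodes)
  expect_false(any(bnd$fixed_nodes %in% slaves))
  ## fixed nodes sit on the anterior aspect of the end faces
  y_fixed <- sc$mesh$nodes[setdiff(bnd$fixed_nodes,
                                   sc$mesh$boundary$mat_ends), 2]
  expect_true(all(y_fixed > max(sc$mesh$nodes[skin, 2])))
})

test_that("deformable-mat scene carries two contact pairs below onset", {
  sc <- coarse_scene()
  ctrl <- solver_control(mat_model = "deformable")
  sol <- solve_traction(sc$mesh, material_table(), traction_protocol(),
                        sc$geom, tl = 4, control = ctrl)
  ## below onset: converged trivially with no contact force anywhere
  expect_lt(max(abs(sol$u)), 1e-8)
  expect_equal(sol$levels[[4]]$n_active, 0L)
})

test_that("disc averages are mesh-converged at the default resolution", {
  ## halving the target edge changes disc means by under 5%.  Checked at
  ## TL7: at TL9 the finer mesh resolves the local fat compression under
  ## the roller flank beyond what small-strain incremental kinematics can
  ## represent (the solver detects element inversion), so the comparison
  ## level is the highest one both resolutions complete.
  geom <- build_phantom(phantom_spec())
  va <- list()
  for (h in c(5, 2.5)) {
    mesh <- mesh_geometry(geom, h)
    sol <- solve_traction(mesh, material_table(), traction_protocol(),
                          geom, tl = 7)
    va[[as.character(h)]] <- vapply(disc_level_names(), function(d)
      disc_average(sol, mesh, d, "von_mises_stress", 7), numeric(1))
  }
  rel <- abs(va[["2.5"]] - va[["5"]]) / va[["5"]]
  expect_true(all(rel <= 0.05))
})
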