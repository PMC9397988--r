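## Plane-strain FEM on 6-node quadratic triangles (T6), 3-point quadrature.
##
## T6 avoids the volumetric locking that linear triangles exhibit at the
## near-incompressible Poisson ratios (nu = 0.49) of most tissues here.
## Elements are straight-sided (midside nodes at edge midpoints), so the
## 3-point rule integrates the stiffness integrand exactly and the patch
## test is satisfied to machine precision.

## quadrature on the reference triangle (area 1/2)
t6_quadrature <- function() {
  list(pts = rbind(c(1/6, 1/6), c(2/3, 1/6), c(1/6, 2/3)),
       w = rep(1/6, 3))
}

## shape functions and reference-coordinate derivatives at (xi, eta)
t6_shape <- function(xi, eta) {
  L1 <- 1 - xi - eta; L2 <- xi; L3 <- eta
  c(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1),
    4 * L1 * L2, 4 * L2 * L3, 4 * L3 * L1)
}

t6_dshape <- function(xi, eta) {
  L1 <- 1 - xi - eta; L2 <- xi; L3 <- eta
  dxi <- c(-(4 * L1 - 1), 4 * L2 - 1, 0, 4 * (L1 - L2), 4 * L3, -4 * L3)
  deta <- c(-(4 * L1 - 1), 0, 4 * L3 - 1, -4 * L2, 4 * L2, 4 * (L1 - L3))
  list(dxi = dxi, deta = deta)
}

## per-element Cartesian shape derivatives at one quadrature point,
## vectorised over elements; X, Y are m x 6 nodal coordinate matrices
elem_bmat <- function(X, Y, dsh) {
  J11 <- X %*% dsh$dxi; J12 <- X %*% dsh$deta
  J21 <- Y %*% dsh$dxi; J22 <- Y %*% dsh$deta
  detJ <- as.vector(J11 * J22 - J12 * J21)
  Bx <- (outer(as.vector(J22), dsh$dxi) - outer(as.vector(J21), dsh$deta)) / detJ
  By <- (outer(as.vector(J11), dsh$deta) - outer(as.vector(J12), dsh$dxi)) / detJ
  list(Bx = Bx, By = By, detJ = detJ)
}

elem_coord_matrices <- function(nodes, tri) {
  list(X = matrix(nodes[tri, 1], nrow(tri), 6),
       Y = matrix(nodes[tri, 2], nrow(tri), 6))
}

#' Assemble the global plane-strain stiffness operator
#'
#' Sparse symmetric stiffness matrix for a labeled T6 mesh with per-region
#' isotropic materials.  Before boundary conditions its nullspace is spanned
#' by the planar rigid-body modes of each connected component.
#'
#' @param mesh a `labeled_mesh`.
#' @param materials a [material_table()] (or a list with per-element `E_elem`,
#'   `nu_elem` from the internal resolver).
#' @param nu_cap Poisson-ratio cap for conditioning (applied to CSF).
#' @return sparse `dgCMatrix` of dimension `2N x 2N` (dofs ordered x1, y1,
#'   x2, y2, ...).
#' @export
assemble_stiffness <- function(mesh, materials, nu_cap = 0.495) {
  if (inherits(materials, "material_table"))
    materials <- resolve_materials(mesh, materials, nu_cap)
  E <- materials$E_elem; nu <- materials$nu_elem
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  D11 <- c1 * (1 - nu); D12 <- c1 * nu; D33 <- E / (2 * (1 + nu))

  tri <- mesh$tri
  m <- nrow(tri)
  cm <- elem_coord_matrices(mesh$nodes, tri)
  q <- t6_quadrature()

  Kxx <- Kxy <- Kyx <- Kyy <- array(0, c(m, 6, 6))
  for (k in 1:3) {
    dsh <- t6_dshape(q$pts[k, 1], q$pts[k, 2])
    bm <- elem_bmat(cm$X, cm$Y, dsh)
    wd <- q$w[k] * bm$detJ
    for (i in 1:6) for (j in 1:6) {
      Kxx[, i, j] <- Kxx[, i, j] +
        wd * (D11 * bm$Bx[, i] * bm$Bx[, j] + D33 * bm$By[, i] * bm$By[, j])
      Kxy[, i, j] <- Kxy[, i, j] +
        wd * (D12 * bm$Bx[, i] * bm$By[, j] + D33 * bm$By[, i] * bm$Bx[, j])
      Kyx[, i, j] <- Kyx[, i, j] +
        wd * (D12 * bm$By[, i] * bm$Bx[, j] + D33 * bm$Bx[, i] * bm$By[, j])
      Kyy[, i, j] <- Kyy[, i, j] +
        wd * (D11 * bm$By[, i] * bm$By[, j] + D33 * bm$Bx[, i] * bm$Bx[, j])
    }
  }
  dofx <- 2L * tri - 1L   # m x 6
  dofy <- 2L * tri
  ## array index (m, i, j) flattens with i fastest after m; build index grids
  ii <- rep(1:6, times = 6); jj <- rep(1:6, each = 6)
  tri_i <- function(dof) dof[, ii, drop = FALSE]
  tri_j <- function(dof) dof[, jj, drop = FALSE]
  I <- c(tri_i(dofx), tri_i(dofx), tri_i(dofy), tri_i(dofy))
  J <- c(tri_j(dofx), tri_j(dofy), tri_j(dofx), tri_j(dofy))
  V <- c(Kxx, Kxy, Kyx, Kyy)
  N2 <- 2L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = I, j = J, x = V, dims = c(N2, N2))
}

## initial-stress (geometric) stiffness from accumulated quadrature-point
## stresses: K_g[(i,a),(j,b)] = delta_ab * int (grad N_i)^T S (grad N_j) dV
## with S the 2x2 in-plane Cauchy stress.  This carries membrane
## tension/compression stiffening between increments of the
## updated-Lagrangian scheme (e.g. the stretched mat wrapped on a roller).
assemble_geometric_stiffness <- function(mesh, sig_qp) {
  tri <- mesh$tri
  m <- nrow(tri)
  cm <- elem_coord_matrices(mesh$nodes, tri)
  q <- t6_quadrature()
  Kg <- array(0, c(m, 6, 6))
  for (k in 1:3) {
    dsh <- t6_dshape(q$pts[k, 1], q$pts[k, 2])
    bm <- elem_bmat(cm$X, cm$Y, dsh)
    wd <- q$w[k] * bm$detJ
    sxx <- sig_qp[, k, 1]; syy <- sig_qp[, k, 2]; txy <- sig_qp[, k, 3]
    for (i in 1:6) for (j in 1:6) {
      Kg[, i, j] <- Kg[, i, j] + wd *
        (bm$Bx[, i] * sxx * bm$Bx[, j] + bm$By[, i] * syy * bm$By[, j] +
           txy * (bm$Bx[, i] * bm$By[, j] + bm$By[, i] * bm$Bx[, j]))
    }
  }
  dofx <- 2L * tri - 1L
  dofy <- 2L * tri
  ii <- rep(1:6, times = 6); jj <- rep(1:6, each = 6)
  I <- c(dofx[, ii], dofy[, ii])
  J <- c(dofx[, jj], dofy[, jj])
  V <- c(Kg, Kg)
  N2 <- 2L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = I, j = J, x = V, dims = c(N2, N2))
}

## strain (exx, eyy, gxy) at the quadrature points for displacement u;
## returns array (m, 3 qp, 3 comps)
qp_strains <- function(mesh, u) {
  tri <- mesh$tri
  m <- nrow(tri)
  cm <- elem_coord_matrices(mesh$nodes, tri)
  Ux <- matrix(u[2L * tri - 1L], m, 6)
  Uy <- matrix(u[2L * tri], m, 6)
  q <- t6_quadrature()
  out <- array(0, c(m, 3, 3))
  for (k in 1:3) {
    dsh <- t6_dshape(q$pts[k, 1], q$pts[k, 2])
    bm <- elem_bmat(cm$X, cm$Y, dsh)
    out[, k, 1] <- rowSums(bm$Bx * Ux)
    out[, k, 2] <- rowSums(bm$By * Uy)
    out[, k, 3] <- rowSums(bm$By * Ux + bm$Bx * Uy)
  }
  out
}

## quadrature weights w * detJ, (m x 3)
qp_weights <- function(mesh) {
  tri <- mesh$tri
  cm <- elem_coord_matrices(mesh$nodes, tri)
  q <- t6_quadrature()
  sapply(1:3, function(k) {
    dsh <- t6_dshape(q$pts[k, 1], q$pts[k, 2])
    bm <- elem_bmat(cm$X, cm$Y, dsh)
    q$w[k] * bm$detJ
  })
}

## extrapolation matrix from the 3 quadrature points to the 6 element nodes
## (linear fit through the qp values, evaluated at the nodes)
qp_to_node_matrix <- function() {
  q <- t6_quadrature()
  M <- cbind(1, q$pts)
  nodes <- rbind(c(0, 0), c(1, 0), c(0, 1),
                 c(0.5, 0), c(0.5, 0.5), c(0, 0.5))
  cbind(1, nodes) %*% solve(M)
}

## fixed-dof helper: boundary condition spec for the traction scene
#' Boundary conditions for the traction scene
#'
#' Implements the anterior fixed-node condition: zero translation on the
#' anterior-most `anterior_fraction` of the cranial and caudal end faces of
#' the body, plus full clamping of the mat's craniocaudal ends (the mat is
#' attached to the bed frame).
#'
#' @param mesh a `labeled_mesh` from [mesh_geometry()].
#' @param anterior_fraction fraction (default 0.1) of each end-face depth,
#'   measured from the anterior surface, whose nodes are fixed.
#' @return object of class `boundary_spec` with `fixed_nodes`, `fixed_dofs`.
#' @export
boundary_spec <- function(mesh, anterior_fraction = 0.1) {
  stopifnot(anterior_fraction > 0, anterior_fraction <= 1)
  pick <- function(chain) {
    y <- mesh$nodes[chain, 2]
    depth <- max(y) - min(y)
    chain[y >= max(y) - anterior_fraction * depth - 1e-9]
  }
  fixed <- sort(unique(c(pick(mesh$boundary$end_cranial),
                         pick(mesh$boundary$end_caudal),
                         mesh$boundary$mat_ends)))
  ## fixed sets must not intersect the contact surfaces
  contact <- unique(c(mesh$boundary$posterior_skin, mesh$boundary$mat_top,
                      mesh$boundary$mat_bottom))
  overlap <- intersect(fixed, contact)
  structure(list(fixed_nodes = fixed,
                 fixed_dofs = sort(c(2L * fixed - 1L, 2L * fixed)),
                 anterior_fraction = anterior_fraction,
                 contact_overlap = overlap),
            class = "boundary_spec")
}
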