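## Frictionless contact: node-to-segment penalty.
##
## "Hard contact" in the normal direction is approximated by a stiff penalty
## (pressure proportional to penetration, non-physical penetration held
## within the gap_tol budget); the tangential direction is exactly
## frictionless (forces act along the contact normal only).  The penalty law
## is C^1-regularized in a 0.005 mm band around zero gap so that the Newton
## iteration is not derailed by marginal nodes flickering across the contact
## boundary.  Pair types: rigid (cushioned) roller circles against slave
## nodes, and a deformable master polyline against slave nodes for the
## meshed-mat mode.

## regularized penalty force magnitude and tangent stiffness for
## penetration p = -gap > 0
pen_force <- function(p, k, eps) {
  ifelse(p <= 0, 0, ifelse(p < eps, k * p^2 / (2 * eps), k * (p - eps / 2)))
}
pen_stiff <- function(p, k, eps) {
  ifelse(p <= 0, 0, ifelse(p < eps, k * p / eps, k))
}

## vertex normals of an ordered chain: mean of adjacent segment normals
## (left of the walking direction; the mat-top chain runs cranial -> caudal
## along +x, so its normals point anteriorly, toward the body)
chain_vertex_normals <- function(mp) {
  nv <- nrow(mp)
  t_seg <- mp[-1, , drop = FALSE] - mp[-nv, , drop = FALSE]
  len <- sqrt(rowSums(t_seg^2))
  seg_n <- cbind(-t_seg[, 2], t_seg[, 1]) / len
  vert_n <- rbind(seg_n[1, , drop = FALSE],
                  (seg_n[-1, , drop = FALSE] +
                     seg_n[-(nv - 1L), , drop = FALSE]),
                  seg_n[nv - 1L, , drop = FALSE])
  vert_n / sqrt(rowSums(vert_n^2))
}

## tributary boundary length per node of an ordered chain, from coordinates
chain_trib_lengths <- function(nodes, chain) {
  p <- nodes[chain, , drop = FALSE]
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  tl <- numeric(length(chain))
  tl[-length(tl)] <- tl[-length(tl)] + seg / 2
  tl[-1] <- tl[-1] + seg / 2
  tl
}

## node-to-circle contact (rigid rollers). x: current N x 2 coords.
## `geometric` includes the curvature term -(F/r)(I - n n^T) of the
## consistent tangent: correct and quadratic-converging when the slave
## surface is well anchored (skin on the body); destabilizing when the slave
## is a nearly floating membrane (deformable mat), where it is omitted.
contact_circle <- function(x, slaves, centers, R, kpen_node, eps,
                           stab = 0, geometric = TRUE) {
  fi <- integer(0); fv <- numeric(0)
  ki <- integer(0); kj <- integer(0); kv <- numeric(0)
  gap <- rep(Inf, length(slaves))
  force <- numeric(length(slaves))
  for (c_i in seq_len(nrow(centers))) {
    d <- sweep(x[slaves, , drop = FALSE], 2, centers[c_i, ])
    r <- sqrt(rowSums(d^2))
    g <- r - R
    gap <- pmin(gap, g)
    act <- which(g < 0)
    for (a in act) {
      n <- d[a, ] / r[a]
      k <- kpen_node[a]
      p <- -g[a]
      Fm <- pen_force(p, k, eps)
      kt <- pen_stiff(p, k, eps)
      f <- Fm * n
      nd <- slaves[a]
      fi <- c(fi, 2L * nd - 1L, 2L * nd)
      fv <- c(fv, f)
      Kc <- kt * (n %o% n)
      if (geometric) Kc <- Kc - (Fm / r[a]) * (diag(2) - n %o% n)
      if (stab > 0) Kc <- Kc + stab * kt * (diag(2) - n %o% n)
      dd <- c(2L * nd - 1L, 2L * nd)
      ki <- c(ki, rep(dd, 2)); kj <- c(kj, rep(dd, each = 2))
      kv <- c(kv, as.vector(Kc))
      force[a] <- force[a] + Fm
    }
  }
  list(fi = fi, fv = fv, ki = ki, kj = kj, kv = kv, gap = gap, force = force)
}

## node-to-segment contact of slave nodes against a deformable master
## polyline (ordered node chain).  The slave's closest-point projection onto
## the current master geometry handles tangential sliding (frictionless);
## the normal field interpolates vertex normals along each segment so the
## force direction is continuous across facet junctions.  Passing `normals`
## (vertex normals frozen at the start of an increment) makes the gap nearly
## linear in the increment and keeps the Newton linearization consistent.
contact_nts <- function(x, slaves, master_chain, kpen_node, eps,
                        normals = NULL, stab = 0.05) {
  mp <- x[master_chain, , drop = FALSE]
  nv <- nrow(mp)
  nseg <- nv - 1L
  t_seg <- mp[-1, , drop = FALSE] - mp[-nv, , drop = FALSE]
  len2 <- rowSums(t_seg^2)
  vert_n <- if (is.null(normals)) chain_vertex_normals(mp) else normals
  fi <- integer(0); fv <- numeric(0)
  ki <- integer(0); kj <- integer(0); kv <- numeric(0)
  gap <- rep(Inf, length(slaves))
  force <- numeric(length(slaves))
  sx <- x[slaves, , drop = FALSE]
  ## nearest master vertex (2D) seeds the projection; robust to locally
  ## non-monotone deformed chains
  d2 <- outer(sx[, 1], mp[, 1], "-")^2 + outer(sx[, 2], mp[, 2], "-")^2
  v0 <- max.col(-d2, ties.method = "first")
  for (a in seq_along(slaves)) {
    best <- NULL
    for (s in unique(pmax(1L, pmin(nseg, v0[a] + (-2:1))))) {
      tv <- t_seg[s, ]
      tt <- sum((sx[a, ] - mp[s, ]) * tv) / len2[s]
      tt <- min(max(tt, 0), 1)
      q <- mp[s, ] + tt * tv
      nrm <- (1 - tt) * vert_n[s, ] + tt * vert_n[s + 1L, ]
      nrm <- nrm / sqrt(sum(nrm^2))
      g <- sum((sx[a, ] - q) * nrm)
      if (is.null(best) || abs(g) < abs(best$g))
        best <- list(s = s, t = tt, g = g, n = nrm)
    }
    gap[a] <- best$g
    if (best$g < 0) {
      k <- kpen_node[a]
      p <- -best$g
      Fm <- pen_force(p, k, eps)
      kt <- pen_stiff(p, k, eps)
      w <- c(1, -(1 - best$t), -best$t)       # slave, master1, master2
      nd <- c(slaves[a], master_chain[best$s], master_chain[best$s + 1L])
      dofs <- as.vector(rbind(2L * nd - 1L, 2L * nd))
      gradg <- as.vector(t(cbind(w * best$n[1], w * best$n[2])))
      fi <- c(fi, dofs); fv <- c(fv, Fm * gradg)
      ## tangential stabilization (iteration matrix only; see contact_circle)
      tau <- c(-best$n[2], best$n[1])
      gradt <- as.vector(t(cbind(w * tau[1], w * tau[2])))
      Kc <- kt * (gradg %o% gradg) + stab * kt * (gradt %o% gradt)
      ki <- c(ki, rep(dofs, 6)); kj <- c(kj, rep(dofs, each = 6))
      kv <- c(kv, as.vector(Kc))
      force[a] <- Fm
    }
  }
  list(fi = fi, fv = fv, ki = ki, kj = kj, kv = kv, gap = gap, force = force)
}

## evaluate all contact pairs of a traction scene at configuration x.
## In "cushion"/"none" mode the (cushioned) rigid rollers contact the
## posterior skin directly; in "deformable" mode the meshed mat carries two
## pairs (rollers/mat underside and mat top/skin).  `hard_penetration` is the
## non-physical penalty part of the penetration (cushion compression is a
## physical deflection of the mat layer).
scene_contact <- function(x, scene) {
  n2 <- 2L * nrow(x)
  if (scene$mode %in% c("cushion", "none")) {
    cA <- contact_circle(x, scene$skin_slaves, scene$rollers$centers,
                         scene$rollers$R + scene$radius_extra,
                         scene$kpen_cushion, scene$eps_reg, scene$stab,
                         geometric = TRUE)
    forces <- list(fi = cA$fi, fv = cA$fv)
    ki <- cA$ki; kj <- cA$kj; kv <- cA$kv
    active <- cA$force > 1e-12
    gap <- cA$gap
    force <- cA$force
    hard_pen <- max(0, cA$force / scene$kpen_hard)
    roller_fy <- if (length(cA$fi)) sum(cA$fv[cA$fi %% 2L == 0L]) else 0
  } else {
    cA <- contact_circle(x, scene$mat_bottom_slaves, scene$rollers$centers,
                         scene$rollers$R, scene$kpen_mat, scene$eps_reg,
                         scene$stab, geometric = FALSE)
    cB <- contact_nts(x, scene$skin_chain, scene$mat_top_chain,
                      scene$kpen_skin, scene$eps_reg, scene$nts_normals,
                      scene$stab)
    forces <- list(fi = c(cA$fi, cB$fi), fv = c(cA$fv, cB$fv))
    ki <- c(cA$ki, cB$ki); kj <- c(cA$kj, cB$kj); kv <- c(cA$kv, cB$kv)
    active <- c(cA$force > 1e-12, cB$force > 1e-12)
    gap <- c(cA$gap, cB$gap)
    force <- c(cA$force, cB$force)
    hard_pen <- max(0, -min(gap))
    roller_fy <- if (length(cA$fi)) sum(cA$fv[cA$fi %% 2L == 0L]) else 0
  }
  f <- numeric(n2)
  if (length(forces$fi)) {
    agg <- rowsum(forces$fv, forces$fi)
    f[as.integer(rownames(agg))] <- agg[, 1]
  }
  Kc <- if (length(ki))
    Matrix::sparseMatrix(i = ki, j = kj, x = kv, dims = c(n2, n2))
  else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n2, n2))
  list(f = f, Kc = Kc, active = active, gap = gap, force = force,
       hard_penetration = hard_pen,
       roller_force_y = roller_fy)
}
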