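## Independent element-stiffness oracle: quadratic Lagrange shape functions
## recovered from a Vandermonde solve against the monomial basis
## {1, x, e, x^2, x*e, e^2} on the reference triangle, integrated with a
## dense midpoint rule over a fine sub-triangulation.  Shares no code with
## the production assembly.
oracle_t6_stiffness <- function(xy, D) {
  ref <- rbind(c(0, 0), c(1, 0), c(0, 1),
               c(0.5, 0), c(0.5, 0.5), c(0, 0.5))
  mono <- function(p) c(1, p[1], p[2], p[1]^2, p[1] * p[2], p[2]^2)
  V <- t(apply(ref, 1, mono))
  C <- solve(V)                       # column j: coefficients of N_j
  dmono_dx <- function(p) c(0, 1, 0, 2 * p[1], p[2], 0)
  dmono_de <- function(p) c(0, 0, 1, 0, p[1], 2 * p[2])

  n <- 40L                            # fine sub-triangulation of the ref tri
  K <- matrix(0, 12, 12)
  h <- 1 / n
  for (i in seq_len(n)) for (j in seq_len(n - i + 1L)) {
    ## two sub-triangles per (i,j) cell; use their centroids, weight = area
    cells <- list(c((i - 1) * h + h / 3, (j - 1) * h + h / 3))
    if (j <= n - i) cells <- c(cells, list(c((i - 1) * h + 2 * h / 3,
                                             (j - 1) * h + 2 * h / 3)))
    for (p in cells) {
      dNdxi <- as.numeric(crossprod(C, dmono_dx(p)))
      dNdeta <- as.numeric(crossprod(C, dmono_de(p)))
      J <- rbind(c(sum(dNdxi * xy[, 1]), sum(dNdeta * xy[, 1])),
                 c(sum(dNdxi * xy[, 2]), sum(dNdeta * xy[, 2])))
      detJ <- det(J)
      g <- solve(t(J), rbind(dNdxi, dNdeta))   # rows: d/dx, d/dy
      B <- matrix(0, 3, 12)
      B[1, seq(1, 12, 2)] <- g[1, ]
      B[2, seq(2, 12, 2)] <- g[2, ]
      B[3, seq(1, 12, 2)] <- g[2, ]
      B[3, seq(2, 12, 2)] <- g[1, ]
      K <- K + t(B) %*% D %*% B * detJ * (h^2 / 2)
    }
  }
  K
}
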