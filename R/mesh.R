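## Structured, layer-conforming mesh generation.
##
## The phantom is a curved laminate: every tissue interface is either a
## vertical shift of the lordosis curve (inner layers, vertebral column) or a
## true normal offset of it (fat, skin, mat).  A mapped structured grid with
## rows on those interfaces therefore yields a conforming triangulation with
## exact region boundaries; cells are split into triangles and promoted to
## 6-node quadratic (T6) elements (midside nodes at edge midpoints).

## subdivide [a,b] into ceil((b-a)/target) >= 1 uniform pieces
subdiv <- function(a, b, target) {
  n <- max(1L, ceiling((b - a) / target - 1e-9))
  seq(a, b, length.out = n + 1L)
}

## split a structured grid of node indices (R rows x C cols) into CCW T3
## triangles; `nid` is an R x C matrix of node ids, rows ordered posterior ->
## anterior (increasing y)
grid_triangles <- function(nid) {
  R <- nrow(nid); C <- ncol(nid)
  i <- rep(seq_len(R - 1L), C - 1L)
  j <- rep(seq_len(C - 1L), each = R - 1L)
  n00 <- nid[cbind(i, j)]
  n01 <- nid[cbind(i, j + 1L)]
  n10 <- nid[cbind(i + 1L, j)]
  n11 <- nid[cbind(i + 1L, j + 1L)]
  ## diagonal n00-n11: triangles (n00, n01, n11) and (n00, n11, n10)
  rbind(cbind(n00, n01, n11), cbind(n00, n11, n10))
}

tri_signed_area <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

## promote a T3 mesh to T6: unique midside node per edge
## returns list(nodes, tri6) with tri6 columns 1:3 corners, 4 = mid(1,2),
## 5 = mid(2,3), 6 = mid(3,1)
t3_to_t6 <- function(nodes, tri) {
  m <- nrow(tri)
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key_a <- pmin(e[, 1], e[, 2])
  key_b <- pmax(e[, 1], e[, 2])
  key <- paste(key_a, key_b)
  uk <- !duplicated(key)
  edge_id <- match(key, key[uk])
  ua <- key_a[uk]; ub <- key_b[uk]
  mid <- (nodes[ua, , drop = FALSE] + nodes[ub, , drop = FALSE]) / 2
  n0 <- nrow(nodes)
  tri6 <- cbind(tri,
                n0 + edge_id[seq_len(m)],
                n0 + edge_id[m + seq_len(m)],
                n0 + edge_id[2 * m + seq_len(m)])
  list(nodes = rbind(nodes, mid), tri6 = tri6,
       edge_mid = cbind(ua, ub, n0 + seq_len(sum(uk))))
}

## ordered boundary node chain for a structured grid row, at T6 resolution
## (corner and midside nodes interleaved); `row_ids` are the corner node ids
## in column order, `edge_mid` maps corner pairs to midside ids
row_chain <- function(row_ids, edge_mid) {
  key <- paste(pmin(edge_mid[, 1], edge_mid[, 2]),
               pmax(edge_mid[, 1], edge_mid[, 2]))
  a <- row_ids[-length(row_ids)]
  b <- row_ids[-1]
  mids <- edge_mid[match(paste(pmin(a, b), pmax(a, b)), key), 3]
  out <- integer(2 * length(a) + 1L)
  out[seq(1, length(out), by = 2)] <- row_ids
  out[seq(2, length(out) - 1, by = 2)] <- mids
  out
}

new_labeled_mesh <- function(nodes, tri6, region_id, labels, boundary,
                             target_edge) {
  region_nodes <- lapply(split(seq_len(nrow(tri6)), region_id), function(el)
    sort(unique(as.vector(tri6[el, , drop = FALSE]))))
  structure(list(nodes = nodes, tri = tri6,
                 region_id = as.integer(region_id),
                 labels = labels, boundary = boundary,
                 region_nodes = region_nodes,
                 target_edge = target_edge),
            class = "labeled_mesh")
}

#' Mesh a phantom geometry into labeled quadratic triangles
#'
#' Generates a conforming mesh of the phantom cross-section (body plus bed
#' mat as two disconnected components) with 6-node quadratic triangles and a
#' region label per element.  Grid rows follow the tissue interfaces exactly;
#' columns follow the vertebra/disc segmentation, so region boundaries are
#' resolved exactly and interfaces share nodes.
#'
#' @param geometry a `phantom_geometry` from [build_phantom()].
#' @param target_edge_mm target element edge length; defaults to the value in
#'   the phantom spec.
#' @return A `labeled_mesh`: `nodes` (N x 2, mm), `tri` (M x 6 connectivity),
#'   `region_id` (M), `labels` (region table), `boundary` (named ordered node
#'   chains: `posterior_skin`, `anterior`, `mat_top`, `mat_bottom`,
#'   `end_cranial`, `end_caudal`, `mat_ends`), and `region_nodes`.
#' @export
mesh_geometry <- function(geometry, target_edge_mm = NULL) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  spec <- geometry$spec
  if (is.null(target_edge_mm)) target_edge_mm <- spec$mesh_target_edge_mm
  h <- target_edge_mm
  lord <- geometry$lord

  ## column grid: x-breakpoints at all column segment boundaries
  segs <- geometry$column_segments
  brk <- sort(unique(c(0, segs$x0, segs$x1, spec$body_length_mm)))
  xs <- unique(unlist(lapply(seq_len(length(brk) - 1L), function(i)
    subdiv(brk[i], brk[i + 1L], h))))
  xs <- sort(xs)
  C <- length(xs)

  ## body rows: posterior offsets (skin, fat; d decreasing to 0) then the
  ## inner laminate (z increasing from 0)
  d_skin <- rev(subdiv(geometry$bands$skin[1], geometry$bands$skin[2], h))
  d_fat <- rev(subdiv(geometry$bands$fat[1], geometry$bands$fat[2], h))
  d_rows <- c(d_skin, d_fat[-1])              # d from fat+skin down to 0
  z_rows <- numeric(0)
  row_layer <- character(length(d_rows) - 1L)
  row_layer[seq_along(d_skin[-1])] <- "skin"
  row_layer[(length(d_skin)):(length(d_rows) - 1L)] <- "subcut_fat"
  z_prev <- 0
  layer_of_cell_row <- row_layer
  for (l in geometry$layers) {
    zz <- subdiv(l$z0, l$z1, h)
    z_rows <- c(z_rows, zz[-1])
    layer_of_cell_row <- c(layer_of_cell_row, rep(l$tissue, length(zz) - 1L))
  }

  ## body node grid
  n_off <- length(d_rows)
  n_z <- length(z_rows)
  R <- n_off + n_z
  nodes <- matrix(0, R * C, 2)
  for (i in seq_len(n_off))
    nodes[(i - 1) * C + seq_len(C), ] <- offset_point(xs, d_rows[i], lord)
  gx <- lord$g(xs)
  for (i in seq_len(n_z))
    nodes[(n_off + i - 1) * C + seq_len(C), ] <- cbind(xs, gx + z_rows[i])
  nid <- matrix(seq_len(R * C), nrow = R, ncol = C, byrow = TRUE)

  tri <- grid_triangles(nid)
  ## cell row index of each triangle (two triangles per cell, stacked blocks)
  ncell <- (R - 1L) * (C - 1L)
  cell_i <- rep(rep(seq_len(R - 1L), C - 1L), 2L)
  cell_j <- rep(rep(seq_len(C - 1L), each = R - 1L), 2L)

  ## region label per cell
  rt <- region_table(geometry)
  lab_of <- function(tissue_row, xmid) {
    if (tissue_row == "skin") return("SKIN")
    if (tissue_row == "subcut_fat") return("SUBCUT_FAT")
    if (tissue_row == "soft_tissue") return("SOFT_TISSUE")
    if (tissue_row == "anterior_soft") return("SOFT_TISSUE")
    if (tissue_row == "muscle") return("MUSCLE")
    if (tissue_row == "epidural_fat") return("EPIDURAL_FAT")
    if (tissue_row == "csf") return("CSF")
    if (tissue_row == "cord") return("CORD")
    if (tissue_row == "column") {
      k <- which(segs$x0 <= xmid & xmid < segs$x1 + 1e-9)[1]
      lab <- segs$label[k]
      if (lab == "soft_tissue") return("SOFT_TISSUE")
      return(lab)
    }
    stop("internal: unknown layer tissue '", tissue_row, "'")
  }
  xmid <- (xs[cell_j] + xs[cell_j + 1L]) / 2
  tissue_row <- layer_of_cell_row[cell_i]
  elem_label <- vapply(seq_along(tissue_row), function(k)
    lab_of(tissue_row[k], xmid[k]), character(1))

  ## mat grid (separate body)
  d_mat <- rev(subdiv(geometry$bands$mat[1], geometry$bands$mat[2], h))
  Rm <- length(d_mat)
  mnodes <- matrix(0, Rm * C, 2)
  for (i in seq_len(Rm))
    mnodes[(i - 1) * C + seq_len(C), ] <- offset_point(xs, d_mat[i], lord)
  mnid <- matrix(nrow(nodes) + seq_len(Rm * C), nrow = Rm, ncol = C,
                 byrow = TRUE)
  mtri <- grid_triangles(mnid)
  nodes <- rbind(nodes, mnodes)
  tri <- rbind(tri, mtri)
  elem_label <- c(elem_label, rep("MAT", nrow(mtri)))

  ## orientation fix then promote to T6
  sa <- tri_signed_area(nodes, tri)
  flip <- sa < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  if (any(abs(tri_signed_area(nodes, tri)) < 1e-12))
    stop("mesh_geometry: degenerate (zero-area) element produced; ",
         "geometry dump: ", paste(utils::capture.output(utils::str(spec)),
                                  collapse = " "), call. = FALSE)
  p6 <- t3_to_t6(nodes, tri)

  region_id <- rt$region_id[match(elem_label, rt$label)]
  if (anyNA(region_id))
    stop("internal: unlabeled elements (", paste(unique(
      elem_label[is.na(region_id)]), collapse = ", "), ")")

  boundary <- list(
    posterior_skin = row_chain(nid[1, ], p6$edge_mid),
    anterior = row_chain(nid[R, ], p6$edge_mid),
    mat_top = row_chain(mnid[Rm, ], p6$edge_mid),
    mat_bottom = row_chain(mnid[1, ], p6$edge_mid),
    end_cranial = row_chain(nid[, 1], p6$edge_mid),
    end_caudal = row_chain(nid[, C], p6$edge_mid),
    mat_ends = c(row_chain(mnid[, 1], p6$edge_mid),
                 row_chain(mnid[, C], p6$edge_mid))
  )

  new_labeled_mesh(p6$nodes, p6$tri6, region_id, rt, boundary, h)
}

#' Mesh a homogeneous rectangle (verification workhorse)
#'
#' Structured T6 mesh of the rectangle `[0, width] x [0, height]` with a
#' single region label, used by the analytic verification problems (patch
#' test, cantilever, indentation).  Custom grid lines allow local refinement.
#'
#' @param width,height rectangle dimensions (mm).
#' @param target_edge_mm target element edge (ignored where custom lines are
#'   given).
#' @param x_lines,y_lines optional explicit grid line coordinates.
#' @param label region label for all elements.
#' @return A `labeled_mesh` with boundary chains `bottom`, `top`, `left`,
#'   `right`.
#' @export
mesh_rectangle <- function(width, height, target_edge_mm,
                           x_lines = NULL, y_lines = NULL, label = "BLOCK") {
  xs <- if (is.null(x_lines)) subdiv(0, width, target_edge_mm) else sort(unique(x_lines))
  ys <- if (is.null(y_lines)) subdiv(0, height, target_edge_mm) else sort(unique(y_lines))
  C <- length(xs); R <- length(ys)
  nodes <- matrix(0, R * C, 2)
  for (i in seq_len(R)) nodes[(i - 1) * C + seq_len(C), ] <- cbind(xs, ys[i])
  nid <- matrix(seq_len(R * C), nrow = R, ncol = C, byrow = TRUE)
  tri <- grid_triangles(nid)
  sa <- tri_signed_area(nodes, tri)
  tri[sa < 0, ] <- tri[sa < 0, c(1, 3, 2)]
  p6 <- t3_to_t6(nodes, tri)
  labels <- data.frame(region_id = 1L, label = label, tissue = "block",
                       level = NA_character_, stringsAsFactors = FALSE)
  boundary <- list(
    bottom = row_chain(nid[1, ], p6$edge_mid),
    top = row_chain(nid[R, ], p6$edge_mid),
    left = row_chain(nid[, 1], p6$edge_mid),
    right = row_chain(nid[, C], p6$edge_mid)
  )
  new_labeled_mesh(p6$nodes, p6$tri6, rep(1L, nrow(p6$tri6)), labels,
                   boundary, target_edge_mm)
}

#' Element areas of a labeled mesh
#' @param mesh a `labeled_mesh`.
#' @return numeric vector of (positive) element areas, mm^2.
#' @export
element_areas <- function(mesh) {
  tri_signed_area(mesh$nodes, mesh$tri[, 1:3, drop = FALSE])
}

#' Per-region mesh areas
#' @param mesh a `labeled_mesh`.
#' @return named numeric vector of summed element areas by region label.
#' @export
mesh_region_areas <- function(mesh) {
  a <- tapply(element_areas(mesh), mesh$region_id, sum)
  out <- as.numeric(a)
  names(out) <- mesh$labels$label[match(as.integer(names(a)),
                                        mesh$labels$region_id)]
  out
}

## all unique element edge lengths (corner-to-corner at T3 level)
mesh_edge_lengths <- function(mesh) {
  tri <- mesh$tri
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(key), , drop = FALSE]
  sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                  mesh$nodes[e[, 2], , drop = FALSE])^2))
}

#' Validate LabeledMesh invariants
#'
#' Checks positive element areas, conformity by construction (shared nodes on
#' interfaces), the presence and node-count of the six disc ROIs, and edge
#' lengths within `[0.2, 3]` times the target edge.
#'
#' @param mesh a `labeled_mesh`.
#' @param min_disc_nodes minimum nodes per disc ROI (default 50).
#' @return invisibly TRUE; stops with a message on violation.
#' @export
check_mesh <- function(mesh, min_disc_nodes = 50L) {
  a <- element_areas(mesh)
  if (any(a <= 0)) stop("mesh check: ", sum(a <= 0),
                        " non-positive element areas", call. = FALSE)
  disc_ids <- mesh$labels$region_id[startsWith(mesh$labels$label, "DISC:")]
  if (length(disc_ids)) {
    if (length(disc_ids) != 6L)
      stop("mesh check: expected 6 disc regions, found ", length(disc_ids),
           call. = FALSE)
    cnt <- vapply(as.character(disc_ids), function(id)
      length(mesh$region_nodes[[id]]), integer(1))
    if (any(cnt < min_disc_nodes))
      stop("mesh check: disc ROI below ", min_disc_nodes, " nodes (",
           paste(cnt, collapse = ","), ")", call. = FALSE)
  }
  len <- mesh_edge_lengths(mesh)
  if (any(len < 0.2 * mesh$target_edge - 1e-9) ||
      any(len > 3 * mesh$target_edge + 1e-9))
    stop("mesh check: edge lengths outside [0.2, 3] x target (range ",
         signif(min(len), 3), "..", signif(max(len), 3), " mm)", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("Labeled T6 mesh: %d nodes, %d elements, %d regions (target edge %.2g mm)\n",
              nrow(x$nodes), nrow(x$tri), length(unique(x$region_id)),
              x$target_edge))
  invisible(x)
}

#' Node indices of a disc region
#' @param mesh a `labeled_mesh`.
#' @param disc_level disc name, e.g. `"L2-L3"`.
#' @return integer node indices of the disc ROI.
#' @export
disc_nodes <- function(mesh, disc_level) {
  lab <- paste0("DISC:", disc_level)
  id <- mesh$labels$region_id[mesh$labels$label == lab]
  if (!length(id)) stop("no disc region '", disc_level, "' in mesh",
                        call. = FALSE)
  mesh$region_nodes[[as.character(id)]]
}
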