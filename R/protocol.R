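#' Traction protocol of the roller actuator
#'
#' Describes the posteroanterior traction kinematics of the massage-bed
#' actuator: the vertical travel is divided into `n_levels = 9` traction
#' levels (TL) with a full range of 62 mm at TL9, i.e. exactly 62/9 = 6.889 mm
#' per level.  Two active semi-cylindrical front rollers of radius
#' `roller_radius_mm` are centered under the L2--L4 vertebral span; at rest
#' their apex sits `initial_clearance_mm` below the mat underside.  The
#' default clearance of `4 * 62/9` mm (about 27.6 mm) makes the roller--mat--
#' skin chain engage between TL4 and TL5, so that disc stresses are zero for
#' TL4 and below and first become nonzero at TL5.
#'
#' @param n_levels number of traction levels (9).
#' @param full_range_mm maximal vertical displacement at the top level (62).
#' @param roller_radius_mm roller radius (default 25).
#' @param roller_center_x craniocaudal roller centers (mm); `NULL` places the
#'   two front rollers at the quarter points of the L2--L4 span of the
#'   phantom when the scene is assembled.
#' @param initial_clearance_mm rest gap between roller apex and mat underside.
#' @return object of class `traction_protocol`.
#' @export
traction_protocol <- function(n_levels = 9L,
                              full_range_mm = 62,
                              roller_radius_mm = 25,
                              roller_center_x = NULL,
                              initial_clearance_mm = 4 * 62 / 9) {
  stopifnot(n_levels >= 1, full_range_mm > 0, roller_radius_mm > 0,
            initial_clearance_mm >= 0)
  structure(list(n_levels = as.integer(n_levels),
                 full_range_mm = full_range_mm,
                 roller_radius_mm = roller_radius_mm,
                 roller_center_x = roller_center_x,
                 initial_clearance_mm = initial_clearance_mm),
            class = "traction_protocol")
}

#' Vertical actuator displacement at a traction level
#'
#' The displacement schedule is affine in TL with uniform increments:
#' `tl * full_range / n_levels`, i.e. `tl * 62/9` mm by default, honouring
#' the 62 mm maximum at TL9 exactly (the per-level increment is then
#' approximately 6.9 mm).
#'
#' @param tl integer traction level, 0 to `n_levels`.
#' @param protocol a [traction_protocol()].
#' @return displacement in mm.
#' @export
#' @examples
#' tl_to_displacement(9)  # 62
#' tl_to_displacement(5)  # 34.44...
tl_to_displacement <- function(tl, protocol = traction_protocol()) {
  if (any(tl < 0 | tl > protocol$n_levels) || any(tl != round(tl)))
    stop("traction level must be an integer in 0..", protocol$n_levels,
         call. = FALSE)
  tl * protocol$full_range_mm / protocol$n_levels
}

## default roller placement: quarter points of the L2..L4 vertebral span
default_roller_centers <- function(geometry) {
  segs <- geometry$column_segments
  x0 <- segs$x0[segs$label == "VERTEBRA:L2"]
  x1 <- segs$x1[segs$label == "VERTEBRA:L4"]
  span <- x1 - x0
  c(x0 + span / 4, x1 - span / 4)
}

## rigid roller state at a traction level: circle centers and radius.
## The rest position is calibrated against the sampled mat underside so that
## the roller surface (not just its apex: the flank can touch the curved mat
## first) makes first contact after exactly `initial_clearance_mm` of lift;
## centers then rise by tl * 62/9.
roller_state <- function(protocol, geometry, tl) {
  cx <- protocol$roller_center_x
  if (is.null(cx)) cx <- default_roller_centers(geometry)
  R <- protocol$roller_radius_mm
  d_bot <- geometry$bands$mat[2]
  L <- geometry$spec$body_length_mm
  cy0 <- vapply(cx, function(cxi) {
    xs <- seq(max(0, cxi - R - 10), min(L, cxi + R + 10), by = 0.25)
    P <- offset_point(xs, d_bot, geometry$lord)
    gapfun <- function(cy) min(sqrt((P[, 1] - cxi)^2 + (P[, 2] - cy)^2)) - R
    ylo <- min(P[, 2]) - R - 2 * protocol$full_range_mm
    yhi <- P[which.min(abs(P[, 1] - cxi)), 2]   # center on the curve: overlap
    touch <- stats::uniroot(gapfun, c(ylo, yhi), tol = 1e-10)$root
    touch - protocol$initial_clearance_mm
  }, numeric(1))
  list(cx = cx, cy = cy0 + tl_to_displacement(tl, protocol), R = R)
}

#' Rigid roller boundary curves at a traction level
#'
#' Returns the semi-circular (upper half) roller profiles, rigidly elevated
#' by the traction-level displacement relative to the rest position.
#'
#' @param protocol a [traction_protocol()].
#' @param geometry a `phantom_geometry` (fixes the mat underside elevation
#'   and default roller placement).
#' @param tl traction level.
#' @param n_arc points per arc.
#' @return list of matrices (one per roller) of xy points on the upper
#'   semi-circle, plus attributes `center` and `radius`.
#' @export
roller_profile <- function(protocol, geometry, tl, n_arc = 61) {
  st <- roller_state(protocol, geometry, tl)
  th <- seq(0, pi, length.out = n_arc)
  out <- lapply(seq_along(st$cx), function(i)
    cbind(st$cx[i] + st$R * cos(th), st$cy[i] + st$R * sin(th)))
  attr(out, "center") <- cbind(st$cx, st$cy)
  attr(out, "radius") <- st$R
  out
}

#' First traction level with actuator-to-back contact
#'
#' Computes the smallest traction level at which the roller--mat--skin chain
#' can transmit force: the roller apex must clear both the rest clearance to
#' the mat underside and the mat-to-skin clearance.  With the default
#' calibration (clearance of four level increments) this is TL5, matching the
#' observed near-zero disc response at TL4 and below.
#'
#' @param protocol a [traction_protocol()].
#' @param geometry a `phantom_geometry`.
#' @return integer traction level, or `NA` (sentinel "none") when no contact
#'   occurs within the protocol range.
#' @export
contact_onset_level <- function(protocol, geometry) {
  dead_travel <- protocol$initial_clearance_mm +
    geometry$spec$mat_clearance_mm
  inc <- protocol$full_range_mm / protocol$n_levels
  tl <- ceiling(dead_travel / inc - 1e-12)
  if (tl_to_displacement(min(tl, protocol$n_levels), protocol) <=
      dead_travel + 1e-12)
    tl <- tl + 1
  if (tl > protocol$n_levels) return(NA_integer_)
  as.integer(max(tl, 1L))
}

#' @export
print.traction_protocol <- function(x, ...) {
  cat(sprintf(
    "Traction protocol: %d levels, %.0f mm full range (%.3f mm/level), roller R = %.0f mm, rest clearance %.2f mm\n",
    x$n_levels, x$full_range_mm, x$full_range_mm / x$n_levels,
    x$roller_radius_mm, x$initial_clearance_mm))
  invisible(x)
}
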