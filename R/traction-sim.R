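#' Simulate posteroanterior lumbar traction on a BMI phantom
#'
#' High-level entry point: builds the phantom for a BMI class, meshes it,
#' assembles the actuator scene and runs the incremental contact solve up to
#' the requested traction level.  Returns a classed object with `print`,
#' `summary` and `plot` methods.
#'
#' @param bmi_class one of [bmi_classes()] (fat thickness 13/26/52/86 mm).
#' @param tl target traction level (0-9; each level lifts the rollers by
#'   62/9 mm, contact begins between TL4 and TL5).
#' @param config a [default_config()]-style configuration; individual blocks
#'   (phantom dimensions, materials, protocol, solver) are taken from it.
#' @param progress print solver progress.
#' @return object of class `traction_sim` with components `solution`
#'   (the `traction_solution`), `mesh`, `geometry`, `protocol`, `config`,
#'   `bmi_class`, `disc_table` (per-level per-disc means).
#' @export
#' @examples
#' \donttest{
#' sim <- traction_sim("normal", tl = 9)
#' summary(sim)
#' }
traction_sim <- function(bmi_class = "normal", tl = 9L,
                         config = default_config(), progress = FALSE) {
  spec <- config_phantom_spec(config)
  spec$fat_mm <- bmi_class_fat_thickness(bmi_class)
  geom <- build_phantom(spec)
  mesh <- mesh_geometry(geom)
  prot <- config_protocol(config)
  mt <- config_materials(config)
  control <- config_control(config)
  if (progress) control$verbose <- TRUE
  bnd <- boundary_spec(mesh, config$solver$anterior_fraction)
  sol <- solve_traction(mesh, mt, prot, geom, boundary = bnd, tl = tl,
                        control = control)
  rows <- list()
  for (lv in seq_len(tl)) for (d in disc_level_names()) {
    rows[[length(rows) + 1L]] <- data.frame(
      bmi_class = bmi_class, traction_level = lv, disc = d,
      mean_stress_MPa = disc_average(sol, mesh, d, "von_mises_stress", lv),
      mean_strain = disc_average(sol, mesh, d, "equivalent_strain", lv),
      n_nodes = length(disc_nodes(mesh, d)), failed = FALSE)
  }
  disc_table <- do.call(rbind, rows)
  class(disc_table) <- c("disc_summary", "data.frame")
  structure(list(solution = sol, mesh = mesh, geometry = geom,
                 protocol = prot, materials = mt, config = config,
                 bmi_class = bmi_class, tl = tl, disc_table = disc_table),
            class = "traction_sim")
}

#' @export
print.traction_sim <- function(x, ...) {
  cat(sprintf("PA traction simulation: %s phantom (fat %.0f mm), TL%d (%.1f mm lift)\n",
              x$bmi_class, x$geometry$spec$fat_mm, x$tl,
              tl_to_displacement(x$tl, x$protocol)))
  cat(sprintf("  mesh: %d nodes, %d T6 elements; contact onset at TL%d\n",
              nrow(x$mesh$nodes), nrow(x$mesh$tri),
              contact_onset_level(x$protocol, x$geometry)))
  if (x$tl >= 1) {
    lv <- x$solution$levels[[x$tl]]
    cat(sprintf("  final level: roller force %.1f N/mm, %d active contact nodes, max penalty penetration %.2g mm\n",
                lv$roller_force_y, lv$n_active, lv$max_penetration))
  }
  invisible(x)
}

#' @param object a `traction_sim`.
#' @param level traction level to summarise (default: the solved level).
#' @param ... unused.
#' @rdname traction_sim
#' @export
summary.traction_sim <- function(object, level = object$tl, ...) {
  d <- object$disc_table
  d <- d[d$traction_level == level, , drop = FALSE]
  out <- list(bmi_class = object$bmi_class, level = level,
              displacement_mm = tl_to_displacement(level, object$protocol),
              disc_table = d,
              safety = safety_check(object$disc_table))
  class(out) <- "summary.traction_sim"
  out
}

#' @export
print.summary.traction_sim <- function(x, ...) {
  cat(sprintf("Per-disc means, %s phantom at TL%d (%.1f mm):\n",
              x$bmi_class, x$level, x$displacement_mm))
  d <- x$disc_table
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-7s  von Mises %.4f MPa   strain %.5f\n",
                d$disc[i], d$mean_stress_MPa[i], d$mean_strain[i]))
  print(x$safety)
  invisible(x)
}

#' Plot a traction simulation
#'
#' Draws the deformed phantom cross-section (element edges) coloured by
#' nodal von Mises stress, with the roller positions overlaid.
#'
#' @param x a `traction_sim`.
#' @param level traction level to draw.
#' @param quantity `"von_mises"` or `"eq_strain"`.
#' @param ... passed to `plot.default`.
#' @export
plot.traction_sim <- function(x, level = x$tl,
                              quantity = c("von_mises", "eq_strain"), ...) {
  quantity <- match.arg(quantity)
  f <- recover_fields(x$solution, level)
  v <- if (quantity == "von_mises") f$von_mises else f$eq_strain
  u <- matrix(x$solution$levels[[level]]$u, ncol = 2, byrow = TRUE)
  nd <- x$mesh$nodes + u
  tri <- x$mesh$tri[, 1:3, drop = FALSE]
  vc <- (v[tri[, 1]] + v[tri[, 2]] + v[tri[, 3]]) / 3
  pal <- grDevices::hcl.colors(64, "viridis")
  col <- pal[pmin(64L, pmax(1L, floor(63 * vc / max(vc, 1e-12)) + 1L))]
  graphics::plot(NA, xlim = range(nd[, 1]), ylim = range(nd[, 2]),
                 asp = 1, xlab = "craniocaudal x (mm)",
                 ylab = "posteroanterior y (mm)",
                 main = sprintf("%s phantom, TL%d: %s", x$bmi_class, level,
                                quantity), ...)
  graphics::polygon(
    x = as.vector(t(cbind(nd[tri[, 1], 1], nd[tri[, 2], 1],
                          nd[tri[, 3], 1], NA))),
    y = as.vector(t(cbind(nd[tri[, 1], 2], nd[tri[, 2], 2],
                          nd[tri[, 3], 2], NA))),
    col = col, border = NA)
  rp <- roller_profile(x$protocol, x$geometry, level)
  for (arc in rp) graphics::lines(arc, lwd = 2, col = "red3")
  invisible(x)
}

#' Aggregated shielding and safety report for a sweep
#'
#' Percent reductions of each BMI class relative to the reference class
#' (default aggregation: all six discs over the post-onset levels present),
#' the disc ordering at the highest level, and the safety check.
#'
#' @param summary a `disc_summary`.
#' @param reference_class the reference BMI class (default `"normal"`).
#' @param thresholds a [safety_thresholds()] list.
#' @return list of class `comparison_report`.
#' @export
comparison_report <- function(summary, reference_class = "normal",
                              thresholds = safety_thresholds()) {
  classes <- unique(summary$bmi_class)
  others <- setdiff(classes, reference_class)
  red_s <- vapply(others, function(cl)
    percent_reduction(summary, reference_class, cl, "stress"), numeric(1))
  red_e <- vapply(others, function(cl)
    percent_reduction(summary, reference_class, cl, "strain"), numeric(1))
  tl_max <- max(summary$traction_level)
  ord <- lapply(stats::setNames(classes, classes), function(cl)
    disc_ordering(summary, cl, tl_max))
  structure(list(reference_class = reference_class,
                 stress_reduction_pct = red_s,
                 strain_reduction_pct = red_e,
                 ordering_at_top_level = ord,
                 top_level = tl_max,
                 safety = safety_check(summary, thresholds)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Load shielding vs", x$reference_class, "phantom (mean over discs and levels):\n")
  for (cl in names(x$stress_reduction_pct))
    cat(sprintf("  %-15s stress -%.1f%%   strain -%.1f%%\n", cl,
                x$stress_reduction_pct[[cl]], x$strain_reduction_pct[[cl]]))
  cat(sprintf("Disc ranking at TL%d (%s): %s\n", x$top_level,
              x$reference_class,
              paste(x$ordering_at_top_level[[x$reference_class]],
                    collapse = " > ")))
  print(x$safety)
  invisible(x)
}
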