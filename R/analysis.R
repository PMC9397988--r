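#' Mean von Mises stress or equivalent strain over a disc ROI
#'
#' Arithmetic mean of the nodal quantity over the node set of one
#' intervertebral disc region.  Nodal values are recovered with
#' region-restricted averaging (only elements of that disc contribute), so
#' the stiff vertebral neighbours do not smear into the ROI.
#'
#' @param solution a `traction_solution`.
#' @param mesh the `labeled_mesh` of the solution.
#' @param disc_level disc name, e.g. `"L2-L3"`.
#' @param quantity `"von_mises_stress"` (MPa) or `"equivalent_strain"`.
#' @param level traction level (defaults to the solved level).
#' @return scalar mean over the disc ROI.
#' @export
disc_average <- function(solution, mesh = solution$mesh, disc_level,
                         quantity = c("von_mises_stress",
                                      "equivalent_strain"),
                         level = solution$tl) {
  quantity <- match.arg(quantity)
  nd <- disc_nodes(mesh, disc_level)
  if (!length(nd)) stop("empty disc ROI '", disc_level, "'", call. = FALSE)
  if (level == 0) return(0)
  f <- recover_fields(solution, level,
                      region_restrict = paste0("DISC:", disc_level))
  v <- if (quantity == "von_mises_stress") f$von_mises else f$eq_strain
  mean(v[nd])
}

#' Sweep BMI classes and traction levels
#'
#' Runs one incremental solve per BMI phantom up to the highest requested
#' traction level and harvests the per-disc stress/strain summaries at every
#' requested level (the incremental solver visits each level on the way up).
#'
#' @param bmi_classes character vector of BMI classes (see [bmi_classes()]).
#' @param traction_levels integer vector of levels to report.
#' @param config a [default_config()]-style configuration list.
#' @param progress print progress lines.
#' @return object of class `disc_summary`: data.frame with columns
#'   `bmi_class`, `traction_level`, `disc`, `mean_stress_MPa`, `mean_strain`,
#'   `n_nodes`, `failed`, plus attributes with solver metadata.
#' @export
run_sweep <- function(bmi_classes = c("normal", "overweight",
                                      "moderate_obese", "extreme_obese"),
                      traction_levels = 5:9,
                      config = default_config(),
                      progress = FALSE) {
  stopifnot(all(traction_levels >= 0))
  prot <- config_protocol(config)
  mt <- config_materials(config)
  control <- config_control(config)
  tl_max <- max(traction_levels)
  rows <- list()
  meta <- list()
  for (cl in bmi_classes) {
    if (progress) message("sweep: ", cl)
    spec <- config_phantom_spec(config)
    spec$fat_mm <- bmi_class_fat_thickness(cl)
    geom <- build_phantom(spec)
    mesh <- mesh_geometry(geom)
    sol <- NULL
    err <- tryCatch({
      sol <- solve_traction(mesh, mt, prot, geom, tl = tl_max,
                            control = control)
      NULL
    }, error = function(e) conditionMessage(e))
    for (tl in traction_levels) for (d in disc_level_names()) {
      nd <- disc_nodes(mesh, d)
      if (is.null(sol) || tl > sol$tl) {
        rows[[length(rows) + 1L]] <- data.frame(
          bmi_class = cl, traction_level = tl, disc = d,
          mean_stress_MPa = NA_real_, mean_strain = NA_real_,
          n_nodes = length(nd), failed = TRUE)
      } else {
        s <- if (tl == 0) 0 else
          disc_average(sol, mesh, d, "von_mises_stress", level = tl)
        e <- if (tl == 0) 0 else
          disc_average(sol, mesh, d, "equivalent_strain", level = tl)
        rows[[length(rows) + 1L]] <- data.frame(
          bmi_class = cl, traction_level = tl, disc = d,
          mean_stress_MPa = s, mean_strain = e,
          n_nodes = length(nd), failed = FALSE)
      }
    }
    meta[[cl]] <- list(error = err,
                       n_nodes = nrow(mesh$nodes), n_elem = nrow(mesh$tri))
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- meta
  attr(out, "config_hash") <- config_hash(config)
  class(out) <- c("disc_summary", "data.frame")
  out
}

#' Aggregated percent reduction of one BMI class versus a reference
#'
#' `100 * (1 - mean(other) / mean(reference))`, with the mean taken over all
#' six discs and the post-onset traction levels present in the summary (the
#' default aggregation; restrict via `traction_levels` / `discs`).  This is
#' the load-shielding measure: thicker subcutaneous fat attenuates the disc
#' stress produced by the same actuator displacement.
#'
#' @param summary a `disc_summary` (from [run_sweep()] or
#'   [reference_disc_summary()]).
#' @param reference_class,other_class BMI class names.
#' @param quantity `"stress"` or `"strain"`.
#' @param traction_levels levels included in the aggregation (default: all in
#'   the summary).
#' @param discs discs included (default: all six).
#' @return percent reduction (positive when `other_class` is shielded).
#' @export
percent_reduction <- function(summary, reference_class, other_class,
                              quantity = c("stress", "strain"),
                              traction_levels = NULL, discs = NULL) {
  quantity <- match.arg(quantity)
  col <- if (quantity == "stress") "mean_stress_MPa" else "mean_strain"
  sel <- function(cl) {
    d <- summary[summary$bmi_class == cl, , drop = FALSE]
    if (!nrow(d)) stop("class '", cl, "' not present in summary",
                       call. = FALSE)
    if (!is.null(traction_levels))
      d <- d[d$traction_level %in% traction_levels, , drop = FALSE]
    if (!is.null(discs)) d <- d[d$disc %in% discs, , drop = FALSE]
    d[[col]]
  }
  mref <- mean(sel(reference_class), na.rm = TRUE)
  moth <- mean(sel(other_class), na.rm = TRUE)
  if (!is.finite(mref) || mref == 0)
    stop("reference mean is zero or undefined; cannot form a reduction",
         call. = FALSE)
  100 * (1 - moth / mref)
}

#' Rank discs by mean stress at one (BMI class, traction level)
#'
#' @param summary a `disc_summary`.
#' @param bmi_class,tl the cell to rank.
#' @param quantity `"stress"` or `"strain"`.
#' @return character vector of disc names, highest first; ties broken in
#'   anatomical (cranial-first) order.
#' @export
disc_ordering <- function(summary, bmi_class, tl,
                          quantity = c("stress", "strain")) {
  quantity <- match.arg(quantity)
  col <- if (quantity == "stress") "mean_stress_MPa" else "mean_strain"
  d <- summary[summary$bmi_class == bmi_class &
                 summary$traction_level == tl, , drop = FALSE]
  if (!nrow(d)) stop("no entries for (", bmi_class, ", TL", tl, ")",
                     call. = FALSE)
  anat <- match(d$disc, disc_level_names())
  d <- d[order(-d[[col]], anat), ]
  d$disc
}

#' Check disc summaries against damage thresholds
#'
#' Flags every (BMI class, traction level, disc) entry whose mean stress
#' exceeds the ultimate stress (2.94 MPa) or whose mean strain exceeds the
#' ultimate tensile strain (21.3 %), and reports the global maxima and safety
#' margins.
#'
#' @param summary a `disc_summary`.
#' @param thresholds a [safety_thresholds()] list.
#' @return list of class `safety_report`: `pass`, `flagged` (data.frame),
#'   `max_stress_MPa`, `max_strain`, `stress_margin_MPa`, `strain_margin`.
#' @export
safety_check <- function(summary, thresholds = safety_thresholds()) {
  s_lim <- thresholds$ultimate_stress_MPa
  e_lim <- thresholds$ultimate_strain_pct / 100
  bad <- summary[!is.na(summary$mean_stress_MPa) &
                   (summary$mean_stress_MPa > s_lim |
                      summary$mean_strain > e_lim), , drop = FALSE]
  ms <- max(summary$mean_stress_MPa, na.rm = TRUE)
  me <- max(summary$mean_strain, na.rm = TRUE)
  structure(list(pass = nrow(bad) == 0L, flagged = bad,
                 max_stress_MPa = ms, max_strain = me,
                 stress_margin_MPa = s_lim - ms,
                 strain_margin = e_lim - me,
                 thresholds = thresholds),
            class = "safety_report")
}

#' @export
print.safety_report <- function(x, ...) {
  cat(sprintf("Safety check vs ultimate stress %.2f MPa / strain %.1f%%: %s\n",
              x$thresholds$ultimate_stress_MPa,
              x$thresholds$ultimate_strain_pct,
              if (x$pass) "all entries below thresholds" else
                paste(nrow(x$flagged), "entries flagged")))
  cat(sprintf("  max stress %.4g MPa (margin %.4g), max strain %.4g (margin %.4g)\n",
              x$max_stress_MPa, x$stress_margin_MPa, x$max_strain,
              x$strain_margin))
  invisible(x)
}

#' Reference disc summaries from the full-scale 3D study
#'
#' Mean lumbar-disc von Mises stresses (MPa) and strains reported by a
#' subject-specific 3D simulation of the same traction device (four BMI
#' models, traction levels 5/7/9), shipped as packaged CSV fixtures.  Used to
#' validate the analysis arithmetic (ordering, percent reduction, safety
#' checks) independently of this package's solver.
#'
#' @return a `disc_summary` data.frame with the same columns as
#'   [run_sweep()] output.
#' @export
reference_disc_summary <- function() {
  f_s <- system.file("extdata", "reference_disc_stress.csv",
                     package = "patraction", mustWork = TRUE)
  f_e <- system.file("extdata", "reference_disc_strain.csv",
                     package = "patraction", mustWork = TRUE)
  s <- utils::read.csv(f_s, stringsAsFactors = FALSE)
  e <- utils::read.csv(f_e, stringsAsFactors = FALSE)
  long <- function(d, val) {
    out <- do.call(rbind, lapply(disc_level_names(), function(dn) {
      col <- gsub("-", ".", dn)
      data.frame(bmi_class = d$bmi_class, traction_level = d$traction_level,
                 disc = dn, value = d[[col]], stringsAsFactors = FALSE)
    }))
    names(out)[4] <- val
    out
  }
  m <- merge(long(s, "mean_stress_MPa"), long(e, "mean_strain"),
             by = c("bmi_class", "traction_level", "disc"))
  m$n_nodes <- 20000L
  m$failed <- FALSE
  m <- m[order(match(m$bmi_class, bmi_classes()), m$traction_level,
               match(m$disc, disc_level_names())), ]
  rownames(m) <- NULL
  class(m) <- c("disc_summary", "data.frame")
  m
}

#' @export
print.disc_summary <- function(x, ...) {
  cat("Disc summary:", length(unique(x$bmi_class)), "BMI class(es) x",
      length(unique(x$traction_level)), "traction level(s) x",
      length(unique(x$disc)), "discs\n")
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("  ...", nrow(x) - 12, "more rows\n")
  invisible(x)
}

#' Plot disc stress (or strain) against traction level
#'
#' One curve per disc, one panel per BMI class — the standard way of reading
#' the sweep output: stresses stay near zero up to the contact-onset level
#' and then grow nonlinearly, with thicker fat shielding the discs.
#'
#' @param x a `disc_summary`.
#' @param quantity `"stress"` or `"strain"`.
#' @param ... passed to `matplot`.
#' @export
plot.disc_summary <- function(x, quantity = c("stress", "strain"), ...) {
  quantity <- match.arg(quantity)
  col <- if (quantity == "stress") "mean_stress_MPa" else "mean_strain"
  classes <- unique(x$bmi_class)
  op <- graphics::par(mfrow = c(1, length(classes)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cl in classes) {
    d <- x[x$bmi_class == cl, ]
    tls <- sort(unique(d$traction_level))
    mat <- sapply(disc_level_names(), function(dn)
      d[[col]][d$disc == dn][order(d$traction_level[d$disc == dn])])
    graphics::matplot(tls, mat, type = "b", pch = 1:6, lty = 1,
                      xlab = "traction level",
                      ylab = if (quantity == "stress")
                        "mean von Mises stress (MPa)" else "mean strain",
                      main = cl, ...)
    graphics::legend("topleft", disc_level_names(), pch = 1:6, lty = 1,
                     col = 1:6, cex = 0.6, bty = "n")
  }
  invisible(x)
}
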