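#' Parametric specification of the synthetic mid-sagittal lumbar phantom
#'
#' Defines the geometry of a layered, lordotic mid-sagittal cross-section of
#' the lower torso used as a stand-in for subject-specific imaging: nine
#' tissue classes (skin, subcutaneous fat, soft tissue, muscle, intervertebral
#' disc, vertebrae, epidural fat, CSF, spinal cord) plus the deformable bed
#' mat.  The craniocaudal axis is x (mm, head at x = 0), the posteroanterior
#' axis is y (mm, increasing anteriorly); the posterior skin is the y-minimum
#' surface facing the actuator rollers.  All lengths are in mm (consistent
#' mm--MPa--N unit system).
#'
#' The subcutaneous fat thickness encodes the BMI class: 13 mm (normal),
#' 26 mm (overweight), 52 mm (moderate obese), 86 mm (extreme obese); see
#' [bmi_class_fat_thickness()].  Lumbar lordosis is a smooth (sine-squared)
#' anterior bump of depth `lordosis_depth_mm` over `lordosis_span_mm`.
#' Vertebra/disc dimensions default to textbook adult lumbar anatomy
#' (vertebral body 30 mm high x 35 mm deep, disc 10 mm).
#'
#' @param body_length_mm craniocaudal extent of the modeled torso segment.
#' @param skin_mm skin thickness (default 1 mm).
#' @param fat_mm subcutaneous fat thickness; 13/26/52/86 mm for the four BMI
#'   classes.
#' @param soft_tissue_mm posterior soft-tissue layer between fat and muscle.
#' @param muscle_mm paraspinal muscle layer thickness.
#' @param epidural_fat_mm,csf_mm,cord_mm thin strips between muscle and the
#'   vertebral column (posterior epidural fat, cerebrospinal fluid, spinal
#'   cord/dura); set to 0 to disable a strip.
#' @param vertebra_height_mm craniocaudal height of each vertebral body.
#' @param vertebra_depth_mm posteroanterior depth of the vertebral column.
#' @param disc_height_mm craniocaudal height of each intervertebral disc.
#' @param anterior_soft_mm anterior soft-tissue layer in front of the column
#'   (its anterior face carries the fixed-end boundary condition).
#' @param lordosis_depth_mm,lordosis_span_mm depth and craniocaudal span of
#'   the lordotic curve (anterior-convex lumbar curvature).
#' @param mat_thickness_mm thickness of the bed mat strip.
#' @param mat_clearance_mm resting clearance between mat top and skin.
#' @param mesh_target_edge_mm default target element edge for meshing.
#' @param rng_seed integer seed stored with the parameters (construction is
#'   fully deterministic; the seed is kept for provenance of derived runs).
#' @return An object of class `phantom_spec`.
#' @seealso [build_phantom()], [dilate_fat()], [mesh_geometry()]
#' @export
phantom_spec <- function(body_length_mm = 300,
                         skin_mm = 1,
                         fat_mm = 13,
                         soft_tissue_mm = 15,
                         muscle_mm = 30,
                         epidural_fat_mm = 5,
                         csf_mm = 3,
                         cord_mm = 8,
                         vertebra_height_mm = 30,
                         vertebra_depth_mm = 35,
                         disc_height_mm = 10,
                         anterior_soft_mm = 15,
                         lordosis_depth_mm = 25,
                         lordosis_span_mm = 250,
                         mat_thickness_mm = 10,
                         mat_clearance_mm = 0.1,
                         mesh_target_edge_mm = 5,
                         rng_seed = 1L) {
  spec <- list(
    body_length_mm = body_length_mm,
    skin_mm = skin_mm,
    fat_mm = fat_mm,
    soft_tissue_mm = soft_tissue_mm,
    muscle_mm = muscle_mm,
    epidural_fat_mm = epidural_fat_mm,
    csf_mm = csf_mm,
    cord_mm = cord_mm,
    vertebra_height_mm = vertebra_height_mm,
    vertebra_depth_mm = vertebra_depth_mm,
    disc_height_mm = disc_height_mm,
    anterior_soft_mm = anterior_soft_mm,
    lordosis_depth_mm = lordosis_depth_mm,
    lordosis_span_mm = lordosis_span_mm,
    mat_thickness_mm = mat_thickness_mm,
    mat_clearance_mm = mat_clearance_mm,
    mesh_target_edge_mm = mesh_target_edge_mm,
    rng_seed = as.integer(rng_seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  required_pos <- c("body_length_mm", "skin_mm", "fat_mm", "soft_tissue_mm",
                    "muscle_mm", "vertebra_height_mm", "vertebra_depth_mm",
                    "disc_height_mm", "anterior_soft_mm", "mat_thickness_mm",
                    "mesh_target_edge_mm")
  for (f in required_pos) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("phantom_spec: '", f, "' must be a single positive number (got ",
           deparse(spec[[f]]), ")", call. = FALSE)
  }
  for (f in c("epidural_fat_mm", "csf_mm", "cord_mm", "lordosis_depth_mm",
              "mat_clearance_mm")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("phantom_spec: '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (spec$lordosis_span_mm <= 0 || spec$lordosis_span_mm > spec$body_length_mm)
    stop("phantom_spec: 'lordosis_span_mm' must lie in (0, body_length_mm]",
         call. = FALSE)
  col_len <- 7 * spec$vertebra_height_mm + 6 * spec$disc_height_mm
  if (col_len > spec$body_length_mm)
    stop("phantom_spec: vertebral column (", col_len,
         " mm: 7 vertebrae T12..S plus 6 discs) exceeds 'body_length_mm' (",
         spec$body_length_mm, " mm)", call. = FALSE)
  invisible(spec)
}

#' Subcutaneous fat thickness for a BMI class
#'
#' Maps the four BMI classes onto the posterior subcutaneous fat thickness of
#' the corresponding phantom: normal 13 mm, overweight 26 mm, moderate obese
#' 52 mm, extreme (severe) obese 86 mm.
#'
#' @param class_name one of `"normal"`, `"overweight"`, `"moderate_obese"`,
#'   `"extreme_obese"` (`"severe_obese"` is accepted as an alias for the
#'   latter).
#' @return Fat thickness in mm.
#' @export
#' @examples
#' bmi_class_fat_thickness("normal")       # 13
#' bmi_class_fat_thickness("extreme_obese") # 86
bmi_class_fat_thickness <- function(class_name) {
  tab <- c(normal = 13, overweight = 26, moderate_obese = 52,
           extreme_obese = 86, severe_obese = 86)
  if (length(class_name) != 1L || !class_name %in% names(tab))
    stop("unknown BMI class '", paste(class_name, collapse = ","),
         "'; valid classes: normal, overweight, moderate_obese, extreme_obese",
         call. = FALSE)
  unname(tab[[class_name]])
}

#' Names of the BMI classes, disc levels and vertebral levels
#' @return character vector of names.
#' @export
bmi_classes <- function() c("normal", "overweight", "moderate_obese",
                            "extreme_obese")

#' @rdname bmi_classes
#' @export
disc_level_names <- function() {
  c("T12-L1", "L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S")
}

#' @rdname bmi_classes
#' @export
vertebra_level_names <- function() {
  c("T12", "L1", "L2", "L3", "L4", "L5", "S")
}

## lordosis curve g(x): smooth anterior bump, C^1 at the span edges
lordosis_fun <- function(spec) {
  d <- spec$lordosis_depth_mm
  s <- spec$lordosis_span_mm
  x0 <- (spec$body_length_mm - s) / 2
  list(
    g = function(x) {
      t <- (x - x0) / s
      out <- ifelse(t > 0 & t < 1, d * sin(pi * t)^2, 0)
      out
    },
    gp = function(x) {
      t <- (x - x0) / s
      ifelse(t > 0 & t < 1, d * (pi / s) * sin(2 * pi * t), 0)
    },
    gpp = function(x) {
      t <- (x - x0) / s
      ifelse(t > 0 & t < 1, 2 * d * (pi / s)^2 * cos(2 * pi * t), 0)
    }
  )
}

## point on the outward (posterior) normal offset of the base curve
## B(x) = (x, g(x)); offset distance d >= 0 moves posteriorly (toward -y)
offset_point <- function(x, d, lord) {
  gp <- lord$gp(x)
  s <- sqrt(1 + gp^2)
  cbind(x + d * gp / s, lord$g(x) - d / s)
}

## minimal concave-side curvature radius of the base curve (self-intersection
## guard for posterior offsets); returns +Inf for a straight spine
min_offset_radius <- function(spec, n = 2001) {
  lord <- lordosis_fun(spec)
  x <- seq(0, spec$body_length_mm, length.out = n)
  gpp <- lord$gpp(x)
  conc <- gpp < 0   # concave toward -y: offset runs toward curvature center
  if (!any(conc)) return(list(radius = Inf, x = NA_real_))
  r <- (1 + lord$gp(x)[conc]^2)^1.5 / abs(gpp[conc])
  i <- which.min(r)
  list(radius = r[i], x = x[conc][i])
}

#' Build the synthetic lumbar phantom geometry
#'
#' Constructs the labeled planar region decomposition of the phantom: a
#' posterior band of skin and subcutaneous fat following the true normal
#' offset of the body surface, an inner laminate (posterior soft tissue,
#' muscle, epidural fat, CSF, cord), the vertebral column with seven
#' vertebrae (T12..S) alternating with six discs along the lordotic curve, an
#' anterior soft-tissue layer, and the bed mat strip resting
#' `mat_clearance_mm` below the skin.  Fat dilation for higher BMI classes
#' displaces only the fat and skin bands (see [dilate_fat()]); all interior
#' tissue is unaffected.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_geometry` holding the layer bands,
#'   column segmentation and lordosis curve; mesh it with [mesh_geometry()].
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  lord <- lordosis_fun(spec)

  ## guard: posterior offsets must stay inside the curvature radius
  d_max <- spec$fat_mm + spec$skin_mm + spec$mat_clearance_mm +
    spec$mat_thickness_mm
  rad <- min_offset_radius(spec)
  if (d_max >= rad$radius)
    stop("phantom geometry self-intersects: total posterior offset ", d_max,
         " mm exceeds the lordosis curvature radius ",
         signif(rad$radius, 4), " mm near x = ", signif(rad$x, 4),
         " mm; reduce 'lordosis_depth_mm' or fat/mat thicknesses",
         call. = FALSE)

  ## inner laminate, anterior (+z) from the base curve (posterior soft-tissue
  ## surface, z = 0); order inside-out is muscle -> soft tissue -> fat -> skin
  layers <- list()
  z <- 0
  add_layer <- function(layers, tissue, thick) {
    if (thick <= 0) return(layers)
    c(layers, list(list(tissue = tissue, z0 = z, z1 = z + thick)))
  }
  layers <- add_layer(layers, "soft_tissue", spec$soft_tissue_mm)
  z <- z + spec$soft_tissue_mm
  layers <- add_layer(layers, "muscle", spec$muscle_mm)
  z <- z + spec$muscle_mm
  layers <- add_layer(layers, "epidural_fat", spec$epidural_fat_mm)
  z <- z + spec$epidural_fat_mm
  layers <- add_layer(layers, "csf", spec$csf_mm)
  z <- z + spec$csf_mm
  layers <- add_layer(layers, "cord", spec$cord_mm)
  z <- z + spec$cord_mm
  column_z0 <- z
  layers <- add_layer(layers, "column", spec$vertebra_depth_mm)
  z <- z + spec$vertebra_depth_mm
  layers <- add_layer(layers, "anterior_soft", spec$anterior_soft_mm)
  z <- z + spec$anterior_soft_mm

  ## craniocaudal segmentation of the column band: 7 vertebrae / 6 discs,
  ## centered, margins filled with soft tissue
  col_len <- 7 * spec$vertebra_height_mm + 6 * spec$disc_height_mm
  margin <- (spec$body_length_mm - col_len) / 2
  vert <- vertebra_level_names()
  disc <- disc_level_names()
  segs <- data.frame(label = character(0), x0 = numeric(0), x1 = numeric(0),
                     stringsAsFactors = FALSE)
  xcur <- margin
  if (margin > 0)
    segs <- rbind(segs, data.frame(label = "soft_tissue", x0 = 0, x1 = margin))
  for (i in seq_len(7)) {
    segs <- rbind(segs, data.frame(label = paste0("VERTEBRA:", vert[i]),
                                   x0 = xcur, x1 = xcur + spec$vertebra_height_mm))
    xcur <- xcur + spec$vertebra_height_mm
    if (i <= 6) {
      segs <- rbind(segs, data.frame(label = paste0("DISC:", disc[i]),
                                     x0 = xcur, x1 = xcur + spec$disc_height_mm))
      xcur <- xcur + spec$disc_height_mm
    }
  }
  if (margin > 0)
    segs <- rbind(segs, data.frame(label = "soft_tissue", x0 = xcur,
                                   x1 = spec$body_length_mm))

  geom <- list(
    spec = spec,
    lord = lord,
    layers = layers,
    column_segments = segs,
    column_z = c(column_z0, column_z0 + spec$vertebra_depth_mm),
    z_anterior = z,
    ## posterior bands, by offset distance d >= 0 from the base curve
    bands = list(
      fat  = c(0, spec$fat_mm),
      skin = c(spec$fat_mm, spec$fat_mm + spec$skin_mm),
      mat  = spec$fat_mm + spec$skin_mm + spec$mat_clearance_mm +
        c(0, spec$mat_thickness_mm)
    )
  )
  class(geom) <- "phantom_geometry"
  geom
}

#' Dilate the subcutaneous fat of a phantom to a new thickness
#'
#' Reproduces, in the parametric setting, the image-based procedure of
#' merging fat with skin, dilating isometrically and recovering the skin
#' mask: the fat band is widened to `new_fat_mm` by offsetting the skin
#' normal to the original body surface, the skin retains its original
#' thickness, and every interior tissue (soft tissue inward) is exactly
#' unchanged.
#'
#' @param geometry a `phantom_geometry` from [build_phantom()].
#' @param new_fat_mm target fat thickness, at least the current thickness.
#' @return A new `phantom_geometry`.
#' @export
dilate_fat <- function(geometry, new_fat_mm) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  old <- geometry$spec$fat_mm
  if (new_fat_mm < old - 1e-12)
    stop("dilate_fat: new thickness (", new_fat_mm,
         " mm) is below the current fat thickness (", old, " mm); ",
         "fat can only be dilated outward", call. = FALSE)
  spec <- geometry$spec
  spec$fat_mm <- new_fat_mm
  build_phantom(spec)
}

#' Region inventory of a phantom geometry
#'
#' @param geometry a `phantom_geometry`.
#' @return data.frame with columns `region_id`, `label` (e.g. `"DISC:L2-L3"`),
#'   `tissue` (material key) and `level` (spinal level or NA).
#' @export
region_table <- function(geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  base <- data.frame(
    label = c("SKIN", "SUBCUT_FAT", "SOFT_TISSUE", "MUSCLE", "EPIDURAL_FAT",
              "CSF", "CORD", "MAT"),
    tissue = c("skin", "subcut_fat", "soft_tissue", "muscle", "epidural_fat",
               "csf", "cord", "mat"),
    level = NA_character_,
    stringsAsFactors = FALSE
  )
  keep <- c(TRUE, TRUE, TRUE, geometry$spec$muscle_mm > 0,
            geometry$spec$epidural_fat_mm > 0, geometry$spec$csf_mm > 0,
            geometry$spec$cord_mm > 0, TRUE)
  base <- base[keep, , drop = FALSE]
  vert <- data.frame(label = paste0("VERTEBRA:", vertebra_level_names()),
                     tissue = "vertebrae", level = vertebra_level_names(),
                     stringsAsFactors = FALSE)
  disc <- data.frame(label = paste0("DISC:", disc_level_names()),
                     tissue = "disc", level = disc_level_names(),
                     stringsAsFactors = FALSE)
  out <- rbind(base, vert, disc)
  out$region_id <- seq_len(nrow(out))
  out[, c("region_id", "label", "tissue", "level")]
}

## exact area of a region (independent of any mesh): offset-band regions via
## the parallel-curve area formula, laminate regions are exact rectangles in
## (x, z) because vertical shifts by g(x) preserve area
region_area_exact <- function(geometry, label, n = 4000) {
  spec <- geometry$spec
  lord <- geometry$lord
  L <- spec$body_length_mm
  band_area <- function(d0, d1) {
    ## area between offsets d0 < d1 of curve (x, g(x)):
    ## A = int (d1-d0) * (s - kappa*(d0+d1)/2 / s^2 ...) using exact jacobian:
    ## dA = (1 - kappa*d) ds dd with ds = sqrt(1+g'^2) dx,
    ## kappa = g'' / s^3 (signed; posterior offset flips sign)
    x <- seq(0, L, length.out = n + 1)
    s <- sqrt(1 + lord$gp(x)^2)
    kap <- lord$gpp(x) / s^3          # curvature of base curve
    ## posterior offset by d: local stretch factor (1 + kap*d) along the curve
    f <- function(d) s * (1 + kap * d)
    ## integrate over d analytically: int_{d0}^{d1} (1+kap d) dd
    integrand <- s * ((d1 - d0) + kap * (d1^2 - d0^2) / 2)
    sum((integrand[-1] + integrand[-(n + 1)]) / 2 * diff(x))
  }
  seg_area <- function(lab) {
    segs <- geometry$column_segments
    sel <- segs[segs$label == lab, , drop = FALSE]
    sum(sel$x1 - sel$x0) * spec$vertebra_depth_mm
  }
  lay <- function(tissue) {
    a <- 0
    for (l in geometry$layers)
      if (l$tissue == tissue) a <- a + (l$z1 - l$z0) * L
    a
  }
  if (label == "SKIN") return(band_area(geometry$bands$skin[1], geometry$bands$skin[2]))
  if (label == "SUBCUT_FAT") return(band_area(geometry$bands$fat[1], geometry$bands$fat[2]))
  if (label == "MAT") return(band_area(geometry$bands$mat[1], geometry$bands$mat[2]))
  if (label == "MUSCLE") return(lay("muscle"))
  if (label == "EPIDURAL_FAT") return(lay("epidural_fat"))
  if (label == "CSF") return(lay("csf"))
  if (label == "CORD") return(lay("cord"))
  if (label == "SOFT_TISSUE") {
    segs <- geometry$column_segments
    sel <- segs[segs$label == "soft_tissue", , drop = FALSE]
    return(lay("soft_tissue") + lay("anterior_soft") +
             sum(sel$x1 - sel$x0) * spec$vertebra_depth_mm)
  }
  if (startsWith(label, "VERTEBRA:") || startsWith(label, "DISC:"))
    return(seg_area(label))
  stop("unknown region label '", label, "'", call. = FALSE)
}

#' Exact region areas of a phantom geometry
#'
#' Areas are computed analytically from the parametric construction (parallel
#' curve area element for the posterior offset bands), independently of any
#' mesh, so they can be used to verify area conservation under meshing.
#'
#' @param geometry a `phantom_geometry`.
#' @return named numeric vector of areas (mm^2), named by region label.
#' @export
region_areas <- function(geometry) {
  rt <- region_table(geometry)
  a <- vapply(rt$label, function(l) region_area_exact(geometry, l), numeric(1))
  names(a) <- rt$label
  a
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Lumbar phantom specification\n")
  cat(sprintf("  body length %.0f mm; skin %.1f mm; fat %.1f mm; lordosis %.0f mm over %.0f mm\n",
              x$body_length_mm, x$skin_mm, x$fat_mm,
              x$lordosis_depth_mm, x$lordosis_span_mm))
  cat(sprintf("  column: 7 vertebrae %.0f x %.0f mm, 6 discs %.0f mm; mat %.0f mm\n",
              x$vertebra_height_mm, x$vertebra_depth_mm, x$disc_height_mm,
              x$mat_thickness_mm))
  invisible(x)
}

#' @export
print.phantom_geometry <- function(x, ...) {
  rt <- region_table(x)
  cat("Lumbar phantom geometry:", nrow(rt), "labeled regions",
      sprintf("(fat %.1f mm, lordosis %.0f mm)\n",
              x$spec$fat_mm, x$spec$lordosis_depth_mm))
  invisible(x)
}
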