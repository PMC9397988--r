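#' Default tissue material table
#'
#' Linear-elastic constants for every tissue class of the phantom, in the
#' mm--MPa--N unit system: Young's modulus E (MPa), Poisson ratio (-) and
#' density (kg m^-3).  The soft tissues are nearly incompressible (nu = 0.49);
#' CSF is specified through its bulk modulus K = 2250 MPa at nu = 0.499 and
#' its effective Young's modulus is derived via `E = 3K(1 - 2 nu)` (see
#' [csf_effective_modulus()]).  Densities are carried for completeness but
#' unused by the quasi-static solver.  The bed mat is a soft foam strip
#' (E = 5 MPa, nu = 0.3 by default; not a tissue, exposed for configuration).
#'
#' @param mat_E,mat_nu,mat_rho bed mat elastic constants.
#' @param csf_K,csf_nu CSF bulk modulus (MPa) and Poisson ratio.
#' @return An object of class `material_table`: data.frame with columns
#'   `tissue`, `E`, `nu`, `rho` (plus attributes recording the CSF bulk
#'   modulus).
#' @export
material_table <- function(mat_E = 5, mat_nu = 0.3, mat_rho = 50,
                           csf_K = 2250, csf_nu = 0.499) {
  tab <- data.frame(
    tissue = c("skin", "muscle", "soft_tissue", "vertebrae", "disc",
               "subcut_fat", "epidural_fat", "csf", "cord", "mat"),
    E = c(160, 7, 23.5, 17000, 17, 3, 3,
          csf_effective_modulus(csf_K, csf_nu), 10, mat_E),
    nu = c(0.49, 0.49, 0.49, 0.30, 0.49, 0.49, 0.49, csf_nu, 0.49, mat_nu),
    rho = c(1020, 1100, 1057, 1800, 1100, 920, 920, 1000, 1057, mat_rho),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("material_table", "data.frame"),
            csf_K = csf_K)
}

#' Effective Young's modulus of a fluid given bulk modulus and Poisson ratio
#'
#' Standard isotropic elasticity identity `E = 3 K (1 - 2 nu)`, used to
#' convert the CSF bulk-modulus specification (K = 2250 MPa, nu = 0.499,
#' giving E = 13.5 MPa) into the (E, nu) form the plane-strain operator uses.
#'
#' @param K bulk modulus (MPa).
#' @param nu Poisson ratio, strictly below 0.5.
#' @return Young's modulus E (MPa).
#' @export
#' @examples
#' csf_effective_modulus(2250, 0.499)  # 13.5
csf_effective_modulus <- function(K, nu) {
  if (!is.numeric(K) || K <= 0) stop("bulk modulus K must be positive",
                                     call. = FALSE)
  if (!is.numeric(nu) || nu <= 0 || nu >= 0.5)
    stop("Poisson ratio must lie in (0, 0.5); the incompressible limit ",
         "nu = 0.5 is unsupported", call. = FALSE)
  3 * K * (1 - 2 * nu)
}

#' Look up elastic constants for a mesh region
#'
#' @param table a [material_table()].
#' @param region a region label such as `"SKIN"`, `"DISC:L2-L3"` or
#'   `"VERTEBRA:L4"` (all disc levels share one disc material), or a bare
#'   tissue key such as `"disc"`.
#' @return list with elements `E` (MPa), `nu`, `rho` (kg m^-3).
#' @export
material_lookup <- function(table, region) {
  stopifnot(inherits(table, "material_table"))
  tissue <- region_tissue_key(region)
  i <- match(tissue, table$tissue)
  if (is.na(i))
    stop("no material entry for region '", region, "' (tissue key '",
         tissue, "')", call. = FALSE)
  list(E = table$E[i], nu = table$nu[i], rho = table$rho[i])
}

region_tissue_key <- function(region) {
  if (region %in% c("SKIN", "skin")) return("skin")
  if (region %in% c("SUBCUT_FAT", "subcut_fat")) return("subcut_fat")
  if (region %in% c("SOFT_TISSUE", "soft_tissue")) return("soft_tissue")
  if (region %in% c("MUSCLE", "muscle")) return("muscle")
  if (region %in% c("EPIDURAL_FAT", "epidural_fat")) return("epidural_fat")
  if (region %in% c("CSF", "csf")) return("csf")
  if (region %in% c("CORD", "cord")) return("cord")
  if (region %in% c("MAT", "mat")) return("mat")
  if (startsWith(region, "DISC:") || region == "disc") return("disc")
  if (startsWith(region, "VERTEBRA:") || region == "vertebrae")
    return("vertebrae")
  region
}

#' Plane-strain constitutive matrix
#'
#' 3x3 symmetric positive-definite operator D mapping engineering strain
#' `(exx, eyy, gxy)` to Cauchy stress `(sxx, syy, txy)` for an isotropic
#' linear-elastic material under plane strain:
#' `D11 = D22 = E(1-nu)/((1+nu)(1-2nu))`, `D12 = E nu/((1+nu)(1-2nu))`,
#' `D33 = E/(2(1+nu))` (the shear modulus).
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio in (0, 0.5) (0 allowed for verification problems).
#' @return 3x3 numeric matrix (MPa).
#' @export
plane_strain_matrix <- function(E, nu) {
  if (!is.numeric(E) || E <= 0) stop("E must be positive", call. = FALSE)
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5)
    stop("nu must lie in [0, 0.5)", call. = FALSE)
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  matrix(c(c1 * (1 - nu), c1 * nu, 0,
           c1 * nu, c1 * (1 - nu), 0,
           0, 0, E / (2 * (1 + nu))), 3, 3)
}

#' Damage thresholds for intervertebral disc tissue
#'
#' Published ultimate values for disc tissue used by [safety_check()]:
#' ultimate stress 2.94 +/- 1.05 MPa and ultimate tensile strain
#' 21.3 +/- 2.1 %.
#'
#' @return list with `ultimate_stress_MPa`, `ultimate_stress_sd`,
#'   `ultimate_strain_pct`, `ultimate_strain_sd`.
#' @export
safety_thresholds <- function() {
  list(ultimate_stress_MPa = 2.94, ultimate_stress_sd = 1.05,
       ultimate_strain_pct = 21.3, ultimate_strain_sd = 2.1)
}

#' Materials for a mesh, with near-incompressibility cap
#'
#' Resolves the material of every region in a mesh and returns per-element
#' constitutive data.  For solver conditioning the CSF Poisson ratio is
#' capped at `nu_cap` (default 0.495); disc ROI results are insensitive to
#' the CSF ratio at this geometry scale.
#'
#' @param mesh a `labeled_mesh`.
#' @param table a [material_table()].
#' @param nu_cap cap applied to Poisson ratios in the solve (default 0.495).
#' @return list with `E`, `nu` (per element) and `D` (3 x 3 x n_regions
#'   lookup by region id).
#' @keywords internal
resolve_materials <- function(mesh, table, nu_cap = 0.495) {
  labs <- mesh$labels
  ent <- lapply(labs$label, function(l) material_lookup(table, l))
  E <- vapply(ent, `[[`, numeric(1), "E")
  nu <- pmin(vapply(ent, `[[`, numeric(1), "nu"), nu_cap)
  idx <- match(mesh$region_id, labs$region_id)
  list(E_elem = E[idx], nu_elem = nu[idx],
       E_region = E, nu_region = nu, region_id = labs$region_id)
}
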