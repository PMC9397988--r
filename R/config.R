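#' Default run configuration
#'
#' Single source of truth for a simulation run: phantom geometry block,
#' material table block, traction protocol block, solver block, analysis
#' block, output directory and seed.  Serialized as YAML; [load_config()]
#' fills omitted keys with these defaults and rejects unknown keys.
#'
#' @return nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    phantom = unclass(phantom_spec()),
    materials = list(mat_E = 5, mat_nu = 0.3, mat_rho = 50,
                     csf_K = 2250, csf_nu = 0.499),
    protocol = list(n_levels = 9L, full_range_mm = 62,
                    roller_radius_mm = 25, roller_center_x = NULL,
                    initial_clearance_mm = 4 * 62 / 9),
    solver = list(rtol = 1e-6, atol = 1e-8, max_iter = 40L,
                  max_halvings = 5L, increments_per_level = 2L,
                  penalty_factor = 200,
                  gap_tol = 0.02, comp_tol = 0.01, kinematics = "updated",
                  mat_model = "cushion", stabilization = 0,
                  nu_cap = 0.495, verbose = FALSE,
                  anterior_fraction = 0.1),
    analysis = list(bmi_classes = bmi_classes(), traction_levels = 5:9,
                    reference_class = "normal"),
    output_dir = "patraction-out",
    rng_seed = 1L,
    log_level = "info"
  ), class = "run_config")
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config: block '", path, "' must be a mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config: unknown key", if (length(unknown) > 1) "s", " '",
         paste0(path, unknown, collapse = "', '"), "'", call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "/"))
    } else {
      defaults[k] <- user[k]   # keeps NULL assignments possible
    }
  }
  defaults
}

validate_config <- function(config) {
  sp <- config_phantom_spec(config)       # runs phantom_spec validation
  if (config$protocol$n_levels < 1 || config$protocol$full_range_mm <= 0)
    stop("config: protocol block invalid", call. = FALSE)
  if (!config$solver$kinematics %in% c("updated", "linear"))
    stop("config: solver/kinematics must be 'updated' or 'linear'",
         call. = FALSE)
  bad <- setdiff(config$analysis$bmi_classes,
                 c(bmi_classes(), "severe_obese"))
  if (length(bad))
    stop("config: unknown BMI class '", paste(bad, collapse = "', '"), "'",
         call. = FALSE)
  invisible(config)
}

#' Load (and validate) a YAML run configuration
#'
#' Missing keys take their defaults; unknown keys are rejected with an error
#' naming the key.  An empty file yields the all-defaults configuration.
#'
#' @param path YAML file path.
#' @return validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Save a run configuration as YAML
#' @param config a `run_config`.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## accessors building typed objects from the config blocks
config_phantom_spec <- function(config) {
  do.call(phantom_spec, config$phantom)
}
config_protocol <- function(config) {
  do.call(traction_protocol, config$protocol)
}
config_materials <- function(config) {
  do.call(material_table, config$materials)
}
config_control <- function(config) {
  s <- config$solver
  solver_control(rtol = s$rtol, atol = s$atol, max_iter = s$max_iter,
                 max_halvings = s$max_halvings,
                 increments_per_level = s$increments_per_level,
                 penalty_factor = s$penalty_factor, gap_tol = s$gap_tol,
                 comp_tol = s$comp_tol, kinematics = s$kinematics,
                 mat_model = s$mat_model, stabilization = s$stabilization,
                 nu_cap = s$nu_cap, verbose = isTRUE(s$verbose))
}

#' Content hash of a configuration
#'
#' MD5 of the canonical YAML serialization; used to key run outputs so that
#' identical configurations reproduce identical output paths.
#'
#' @param config a `run_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  save_config(config, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.run_config <- function(x, ...) {
  cat("patraction run configuration (hash", substr(config_hash(x), 1, 8),
      ")\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
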