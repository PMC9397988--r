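## Memoised expensive fixtures shared across test files.  Everything is
## deterministic (no RNG in the solver), so caching only saves time.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

## coarse phantom (8 mm edge, thin strips disabled) for fast solver tests
coarse_spec <- function(...) {
  phantom_spec(mesh_target_edge_mm = 8, csf_mm = 0, cord_mm = 0,
               epidural_fat_mm = 0, ...)
}

coarse_scene <- function() {
  memo("coarse_scene", {
    geom <- build_phantom(coarse_spec())
    mesh <- mesh_geometry(geom)
    list(geom = geom, mesh = mesh)
  })
}

coarse_solution <- function() {
  memo("coarse_solution", {
    sc <- coarse_scene()
    solve_traction(sc$mesh, material_table(), traction_protocol(), sc$geom,
                   tl = 5)
  })
}

## the full default study: all four BMI phantoms, every traction level
## (one incremental solve per phantom; levels harvested on the way up)
default_study_sweep <- function() {
  memo("default_study_sweep", {
    run_sweep(bmi_classes(), traction_levels = 1:9,
              config = default_config())
  })
}

verification_results <- function() {
  memo("verification_results", verify_suite())
}
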