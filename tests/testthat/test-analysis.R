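ref_sweep <- reference_disc_summary()

test_that("reference tables load as a complete disc summary", {
  expect_s3_class(ref_sweep, "disc_summary")
  expect_equal(nrow(ref_sweep), 4 * 3 * 6)
  expect_setequal(unique(ref_sweep$bmi_class), bmi_classes())
  expect_setequal(unique(ref_sweep$traction_level), c(5, 7, 9))
  expect_true(all(ref_sweep$mean_stress_MPa >= 0))
  expect_true(all(ref_sweep$mean_strain >= 0))
})

test_that("percent reduction arithmetic behaves on constructed summaries", {
  expect_equal(percent_reduction(ref_sweep, "normal", "normal"), 0)
  half <- ref_sweep
  half$mean_stress_MPa[half$bmi_class == "overweight"] <-
    0.5 * half$mean_stress_MPa[half$bmi_class == "normal"]
  expect_equal(percent_reduction(half, "normal", "overweight"), 50)
  ## invariant to uniform rescaling
  scaled <- ref_sweep
  scaled$mean_stress_MPa <- scaled$mean_stress_MPa * 3.7
  expect_equal(percent_reduction(scaled, "normal", "extreme_obese"),
               percent_reduction(ref_sweep, "normal", "extreme_obese"))
  expect_error(percent_reduction(ref_sweep, "normal", "lean"), "not present")
})

test_that("reference-table shielding anchors the aggregation convention", {
  ## severe obese vs normal at the top level, aggregated across discs
  r <- percent_reduction(ref_sweep, "normal", "extreme_obese",
                         traction_levels = 9)
  expect_equal(r, 78.5, tolerance = 0.01)
  ## strain shielding at the top level
  rs <- percent_reduction(ref_sweep, "normal", "extreme_obese", "strain",
                          traction_levels = 9)
  expect_gt(rs, 75)
})

test_that("disc ordering ranks the reference tables as published", {
  ord <- disc_ordering(ref_sweep, "normal", 9)
  expect_equal(ord[1], "L2-L3")
  expect_equal(ord[6], "T12-L1")
  ## ties resolve in anatomical (cranial-first) order
  const <- ref_sweep
  const$mean_stress_MPa <- 1
  expect_equal(disc_ordering(const, "normal", 9), disc_level_names())
  expect_error(disc_ordering(ref_sweep, "normal", 6), "no entries")
})

test_that("safety check flags only entries above the damage thresholds", {
  rep <- safety_check(ref_sweep)
  expect_true(rep$pass)
  expect_equal(rep$max_stress_MPa, 1.686)
  expect_equal(rep$max_strain, 0.09232)
  bad <- ref_sweep
  bad$mean_stress_MPa[1] <- 3.0
  rep2 <- safety_check(bad)
  expect_false(rep2$pass)
  expect_equal(nrow(rep2$flagged), 1L)
})

test_that("disc averages reduce to the mean of the nodal field", {
  sol <- coarse_solution()
  mesh <- coarse_scene()$mesh
  ## constant stress state over the whole mesh: disc mean equals its von
  ## Mises value exactly
  sol2 <- sol
  lv <- sol2$levels[[5]]
  lv$sig_qp[, , 1] <- 2; lv$sig_qp[, , 2] <- 1
  lv$sig_qp[, , 3] <- 0.5; lv$sig_qp[, , 4] <- 0.3
  lv$eps_qp[, , 1] <- 0.01; lv$eps_qp[, , 2] <- -0.004; lv$eps_qp[, , 3] <- 0.002
  sol2$levels[[5]] <- lv
  vm_const <- von_mises_stress(c(2, 1, 0.5, 0.3))
  eq_const <- equivalent_strain(c(0.01, -0.004, 0.002))
  for (d in c("T12-L1", "L3-L4"))
    expect_equal(disc_average(sol2, mesh, d, "von_mises_stress", 5),
                 vm_const, tolerance = 1e-12)
  expect_equal(disc_average(sol2, mesh, "L2-L3", "equivalent_strain", 5),
               eq_const, tolerance = 1e-12)
  ## level 0 is the rest state
  expect_identical(disc_average(sol, mesh, "L2-L3", level = 0), 0)
})

test_that("sweeping only the rest level yields an all-zero column", {
  cfg <- default_config()
  cfg$phantom$mesh_target_edge_mm <- 8
  cfg$phantom$csf_mm <- 0; cfg$phantom$cord_mm <- 0
  cfg$phantom$epidural_fat_mm <- 0
  sw <- run_sweep("normal", traction_levels = 0, config = cfg)
  expect_equal(nrow(sw), 6L)
  expect_true(all(sw$mean_stress_MPa == 0))
  expect_true(all(sw$mean_strain == 0))
  expect_false(any(sw$failed))
})

test_that("comparison report aggregates shielding and safety", {
  rep <- comparison_report(ref_sweep)
  expect_named(rep$stress_reduction_pct,
               c("overweight", "moderate_obese", "extreme_obese"))
  expect_true(all(rep$stress_reduction_pct > 0))
  expect_true(rep$safety$pass)
  expect_output(print(rep), "Load shielding")
})

test_that("disc summary plots render without error", {
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(reference_disc_summary()))
  expect_invisible(plot(reference_disc_summary(), quantity = "strain"))
})
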