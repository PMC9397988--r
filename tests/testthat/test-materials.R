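test_that("default material table carries the published tissue constants", {
  mt <- material_table()
  look <- function(r) material_lookup(mt, r)
  expect_equal(look("SKIN"), list(E = 160, nu = 0.49, rho = 1020))
  expect_equal(look("MUSCLE"), list(E = 7, nu = 0.49, rho = 1100))
  expect_equal(look("SOFT_TISSUE"), list(E = 23.5, nu = 0.49, rho = 1057))
  expect_equal(look("VERTEBRA:L3"), list(E = 17000, nu = 0.30, rho = 1800))
  expect_equal(look("DISC:L2-L3"), list(E = 17, nu = 0.49, rho = 1100))
  ## all disc levels share one entry
  expect_identical(look("DISC:T12-L1"), look("DISC:L5-S"))
  expect_equal(look("SUBCUT_FAT"), list(E = 3, nu = 0.49, rho = 920))
  expect_equal(look("EPIDURAL_FAT")$E, 3)
  expect_equal(look("CORD"), list(E = 10, nu = 0.49, rho = 1057))
  ## CSF stored as bulk modulus, E derived
  expect_equal(look("CSF")$E, 13.5)
  expect_equal(look("CSF")$nu, 0.499)
  expect_error(material_lookup(mt, "CARTILAGE"), "no material entry")
})

test_that("bulk-modulus conversion follows E = 3K(1 - 2 nu)", {
  expect_equal(csf_effective_modulus(2250, 0.499), 13.5)
  expect_equal(csf_effective_modulus(1234, 1 / 3), 1234)
  expect_equal(csf_effective_modulus(1000, 0.25), 1500)
  expect_error(csf_effective_modulus(1000, 0.5), "incompressible")
  expect_error(csf_effective_modulus(-1, 0.3), "positive")
})

test_that("plane-strain operator has the closed-form structure", {
  D0 <- plane_strain_matrix(1, 0)
  expect_equal(D0, matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 0.5), 3, 3))
  D <- plane_strain_matrix(17, 0.49)
  expect_equal(D[1, 1], 17 * (1 - 0.49) / ((1 + 0.49) * (1 - 2 * 0.49)),
               tolerance = 1e-12)
  expect_equal(D[1, 1], 290.9, tolerance = 1e-3)
  ## symmetric positive definite for every default tissue entry
  mt <- material_table()
  for (i in seq_len(nrow(mt))) {
    Di <- plane_strain_matrix(mt$E[i], min(mt$nu[i], 0.495))
    expect_identical(Di, t(Di))
    expect_true(all(eigen(Di, symmetric = TRUE)$values > 0))
  }
})

test_that("uniaxial-strain response matches the constrained modulus", {
  set.seed(42)
  for (k in 1:10) {
    E <- runif(1, 0.5, 2000)
    nu <- runif(1, 0.05, 0.49)
    D <- plane_strain_matrix(E, nu)
    s <- D %*% c(1, 0, 0)     # unit exx, lateral strain blocked
    M <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
    expect_equal(s[1, 1], M, tolerance = 1e-12)
    expect_equal(s[3, 1], 0)
  }
})

test_that("safety thresholds carry the published ultimate values", {
  th <- safety_thresholds()
  expect_equal(th$ultimate_stress_MPa, 2.94)
  expect_equal(th$ultimate_stress_sd, 1.05)
  expect_equal(th$ultimate_strain_pct, 21.3)
  expect_equal(th$ultimate_strain_sd, 2.1)
})
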