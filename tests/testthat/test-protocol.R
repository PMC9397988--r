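test_that("traction-level displacement schedule is affine with a 62 mm top", {
  expect_identical(tl_to_displacement(9), 62)
  expect_identical(tl_to_displacement(0), 0)
  expect_equal(tl_to_displacement(5), 5 * 62 / 9)
  incs <- diff(vapply(0:9, tl_to_displacement, numeric(1)))
  expect_true(all(abs(incs - 62 / 9) < 1e-12))
  expect_equal(sum(incs), 62)
  expect_error(tl_to_displacement(10), "0..9")
  expect_error(tl_to_displacement(-1), "0..9")
  expect_error(tl_to_displacement(4.5), "0..9")
})

test_that("roller profiles are disjoint arcs that rise rigidly per level", {
  geom <- build_phantom(phantom_spec())
  prot <- traction_protocol()
  p0 <- roller_profile(prot, geom, 0)
  p1 <- roller_profile(prot, geom, 1)
  expect_length(p0, 2L)
  ## rigid vertical shift by one increment
  for (i in 1:2)
    expect_equal(p1[[i]] - p0[[i]],
                 cbind(rep(0, nrow(p0[[i]])), rep(62 / 9, nrow(p0[[i]]))),
                 tolerance = 1e-9)
  ## arcs never intersect at any level: gap between centers exceeds 2R
  ctr <- attr(p0, "center")
  expect_gt(abs(diff(ctr[, 1])), 2 * attr(p0, "radius"))
})

test_that("contact onset level follows the clearance calibration", {
  geom <- build_phantom(phantom_spec())
  expect_identical(contact_onset_level(traction_protocol(), geom), 5L)
  expect_identical(
    contact_onset_level(traction_protocol(initial_clearance_mm = 0), geom),
    1L)
  expect_true(is.na(
    contact_onset_level(traction_protocol(initial_clearance_mm = 70), geom)))
})

test_that("rest calibration puts first roller touch exactly one clearance away", {
  geom <- build_phantom(phantom_spec())
  prot <- traction_protocol()
  st <- patraction:::roller_state(prot, geom, 0)
  ## after exactly one clearance of vertical travel the roller surface
  ## touches the sampled mat underside (the flank, not necessarily the
  ## apex, touches first on a curved mat); at rest it is clear of it
  d_bot <- geom$bands$mat[2]
  xs <- seq(0, 300, by = 0.25)
  P <- patraction:::offset_point(xs, d_bot, geom$lord)
  for (i in 1:2) {
    mingap <- function(cy)
      min(sqrt((P[, 1] - st$cx[i])^2 + (P[, 2] - cy)^2)) - st$R
    expect_equal(mingap(st$cy[i] + prot$initial_clearance_mm), 0,
                 tolerance = 1e-6)
    expect_gt(mingap(st$cy[i]), 0)
  }
})
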