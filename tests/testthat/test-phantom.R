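test_that("phantom spec validates its parameters", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(fat_mm = -1), "fat_mm")
  expect_error(phantom_spec(skin_mm = 0), "skin_mm")
  expect_error(phantom_spec(body_length_mm = 200,
                            lordosis_span_mm = 200), "exceeds")
  expect_error(phantom_spec(lordosis_span_mm = 400), "lordosis_span_mm")
})

test_that("BMI classes map to the four fat thicknesses", {
  expect_equal(bmi_class_fat_thickness("normal"), 13)
  expect_equal(bmi_class_fat_thickness("overweight"), 26)
  expect_equal(bmi_class_fat_thickness("moderate_obese"), 52)
  expect_equal(bmi_class_fat_thickness("extreme_obese"), 86)
  expect_equal(bmi_class_fat_thickness("severe_obese"), 86)
  expect_error(bmi_class_fat_thickness("slim"), "valid classes")
})

test_that("phantom construction yields the full labeled region inventory", {
  geom <- build_phantom(phantom_spec())
  rt <- region_table(geom)
  expect_equal(sum(startsWith(rt$label, "DISC:")), 6L)
  expect_equal(sum(startsWith(rt$label, "VERTEBRA:")), 7L)
  expect_setequal(
    rt$label[!grepl(":", rt$label)],
    c("SKIN", "SUBCUT_FAT", "SOFT_TISSUE", "MUSCLE", "EPIDURAL_FAT", "CSF",
      "CORD", "MAT"))
  ## every region label present in the default mesh
  mesh <- mesh_geometry(geom)
  expect_setequal(unique(mesh$region_id), rt$region_id)
})

test_that("geometry self-intersection is caught with a helpful message", {
  expect_error(build_phantom(phantom_spec(lordosis_depth_mm = 80,
                                          fat_mm = 86)),
               "curvature radius")
})

test_that("straight spine gives collinear disc centroids", {
  geom <- build_phantom(phantom_spec(lordosis_depth_mm = 0))
  mesh <- mesh_geometry(geom)
  cy <- vapply(disc_level_names(), function(d) {
    id <- mesh$labels$region_id[mesh$labels$label == paste0("DISC:", d)]
    el <- which(mesh$region_id == id)
    mean(mesh$nodes[unique(as.vector(mesh$tri[el, 1:3])), 2])
  }, numeric(1))
  expect_lt(diff(range(cy)), 1e-9)
})

test_that("posterior fat layer thickness matches the BMI class value, measured normal to the skin", {
  for (fat in c(13, 86)) {
    geom <- build_phantom(phantom_spec(fat_mm = fat))
    mesh <- mesh_geometry(geom)
    rt <- mesh$labels
    id_of <- function(lab) rt$region_id[rt$label == lab]
    fat_nodes <- mesh$region_nodes[[as.character(id_of("SUBCUT_FAT"))]]
    outer_iface <- intersect(fat_nodes,
                             mesh$region_nodes[[as.character(id_of("SKIN"))]])
    inner_iface <- intersect(fat_nodes,
                             mesh$region_nodes[[as.character(id_of("SOFT_TISSUE"))]])
    po <- mesh$nodes[outer_iface, , drop = FALSE]
    pi_ <- mesh$nodes[inner_iface, , drop = FALSE]
    ## thickness normal to the skin = distance between the two offset curves
    mid <- po[abs(po[, 1] - 150) < 50, , drop = FALSE]
    d <- apply(mid, 1, function(p)
      min(sqrt((pi_[, 1] - p[1])^2 + (pi_[, 2] - p[2])^2)))
    expect_lt(max(d), fat + 0.5)
    expect_gt(max(d), fat - 0.5)
  }
})

test_that("fat dilation leaves interior tissue bit-identical", {
  g13 <- build_phantom(phantom_spec(fat_mm = 13))
  g86 <- dilate_fat(g13, 86)
  expect_equal(g86$spec$fat_mm, 86)
  m13 <- mesh_geometry(g13)
  m86 <- mesh_geometry(g86)
  inner_coords <- function(mesh) {
    rt <- mesh$labels
    inner <- rt$region_id[!rt$label %in% c("SKIN", "SUBCUT_FAT", "MAT")]
    nd <- sort(unique(unlist(mesh$region_nodes[as.character(inner)])))
    xy <- mesh$nodes[nd, , drop = FALSE]
    xy[order(xy[, 1], xy[, 2]), ]
  }
  expect_identical(inner_coords(m13), inner_coords(m86))
  ## dilation to the current thickness is the identity
  expect_identical(mesh_geometry(dilate_fat(g13, 13))$nodes, m13$nodes)
  ## dilation composes: 13 -> 26 -> 52 equals 13 -> 52
  g52a <- dilate_fat(dilate_fat(g13, 26), 52)
  g52b <- dilate_fat(g13, 52)
  expect_identical(mesh_geometry(g52a)$nodes, mesh_geometry(g52b)$nodes)
  ## shrinking is refused
  expect_error(dilate_fat(g86, 13), "dilated outward")
})

test_that("meshing conserves region areas and passes invariants for all BMI classes", {
  for (cl in bmi_classes()) {
    geom <- build_phantom(phantom_spec(fat_mm = bmi_class_fat_thickness(cl)))
    mesh <- mesh_geometry(geom)
    expect_silent(check_mesh(mesh))
    exact <- region_areas(geom)
    meshed <- mesh_region_areas(mesh)
    expect_true(all(abs(meshed - exact[names(meshed)]) /
                      exact[names(meshed)] < 0.005))
    expect_true(all(element_areas(mesh) > 0))
  }
})

test_that("phantom construction is deterministic", {
  s <- phantom_spec()
  m1 <- mesh_geometry(build_phantom(s))
  m2 <- mesh_geometry(build_phantom(s))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tri, m2$tri)
  expect_identical(m1$region_id, m2$region_id)
})

test_that("halving the target edge multiplies the element count by 3 to 6", {
  geom <- build_phantom(phantom_spec())
  n1 <- nrow(mesh_geometry(geom, 5)$tri)
  n2 <- nrow(mesh_geometry(geom, 2.5)$tri)
  expect_gte(n2 / n1, 3)
  expect_lte(n2 / n1, 6)
})

test_that("rectangle mesher gives a single-label conforming mesh", {
  rm <- mesh_rectangle(1, 1, 0.5)
  expect_true(all(rm$region_id == 1L))
  expect_true(all(element_areas(rm) > 0))
  expect_equal(sum(element_areas(rm)), 1, tolerance = 1e-12)
})

test_that("each disc ROI carries enough nodes for averaging", {
  mesh <- mesh_geometry(build_phantom(phantom_spec()))
  for (d in disc_level_names())
    expect_gte(length(disc_nodes(mesh, d)), 50L)
  expect_error(disc_nodes(mesh, "L9-L10"), "no disc region")
})
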