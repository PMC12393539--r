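test_that("default phantom reproduces the study geometry", {
  spec <- phantom_spec()
  expect_equal(spec$mc_diameter_nm, 300)
  expect_equal(spec$mc_length_nm, 500)
  expect_equal(spec$n_da, 9L)
  expect_equal(spec$voxel_size_nm, 9)
  ph <- fixture("naked", function() build_phantom(stage_phantom_spec("NAKED")))
  # MC voxel extent matches the cylinder within a voxel
  mc <- which(ph$volume$data == 1L, arr.ind = TRUE)
  W <- voxel_world_coords(ph$volume, mc)
  cyl <- to_cylindrical(W, ph$truth$frame)
  expect_lt(abs(max(cyl[, "r_nm"]) - 150), 9)
  # voxel-centre extent understates the face-to-face length by up to two
  # voxels depending on grid phase
  expect_lt(abs(diff(range(cyl[, "z_nm"])) - 500), 18.01)
  expect_equal(ph$truth$true_stage, "NAKED")
  # only MC and DA labels present
  expect_setequal(setdiff(unique(as.vector(ph$volume$data)), 0L), c(1L, 2L))
})

test_that("arc-torus ground truth follows the closed forms", {
  # span 207 deg: gap = 360 - 207 = 153, area = 4 pi^2 R r * 207/360
  prim <- membrane_primitive("arc_torus", major_radius_nm = 310,
                             tube_radius_nm = 50, arc_start_deg = 10,
                             arc_end_deg = 217, z_nm = -50)
  spec <- phantom_spec(membranes = list(prim))
  ph <- build_phantom(spec)
  expect_equal(ph$truth$true_gap_deg, 153)
  expect_equal(ph$truth$analytic_surface_area_nm2,
               4 * pi^2 * 310 * 50 * 207 / 360)
  # sphere: 4 pi r^2; toroid: gap 0 and full 4 pi^2 R r
  sph <- membrane_primitive("sphere", center_nm = c(305, 0, -50),
                            radius_nm = 45)
  tor <- membrane_primitive("toroid", major_radius_nm = 310,
                            tube_radius_nm = 50, z_nm = -50)
  ph2 <- build_phantom(phantom_spec(membranes = list(sph, tor)))
  expect_equal(ph2$truth$analytic_surface_area_nm2,
               c(4 * pi * 45^2, 4 * pi^2 * 310 * 50))
  expect_equal(ph2$truth$true_gap_deg, c(NA_real_, 0))
})

test_that("analytic tip distances match independent hand computation", {
  # sphere centred on the radial line through tip 1 (theta = 0):
  # centre radius 305, sphere radius 45, tip at radius 250 -> standoff 10
  sph <- membrane_primitive("sphere", center_nm = c(305, 0, -50),
                            radius_nm = 45)
  ph <- build_phantom(phantom_spec(membranes = list(sph)))
  d <- ph$truth$true_min_distance_nm[1, ]
  expect_equal(d[1], 10)
  # tip 2 at theta = 40 deg: law of cosines to the centre, minus radius
  tip2 <- c(250 * cos(40 * pi / 180), 250 * sin(40 * pi / 180), -50)
  ctr <- c(305, 0, -50)
  expect_equal(d[2], sqrt(sum((tip2 - ctr)^2)) - 45, tolerance = 1e-12)
})

test_that("label precedence keeps membranes out of the MC body", {
  # a toroid deliberately overlapping the MC wall: precedence must leave
  # every voxel inside the MC cylinder labelled mc_body
  spec <- stage_phantom_spec("NAKED")
  spec$membranes <- list(membrane_primitive(
    "toroid", major_radius_nm = 190, tube_radius_nm = 50, z_nm = -50))
  ph <- build_phantom(spec)
  mem <- which(ph$volume$data == 3L, arr.ind = TRUE)
  expect_gt(nrow(mem), 0)
  cyl <- to_cylindrical(voxel_world_coords(ph$volume, mem), ph$truth$frame)
  inside_mc <- cyl[, "r_nm"] <= 150 - 1e-9 &
    cyl[, "z_nm"] <= -1e-9 & cyl[, "z_nm"] >= -500 + 1e-9
  expect_false(any(inside_mc))
})

test_that("cohort sampling is deterministic and respects ranges", {
  a <- sample_cohort("CCV", 3, list(gap_deg = c(40, 160)), rng_seed = 5)
  b <- sample_cohort("CCV", 3, list(gap_deg = c(40, 160)), rng_seed = 5)
  expect_identical(lapply(a, function(p) p$volume$data),
                   lapply(b, function(p) p$volume$data))
  gaps_a <- vapply(a, function(p) p$truth$true_gap_deg[1], numeric(1))
  expect_true(all(gaps_a >= 40 & gaps_a <= 160))
  # a different seed changes at least one ground-truth parameter
  c3 <- sample_cohort("CCV", 3, list(gap_deg = c(40, 160)), rng_seed = 6)
  gaps_c <- vapply(c3, function(p) p$truth$true_gap_deg[1], numeric(1))
  expect_false(identical(gaps_a, gaps_c))
})

test_that("cohort sampling validates its inputs", {
  expect_error(sample_cohort("CCV", 2, list(gap_deg = c(160, 40))),
               "range")
  expect_error(sample_cohort("CCV", 2, rng_seed = NA), "integer")
})

test_that("voxelization error of a sphere shrinks with voxel size", {
  errs <- vapply(c(9, 3), function(vs) {
    vol <- sphere_volume(200, voxel_size_nm = vs)
    abs(mesh_area(extract_surface_mesh(vol, 3L)) - 4 * pi * 100^2)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})
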