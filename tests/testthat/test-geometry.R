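test_that("frame fit recovers a z-aligned phantom", {
  ph <- fixture("naked", function() build_phantom(stage_phantom_spec("NAKED")))
  fr <- fit_centriole_frame(ph$volume)
  expect_lt(angle_between_deg(fr$axis, c(0, 0, 1)), 1)
  expect_lt(sqrt(sum((fr$origin_nm - ph$truth$frame$origin_nm)^2)), 9)
  expect_equal(fr$mc_radius_nm, 150, tolerance = 0.05)
  expect_equal(fr$mc_length_nm, 500, tolerance = 0.05)
})

test_that("frame fit recovers a phantom rotated 30 degrees about y", {
  Q <- rotation_matrix(c(0, 1, 0), 30)
  ph <- build_phantom(stage_phantom_spec("NAKED", orientation = Q))
  fr <- fit_centriole_frame(ph$volume)
  expect_lt(angle_between_deg(fr$axis, ph$truth$frame$axis), 2)
  expect_lt(sqrt(sum((fr$origin_nm - ph$truth$frame$origin_nm)^2)), 9)
})

test_that("frame fit refuses degenerate inputs", {
  vol <- label_volume(array(0L, c(8, 8, 8)), 9)
  expect_error(fit_centriole_frame(vol), "mc_body")
  # a spherical MC has no dominant axis
  sph <- sphere_volume(200, label = 1L)
  sph$data[1, 1, 1] <- 2L  # token DA voxel
  expect_error(fit_centriole_frame(sph), "dominant axis")
})

test_that("cylindrical transform matches its definition and inverts exactly", {
  fr <- centriole_frame(c(100, 200, 300), c(0, 0, 1), c(1, 0, 0), 150, 500)
  p_ref <- rbind(c(100, 200, 300) + 150 * c(1, 0, 0))
  expect_equal(unname(to_cylindrical(p_ref, fr)[1, ]), c(150, 0, 0))
  p_anti <- rbind(c(100, 200, 300) - 150 * c(1, 0, 0))
  expect_equal(unname(to_cylindrical(p_anti, fr)[1, ]), c(150, 180, 0))
  # a point on the axis has r = 0 and theta = 0 by convention
  expect_equal(unname(to_cylindrical(rbind(c(100, 200, 310)), fr)[1, ]),
               c(0, 0, 10))

  # round trip on 1000 random points in a tilted frame
  set.seed(3)
  ax <- c(1, 2, 3) / sqrt(14)
  ref <- c(1, -1, 0); ref <- ref - sum(ref * ax) * ax
  ref <- ref / sqrt(sum(ref^2))
  fr2 <- centriole_frame(c(-5, 8, 2), ax, ref, 150, 500)
  P <- matrix(rnorm(3000, sd = 400), ncol = 3)
  back <- from_cylindrical(to_cylindrical(P, fr2), fr2)
  expect_lt(max(abs(back - P)), 1e-9)
})

test_that("DA tips are found with nine-fold symmetry", {
  ph <- fixture("naked", function() build_phantom(stage_phantom_spec("NAKED")))
  fr <- fit_centriole_frame(ph$volume)
  tips <- detect_da_tips(ph$volume, fr)
  expect_equal(nrow(tips), 9)
  # consecutive azimuth spacings are 40 +/- 3 degrees
  spacing <- diff(c(tips$theta_deg, tips$theta_deg[1] + 360))
  expect_true(all(abs(spacing - 40) < 3))
  # tip radius = mc_radius + da_length within one voxel
  expect_true(all(abs(tips$radial_nm - 250) <= 9))
  # tips match the analytic ground-truth tip points within one voxel
  d <- vapply(seq_len(9), function(i) {
    min(sqrt(colSums((t(ph$truth$da_tip_points_nm) -
                        c(tips$tip_x_nm[i], tips$tip_y_nm[i],
                          tips$tip_z_nm[i]))^2)))
  }, numeric(1))
  expect_true(all(d <= 9))
})

test_that("theta differences are invariant under rigid rotation", {
  spec0 <- stage_phantom_spec("CCV", gap_deg = 120)
  ph0 <- build_phantom(spec0)
  rep0 <- analyze_cell(ph0$volume)
  Q <- rotation_matrix(c(1, 1, 0), 55)
  ph1 <- build_phantom(stage_phantom_spec("CCV", gap_deg = 120,
                                          orientation = Q))
  rep1 <- analyze_cell(ph1$volume)
  expect_equal(rep0$components$gap_deg, rep1$components$gap_deg,
               tolerance = 6 / 120)  # +/- 6 deg on a 120 deg gap
})

test_that("isosurface meshes are closed and components stay separate", {
  # single voxel: a closed mesh with positive area
  arr <- array(0L, c(5, 5, 5)); arr[3, 3, 3] <- 3L
  vol <- label_volume(arr, 9)
  m1 <- extract_surface_mesh(vol, 3L, smooth_iters = 0L)
  expect_gt(mesh_area(m1), 0)
  expect_true(mesh_is_closed(m1))

  # solid sphere: one closed component
  msphere <- extract_surface_mesh(sphere_volume(120), 3L)
  expect_true(mesh_is_closed(msphere))

  # two disjoint spheres: mesh area is additive over components
  n <- 41
  arr2 <- array(0L, c(n, n, n))
  ax <- (seq_len(n) - 1) * 9
  g <- expand.grid(z = ax, y = ax, x = ax)
  c1 <- c(90, 90, 90); c2 <- c(270, 270, 270)
  arr2[sqrt((g$x - c1[1])^2 + (g$y - c1[2])^2 + (g$z - c1[3])^2) <= 55] <- 3L
  arr2[sqrt((g$x - c2[1])^2 + (g$y - c2[2])^2 + (g$z - c2[3])^2) <= 55] <- 3L
  vol2 <- label_volume(arr2, 9)
  combined <- extract_surface_mesh(vol2, 3L)
  comps <- detect_membrane_components(vol2)
  expect_length(comps, 2)
  expect_equal(sum(vapply(comps, surface_area, numeric(1))),
               mesh_area(combined), tolerance = 1e-6)
  expect_error(extract_surface_mesh(vol2, 5L), "not present")
})
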