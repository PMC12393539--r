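test_that("theta_gap equals the exhaustive circular-spacing oracle", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(3:200, 1)
    th <- runif(n, 0, 360)
    if (i %% 5 == 0) th[1:2] <- th[3]  # duplicates
    g <- theta_gap(th)
    expect_identical(g$gap_deg, brute_circular_gap(th))
    expect_equal(g$gap_deg + g$coverage_deg, 360)
  }
  expect_error(theta_gap(c(1, 2)), "at least 3")
})

test_that("gap interval marks the empty arc", {
  g <- theta_gap(c(10, 20, 30, 300))
  expect_equal(g$gap_deg, 270)
  expect_equal(unname(g$gap_interval), c(30, 300))
  # wrap-around gap
  g2 <- theta_gap(c(100, 150, 200))
  expect_equal(g2$gap_deg, 260)
  expect_equal(unname(g2$gap_interval), c(200, 100))
})

test_that("vesicle filter keeps only multi-slice components above 30 nm", {
  build_multi <- function() {
    # four spheres of diameters 18, 28, 36, 90 nm plus a single-slice
    # artifact, all in one volume, spaced apart
    n <- 61; vs <- 9
    arr <- array(0L, c(n, n, n))
    ax <- (seq_len(n) - 1) * vs
    g <- expand.grid(z = ax, y = ax, x = ax)
    centres <- list(c(90, 90, 90), c(90, 90, 360), c(90, 360, 90),
                    c(360, 120, 120))
    diams <- c(18, 28, 36, 90)
    for (i in seq_along(diams)) {
      cc <- centres[[i]]
      d <- sqrt((g$x - cc[1])^2 + (g$y - cc[2])^2 + (g$z - cc[3])^2)
      arr[d <= diams[i] / 2] <- 3L
    }
    # single-slice artifact: a 60 nm disk confined to one section
    zi <- 45L
    disk <- g$z == ax[zi] &
      sqrt((g$x - 400)^2 + (g$y - 400)^2) <= 30
    arr[disk] <- 3L
    label_volume(arr, vs)
  }
  vol <- build_multi()
  comps <- detect_membrane_components(vol)
  diams <- sort(vapply(comps, `[[`, numeric(1), "diameter_nm"))
  expect_length(comps, 2)
  expect_lt(abs(diams[1] - 36), 9)
  expect_lt(abs(diams[2] - 90), 9)
  excl <- attr(comps, "excluded")
  expect_equal(nrow(excl), 3)
  expect_true("too_few_z_slices" %in% excl$reason)
  expect_true("diameter_at_or_below_minimum" %in% excl$reason)
})

test_that("absent membranes give an empty, well-formed result", {
  vol <- label_volume(array(0L, c(8, 8, 8)), 9)
  comps <- detect_membrane_components(vol)
  expect_length(comps, 0)
  expect_s3_class(attr(comps, "excluded"), "data.frame")
})

test_that("docking distance matches the analytic sphere standoff", {
  # sphere of radius 45 whose centre is 65 nm from a tip: min distance 20
  vol <- sphere_volume(90)
  comps <- detect_membrane_components(vol)
  ctr <- unname(comps[[1]]$centroid_nm)
  tips <- data.frame(da_id = 1:2,
                     tip_x_nm = ctr[1] + c(65, 120), tip_y_nm = ctr[2],
                     tip_z_nm = ctr[3], theta_deg = c(0, 40),
                     radial_nm = 250, axial_nm = -50)
  dr <- docking_assessment(comps[[1]], tips)
  expect_equal(dr$distances$min_distance_nm[1], 20, tolerance = 9 / 20)
  expect_equal(dr$distances$min_distance_nm[2], 75, tolerance = 9 / 75)
  expect_true(dr$docked)
  expect_equal(dr$closest_da_id, 1)
  # a tip on the membrane surface itself: distance ~0, docked
  tips0 <- tips[1, ]
  tips0$tip_x_nm <- ctr[1] + 45
  expect_lt(docking_assessment(comps[[1]], tips0)$min_distance_nm, 9)
  expect_error(docking_assessment(comps[[1]], tips[0, ]), "tips")
})

test_that("tips inside the gap are excluded from docking decisions", {
  ph <- fixture("ccv100", function()
    build_phantom(stage_phantom_spec("CCV", gap_deg = 100)))
  fr <- fit_centriole_frame(ph$volume)
  tips <- detect_da_tips(ph$volume, fr)
  comps <- detect_membrane_components(ph$volume)
  g <- compute_gap(comps[[1]], fr)
  dr <- docking_assessment(comps[[1]], tips, gap = g)
  in_gap <- ciliovem:::theta_in_gap(tips$theta_deg, g$gap_interval)
  expect_identical(dr$distances$excluded, unname(in_gap))
  expect_gt(sum(in_gap), 0)
  expect_true(dr$docked)
  expect_false(dr$closest_da_id %in% tips$da_id[in_gap])
})

test_that("measured gap tracks the built arc span monotonically", {
  gaps_true <- c(60, 150, 240)
  measured <- vapply(gaps_true, function(gd) {
    ph <- build_phantom(stage_phantom_spec("CCV", gap_deg = gd))
    fr <- fit_centriole_frame(ph$volume)
    comps <- detect_membrane_components(ph$volume)
    compute_gap(comps[[1]], fr)$gap_deg
  }, numeric(1))
  expect_true(all(abs(measured - gaps_true) <= 6))
  expect_true(all(diff(measured) > 0))
})

test_that("surface areas match closed forms within 10%", {
  a_sphere <- surface_area(detect_membrane_components(
    sphere_volume(200))[[1]])
  expect_equal(a_sphere, 4 * pi * 100^2, tolerance = 0.1)
  a_torus <- surface_area(detect_membrane_components(
    torus_volume(160, 40))[[1]])
  expect_equal(a_torus, 4 * pi^2 * 160 * 40, tolerance = 0.1)
})

test_that("enlargement flags use mean + k * sample SD with strict inequality", {
  ref <- c(50, 60, 70) * 1e3   # mean 60e3, SD 10e3, threshold 70e3
  flags <- enlargement_flags(c(75, 70, 65) * 1e3, ref)
  expect_identical(flags, c(TRUE, FALSE, FALSE))
  expect_false(any(enlargement_flags(rep(60e3, 5), ref)))
  # multiplier honoured
  cfg2 <- analysis_config(enlargement_sd_multiplier = 2)
  expect_identical(enlargement_flags(c(75, 81) * 1e3, ref, cfg2),
                   c(FALSE, TRUE))
  expect_error(enlargement_flags(1, 5), "at least 2")
})

test_that("docked-membrane summaries count and sum correctly", {
  mk_comp <- function(id, area) structure(
    list(component_id = id, surface_area_nm2 = area), class = "membrane_component")
  mk_dock <- function(id, d, docked) structure(
    list(component_id = id, docked = docked, min_distance_nm = d,
         distances = data.frame(da_id = 1:3, min_distance_nm = d + c(0, 5, 9),
                                excluded = c(FALSE, FALSE, TRUE))),
    class = "docking_result")
  comps <- lapply(1:5, function(i) mk_comp(i, i * 1e4))
  docks <- Map(mk_dock, 1:5, c(10, 20, 25, 40, 50),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  s <- summarize_docked_membranes(comps, docks)
  expect_equal(s$n_docked, 3)
  expect_equal(s$total_area_nm2, (1 + 2 + 3) * 1e4)
  expect_equal(s$mean_docking_distance_nm, mean(c(10, 20, 25)))
  # per-DA minima pool over docked components, excluded tips omitted
  expect_equal(s$per_da_min_nm, c(10, 15, NA))
  s0 <- summarize_docked_membranes(list(), list())
  expect_equal(s0$n_docked, 0)
  expect_equal(s0$total_area_nm2, 0)
})
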