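test_that("each canonical stage phantom classifies as its ground truth", {
  for (stg in c("NAKED", "DAV", "TCV", "CV", "CILIUM")) {
    ph <- build_phantom(stage_phantom_spec(stg))
    rep <- analyze_cell(ph$volume, cell_id = stg)
    expect_equal(rep$stage, ph$truth$true_stage, label = stg)
  }
  # CCV with the 10-degree gap seen in near-closed intermediates
  ph10 <- build_phantom(stage_phantom_spec("CCV", gap_deg = 10))
  expect_equal(analyze_cell(ph10$volume)$stage, "CCV")
})

test_that("DAV/CCV boundary honours the strict 180-degree rule", {
  # spans 178 and 182 -> gaps 182 and 178; +/- 6 deg voxelization keeps
  # both clear of the threshold
  ph_dav <- build_phantom(stage_phantom_spec("CCV", gap_deg = 182))
  ph_ccv <- build_phantom(stage_phantom_spec("CCV", gap_deg = 178))
  expect_equal(analyze_cell(ph_dav$volume)$stage, "DAV")
  expect_equal(analyze_cell(ph_ccv$volume)$stage, "CCV")
})

test_that("adding membranes only advances the stage ladder", {
  spec <- stage_phantom_spec("NAKED")
  expect_equal(analyze_cell(build_phantom(spec)$volume)$stage, "NAKED")
  dav_spec <- stage_phantom_spec("DAV", n_dav = 1)
  spec$membranes <- dav_spec$membranes
  expect_equal(analyze_cell(build_phantom(spec)$volume)$stage, "DAV")
  ccv_spec <- stage_phantom_spec("CCV", gap_deg = 120)
  # rotate the DAV sphere into the gap so it does not touch the arc
  dav2 <- stage_phantom_spec("DAV")$membranes[[1]]
  th <- 180 * pi / 180
  rc <- sqrt(sum(dav2$center_nm[1:2]^2))
  dav2$center_nm <- c(rc * cos(th), rc * sin(th), dav2$center_nm[3])
  spec$membranes <- c(ccv_spec$membranes, list(dav2))
  expect_equal(analyze_cell(build_phantom(spec)$volume)$stage, "CCV")
})

test_that("the TCV call needs an encircling loop, not just a small gap", {
  ph <- fixture("tcv", function() build_phantom(stage_phantom_spec("TCV")))
  rep <- analyze_cell(ph$volume)
  expect_equal(rep$stage, "TCV")
  expect_lte(rep$components$gap_deg[1], 3)
  # the classifying component keeps all vertices outside half the MC radius
  fr <- rep$frame
  comps <- detect_membrane_components(ph$volume)
  g <- compute_gap(comps[[1]], fr)
  expect_gt(g$min_radial_nm, 0.5 * fr$mc_radius_nm)
})

test_that("PM docking classifies tips by the 30 nm rule", {
  # no pm label: empty result flagged as absent
  naked <- fixture("naked", function() build_phantom(stage_phantom_spec("NAKED")))
  fr <- fit_centriole_frame(naked$volume)
  tips <- detect_da_tips(naked$volume, fr)
  none <- detect_pm_docking(naked$volume, tips)
  expect_length(none, 0)
  expect_equal(attr(none, "summary"), "absent")

  # flat PM sheet 15 nm beyond all tips (plane z = -65 in frame coords,
  # tips at z = -50): all nine dock
  spec_all <- stage_phantom_spec("NAKED")
  spec_all$membranes <- list(membrane_primitive(
    "sheet", point_nm = c(0, 0, -65), normal = c(0, 0, 1), role = "pm"))
  ph_all <- build_phantom(spec_all)
  fr_all <- fit_centriole_frame(ph_all$volume)
  tips_all <- detect_da_tips(ph_all$volume, fr_all)
  ids_all <- detect_pm_docking(ph_all$volume, tips_all)
  expect_setequal(as.integer(ids_all), tips_all$da_id)
  expect_equal(attr(ids_all, "summary"), "all")

  # tilted sheet near two tips, > 30 nm from the rest: partial docking
  spec_two <- stage_phantom_spec("NAKED")
  nrm <- c(sin(70 * pi / 180), 0, cos(70 * pi / 180))
  spec_two$membranes <- list(membrane_primitive(
    "sheet", point_nm = c(265, 0, -50), normal = nrm, role = "pm"))
  ph_two <- build_phantom(spec_two)
  fr_two <- fit_centriole_frame(ph_two$volume)
  tips_two <- detect_da_tips(ph_two$volume, fr_two)
  ids_two <- detect_pm_docking(ph_two$volume, tips_two)
  # analytic plane distances at the true tips decide the expected set
  tipsF <- ciliovem:::da_tip_points_frame(spec_two)
  d_true <- abs((tipsF[, 1] - 265) * nrm[1] + (tipsF[, 3] + 50) * nrm[3])
  expected <- which(d_true < 21)      # margin below the 30 nm threshold
  far <- which(d_true > 39)           # margin above
  idx_map <- match_tips(tips_two, ph_two$truth$da_tip_points_nm)
  docked_truth_idx <- idx_map[as.integer(ids_two)]
  expect_true(all(expected %in% docked_truth_idx))
  expect_false(any(far %in% docked_truth_idx))
  expect_equal(attr(ids_two, "summary"), "partial")
})
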