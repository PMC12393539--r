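test_that("analyze_cell produces a complete, deterministic report", {
  naked <- fixture("naked", function() build_phantom(stage_phantom_spec("NAKED")))
  rep <- analyze_cell(naked$volume, cell_id = "n1")
  expect_equal(rep$stage, "NAKED")
  expect_equal(nrow(rep$components), 0)

  ph <- fixture("ccv93", function()
    build_phantom(stage_phantom_spec("CCV", gap_deg = 93)))
  r1 <- analyze_cell(ph$volume, cell_id = "c1")
  expect_equal(nrow(r1$components), 1)
  expect_true(r1$components$docked[1])
  expect_equal(r1$components$gap_deg[1], 93, tolerance = 6 / 93)
  expect_equal(r1$stage, "CCV")
  r2 <- analyze_cell(ph$volume, cell_id = "c1")
  expect_identical(r1, r2)
})

test_that("cell reports serialize to CSV and JSON", {
  ph <- fixture("ccv93", function()
    build_phantom(stage_phantom_spec("CCV", gap_deg = 93)))
  rep <- analyze_cell(ph$volume, cell_id = "c1")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, csv, format = "csv")
  expect_equal(nrow(read.csv(csv)), 1)
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, js, format = "json")
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$stage, "CCV")
  expect_equal(back$components$gap_deg, rep$components$gap_deg)
})

test_that("cohort aggregation counts stages and handles n = 1 groups", {
  mk_report <- function(id, group_stage, dock = c(15, 20), areas = 1e5) {
    structure(list(
      cell_id = id, stage = group_stage,
      per_da_min_nm = dock,
      summary = list(n_docked = length(areas), areas_nm2 = areas,
                     total_area_nm2 = sum(areas)),
      config = analysis_config()), class = "cell_report")
  }
  stages <- c(rep("DAV", 4), rep("CCV", 3), rep("CV", 2), "NAKED")
  reports <- Map(mk_report, sprintf("c%02d", 1:10), stages)
  summ <- aggregate_cohort(reports)
  freq <- summ$stage_table["all", ] / 10
  expect_equal(unname(freq[c("DAV", "CCV", "CV", "NAKED")]),
               c(0.4, 0.3, 0.2, 0.1))
  expect_equal(sum(summ$stage_table["all", ]), summ$groups$n_cells)

  # n = 1 group: SD/SEM absent, not zero
  one <- aggregate_cohort(list(mk_report("solo", "DAV", dock = 12)))
  expect_true(is.na(one$groups$sem_docking_nm))
  expect_true(is.na(one$groups$sd_total_area_nm2))

  expect_error(
    aggregate_cohort(reports, grouping = c(c01 = "a")), "absent")
})

test_that("pooled docking distances recover the generative mean", {
  # 8 cells x 9 DA distances from truncated Normal(19, 5^2) on [5, 30]
  set.seed(97)
  rtnorm <- function(n) {
    x <- rnorm(n * 3, 19, 5)
    x <- x[x >= 5 & x <= 30]
    x[seq_len(n)]
  }
  mk <- function(id) structure(list(
    cell_id = id, stage = "DAV", per_da_min_nm = rtnorm(9),
    summary = list(n_docked = 1, areas_nm2 = 1e5, total_area_nm2 = 1e5),
    config = analysis_config()), class = "cell_report")
  reports <- lapply(sprintf("c%d", 1:8), mk)
  summ <- aggregate_cohort(reports)
  expect_equal(summ$groups$mean_docking_nm, 19, tolerance = 2 / 19)
  expect_equal(summ$groups$sem_docking_nm,
               sd(unlist(lapply(reports, `[[`, "per_da_min_nm"))) / sqrt(72),
               tolerance = 1e-9)
})

test_that("group comparison matches hand-computed pooled t and picks ANOVA", {
  null_case <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(null_case$statistic, 0)
  expect_equal(null_case$p_value, 1)

  # {1,2,3} vs {4,5,6}: pooled s^2 = 1, se = sqrt(2/3), t = -3/se
  res <- compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$test, "student_t")
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-5)
  expect_equal(res$stars, "*")

  three <- compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6),
                               c = c(2, 3, 4)))
  expect_equal(three$test, "anova")
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("cohort statistics are invariant to cell processing order", {
  mk <- function(id, stage, d) structure(list(
    cell_id = id, stage = stage, per_da_min_nm = d,
    summary = list(n_docked = 1, areas_nm2 = 1e5, total_area_nm2 = 1e5),
    config = analysis_config()), class = "cell_report")
  reports <- list(mk("a", "DAV", 10), mk("b", "CCV", 20), mk("c", "DAV", 15))
  s1 <- aggregate_cohort(reports)
  s2 <- aggregate_cohort(rev(reports))
  expect_equal(sort(as.vector(s1$stage_table)),
               sort(as.vector(s2$stage_table)))
  expect_equal(s1$groups$mean_docking_nm, s2$groups$mean_docking_nm)
})
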