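# Per-cell analysis pipeline, cohort aggregation and group statistics.

#' Analyze one centriole volume end to end
#'
#' Runs frame fit, DA tip detection, membrane component detection and
#' filtering, per-component gap determination, docking assessment (with
#' gap exclusion for components covering more than half the
#' circumference), surface areas, PM docking and stage classification.
#' Deterministic given (volume, config).
#'
#' @param volume A [label_volume] with mc_body and da labels.
#' @param config An [analysis_config()].
#' @param cell_id Identifier recorded in the report.
#' @return A `cell_report`: list with `cell_id`, `stage`, `pm_docked_da_ids`,
#'   `pm_summary`, `components` (data frame, one row per surviving
#'   membrane component), `excluded_components`, `per_da_min_nm`,
#'   `summary` (from [summarize_docked_membranes()]), `frame`,
#'   `da_tips`, `config`, `version`.
#' @export
analyze_cell <- function(volume, config = analysis_config(),
                         cell_id = "cell") {
  frame <- tryCatch(fit_centriole_frame(volume),
                    error = function(e) stop("cell ", cell_id, ": ",
                                             conditionMessage(e)))
  tips <- detect_da_tips(volume, frame)
  comps <- detect_membrane_components(volume, config)
  excluded <- attr(comps, "excluded")
  gaps <- lapply(comps, function(cc)
    tryCatch(compute_gap(cc, frame, config), error = function(e) NULL))
  dockings <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    g <- gaps[[i]]
    use_gap <- !is.null(g) && g$gap_deg < config$dav_ccv_gap_deg
    dockings[[i]] <- docking_assessment(comps[[i]], tips, config,
                                        gap = if (use_gap) g else NULL)
  }
  summary <- summarize_docked_membranes(comps, dockings, config)
  stage <- classify_mc_stage(comps, dockings, gaps, frame, config,
                             volume = volume)
  pm <- detect_pm_docking(volume, tips, config)

  comp_tab <- if (length(comps)) data.frame(
    cell_id = cell_id,
    component_id = vapply(comps, `[[`, integer(1), "component_id"),
    n_voxels = vapply(comps, function(x) nrow(x$voxels_zyx), integer(1)),
    diameter_nm = vapply(comps, `[[`, numeric(1), "diameter_nm"),
    z_slice_count = vapply(comps, `[[`, integer(1), "z_slice_count"),
    surface_area_nm2 = vapply(comps, `[[`, numeric(1), "surface_area_nm2"),
    gap_deg = vapply(gaps, function(g)
      if (is.null(g)) NA_real_ else g$gap_deg, numeric(1)),
    coverage_deg = vapply(gaps, function(g)
      if (is.null(g)) NA_real_ else g$coverage_deg, numeric(1)),
    min_distance_nm = vapply(dockings, `[[`, numeric(1), "min_distance_nm"),
    closest_da_id = vapply(dockings, `[[`, integer(1), "closest_da_id"),
    docked = vapply(dockings, `[[`, logical(1), "docked"))
  else data.frame(
    cell_id = character(0), component_id = integer(0), n_voxels = integer(0),
    diameter_nm = numeric(0), z_slice_count = integer(0),
    surface_area_nm2 = numeric(0), gap_deg = numeric(0),
    coverage_deg = numeric(0), min_distance_nm = numeric(0),
    closest_da_id = integer(0), docked = logical(0))

  structure(list(
    cell_id = cell_id,
    stage = stage$stage,
    stage_evidence = stage$evidence,
    classifying_component_id = stage$classifying_component_id,
    pm_docked_da_ids = as.integer(pm),
    pm_summary = attr(pm, "summary"),
    components = comp_tab,
    excluded_components = excluded,
    per_da_min_nm = summary$per_da_min_nm,
    summary = summary,
    frame = frame,
    da_tips = tips,
    config = config,
    version = pkg_version()), class = "cell_report")
}

#' @export
print.cell_report <- function(x, ...) {
  cat(sprintf("<cell_report> %s: stage %s, %d membrane component(s), %d docked\n",
              x$cell_id, x$stage, nrow(x$components), x$summary$n_docked))
  invisible(x)
}

#' Aggregate cell reports into a cohort summary
#'
#' Per group: number of cells, stage frequency table, pooled per-DA
#' docking distances (mean +/- SEM), docked-component count distribution,
#' per-component and per-cell total surface-area distributions
#' (mean +/- SD). SEM uses the sample SD over sqrt(n) and is reported as
#' `NA` for n = 1.
#'
#' @param reports List of `cell_report`s.
#' @param grouping Named character vector mapping `cell_id` to group label
#'   (or `NULL` for a single group `"all"`).
#' @return A `cohort_summary`: list with `groups` (one row per group),
#'   `stage_table`, and `samples` (per-group raw vectors for group tests).
#' @export
aggregate_cohort <- function(reports, grouping = NULL) {
  stopifnot(length(reports) >= 1)
  ids <- vapply(reports, `[[`, character(1), "cell_id")
  if (is.null(grouping)) grouping <- setNames(rep("all", length(ids)), ids)
  missing <- setdiff(ids, names(grouping))
  if (length(missing))
    stop("reports reference cells absent from `grouping`: ",
         paste(missing, collapse = ", "))
  groups <- unique(unname(grouping[ids]))
  stage_tab <- table(
    group = factor(unname(grouping[ids]), levels = groups),
    stage = factor(vapply(reports, `[[`, character(1), "stage"),
                   levels = STAGE_LEVELS))
  samples <- list()
  rows <- lapply(groups, function(g) {
    sel <- which(unname(grouping[ids]) == g)
    reps <- reports[sel]
    dock <- unlist(lapply(reps, function(r)
      r$per_da_min_nm[!is.na(r$per_da_min_nm) &
                        r$per_da_min_nm <= r$config$dock_threshold_nm]))
    counts <- vapply(reps, function(r) r$summary$n_docked, numeric(1))
    areas <- unlist(lapply(reps, function(r) r$summary$areas_nm2))
    totals <- vapply(reps, function(r) r$summary$total_area_nm2, numeric(1))
    samples[[g]] <<- list(docking_nm = dock, n_docked = counts,
                          component_areas_nm2 = areas,
                          total_area_nm2 = totals)
    data.frame(
      group = g, n_cells = length(reps),
      mean_docking_nm = if (length(dock)) mean(dock) else NA_real_,
      sem_docking_nm = if (length(dock) > 1)
        sd(dock) / sqrt(length(dock)) else NA_real_,
      mean_n_docked = mean(counts),
      sd_n_docked = if (length(counts) > 1) sd(counts) else NA_real_,
      mean_component_area_nm2 = if (length(areas)) mean(areas) else NA_real_,
      sd_component_area_nm2 = if (length(areas) > 1) sd(areas) else NA_real_,
      mean_total_area_nm2 = mean(totals),
      sd_total_area_nm2 = if (length(totals) > 1) sd(totals) else NA_real_)
  })
  structure(list(groups = do.call(rbind, rows), stage_table = stage_tab,
                 samples = samples), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$stage_table)
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Compare groups with a Student t-test or one-way ANOVA
#'
#' Two groups: unpaired two-tailed Student t-test with pooled variance
#' (Welch behind `welch = TRUE`). Three or more groups (or
#' `test = "anova"`): one-way ANOVA. Significance stars: * P < 0.05,
#' ** P < 0.01, *** P < 0.001.
#'
#' @param samples Named list of numeric vectors, one per group.
#' @param test `"auto"` (default: t-test for 2 groups, ANOVA otherwise),
#'   `"t_test"` or `"anova"`.
#' @param welch Use the Welch t-test instead of pooled variance.
#' @return List with `test`, `statistic`, `df`, `p_value`, `stars`.
#' @export
compare_groups <- function(samples, test = c("auto", "t_test", "anova"),
                           welch = FALSE) {
  test <- match.arg(test)
  stopifnot(is.list(samples), length(samples) >= 2)
  if (test == "auto") test <- if (length(samples) == 2) "t_test" else "anova"
  if (test == "t_test") {
    if (length(samples) != 2)
      stop("t-test requires exactly 2 groups")
    if (any(vapply(samples, length, integer(1)) < 2))
      stop("t-test requires n >= 2 per group")
    ht <- t.test(samples[[1]], samples[[2]], var.equal = !welch)
    out <- list(test = if (welch) "welch_t" else "student_t",
                statistic = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  } else {
    if (length(samples) < 2) stop("ANOVA requires at least 2 groups")
    values <- unlist(samples, use.names = FALSE)
    grp <- factor(rep(names(samples), vapply(samples, length, integer(1))))
    fit <- aov(values ~ grp)
    s <- summary(fit)[[1]]
    out <- list(test = "anova", statistic = s[["F value"]][1],
                df = s[["Df"]], p_value = s[["Pr(>F)"]][1])
  }
  out$stars <- if (out$p_value < 0.001) "***" else if (out$p_value < 0.01)
    "**" else if (out$p_value < 0.05) "*" else "ns"
  out
}
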