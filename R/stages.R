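# Stage classification of the mother centriole's membrane state and
# plasma-membrane docking.

STAGE_LEVELS <- c("NAKED", "DAV", "CCV", "TCV", "CV", "CILIUM")

#' Classify the ciliogenesis membrane stage of one centriole
#'
#' Decision ladder over *docked* components, most advanced stage first:
#'
#' 1. `CILIUM`: a docked component extends more than
#'    `cilium_axial_extent_nm` above the distal end.
#' 2. `CV`: a docked component covers the distal cap — at least
#'    `cv_occupancy_fraction` of the distal disk (radius `mc_radius_nm`)
#'    has component voxels above it (0 < z <= `cilium_axial_extent_nm`).
#' 3. `TCV`: a docked component closes into a loop encircling the axis:
#'    its gap is at most the closure tolerance (by default the angular
#'    footprint of one voxel at the component's mean radius) and all its
#'    vertices stay outside half the MC radius (a dense blob near the
#'    axis fails this encircling test).
#' 4. `CCV`: a docked component has a gap strictly below
#'    `dav_ccv_gap_deg` (180 degrees), i.e. covers more than half the
#'    circumference without fully encircling the MC.
#' 5. `DAV`: at least one docked component exists (necessarily with gap
#'    >= 180 degrees).
#' 6. `NAKED` otherwise.
#'
#' @param components List from [detect_membrane_components()].
#' @param dockings Parallel list of `docking_result`.
#' @param gaps Parallel list of `gap_result` (entries may be `NULL` for
#'   components with too few theta samples).
#' @param frame A [centriole_frame].
#' @param config An [analysis_config()].
#' @param volume Optional [label_volume] (voxel size for the closure
#'   tolerance default; taken from the frame-fit otherwise).
#' @param voxel_size_nm Voxel size used for the closure default when
#'   `volume` is absent.
#' @return A `stage_classification`: list with `stage`, `evidence`,
#'   `classifying_component_id`.
#' @export
classify_mc_stage <- function(components, dockings, gaps, frame,
                              config = analysis_config(), volume = NULL,
                              voxel_size_nm = NULL) {
  stopifnot(length(components) == length(dockings),
            length(components) == length(gaps))
  if (length(components)) {
    ids_c <- vapply(components, `[[`, integer(1), "component_id")
    ids_d <- vapply(dockings, `[[`, integer(1), "component_id")
    if (!identical(ids_c, ids_d))
      stop("component ids of `components` and `dockings` do not match")
  }
  vs <- if (!is.null(volume)) volume$voxel_size_nm else voxel_size_nm
  docked <- which(vapply(dockings, `[[`, logical(1), "docked"))

  evidence <- list(max_coverage_deg = NA_real_, min_gap_deg = NA_real_,
                   cap_occupancy = NA_real_, max_axial_extent_nm = NA_real_)
  decide <- function(stage, id) {
    structure(list(stage = stage, evidence = evidence,
                   classifying_component_id = id),
              class = "stage_classification")
  }
  if (!length(docked)) return(decide("NAKED", NA_integer_))

  axial_extent <- vapply(docked, function(i) {
    z <- to_cylindrical(components[[i]]$voxels_world, frame)[, "z_nm"]
    max(z)
  }, numeric(1))
  evidence$max_axial_extent_nm <- max(axial_extent)
  gap_of <- vapply(docked, function(i)
    if (is.null(gaps[[i]])) NA_real_ else gaps[[i]]$gap_deg, numeric(1))
  evidence$min_gap_deg <- suppressWarnings(min(gap_of, na.rm = TRUE))
  evidence$max_coverage_deg <- 360 - evidence$min_gap_deg

  # (1) cilium
  i_cil <- which(axial_extent > config$cilium_axial_extent_nm)
  if (length(i_cil))
    return(decide("CILIUM",
                  components[[docked[i_cil[1]]]]$component_id))
  # (2) ciliary vesicle: distal-disk coverage in axial projection
  occ <- vapply(docked, function(i)
    distal_disk_occupancy(components[[i]], frame, config, vs), numeric(1))
  evidence$cap_occupancy <- max(occ)
  i_cv <- which(occ >= config$cv_occupancy_fraction)
  if (length(i_cv))
    return(decide("CV", components[[docked[i_cv[1]]]]$component_id))
  # (3) toroid: closed loop encircling the axis
  for (j in seq_along(docked)) {
    i <- docked[j]
    g <- gaps[[i]]
    if (is.null(g)) next
    closure <- config$tcv_closure_deg
    if (is.null(closure))
      closure <- (vs / g$mean_radial_nm) * 180 / pi
    if (g$gap_deg <= closure && g$min_radial_nm > 0.5 * frame$mc_radius_nm)
      return(decide("TCV", components[[i]]$component_id))
  }
  # (4) CCV
  i_ccv <- which(!is.na(gap_of) & gap_of < config$dav_ccv_gap_deg)
  if (length(i_ccv)) {
    best <- i_ccv[which.min(gap_of[i_ccv])]
    return(decide("CCV", components[[docked[best]]]$component_id))
  }
  # (5) DAV
  decide("DAV", components[[docked[1]]]$component_id)
}

# Fraction of the distal disk (radius mc_radius) covered by the
# component's voxels in axial projection, considering voxels with
# 0 < z <= cilium_axial_extent_nm. Cells of size 2 voxels.
#' @noRd
distal_disk_occupancy <- function(component, frame, config, voxel_size_nm) {
  cyl <- to_cylindrical(component$voxels_world, frame)
  sel <- cyl[, "z_nm"] > 0 & cyl[, "z_nm"] <= config$cilium_axial_extent_nm
  if (!any(sel)) return(0)
  cell <- 2 * voxel_size_nm
  rmax <- frame$mc_radius_nm
  m <- ceiling(rmax / cell)
  ax <- seq(-m, m) * cell  # cell centres
  grid <- expand.grid(gx = ax, gy = ax)
  in_disk <- sqrt(grid$gx^2 + grid$gy^2) <= rmax
  grid <- grid[in_disk, ]
  th <- cyl[sel, "theta_deg"] * pi / 180
  px <- cyl[sel, "r_nm"] * cos(th)
  py <- cyl[sel, "r_nm"] * sin(th)
  ix <- round(px / cell); iy <- round(py / cell)
  occupied <- unique(paste(ix, iy))
  keys <- paste(round(grid$gx / cell), round(grid$gy / cell))
  mean(keys %in% occupied)
}

#' Plasma-membrane docking of DA tips
#'
#' A DA tip is PM-docked when its minimal distance to the plasma-membrane
#' surface is at most `dock_threshold_nm`. Returns the docked tip ids; the
#' `"summary"` attribute is `"all"`, `"partial"` or `"none"` (and
#' `"absent"` when the volume has no pm label, in which case an empty
#' result is returned with a note).
#'
#' @param volume A [label_volume].
#' @param tips Data frame from [detect_da_tips()].
#' @param config An [analysis_config()].
#' @return Integer vector of PM-docked `da_id`s.
#' @export
detect_pm_docking <- function(volume, tips, config = analysis_config()) {
  if (!"pm" %in% names(volume$label_map) ||
      !any(volume$data == volume$label_map[["pm"]])) {
    out <- integer(0)
    attr(out, "summary") <- "absent"
    return(out)
  }
  mesh <- extract_surface_mesh(volume, "pm", fill = FALSE,
                               smooth_iters = config$smooth_iters)
  pts <- as.matrix(tips[, c("tip_x_nm", "tip_y_nm", "tip_z_nm")])
  d <- .point_mesh_min_dist(pts, mesh$vertices, mesh$faces)
  ids <- tips$da_id[d <= config$dock_threshold_nm]
  attr(ids, "summary") <- if (length(ids) == nrow(tips)) "all"
    else if (length(ids)) "partial" else "none"
  attr(ids, "distances_nm") <- d
  ids
}
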