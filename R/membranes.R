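# Membrane component detection and per-structure measurements: Feret
# diameter, docking distance to DA tips, C-shape gap angle, surface area,
# enlargement flags.

#' Analysis configuration
#'
#' Defaults encode the vEM analysis rules: membranes dock when 30 nm or
#' less from a DA distal end; vesicles count when larger than 30 nm in
#' diameter and present in at least two consecutive sections; a docked
#' structure with a gap below 180 degrees (coverage above 50% of the
#' circumference) is a CCV; enlargement is flagged above mean + 1 SD of
#' the reference group.
#'
#' @param dock_threshold_nm Docking distance threshold (nm).
#' @param min_vesicle_diameter_nm Minimal vesicle (Feret) diameter; the
#'   filter keeps components strictly larger.
#' @param min_z_slices Minimal number of consecutive sections a component
#'   must span.
#' @param dav_ccv_gap_deg Gap threshold separating CCV (gap strictly
#'   below) from DAV.
#' @param tcv_closure_deg Angular continuity tolerance for closed loops;
#'   `NULL` (default) uses the angular footprint of one voxel at the
#'   component's mean radius.
#' @param cilium_axial_extent_nm Axial extent above the distal end beyond
#'   which a docked component is called a cilium.
#' @param enlargement_sd_multiplier SD multiplier for enlargement flags.
#' @param cv_occupancy_fraction Fraction of the distal disk that must be
#'   covered (in axial projection) to call a ciliary vesicle.
#' @param smooth_iters Box-smoothing passes for isosurface extraction.
#' @param theta_source `"mesh"` (default: mesh vertices) or `"voxels"`
#'   (voxel centres) as the sample set for gap determination.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(dock_threshold_nm = 30,
                            min_vesicle_diameter_nm = 30,
                            min_z_slices = 2L,
                            dav_ccv_gap_deg = 180,
                            tcv_closure_deg = NULL,
                            cilium_axial_extent_nm = 500,
                            enlargement_sd_multiplier = 1,
                            cv_occupancy_fraction = 0.9,
                            smooth_iters = 1L,
                            theta_source = c("mesh", "voxels")) {
  stopifnot(dock_threshold_nm > 0, min_vesicle_diameter_nm > 0,
            min_z_slices >= 1, dav_ccv_gap_deg > 0, dav_ccv_gap_deg < 360,
            cilium_axial_extent_nm > 0, enlargement_sd_multiplier > 0,
            cv_occupancy_fraction > 0, cv_occupancy_fraction <= 1)
  if (!is.null(tcv_closure_deg)) stopifnot(tcv_closure_deg > 0)
  structure(list(
    dock_threshold_nm = dock_threshold_nm,
    min_vesicle_diameter_nm = min_vesicle_diameter_nm,
    min_z_slices = as.integer(min_z_slices),
    dav_ccv_gap_deg = dav_ccv_gap_deg,
    tcv_closure_deg = tcv_closure_deg,
    cilium_axial_extent_nm = cilium_axial_extent_nm,
    enlargement_sd_multiplier = enlargement_sd_multiplier,
    cv_occupancy_fraction = cv_occupancy_fraction,
    smooth_iters = as.integer(smooth_iters),
    theta_source = match.arg(theta_source)), class = "analysis_config")
}

# 3D Feret (maximal pairwise point) diameter. Exact for modest point
# counts; for large sets the candidate set is restricted to directional
# extreme points (exact for the extreme pairs these directions expose,
# lower-bounded by the projection estimate to well under a voxel).
#' @noRd
feret_diameter <- function(P) {
  n <- nrow(P)
  if (n < 2) return(0)
  if (n > 1500) {
    dirs <- fibonacci_directions(200)
    proj <- P %*% t(dirs)
    cand <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    P <- P[cand, , drop = FALSE]
    n <- nrow(P)
  }
  g <- P %*% t(P)
  sq <- diag(g)
  d2 <- outer(sq, sq, `+`) - 2 * g
  sqrt(max(d2, 0))
}

#' @noRd
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

#' Detect and filter membrane components
#'
#' 26-connected components of the membrane label. Components are kept when
#' they span at least `min_z_slices` consecutive sections and have a Feret
#' diameter strictly greater than `min_vesicle_diameter_nm`; excluded
#' components are recorded (with the failing criterion) in the
#' `"excluded"` attribute of the result. Survivors carry their extracted
#' surface mesh and mesh surface area.
#'
#' @param volume A [label_volume].
#' @param config An [analysis_config()].
#' @return List of `membrane_component` objects (possibly empty), each
#'   with `component_id`, `voxels_zyx`, `voxels_world`, `mesh`,
#'   `diameter_nm`, `z_slice_count`, `surface_area_nm2`, `centroid_nm`.
#' @export
detect_membrane_components <- function(volume, config = analysis_config()) {
  mask <- role_mask(volume, "membrane")
  excluded <- data.frame(component_id = integer(0), reason = character(0),
                         diameter_nm = numeric(0), z_slice_count = integer(0))
  if (!any(mask == 1L)) {
    return(structure(list(), excluded = excluded))
  }
  lab <- .cc_label_26(mask, dim(mask))
  ncomp <- attr(lab, "n_components")
  idx_all <- which(lab > 0)
  comp_all <- lab[idx_all]
  ai_all <- arrayInd(idx_all, dim(mask))
  out <- list()
  for (k in seq_len(ncomp)) {
    sel <- comp_all == k
    ai <- ai_all[sel, , drop = FALSE]
    W <- voxel_world_coords(volume, ai)
    z_slices <- length(unique(ai[, 1]))
    diam <- feret_diameter(W)
    if (z_slices < config$min_z_slices) {
      excluded <- rbind(excluded, data.frame(
        component_id = k, reason = "too_few_z_slices",
        diameter_nm = diam, z_slice_count = z_slices))
      next
    }
    if (diam <= config$min_vesicle_diameter_nm) {
      excluded <- rbind(excluded, data.frame(
        component_id = k, reason = "diameter_at_or_below_minimum",
        diameter_nm = diam, z_slice_count = z_slices))
      next
    }
    lo <- apply(ai, 2, min); hi <- apply(ai, 2, max)
    sub <- array(0L, dim = hi - lo + 1L)
    sub[ai - matrix(lo - 1L, nrow(ai), 3, byrow = TRUE)] <- 1L
    blockers <- crop_other_labels(volume, volume$label_map[["membrane"]],
                                  lo, hi)
    mesh <- mesh_binary_mask(sub, volume$voxel_size_nm, offset_zyx = lo,
                             fill = TRUE, smooth_iters = config$smooth_iters,
                             blockers = blockers)
    out[[length(out) + 1L]] <- structure(list(
      component_id = k,
      voxels_zyx = ai,
      voxels_world = W,
      mesh = mesh,
      diameter_nm = diam,
      z_slice_count = z_slices,
      surface_area_nm2 = mesh_area(mesh),
      centroid_nm = colMeans(W)), class = "membrane_component")
  }
  structure(out, excluded = excluded)
}

#' Surface area of a membrane component
#' @param component A `membrane_component`.
#' @return Surface area in nm^2 (sum of isosurface triangle areas).
#' @export
surface_area <- function(component) {
  if (inherits(component, "surface_mesh")) return(mesh_area(component))
  if (is.null(component$mesh) || nrow(component$mesh$faces) == 0)
    stop("component has no mesh")
  component$surface_area_nm2
}

# ---- C-shape gap -----------------------------------------------------------

#' Largest circular gap of an angle multiset
#'
#' Sorts the angles ascending and returns the largest difference between
#' consecutive values, including the wrap-around term; this is the C-shape
#' gap of a membrane's azimuth samples.
#'
#' @param theta_deg Numeric vector of angles in degrees (any real values;
#'   reduced mod 360). At least 3 values.
#' @return List with `gap_deg`, `coverage_deg` (= 360 - gap),
#'   `gap_interval` (`c(start, end)` of the empty arc, counter-clockwise),
#'   `n_theta_samples`.
#' @export
theta_gap <- function(theta_deg) {
  theta_deg <- theta_deg[!is.na(theta_deg)]
  if (length(theta_deg) < 3)
    stop("gap determination needs at least 3 theta samples")
  th <- sort(theta_deg %% 360)
  d <- c(diff(th), th[1] + 360 - th[length(th)])
  i <- which.max(d)
  gap <- d[i]
  start <- th[i]
  end <- if (i == length(th)) th[1] else th[i + 1]
  list(gap_deg = gap, coverage_deg = 360 - gap,
       gap_interval = c(start_deg = start, end_deg = end),
       n_theta_samples = length(th))
}

#' C-shape gap of a membrane component
#'
#' Transforms the component's mesh vertices (or voxel centres, per
#' `config$theta_source`) to cylindrical coordinates in the centriole
#' frame and computes the largest circular spacing of the sorted azimuths.
#'
#' @param component A `membrane_component` (or a `surface_mesh`).
#' @param frame A [centriole_frame].
#' @param config An [analysis_config()].
#' @return A `gap_result`: list with `component_id`, `gap_deg`,
#'   `coverage_deg`, `gap_interval`, `n_theta_samples`, `min_radial_nm`,
#'   `mean_radial_nm`.
#' @export
compute_gap <- function(component, frame, config = analysis_config()) {
  if (inherits(component, "surface_mesh")) {
    pts <- component$vertices
    cid <- NA_integer_
  } else if (config$theta_source == "voxels") {
    pts <- component$voxels_world
    cid <- component$component_id
  } else {
    pts <- component$mesh$vertices
    cid <- component$component_id
  }
  cyl <- to_cylindrical(pts, frame)
  g <- theta_gap(cyl[, "theta_deg"])
  structure(c(list(component_id = cid), g,
              list(min_radial_nm = min(cyl[, "r_nm"]),
                   mean_radial_nm = mean(cyl[, "r_nm"]))),
            class = "gap_result")
}

#' @noRd
theta_in_gap <- function(theta_deg, gap_interval) {
  span <- (gap_interval[["end_deg"]] - gap_interval[["start_deg"]]) %% 360
  rel <- (theta_deg - gap_interval[["start_deg"]]) %% 360
  rel > 0 & rel < span
}

# ---- docking ---------------------------------------------------------------

#' Docking assessment of a membrane component against DA tips
#'
#' Computes the minimal Euclidean distance from each DA tip point to the
#' component's mesh surface (exact point-to-triangle). When a `gap` result
#' is supplied, tips whose azimuth lies strictly inside the gap interval
#' are excluded from the docking decision and from mean-distance
#' summaries. The component is docked when the minimum over non-excluded
#' tips is at most `config$dock_threshold_nm`.
#'
#' @param component A `membrane_component`.
#' @param tips Data frame from [detect_da_tips()].
#' @param config An [analysis_config()].
#' @param gap Optional `gap_result` for gap exclusion (used for CCVs).
#' @return A `docking_result`: list with `distances` (data frame `da_id`,
#'   `min_distance_nm`, `excluded`), `docked`, `closest_da_id`,
#'   `min_distance_nm`, `excluded_da_ids`.
#' @export
docking_assessment <- function(component, tips, config = analysis_config(),
                               gap = NULL) {
  if (is.null(tips) || nrow(tips) == 0) stop("no DA tips supplied")
  pts <- as.matrix(tips[, c("tip_x_nm", "tip_y_nm", "tip_z_nm")])
  d <- .point_mesh_min_dist(pts, component$mesh$vertices,
                            component$mesh$faces)
  excluded <- rep(FALSE, nrow(tips))
  if (!is.null(gap))
    excluded <- theta_in_gap(tips$theta_deg, gap$gap_interval)
  usable <- which(!excluded)
  if (!length(usable)) usable <- seq_len(nrow(tips))  # degenerate: all in gap
  i_min <- usable[which.min(d[usable])]
  structure(list(
    component_id = component$component_id,
    distances = data.frame(da_id = tips$da_id, min_distance_nm = d,
                           excluded = excluded),
    docked = d[i_min] <= config$dock_threshold_nm,
    closest_da_id = tips$da_id[i_min],
    min_distance_nm = d[i_min],
    excluded_da_ids = tips$da_id[excluded]), class = "docking_result")
}

# ---- enlargement and per-cell summaries ------------------------------------

#' Enlargement flags relative to a reference cohort
#'
#' A surface area is flagged when strictly greater than
#' `mean(reference) + multiplier * sd(reference)` (sample SD, n - 1).
#'
#' @param areas_nm2 Areas to test.
#' @param reference_areas_nm2 Reference areas (>= 2 values).
#' @param config An [analysis_config()] supplying the SD multiplier.
#' @return Logical vector, one flag per area.
#' @export
enlargement_flags <- function(areas_nm2, reference_areas_nm2,
                              config = analysis_config()) {
  if (length(reference_areas_nm2) < 2)
    stop("reference needs at least 2 values for a sample SD")
  thr <- mean(reference_areas_nm2) +
    config$enlargement_sd_multiplier * sd(reference_areas_nm2)
  areas_nm2 > thr
}

#' Per-cell summary of docked membranes
#'
#' @param components List from [detect_membrane_components()].
#' @param dockings List of `docking_result`, parallel to `components`.
#' @param config An [analysis_config()].
#' @return List with `n_docked`, `docked_component_ids`, `areas_nm2`
#'   (docked components), `total_area_nm2`, `mean_docking_distance_nm`
#'   (mean over docked components' minimal non-excluded distances),
#'   `per_da_min_nm` (per-DA minimal distance over docked components,
#'   gap-excluded tips omitted).
#' @export
summarize_docked_membranes <- function(components, dockings,
                                       config = analysis_config()) {
  stopifnot(length(components) == length(dockings))
  docked <- which(vapply(dockings, `[[`, logical(1), "docked"))
  areas <- vapply(components[docked], `[[`, numeric(1), "surface_area_nm2")
  per_da <- NULL
  for (i in docked) {
    dd <- dockings[[i]]$distances
    v <- ifelse(dd$excluded, NA_real_, dd$min_distance_nm)
    per_da <- if (is.null(per_da)) v else pmin(per_da, v, na.rm = TRUE)
  }
  list(
    n_docked = length(docked),
    docked_component_ids = vapply(components[docked], `[[`, integer(1),
                                  "component_id"),
    areas_nm2 = areas,
    total_area_nm2 = sum(areas),
    mean_docking_distance_nm = if (length(docked))
      mean(vapply(dockings[docked], `[[`, numeric(1), "min_distance_nm"))
      else NA_real_,
    per_da_min_nm = per_da)
}
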