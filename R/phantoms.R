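# Synthetic voxel phantoms of the mother centriole (MC), its nine distal
# appendages (DAs), and membrane intermediates, with exact analytic ground
# truth (gap angles, docking distances, surface areas, stage labels).
#
# All primitive geometry is defined in the centriole frame: origin at the
# centre of the MC distal face, +z pointing distal, theta measured from +x.
# The phantom may be rigidly rotated/translated into the world grid; ground
# truth carries the exact frame used.

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (need not be unit length).
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sa * K + (1 - ca) * (K %*% K)
}

#' Uniform random rotation matrix
#'
#' Drawn from the Haar measure on SO(3) via a normalized random quaternion.
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Membrane primitive for phantom construction
#'
#' Supported kinds and their parameters (all nm, centriole-frame
#' coordinates):
#' * `sphere`: `center_nm` (3-vector), `radius_nm`.
#' * `arc_torus`: `major_radius_nm` (R), `tube_radius_nm` (r < R),
#'   `arc_start_deg`, `arc_end_deg` (counter-clockwise span < 360; the arc
#'   ends are capped flat at the limiting angles), `z_nm` (torus plane).
#' * `toroid`: closed torus; `major_radius_nm`, `tube_radius_nm`, `z_nm`.
#' * `cap`: spherical dome; `radius_nm` (sphere radius), `standoff_nm`
#'   (sphere-centre height above the distal face), `z_cut_nm` (dome kept
#'   for z >= z_cut).
#' * `axial_tube`: cylinder shell around the axis; `radius_nm`,
#'   `length_nm`, `z_start_nm`.
#' * `sheet`: plane slab; `point_nm` (3-vector), `normal` (3-vector).
#'
#' Closed primitives (sphere, arc_torus, toroid) are rendered as an inward
#' shell whose outer boundary is the analytic surface and are hole-filled
#' before meshing downstream, so measured areas and docking distances are
#' directly comparable with the analytic values. Open primitives (cap,
#' axial_tube, sheet) are rendered as shells centred on the surface.
#'
#' @param kind Primitive kind (see above).
#' @param ... Kind-specific parameters.
#' @param role `"membrane"` (default) or `"pm"` for plasma-membrane sheets.
#' @param filled If `TRUE`, render the primitive as a filled solid instead
#'   of a shell (robustness testing).
#' @return A `membrane_primitive`.
#' @export
membrane_primitive <- function(kind = c("sphere", "arc_torus", "toroid",
                                        "cap", "axial_tube", "sheet"),
                               ..., role = c("membrane", "pm"),
                               filled = FALSE) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  p <- list(...)
  need <- function(nms) {
    missing <- setdiff(nms, names(p))
    if (length(missing))
      stop(kind, " primitive requires: ", paste(missing, collapse = ", "))
  }
  if (kind == "sphere") {
    need(c("center_nm", "radius_nm"))
    stopifnot(p$radius_nm > 0, length(p$center_nm) == 3)
  } else if (kind %in% c("arc_torus", "toroid")) {
    need(c("major_radius_nm", "tube_radius_nm"))
    if (is.null(p$z_nm)) p$z_nm <- 0
    stopifnot(p$tube_radius_nm < p$major_radius_nm)
    if (kind == "arc_torus") {
      need(c("arc_start_deg", "arc_end_deg"))
      p$arc_start_deg <- p$arc_start_deg %% 360
      span <- (p$arc_end_deg - p$arc_start_deg) %% 360
      if (span == 0)
        stop("arc_torus span must be in (0, 360); use kind 'toroid' for ",
             "a closed torus")
      p$arc_span_deg <- span
    } else {
      p$arc_span_deg <- 360
    }
  } else if (kind == "cap") {
    need(c("radius_nm", "standoff_nm"))
    if (is.null(p$z_cut_nm)) p$z_cut_nm <- -60
    stopifnot(p$radius_nm > 0)
  } else if (kind == "axial_tube") {
    need(c("radius_nm", "length_nm"))
    if (is.null(p$z_start_nm)) p$z_start_nm <- -60
    stopifnot(p$radius_nm > 0, p$length_nm > 0)
  } else if (kind == "sheet") {
    need(c("point_nm", "normal"))
    p$normal <- p$normal / sqrt(sum(p$normal^2))
  }
  structure(c(list(kind = kind, role = role, filled = filled), p),
            class = "membrane_primitive")
}

#' Phantom specification
#'
#' Defaults reproduce the imaging conditions the pipeline targets: an MC
#' cylinder of 300 nm diameter and 500 nm length with nine radial DAs and
#' 9 nm isotropic voxels.
#'
#' @param mc_diameter_nm,mc_length_nm MC cylinder dimensions.
#' @param n_da Number of distal appendages (>= 1).
#' @param da_length_nm Radial DA pin length beyond the MC wall.
#' @param da_radius_nm DA pin (cylinder) radius.
#' @param da_tip_offset_nm Axial offset of the DA ring below the distal face.
#' @param da_phase_deg Azimuth of the first DA.
#' @param voxel_size_nm Isotropic voxel size.
#' @param membranes List of [membrane_primitive()] objects.
#' @param pm_plane_nm Optional plasma-membrane plane distance above the
#'   distal face (normal along the axis); equivalent to adding a `sheet`
#'   primitive with role `"pm"`.
#' @param shell_thickness_nm Membrane shell thickness (default 2 voxels).
#' @param orientation 3 x 3 rotation matrix applied to the whole phantom
#'   (columns = frame axes expressed in world coordinates).
#' @param rng_seed Integer recorded in the spec (phantom construction is
#'   deterministic; the seed matters for [sample_cohort()]).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(mc_diameter_nm = 300, mc_length_nm = 500,
                         n_da = 9L, da_length_nm = 100, da_radius_nm = 20,
                         da_tip_offset_nm = 50, da_phase_deg = 0,
                         voxel_size_nm = 9, membranes = list(),
                         pm_plane_nm = NULL,
                         shell_thickness_nm = 2 * voxel_size_nm,
                         orientation = diag(3), rng_seed = 1L) {
  stopifnot(mc_diameter_nm > 0, mc_length_nm > 0, voxel_size_nm > 0,
            n_da >= 1, da_length_nm > 0, da_radius_nm > 0)
  if (!is.matrix(orientation) || any(dim(orientation) != c(3, 3)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("`orientation` must be a 3 x 3 rotation matrix")
  if (length(membranes) && !all(vapply(membranes, inherits, logical(1),
                                       "membrane_primitive")))
    stop("`membranes` must be a list of membrane_primitive objects")
  structure(list(
    mc_diameter_nm = mc_diameter_nm, mc_length_nm = mc_length_nm,
    n_da = as.integer(n_da), da_length_nm = da_length_nm,
    da_radius_nm = da_radius_nm, da_tip_offset_nm = da_tip_offset_nm,
    da_phase_deg = da_phase_deg, voxel_size_nm = voxel_size_nm,
    membranes = membranes, pm_plane_nm = pm_plane_nm,
    shell_thickness_nm = shell_thickness_nm, orientation = orientation,
    rng_seed = as.integer(rng_seed)), class = "phantom_spec")
}

# ---- analytic ground truth -------------------------------------------------

#' @noRd
primitive_area_nm2 <- function(prim) {
  switch(prim$kind,
    sphere = 4 * pi * prim$radius_nm^2,
    arc_torus = 4 * pi^2 * prim$major_radius_nm * prim$tube_radius_nm *
      prim$arc_span_deg / 360,
    toroid = 4 * pi^2 * prim$major_radius_nm * prim$tube_radius_nm,
    cap = {
      z_top <- prim$standoff_nm + prim$radius_nm
      2 * pi * prim$radius_nm * (z_top - prim$z_cut_nm)
    },
    axial_tube = 2 * pi * prim$radius_nm * prim$length_nm,
    sheet = NA_real_)
}

#' @noRd
primitive_gap_deg <- function(prim) {
  switch(prim$kind,
    arc_torus = 360 - prim$arc_span_deg,
    toroid = 0,
    NA_real_)
}

# Analytic Euclidean distance from frame-coordinate points (n x 3) to the
# primitive's solid/surface (0 inside closed solids).
#' @noRd
primitive_distance <- function(prim, pts) {
  pts <- rbind(pts)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (prim$kind == "sphere") {
    d <- sqrt((x - prim$center_nm[1])^2 + (y - prim$center_nm[2])^2 +
              (z - prim$center_nm[3])^2) - prim$radius_nm
    return(pmax(d, 0))
  }
  if (prim$kind %in% c("arc_torus", "toroid")) {
    R <- prim$major_radius_nm; r <- prim$tube_radius_nm
    zz <- z - prim$z_nm
    rho <- sqrt(x^2 + y^2)
    theta <- (atan2(y, x) * 180 / pi) %% 360
    d_curve <- sqrt((rho - R)^2 + zz^2)
    if (prim$kind == "toroid") return(pmax(d_curve - r, 0))
    a0 <- prim$arc_start_deg; span <- prim$arc_span_deg
    rel <- (theta - a0) %% 360
    inspan <- rel <= span
    d <- ifelse(inspan, pmax(d_curve - r, 0), Inf)
    # flat end faces at both limiting angles
    for (ang in c(a0, (a0 + span) %% 360)) {
      arad <- ang * pi / 180
      e <- c(R * cos(arad), R * sin(arad), prim$z_nm)     # disk centre
      tvec <- c(-sin(arad), cos(arad), 0)                  # tangent
      rel_p <- cbind(x - e[1], y - e[2], z - e[3])
      s <- rel_p %*% tvec
      perp <- rel_p - outer(as.vector(s), tvec)
      q <- sqrt(rowSums(perp^2))
      d_end <- sqrt(pmax(q - r, 0)^2 + as.vector(s)^2)
      d <- pmin(d, d_end)
    }
    return(d)
  }
  if (prim$kind == "cap") {
    ctr <- c(0, 0, prim$standoff_nm)
    v <- cbind(x - ctr[1], y - ctr[2], z - ctr[3])
    vn <- sqrt(rowSums(v^2))
    closest_z <- ctr[3] + prim$radius_nm * v[, 3] / pmax(vn, 1e-12)
    on_zone <- closest_z >= prim$z_cut_nm
    d_sphere <- abs(vn - prim$radius_nm)
    # rim circle at z = z_cut
    a <- sqrt(max(prim$radius_nm^2 - (prim$z_cut_nm - ctr[3])^2, 0))
    rho <- sqrt(x^2 + y^2)
    d_rim <- sqrt((rho - a)^2 + (z - prim$z_cut_nm)^2)
    return(ifelse(on_zone, d_sphere, d_rim))
  }
  if (prim$kind == "axial_tube") {
    rho <- sqrt(x^2 + y^2)
    zc <- pmin(pmax(z, prim$z_start_nm), prim$z_start_nm + prim$length_nm)
    return(sqrt((rho - prim$radius_nm)^2 + (z - zc)^2))
  }
  if (prim$kind == "sheet") {
    d <- abs((x - prim$point_nm[1]) * prim$normal[1] +
             (y - prim$point_nm[2]) * prim$normal[2] +
             (z - prim$point_nm[3]) * prim$normal[3])
    return(d)
  }
  stop("unknown primitive kind")
}

# Points sampled on the primitive surface (for the analytic
# primitive-contact grouping used by the ground-truth stage rule).
#' @noRd
primitive_surface_points <- function(prim, n = 600) {
  u <- runif_det(n); v <- runif_det(n, offset = 0.5)
  if (prim$kind == "sphere") {
    zs <- 2 * u - 1
    t <- 2 * pi * v
    r <- sqrt(pmax(1 - zs^2, 0))
    return(cbind(prim$center_nm[1] + prim$radius_nm * r * cos(t),
                 prim$center_nm[2] + prim$radius_nm * r * sin(t),
                 prim$center_nm[3] + prim$radius_nm * zs))
  }
  if (prim$kind %in% c("arc_torus", "toroid")) {
    a0 <- if (prim$kind == "toroid") 0 else prim$arc_start_deg
    span <- prim$arc_span_deg
    th <- (a0 + span * u) * pi / 180
    ph <- 2 * pi * v
    R <- prim$major_radius_nm; r <- prim$tube_radius_nm
    rho <- R + r * cos(ph)
    return(cbind(rho * cos(th), rho * sin(th),
                 prim$z_nm + r * sin(ph)))
  }
  if (prim$kind == "cap") {
    z_top <- prim$standoff_nm + prim$radius_nm
    zs <- prim$z_cut_nm + (z_top - prim$z_cut_nm) * u
    r <- sqrt(pmax(prim$radius_nm^2 - (zs - prim$standoff_nm)^2, 0))
    t <- 2 * pi * v
    return(cbind(r * cos(t), r * sin(t), zs))
  }
  if (prim$kind == "axial_tube") {
    zs <- prim$z_start_nm + prim$length_nm * u
    t <- 2 * pi * v
    return(cbind(prim$radius_nm * cos(t), prim$radius_nm * sin(t), zs))
  }
  if (prim$kind == "sheet") {
    b <- pracma_nullspace(prim$normal)
    s <- 2000 * (u - 0.5); t <- 2000 * (v - 0.5)
    return(cbind(prim$point_nm[1] + s * b[1, 1] + t * b[1, 2],
                 prim$point_nm[2] + s * b[2, 1] + t * b[2, 2],
                 prim$point_nm[3] + s * b[3, 1] + t * b[3, 2]))
  }
  stop("unknown primitive kind")
}

# deterministic low-discrepancy sequence (keeps ground truth independent of
# the session RNG state)
#' @noRd
runif_det <- function(n, offset = 0) {
  (((seq_len(n) - 0.5) * 0.6180339887498949 + offset) %% 1)
}

#' @noRd
pracma_nullspace <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- ref - sum(ref * n) * n
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(n[2] * b1[3] - n[3] * b1[2],
          n[3] * b1[1] - n[1] * b1[3],
          n[1] * b1[2] - n[2] * b1[1])
  cbind(b1, b2)
}

#' @noRd
da_tip_points_frame <- function(spec) {
  k <- seq_len(spec$n_da)
  th <- (spec$da_phase_deg + (k - 1) * 360 / spec$n_da) %% 360
  rad <- th * pi / 180
  r_tip <- spec$mc_diameter_nm / 2 + spec$da_length_nm
  cbind(x = r_tip * cos(rad), y = r_tip * sin(rad),
        z = -spec$da_tip_offset_nm)
}

# Ground-truth stage from the primitive set alone (closed-form; independent
# of voxelization). Membrane primitives are grouped by analytic surface
# contact (touching/overlapping primitives merge, as they will in the label
# volume); a group is docked if any member is within `dock_threshold_nm` of
# a DA tip.
#' @noRd
true_stage_from_spec <- function(spec, tip_dists, dock_threshold_nm = 30,
                                 cilium_axial_extent_nm = 500) {
  mems <- spec$membranes
  mems <- Filter(function(m) m$role == "membrane", mems)
  if (!length(mems)) return("NAKED")
  n <- length(mems)
  # contact grouping by sampled-surface to analytic-solid distance
  group <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      si <- primitive_surface_points(mems[[i]])
      dij <- min(primitive_distance(mems[[j]], si))
      sj <- primitive_surface_points(mems[[j]])
      dji <- min(primitive_distance(mems[[i]], sj))
      if (min(dij, dji) <= 2 * spec$voxel_size_nm)
        group[group == group[j]] <- group[i]
    }
  }
  mem_idx <- which(vapply(spec$membranes, function(m)
    m$role == "membrane", logical(1)))
  stage_rank <- c(NAKED = 0, DAV = 1, CCV = 2, TCV = 3, CV = 4, CILIUM = 5)
  best <- "NAKED"
  for (g in unique(group)) {
    members <- which(group == g)
    docked <- any(vapply(members, function(i)
      min(tip_dists[mem_idx[i], ]) <= dock_threshold_nm, logical(1)))
    if (!docked) next
    stg <- "DAV"
    for (i in members) {
      m <- mems[[i]]
      cand <- switch(m$kind,
        axial_tube = if (m$z_start_nm + m$length_nm > cilium_axial_extent_nm)
          "CILIUM" else "DAV",
        cap = "CV",
        toroid = "TCV",
        arc_torus = if (360 - m$arc_span_deg < 180) "CCV" else "DAV",
        "DAV")
      if (stage_rank[cand] > stage_rank[stg]) stg <- cand
    }
    if (stage_rank[stg] > stage_rank[best]) best <- stg
  }
  best
}

# ---- voxelization ----------------------------------------------------------

# conservative (rho_max, z_min, z_max) bounds of a primitive in frame coords
#' @noRd
primitive_bounds <- function(prim, shell) {
  t2 <- shell
  switch(prim$kind,
    sphere = {
      c_rho <- sqrt(sum(prim$center_nm[1:2]^2))
      list(rho = c_rho + prim$radius_nm,
           z = prim$center_nm[3] + c(-1, 1) * prim$radius_nm)
    },
    arc_torus = ,
    toroid = list(rho = prim$major_radius_nm + prim$tube_radius_nm,
                  z = prim$z_nm + c(-1, 1) * prim$tube_radius_nm),
    cap = list(rho = prim$radius_nm + t2,
               z = c(prim$z_cut_nm - t2,
                     prim$standoff_nm + prim$radius_nm + t2)),
    axial_tube = list(rho = prim$radius_nm + t2,
                      z = c(prim$z_start_nm,
                            prim$z_start_nm + prim$length_nm)),
    sheet = NULL)
}

# shell membership of frame-coordinate voxel centres for one primitive
#' @noRd
primitive_voxels <- function(prim, fx, fy, fz, shell) {
  if (prim$kind == "sphere") {
    d <- sqrt((fx - prim$center_nm[1])^2 + (fy - prim$center_nm[2])^2 +
              (fz - prim$center_nm[3])^2)
    inside <- d <= prim$radius_nm
    if (prim$filled) return(inside)
    return(inside & d >= prim$radius_nm - shell)
  }
  if (prim$kind %in% c("arc_torus", "toroid")) {
    R <- prim$major_radius_nm; r <- prim$tube_radius_nm
    zz <- fz - prim$z_nm
    rho <- sqrt(fx^2 + fy^2)
    d_curve <- sqrt((rho - R)^2 + zz^2)
    inside <- d_curve <= r
    if (prim$kind == "arc_torus") {
      theta <- (atan2(fy, fx) * 180 / pi) %% 360
      rel <- (theta - prim$arc_start_deg) %% 360
      inside <- inside & rel <= prim$arc_span_deg
      if (prim$filled) return(inside)
      ang_end <- pmin(rel, prim$arc_span_deg - rel) * pi / 180  # radians
      depth <- pmin(r - d_curve, R * ang_end)
      return(inside & depth <= shell)
    }
    if (prim$filled) return(inside)
    return(inside & d_curve >= r - shell)
  }
  if (prim$kind == "cap") {
    d <- sqrt(fx^2 + fy^2 + (fz - prim$standoff_nm)^2)
    abs(d - prim$radius_nm) <= shell / 2 & fz >= prim$z_cut_nm
  } else if (prim$kind == "axial_tube") {
    # outward shell: the inner leaflet is the analytic surface (the tube
    # encloses the structures it docks to)
    rho <- sqrt(fx^2 + fy^2)
    inz <- fz >= prim$z_start_nm & fz <= prim$z_start_nm + prim$length_nm
    if (prim$filled) return(rho <= prim$radius_nm + shell & inz)
    rho >= prim$radius_nm & rho <= prim$radius_nm + shell & inz
  } else if (prim$kind == "sheet") {
    d <- (fx - prim$point_nm[1]) * prim$normal[1] +
         (fy - prim$point_nm[2]) * prim$normal[2] +
         (fz - prim$point_nm[3]) * prim$normal[3]
    abs(d) <= shell / 2
  } else stop("unknown primitive kind")
}

#' Build a voxel phantom with ground truth
#'
#' Voxelizes the MC cylinder, the radial DA pins, all membrane primitives
#' and the optional plasma membrane into a [label_volume], applying the
#' total label precedence mc_body > da > membrane > pm over background.
#' The grid is sized automatically to contain every (non-sheet) primitive
#' with at least a 3-voxel margin.
#'
#' @param spec A [phantom_spec].
#' @return A list of class `phantom` with elements `volume` (the
#'   [label_volume]) and `truth` (ground truth: per-membrane analytic gap
#'   angles, surface areas, tip distances; DA tip points; the exact frame;
#'   the true stage).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size_nm
  shell <- spec$shell_thickness_nm
  r_mc <- spec$mc_diameter_nm / 2
  Q <- spec$orientation

  bounds <- list(
    list(rho = r_mc, z = c(-spec$mc_length_nm, 0)),
    list(rho = r_mc + spec$da_length_nm + spec$da_radius_nm,
         z = -spec$da_tip_offset_nm + c(-1, 1) * spec$da_radius_nm))
  for (m in spec$membranes) {
    b <- primitive_bounds(m, shell)
    if (!is.null(b)) bounds <- c(bounds, list(b))
  }
  if (!is.null(spec$pm_plane_nm))
    bounds <- c(bounds, list(list(rho = r_mc + spec$da_length_nm + 50,
                                  z = spec$pm_plane_nm + c(-1, 1) * shell)))
  z_all <- range(unlist(lapply(bounds, `[[`, "z")))
  zc <- mean(z_all)
  r_bound <- max(vapply(bounds, function(b)
    sqrt(b$rho^2 + max(abs(b$z - zc))^2), numeric(1)))
  half <- r_bound + 3 * vs
  n <- 2L * as.integer(ceiling(half / vs)) + 1L
  centre <- (n - 1) * vs / 2
  origin_world <- c(centre, centre, centre) - Q %*% c(0, 0, zc)

  axes_w <- (seq_len(n) - 1) * vs
  N <- n^3L
  # voxel order: z fastest, then y, then x (dim = c(nz, ny, nx), all = n)
  wz <- rep_len(axes_w, N)
  wy <- rep(rep(axes_w, each = n), times = n)
  wx <- rep(axes_w, each = n * n)
  dx <- wx - origin_world[1]; dy <- wy - origin_world[2]
  dz <- wz - origin_world[3]
  fx <- Q[1, 1] * dx + Q[2, 1] * dy + Q[3, 1] * dz
  fy <- Q[1, 2] * dx + Q[2, 2] * dy + Q[3, 2] * dz
  fz <- Q[1, 3] * dx + Q[2, 3] * dy + Q[3, 3] * dz

  lm <- default_label_map()
  labels <- integer(N)

  # paint lowest precedence first; later paints overwrite
  if (!is.null(spec$pm_plane_nm)) {
    sel <- abs(fz - spec$pm_plane_nm) <= shell / 2
    labels[sel] <- lm[["pm"]]
  }
  for (m in spec$membranes) {
    sel <- primitive_voxels(m, fx, fy, fz, shell)
    labels[sel] <- lm[[m$role]]
  }
  # DA pins: radial cylinders at the DA ring plane
  tipsF <- da_tip_points_frame(spec)
  th <- (spec$da_phase_deg + (seq_len(spec$n_da) - 1) * 360 / spec$n_da) *
    pi / 180
  band <- abs(fz + spec$da_tip_offset_nm) <= spec$da_radius_nm + vs
  rho_all <- sqrt(fx^2 + fy^2)
  band <- band & rho_all >= r_mc - 2 * vs - spec$da_radius_nm &
    rho_all <= r_mc + spec$da_length_nm + spec$da_radius_nm + vs
  bidx <- which(band)
  if (length(bidx)) {
    bx <- fx[bidx]; by <- fy[bidx]; bz <- fz[bidx]
    for (k in seq_len(spec$n_da)) {
      dirx <- cos(th[k]); diry <- sin(th[k])
      ax <- (r_mc - vs) * dirx; ay <- (r_mc - vs) * diry
      az <- -spec$da_tip_offset_nm
      # capsule end-cap centre set back by the pin radius so the rounded
      # end reaches the analytic tip radius r_mc + da_length; half a voxel
      # is added so the expected maximal voxel *centre* sits at the tip
      r_end <- r_mc + spec$da_length_nm - spec$da_radius_nm + vs / 2
      ux <- r_end * dirx - ax
      uy <- r_end * diry - ay
      len2 <- ux^2 + uy^2
      t <- pmin(pmax(((bx - ax) * ux + (by - ay) * uy) / len2, 0), 1)
      d2 <- (bx - (ax + t * ux))^2 + (by - (ay + t * uy))^2 + (bz - az)^2
      labels[bidx[d2 <= spec$da_radius_nm^2]] <- lm[["da"]]
    }
  }
  # MC body solid cylinder (highest precedence)
  sel <- rho_all <= r_mc & fz >= -spec$mc_length_nm & fz <= 0
  labels[sel] <- lm[["mc_body"]]

  dim(labels) <- c(n, n, n)
  vol <- label_volume(labels, vs)

  # ---- ground truth --------------------------------------------------------
  n_mem <- length(spec$membranes)
  tip_dists <- matrix(NA_real_, nrow = max(n_mem, 1), ncol = spec$n_da)
  if (n_mem) {
    for (i in seq_len(n_mem))
      tip_dists[i, ] <- primitive_distance(spec$membranes[[i]], tipsF)
  }
  truth <- structure(list(
    true_stage = true_stage_from_spec(spec, tip_dists),
    true_gap_deg = if (n_mem) vapply(spec$membranes, primitive_gap_deg,
                                     numeric(1)) else numeric(0),
    analytic_surface_area_nm2 = if (n_mem)
      vapply(spec$membranes, primitive_area_nm2, numeric(1)) else numeric(0),
    true_min_distance_nm = if (n_mem) tip_dists else
      matrix(numeric(0), 0, spec$n_da),
    da_tip_points_nm = t(Q %*% t(tipsF) + as.vector(origin_world)),
    frame = centriole_frame(
      origin_nm = as.vector(origin_world),
      axis = as.vector(Q %*% c(0, 0, 1)),
      reference = as.vector(Q %*% c(1, 0, 0)),
      mc_radius_nm = r_mc, mc_length_nm = spec$mc_length_nm),
    spec = spec), class = "phantom_truth")
  structure(list(volume = vol, truth = truth), class = "phantom")
}

# ---- canonical stage phantoms ---------------------------------------------

#' Canonical phantom specification for a ciliogenesis stage
#'
#' Builds a [phantom_spec] whose membranes realize one of the six stages
#' with geometry consistent with the docking rules: arcs and tori sit in
#' the DA ring plane 10 nm beyond the DA tips, DAVs are spheres docked at
#' a tip, the CV is a dome dipping below the distal face to reach the
#' tips, and the cilium is an axial tube joined to a docked toroidal base.
#'
#' @param stage One of `"NAKED"`, `"DAV"`, `"CCV"`, `"TCV"`, `"CV"`,
#'   `"CILIUM"`.
#' @param gap_deg C-shape gap for `"CCV"`/arc phantoms (also accepted for
#'   gap 0, which yields a closed toroid). Gaps of at least 180 degrees
#'   produce an arc that classifies as DAV by the coverage rule.
#' @param n_dav Number of docked spheres for `"DAV"`.
#' @param dav_radius_nm Sphere radius for `"DAV"`.
#' @param standoff_nm Analytic surface-to-tip docking standoff.
#' @param orientation Rotation applied to the phantom.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
stage_phantom_spec <- function(stage = c("NAKED", "DAV", "CCV", "TCV", "CV",
                                         "CILIUM"),
                               gap_deg = 153, n_dav = 1, dav_radius_nm = 45,
                               standoff_nm = 10, orientation = diag(3), ...) {
  stage <- match.arg(stage)
  n_dav <- as.integer(round(n_dav))
  base <- phantom_spec(orientation = orientation, ...)
  r_tip <- base$mc_diameter_nm / 2 + base$da_length_nm
  z_ring <- -base$da_tip_offset_nm
  tube_r <- 50
  R_major <- r_tip + standoff_nm + tube_r   # tips standoff_nm off the surface
  mems <- switch(stage,
    NAKED = list(),
    DAV = {
      lapply(seq_len(n_dav), function(k) {
        th <- (base$da_phase_deg + (k - 1) * 360 / base$n_da) * pi / 180
        rc <- r_tip + standoff_nm + dav_radius_nm
        membrane_primitive("sphere",
          center_nm = c(rc * cos(th), rc * sin(th), z_ring),
          radius_nm = dav_radius_nm)
      })
    },
    CCV = {
      if (gap_deg <= 0) {
        list(membrane_primitive("toroid", major_radius_nm = R_major,
                                tube_radius_nm = tube_r, z_nm = z_ring))
      } else {
        span <- 360 - gap_deg
        a0 <- (base$da_phase_deg - span / 2) %% 360
        list(membrane_primitive("arc_torus", major_radius_nm = R_major,
                                tube_radius_nm = tube_r,
                                arc_start_deg = a0,
                                arc_end_deg = (a0 + span) %% 360,
                                z_nm = z_ring))
      }
    },
    TCV = list(membrane_primitive("toroid", major_radius_nm = R_major,
                                  tube_radius_nm = tube_r, z_nm = z_ring)),
    CV = {
      # dome reaching down past the DA ring so its surface sits
      # standoff_nm from the tips
      standoff_c <- 100
      tip_to_centre <- sqrt(r_tip^2 + (z_ring - standoff_c)^2)
      list(membrane_primitive("cap",
        radius_nm = tip_to_centre - standoff_nm,
        standoff_nm = standoff_c, z_cut_nm = z_ring - 10))
    },
    CILIUM = list(
      # ciliary membrane sheath: an axial tube surrounding the DA ring,
      # its inner leaflet standoff_nm beyond the tips
      membrane_primitive("axial_tube",
        radius_nm = r_tip + standoff_nm,
        length_nm = 660, z_start_nm = z_ring - 10)))
  base$membranes <- mems
  base
}

# ---- cohorts ---------------------------------------------------------------

#' Sample a cohort of randomized phantoms
#'
#' Draws `n_cells` phantoms from a template specification with uniformly
#' sampled parameters and (optionally) uniformly random orientations.
#' Deterministic given `rng_seed`.
#'
#' @param template A `phantom_spec` (or a stage name accepted by
#'   [stage_phantom_spec()], in which case `parameter_ranges` may include
#'   stage-constructor parameters `gap_deg`, `dav_radius_nm`, `n_dav`).
#' @param n_cells Number of phantoms (>= 1).
#' @param parameter_ranges Named list of `c(min, max)` ranges for numeric
#'   [phantom_spec()] fields (e.g. `mc_diameter_nm`) or stage-constructor
#'   parameters.
#' @param rng_seed Integer seed.
#' @param random_orientation If `TRUE` (default) each cell gets a uniform
#'   random rigid rotation.
#' @return List of `phantom` objects (each with `$volume`, `$truth`);
#'   attribute `rng_seed` records the seed.
#' @export
sample_cohort <- function(template, n_cells, parameter_ranges = list(),
                          rng_seed = 1L, random_orientation = TRUE) {
  stopifnot(n_cells >= 1)
  if (!is.numeric(rng_seed) || length(rng_seed) != 1L || is.na(rng_seed))
    stop("`rng_seed` must be a single integer")
  if (length(parameter_ranges)) {
    ok <- vapply(parameter_ranges, function(r)
      is.numeric(r) && length(r) == 2 && r[2] >= r[1], logical(1))
    if (!all(ok)) stop("each parameter range must be c(min, max)")
  }
  stage_mode <- is.character(template)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(rng_seed)
  phantoms <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    draws <- lapply(parameter_ranges, function(r) runif(1, r[1], r[2]))
    ori <- if (random_orientation) random_rotation() else diag(3)
    if (stage_mode) {
      stage_args <- draws[names(draws) %in%
                            c("gap_deg", "dav_radius_nm", "standoff_nm",
                              "n_dav")]
      spec_args <- draws[setdiff(names(draws), names(stage_args))]
      spec <- do.call(stage_phantom_spec,
                      c(list(stage = template, orientation = ori),
                        stage_args, spec_args,
                        list(rng_seed = rng_seed)))
    } else {
      spec <- template
      for (nm in names(draws)) spec[[nm]] <- draws[[nm]]
      spec$orientation <- ori
      spec$rng_seed <- as.integer(rng_seed)
    }
    phantoms[[i]] <- build_phantom(spec)
  }
  attr(phantoms, "rng_seed") <- as.integer(rng_seed)
  phantoms
}
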