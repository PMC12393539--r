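# Centriole reference frame, cylindrical coordinates, DA tip detection and
# isosurface extraction.

#' Centriole reference frame
#'
#' @param origin_nm World coordinates (x, y, z, nm) of the centre of the MC
#'   distal face.
#' @param axis Unit 3-vector pointing distal.
#' @param reference Unit 3-vector orthogonal to `axis`, defining theta = 0.
#' @param mc_radius_nm,mc_length_nm MC cylinder dimensions.
#' @return A `centriole_frame`.
#' @export
centriole_frame <- function(origin_nm, axis, reference, mc_radius_nm,
                            mc_length_nm) {
  axis <- as.numeric(axis); reference <- as.numeric(reference)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9 ||
      abs(sqrt(sum(reference^2)) - 1) > 1e-9)
    stop("`axis` and `reference` must be unit vectors")
  if (abs(sum(axis * reference)) > 1e-9)
    stop("`reference` must be orthogonal to `axis`")
  stopifnot(mc_radius_nm > 0, mc_length_nm > 0)
  structure(list(origin_nm = as.numeric(origin_nm), axis = axis,
                 reference = reference, mc_radius_nm = mc_radius_nm,
                 mc_length_nm = mc_length_nm), class = "centriole_frame")
}

#' @export
print.centriole_frame <- function(x, ...) {
  cat(sprintf(paste0("<centriole_frame> origin (%.1f, %.1f, %.1f) nm, axis ",
                     "(%.3f, %.3f, %.3f), radius %.1f nm, length %.1f nm\n"),
              x$origin_nm[1], x$origin_nm[2], x$origin_nm[3],
              x$axis[1], x$axis[2], x$axis[3],
              x$mc_radius_nm, x$mc_length_nm))
  invisible(x)
}

#' Fit the centriole reference frame from a label volume
#'
#' The axis is the dominant principal direction of the mc_body voxel
#' centres, oriented so that the DA centroid projects toward the positive
#' (distal) end. The origin sits on the axis at the distal face: lateral
#' position from the centroid of the distal-most 10% of mc_body voxels,
#' axial position at the robust maximal axial extent plus half a voxel.
#' The theta = 0 reference is world +x projected off-axis (+y fallback).
#'
#' @param volume A [label_volume] with mc_body (>= 50 voxels) and da labels.
#' @return A [centriole_frame].
#' @export
fit_centriole_frame <- function(volume) {
  mc_idx <- which(volume$data == volume$label_map[["mc_body"]], arr.ind = TRUE)
  if (nrow(mc_idx) < 50)
    stop("mc_body label has fewer than 50 voxels; cannot fit a frame")
  da_idx <- which(volume$data == volume$label_map[["da"]], arr.ind = TRUE)
  if (nrow(da_idx) < 1)
    stop("no da label present; the distal end cannot be determined ",
         "(supply DA voxels or construct the frame manually)")
  P <- voxel_world_coords(volume, mc_idx)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  if (ev$values[1] / ev$values[2] < 1.2)
    stop("mc_body mask has no dominant axis (principal variance ratio < 1.2)")
  axis <- ev$vectors[, 1]
  da_ctr <- colMeans(voxel_world_coords(volume, da_idx))
  if (sum((da_ctr - ctr) * axis) < 0) axis <- -axis

  s <- as.vector(Pc %*% axis)
  s_face <- quantile(s, 0.995, names = FALSE) + volume$voxel_size_nm / 2
  distal <- s >= quantile(s, 0.9, names = FALSE)
  slab_ctr <- colMeans(P[distal, , drop = FALSE])
  lateral <- (slab_ctr - ctr) - sum((slab_ctr - ctr) * axis) * axis
  origin <- ctr + lateral + s_face * axis

  radial <- sqrt(rowSums((Pc - outer(s, axis))^2))
  mc_radius <- quantile(radial, 0.99, names = FALSE) + volume$voxel_size_nm / 2
  mc_length <- diff(quantile(s, c(0.005, 0.995), names = FALSE)) +
    volume$voxel_size_nm

  ref <- c(1, 0, 0)
  ref_perp <- ref - sum(ref * axis) * axis
  if (sqrt(sum(ref_perp^2)) < 0.1) {
    ref <- c(0, 1, 0)
    ref_perp <- ref - sum(ref * axis) * axis
  }
  ref_perp <- ref_perp / sqrt(sum(ref_perp^2))
  centriole_frame(origin, axis, ref_perp, mc_radius, mc_length)
}

#' Transform world points to cylindrical coordinates
#'
#' r is the distance from the axis; theta is measured from the reference
#' direction, right-handed about the axis, in `[0, 360)`; z is the signed
#' distance along the axis from the origin (positive distal). Points on
#' the axis get theta = 0 by convention.
#'
#' @param points_nm Numeric n x 3 matrix of world (x, y, z) in nm.
#' @param frame A [centriole_frame].
#' @return n x 3 matrix with columns `r_nm`, `theta_deg`, `z_nm`.
#' @export
to_cylindrical <- function(points_nm, frame) {
  P <- rbind(points_nm)
  e1 <- frame$reference
  e3 <- frame$axis
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  D <- sweep(P, 2, frame$origin_nm)
  z <- as.vector(D %*% e3)
  u <- as.vector(D %*% e1)
  v <- as.vector(D %*% e2)
  r <- sqrt(u^2 + v^2)
  theta <- ifelse(r < 1e-12, 0, (atan2(v, u) * 180 / pi) %% 360)
  cbind(r_nm = r, theta_deg = theta, z_nm = z)
}

#' Inverse of [to_cylindrical()]
#' @param cyl n x 3 matrix with columns `r_nm`, `theta_deg`, `z_nm`.
#' @param frame A [centriole_frame].
#' @return n x 3 matrix of world (x, y, z) coordinates in nm.
#' @export
from_cylindrical <- function(cyl, frame) {
  cyl <- rbind(cyl)
  e1 <- frame$reference
  e3 <- frame$axis
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  th <- cyl[, 2] * pi / 180
  P <- outer(cyl[, 1] * cos(th), e1) + outer(cyl[, 1] * sin(th), e2) +
    outer(cyl[, 3], e3)
  sweep(P, 2, frame$origin_nm, `+`)
}

#' Detect distal-appendage tips
#'
#' Each DA is one 26-connected component of the da label. The tip point is
#' the centroid of the component's voxel centres lying within one voxel of
#' its maximal radial distance from the axis: averaging over the distal
#' voxel band removes the grid jitter a single farthest-voxel pick suffers
#' at this voxel size, while remaining fully deterministic. Tips are
#' returned sorted by azimuth.
#'
#' @param volume A [label_volume] with a da label.
#' @param frame A [centriole_frame].
#' @return Data frame with columns `da_id`, `tip_x_nm`, `tip_y_nm`,
#'   `tip_z_nm`, `theta_deg`, `radial_nm`, `axial_nm`, `n_voxels`.
#' @export
detect_da_tips <- function(volume, frame) {
  mask <- role_mask(volume, "da")
  lab <- .cc_label_26(mask, dim(mask))
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0) stop("no distal-appendage components found")
  idx <- which(lab > 0)
  comp <- lab[idx]
  ai <- arrayInd(idx, dim(mask))
  W <- voxel_world_coords(volume, ai)
  cyl <- to_cylindrical(W, frame)
  tips <- do.call(rbind, lapply(seq_len(ncomp), function(k) {
    sel <- which(comp == k)
    r <- cyl[sel, 1]
    band <- sel[r >= max(r) - volume$voxel_size_nm]
    ctr <- colMeans(W[band, , drop = FALSE])
    tc <- to_cylindrical(rbind(ctr), frame)
    # direction (theta, z) from the band centroid, radial extent from the
    # farthest voxel: avoids both grid jitter and the inward bias of a
    # plain centroid
    tip_cyl <- cbind(r_nm = max(r), theta_deg = tc[1, 2], z_nm = tc[1, 3])
    tip <- from_cylindrical(tip_cyl, frame)[1, ]
    data.frame(tip_x_nm = tip[1], tip_y_nm = tip[2], tip_z_nm = tip[3],
               theta_deg = tc[1, 2], radial_nm = max(r),
               axial_nm = tc[1, 3], n_voxels = length(sel))
  }))
  tips <- tips[order(tips$theta_deg), , drop = FALSE]
  tips <- cbind(da_id = seq_len(nrow(tips)), tips)
  rownames(tips) <- NULL
  tips
}

# ---- isosurface extraction -------------------------------------------------

# Mesh a binary mask (0/1 array) given in [z, y, x] order. offset_zyx is
# the 1-based index of the mask's [1,1,1] voxel in the parent volume.
# `blockers` (same dim as mask) marks voxels of other labels that wall off
# lumens (e.g. the MC body closing a membrane opening) so hole filling
# cannot leak through them.
#' @noRd
mesh_binary_mask <- function(mask, voxel_size_nm, offset_zyx = c(1L, 1L, 1L),
                             fill = TRUE, smooth_iters = 1L,
                             blockers = NULL) {
  d <- dim(mask)
  pad <- 2L + smooth_iters
  dp <- d + 2L * pad
  arr <- array(0L, dim = dp)
  arr[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask
  if (fill) {
    blk <- NULL
    if (!is.null(blockers)) {
      blk <- array(0L, dim = dp)
      blk[pad + seq_len(d[1]), pad + seq_len(d[2]),
          pad + seq_len(d[3])] <- blockers
    }
    arr <- .fill_holes_6(arr, dim(arr), blk)
  }
  vals <- as.numeric(arr)
  dim(vals) <- dim(arr)
  if (smooth_iters > 0)
    vals <- .smooth_box3(vals, dim(vals), as.integer(smooth_iters))
  mt <- .marching_tetra(vals, dim(vals), 0.5)
  V <- mt$vertices  # columns: x, y, z index units within padded array
  # map back to world nm: padded index -> parent 0-based index
  V[, 1] <- (V[, 1] - pad + offset_zyx[3] - 1) * voxel_size_nm
  V[, 2] <- (V[, 2] - pad + offset_zyx[2] - 1) * voxel_size_nm
  V[, 3] <- (V[, 3] - pad + offset_zyx[1] - 1) * voxel_size_nm
  surface_mesh(V, mt$faces)
}

# 0/1 crop of all labels other than `label` within [lo, hi] (z, y, x)
#' @noRd
crop_other_labels <- function(volume, label, lo, hi) {
  cr <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  blk <- (cr != 0L & cr != label)
  storage.mode(blk) <- "integer"
  blk
}

#' Extract the surface mesh of one label
#'
#' Triangulated isosurface (marching tetrahedra at iso-level 0.5) of the
#' binary mask of `label`, with vertices in world nm. Interior cavities
#' are filled before extraction so closed shells yield a single outer
#' surface, and the binary mask is smoothed with `smooth_iters` passes of
#' a 3x3x3 box mean for sub-voxel surface placement. Meshes of separate
#' 26-connected voxel components are extracted independently and
#' concatenated, so connected mesh components correspond 1:1 to voxel
#' components.
#'
#' @param volume A [label_volume].
#' @param label Integer label value (or role name) to mesh.
#' @param fill Fill interior cavities first (default `TRUE`).
#' @param smooth_iters Passes of 3x3x3 box smoothing (default 1).
#' @return A `surface_mesh`.
#' @export
extract_surface_mesh <- function(volume, label, fill = TRUE,
                                 smooth_iters = 1L) {
  if (is.character(label)) label <- volume$label_map[[label]]
  mask <- volume$data == label
  storage.mode(mask) <- "integer"
  if (!any(mask == 1L)) stop("label ", label, " not present in volume")
  lab <- .cc_label_26(mask, dim(mask))
  ncomp <- attr(lab, "n_components")
  meshes <- lapply(seq_len(ncomp), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
    sub <- array(0L, dim = hi - lo + 1L)
    sub[idx - matrix(lo - 1L, nrow(idx), 3, byrow = TRUE)] <- 1L
    blockers <- crop_other_labels(volume, label, lo, hi)
    mesh_binary_mask(sub, volume$voxel_size_nm, offset_zyx = lo,
                     fill = fill, smooth_iters = smooth_iters,
                     blockers = blockers)
  })
  if (length(meshes) == 1L) return(meshes[[1]])
  vs <- lapply(meshes, `[[`, "vertices")
  fs <- lapply(meshes, `[[`, "faces")
  off <- cumsum(c(0L, vapply(vs, nrow, integer(1))))
  faces <- do.call(rbind, Map(function(f, o) f + o, fs, off[-length(off)]))
  surface_mesh(do.call(rbind, vs), faces)
}
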