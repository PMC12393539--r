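# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# a small random label volume for I/O round trips
small_random_volume <- function(seed = 7, n = 64) {
  set.seed(seed)
  arr <- array(sample(c(0L, 1L, 2L, 3L), n^3, replace = TRUE,
                      prob = c(0.85, 0.05, 0.05, 0.05)), dim = c(n, n, n))
  label_volume(arr, 9)
}

# a membrane-only volume holding one spherical shell of given diameter,
# optionally flattened to a single z slice
sphere_volume <- function(diameter_nm, voxel_size_nm = 9, label = 3L,
                          single_slice = FALSE) {
  r <- diameter_nm / 2
  n <- 2L * as.integer(ceiling((r + 3 * voxel_size_nm) / voxel_size_nm)) + 1L
  ax <- (seq_len(n) - 1) * voxel_size_nm
  ctr <- (n - 1) * voxel_size_nm / 2
  arr <- array(0L, dim = c(n, n, n))
  g <- expand.grid(z = ax, y = ax, x = ax)
  d <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2)
  inside <- d <= r
  if (single_slice) {
    zmid <- which.min(abs(ax - ctr))
    keep <- inside & g$z == ax[zmid]
    arr[keep] <- label
  } else {
    arr[inside] <- label
  }
  label_volume(arr, voxel_size_nm)
}

# membrane-only volume with a closed torus shell (inward shell of
# thickness 2 voxels, hole-fillable to the solid torus)
torus_volume <- function(R = 160, r = 40, voxel_size_nm = 9, label = 3L) {
  ext <- R + r + 3 * voxel_size_nm
  n <- 2L * as.integer(ceiling(ext / voxel_size_nm)) + 1L
  ax <- (seq_len(n) - 1) * voxel_size_nm
  ctr <- (n - 1) * voxel_size_nm / 2
  arr <- array(0L, dim = c(n, n, n))
  g <- expand.grid(z = ax, y = ax, x = ax)
  rho <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2)
  dc <- sqrt((rho - R)^2 + (g$z - ctr)^2)
  arr[dc <= r & dc >= r - 2 * voxel_size_nm] <- label
  label_volume(arr, voxel_size_nm)
}

# unit cube mesh (8 vertices, 12 triangles)
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

# independent circular-gap oracle: for every distinct angle, the
# counter-clockwise spacing to its nearest other distinct angle; the gap
# is the maximum over angles (duplicates occupy one position).
brute_circular_gap <- function(theta_deg) {
  th <- unique(theta_deg %% 360)
  if (length(th) == 1) return(360)
  M <- outer(th, th, function(a, b) (b - a) %% 360)
  diag(M) <- NA
  max(apply(M, 1, min, na.rm = TRUE))
}

angle_between_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# index of the nearest ground-truth tip for each detected tip row
match_tips <- function(tips, truth_world) {
  vapply(seq_len(nrow(tips)), function(i) {
    which.min(colSums((t(truth_world) -
                         c(tips$tip_x_nm[i], tips$tip_y_nm[i],
                           tips$tip_z_nm[i]))^2))
  }, integer(1))
}

# watertightness: every undirected edge borders exactly two triangles
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}
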