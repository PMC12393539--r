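# Label-volume container and file I/O (MRC2014, multi-page TIFF, meshes,
# reports).
#
# Conventions used throughout the package:
#   * volume data are indexed [z, y, x] (z = FIB-SEM sectioning axis);
#   * voxel size is isotropic, in nanometres;
#   * world coordinates are (x, y, z) in nm under the voxel-centre
#     convention: 1-based voxel index (z, y, x) has its centre at
#     world (x-1, y-1, z-1) * voxel_size_nm.

#' Default role-to-label mapping
#'
#' Roles follow the segmentation classes used for centriole volumes:
#' mother-centriole body, distal appendages, membrane structures, plasma
#' membrane and daughter centriole. Background is fixed at 0.
#'
#' @return Named integer vector mapping role names to label values.
#' @export
default_label_map <- function() {
  c(background = 0L, mc_body = 1L, da = 2L, membrane = 3L, pm = 4L, dc = 5L)
}

#' Construct a label volume
#'
#' @param data 3D integer array indexed `[z, y, x]`.
#' @param voxel_size_nm Positive isotropic voxel size in nm.
#' @param label_map Named integer vector mapping roles (`background`,
#'   `mc_body`, `da`, `membrane`, `pm`, `dc`) to label values; background
#'   must map to 0.
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, voxel_size_nm, label_map = default_label_map()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed [z, y, x]")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("`voxel_size_nm` must be a positive scalar")
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L))
    stop("label values must be non-negative integers")
  if (is.null(names(label_map)) || any(!nzchar(names(label_map))))
    stop("`label_map` must be a named integer vector")
  label_map <- vapply(label_map, as.integer, integer(1))
  if (!"background" %in% names(label_map) || label_map[["background"]] != 0L)
    stop("`label_map` must map role 'background' to 0")
  used <- setdiff(unique(as.vector(data)), 0L)
  unknown <- setdiff(used, label_map)
  if (length(unknown))
    stop("labels present in data but absent from label_map: ",
         paste(unknown, collapse = ", "))
  structure(
    list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
         label_map = label_map),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %d x %d x %d voxels (z,y,x) at %.3g nm\n",
              d[1], d[2], d[3], x$voxel_size_nm))
  counts <- table(factor(as.vector(x$data), levels = sort(unique(x$label_map))))
  for (role in names(x$label_map)) {
    lab <- x$label_map[[role]]
    n <- counts[as.character(lab)]
    if (role != "background" && !is.na(n) && n > 0)
      cat(sprintf("  %-9s label %d: %s voxels\n", role, lab,
                  format(as.integer(n), big.mark = ",")))
  }
  invisible(x)
}

#' World coordinates of voxel indices
#'
#' @param volume A `label_volume`.
#' @param indices Integer matrix of 1-based `(z, y, x)` indices.
#' @return Numeric matrix of `(x, y, z)` world coordinates in nm
#'   (voxel-centre convention).
#' @export
voxel_world_coords <- function(volume, indices) {
  indices <- rbind(indices)
  out <- cbind(x = (indices[, 3] - 1) * volume$voxel_size_nm,
               y = (indices[, 2] - 1) * volume$voxel_size_nm,
               z = (indices[, 1] - 1) * volume$voxel_size_nm)
  out
}

#' Mask of one role's label
#' @noRd
role_mask <- function(volume, role) {
  if (!role %in% names(volume$label_map)) stop("unknown role: ", role)
  mask <- volume$data == volume$label_map[[role]]
  storage.mode(mask) <- "integer"
  mask
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "rec", "map")) return("mrc")
  if (ext %in% c("tif", "tiff")) return("tiff_stack")
  stop("cannot infer volume format from extension '.", ext,
       "'; pass `format` explicitly")
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

write_sidecar <- function(volume, path) {
  meta <- list(voxel_size_nm = volume$voxel_size_nm,
               label_map = as.list(volume$label_map))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

# ---- MRC2014 ---------------------------------------------------------------
# Minimal MRC2014 implementation (1024-byte header, little-endian). Cell
# dimensions follow the MRC/CCP4 convention of Angstrom units, so a header
# declaring 9 nm spacing stores cella/mx = 90. Data order: x fastest, then
# y, then z; we transpose to the package's [z, y, x] indexing.

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h1 <- readBin(con, integer(), n = 10, size = 4, endian = "little")
  nx <- h1[1]; ny <- h1[2]; nz <- h1[3]; mode <- h1[4]
  mx <- h1[8]; my <- h1[9]; mz <- h1[10]
  cella <- readBin(con, numeric(), n = 3, size = 4, endian = "little")
  readBin(con, numeric(), n = 3, size = 4, endian = "little")   # cellb
  readBin(con, integer(), n = 3, size = 4, endian = "little")   # mapc/r/s
  readBin(con, numeric(), n = 3, size = 4, endian = "little")   # dmin/max/mean
  readBin(con, integer(), n = 1, size = 4, endian = "little")   # ispg
  nsymbt <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  raw_data <- switch(as.character(mode),
    "0" = readBin(con, integer(), n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, integer(), n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, numeric(), n = n, size = 4, endian = "little"),
    "6" = readBin(con, integer(), n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(raw_data) < n) stop("truncated MRC data block")
  arr <- array(raw_data, dim = c(nx, ny, nz))
  arr <- aperm(arr, c(3, 2, 1))  # -> [z, y, x]
  spacing_nm <- cella / c(mx, my, mz) / 10
  list(data = arr, spacing_nm = spacing_nm)
}

write_mrc <- function(volume, path) {
  d <- dim(volume$data)  # (nz, ny, nx)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  maxv <- max(volume$data)
  if (maxv > 32767L)
    stop("label values exceed the int16 range of MRC mode 1")
  arr <- aperm(volume$data, c(3, 2, 1))  # -> x fastest
  con <- file(path, "wb")
  on.exit(close(con))
  vs_ang <- volume$voxel_size_nm * 10
  writeBin(as.integer(c(nx, ny, nz, 1L, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(nx, ny, nz) * vs_ang), con, size = 4,
           endian = "little")                          # cella (Angstrom)
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(arr), max(arr), mean(arr))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little")  # ispg, nsymbt
  writeBin(raw(100), con)                              # extra words 26-50
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little") # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)     # little-endian stamp
  writeBin(as.numeric(0), con, size = 4, endian = "little")          # rms
  writeBin(as.integer(0), con, size = 4, endian = "little")          # nlabl
  writeBin(raw(800), con)
  writeBin(as.integer(arr), con, size = 2, endian = "little")
  invisible(path)
}

# ---- TIFF stacks -----------------------------------------------------------

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d <- dim(pages[[1]])
  arr <- array(0L, dim = c(nz, d[1], d[2]))
  for (z in seq_len(nz)) arr[z, , ] <- as.integer(round(pages[[z]]))
  arr
}

write_tiff_stack <- function(volume, path) {
  maxv <- max(volume$data)
  if (maxv > 65535L) stop("label values exceed the 16-bit TIFF range")
  pages <- lapply(seq_len(dim(volume$data)[1]),
                  function(z) volume$data[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# ---- public volume I/O -----------------------------------------------------

#' Read a label volume from MRC or multi-page TIFF
#'
#' Voxel size comes from the MRC header (cell dimensions in Angstrom over
#' grid size) or, for TIFF, from the JSON sidecar written alongside the
#' stack (`<path>.json`). A `voxel_size_nm` override is required when the
#' header is anisotropic or metadata are missing; anisotropic headers are
#' never silently averaged.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"mrc"`, `"tiff_stack"`.
#' @param voxel_size_nm Optional isotropic voxel-size override in nm.
#' @param label_map Optional role mapping; defaults to the sidecar's map or
#'   [default_label_map()].
#' @return A [label_volume].
#' @export
read_label_volume <- function(path, format = c("auto", "mrc", "tiff_stack"),
                              voxel_size_nm = NULL, label_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") format <- guess_format(path)
  sidecar <- read_sidecar(path)
  if (is.null(label_map)) {
    label_map <- if (!is.null(sidecar$label_map))
      unlist(sidecar$label_map) else default_label_map()
  }
  if (format == "mrc") {
    raw_vol <- read_mrc(path)
    arr <- raw_vol$data
    if (any(abs(arr - round(arr)) > 1e-6))
      stop("MRC volume contains non-integer voxel values")
    arr <- round(arr)
    storage.mode(arr) <- "integer"
    sp <- raw_vol$spacing_nm
    if (is.null(voxel_size_nm)) {
      if (any(!is.finite(sp)) || any(sp <= 0))
        stop("MRC header lacks a usable voxel size; pass `voxel_size_nm`")
      if (diff(range(sp)) > 1e-6 * mean(sp))
        stop("anisotropic voxel size in MRC header (",
             paste(signif(sp, 6), collapse = " x "),
             " nm); pass `voxel_size_nm` explicitly")
      voxel_size_nm <- sp[1]
    }
  } else {
    arr <- read_tiff_stack(path)
    if (is.null(voxel_size_nm)) {
      if (is.null(sidecar$voxel_size_nm))
        stop("TIFF stacks carry no voxel size; provide a sidecar or ",
             "`voxel_size_nm`")
      voxel_size_nm <- sidecar$voxel_size_nm
    }
  }
  label_volume(arr, voxel_size_nm, label_map)
}

#' Write a label volume to MRC or multi-page TIFF
#'
#' A JSON sidecar (`<path>.json`) carrying the voxel size and role map is
#' written next to the volume so that label semantics survive formats with
#' no label metadata.
#'
#' @param volume A [label_volume].
#' @param path Output file path.
#' @param format `"mrc"` or `"tiff_stack"`.
#' @return The path, invisibly.
#' @export
write_label_volume <- function(volume, path, format = c("mrc", "tiff_stack")) {
  format <- match.arg(format)
  stopifnot(inherits(volume, "label_volume"))
  if (any(volume$data < 0L)) stop("label values must be non-negative")
  if (format == "mrc") write_mrc(volume, path) else write_tiff_stack(volume, path)
  write_sidecar(volume, path)
  invisible(path)
}

# ---- meshes ----------------------------------------------------------------

#' Construct a triangle mesh
#' @param vertices Numeric n x 3 matrix of (x, y, z) coordinates in nm.
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.4g nm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total triangle area of a mesh
#' @param mesh A `surface_mesh`.
#' @return Area in nm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Write a surface mesh as ASCII PLY or OBJ
#'
#' Vertex coordinates are in nm.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param format `"ply"` or `"obj"`.
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "obj")) {
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  if (is.null(f) || nrow(f) < 1L) stop("mesh has no triangles")
  if (any(!is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (format == "ply") {
    header <- c("ply", "format ascii 1.0",
                "comment vertex coordinates in nanometres",
                sprintf("element vertex %d", nrow(v)),
                "property float x", "property float y", "property float z",
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    body_v <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    body_f <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(header, body_v, body_f), path)
  } else {
    body_v <- sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    body_f <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    writeLines(c("# vertex coordinates in nanometres", body_v, body_f), path)
  }
  invisible(path)
}

#' Read an ASCII PLY or OBJ mesh
#' @param path File path.
#' @param format `"auto"`, `"ply"` or `"obj"`.
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") "ply" else if (ext == "obj") "obj" else
      stop("cannot infer mesh format from extension '.", ext, "'")
  }
  lines <- readLines(path)
  if (format == "ply") {
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex ", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face ", lines, value = TRUE)))
    start <- which(lines == "end_header")[1]
    vl <- lines[(start + 1):(start + nv)]
    fl <- lines[(start + nv + 1):(start + nv + nf)]
    v <- do.call(rbind, lapply(strsplit(vl, " "), function(x)
      as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(fl, " "), function(x)
      as.integer(x[2:4]) + 1L))
  } else {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, " +"), function(x)
      as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, " +"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
  }
  surface_mesh(v, f)
}

# ---- reports ---------------------------------------------------------------

#' Write an analysis report as CSV or JSON
#'
#' CSV output has one row per membrane component (or per cell for cohort
#' summaries) with a stable column order; JSON is a lossless superset
#' carrying nested fields (config snapshot, evidence, excluded components).
#'
#' @param report A `cell_report`, `cohort_summary`, or data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass_recursive(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    return(invisible(path))
  }
  tab <- report_table(report)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @noRd
report_table <- function(report) {
  if (is.data.frame(report)) return(report)
  if (inherits(report, "cell_report")) return(report$components)
  if (inherits(report, "cohort_summary")) return(report$groups)
  stop("cannot tabulate object of class ", paste(class(report), collapse = "/"))
}

#' @noRd
unclass_recursive <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}
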