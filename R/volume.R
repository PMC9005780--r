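#' Construct a volume grid
#'
#' A voxelized density map with isotropic physical voxel size in nm and a
#' physical origin (nm) for the centre of voxel (1,1,1).
#'
#' @param data 3D numeric array of density values (all dims >= 2, finite).
#' @param voxel_size_nm voxel edge length, nm (> 0).
#' @param origin_nm 3-vector, nm; default zeros.
#' @param isovalue optional recommended iso-contour level.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_size_nm, origin_nm = c(0, 0, 0),
                        isovalue = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  if (any(dim(data) < 2L)) stop("all three dimensions must be >= 2")
  if (any(!is.finite(data))) stop("density values must be finite")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L || voxel_size_nm <= 0)
    stop("voxel_size_nm must be a single positive number")
  structure(list(data = data, voxel_size_nm = voxel_size_nm,
                 origin_nm = as.numeric(origin_nm), isovalue = isovalue),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Volume grid: %d x %d x %d voxels, %.4g nm/voxel, density [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size_nm, min(x$data), max(x$data)))
  invisible(x)
}

# ---- MRC/CCP4 I/O -----------------------------------------------------------
# MRC2014 layout: 256 x 4-byte header words, mode-2 (float32) data, column
# (x) fastest. Cell dimensions are in Angstrom; internal unit is nm.

#' Read an MRC/CCP4 density map
#'
#' Reads a mode-2 (32-bit float) MRC2014 map. Voxel sizes are converted from
#' the header's Angstrom cell to nm; only isotropic grids (within 1%) are
#' supported. The header origin record is honored (converted to nm).
#'
#' @param path map file (.mrc/.map).
#' @param isovalue optional recommended isovalue to store with the grid.
#' @return a [volume_grid()].
#' @export
read_mrc <- function(path, isovalue = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  seek(con, 0)
  hdr_f <- readBin(con, "numeric", n = 256L, size = 4L, endian = "little")
  seek(con, 0)
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (rawToChar(hdr_raw[209:212]) != "MAP ")
    stop("malformed MRC header: missing MAP stamp")
  nx <- hdr_i[1]; ny <- hdr_i[2]; nz <- hdr_i[3]
  mode <- hdr_i[4]
  if (any(c(nx, ny, nz) <= 0)) stop("malformed MRC header: zero-sized dimension")
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2, float32)")
  mx <- hdr_i[8]; my <- hdr_i[9]; mz <- hdr_i[10]
  cella <- hdr_f[11:13]
  vx <- cella / c(mx, my, mz) / 10  # Angstrom -> nm
  if (any(vx <= 0)) stop("malformed MRC header: non-positive voxel size")
  if (max(vx) / min(vx) > 1.01)
    stop("unsupported grid: anisotropic voxels beyond 1% tolerance")
  nsymbt <- hdr_i[24]
  origin <- hdr_f[50:52] / 10
  seek(con, 1024L + nsymbt)
  dat <- readBin(con, "numeric", n = nx * ny * nz, size = 4L, endian = "little")
  if (length(dat) != nx * ny * nz) stop("malformed MRC file: truncated data")
  volume_grid(array(dat, dim = c(nx, ny, nz)), mean(vx), origin, isovalue)
}

#' Write a volume grid as MRC2014 (mode 2)
#'
#' @param vol a [volume_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d); wi(2L)                       # nx ny nz, mode
  wi(c(0L, 0L, 0L)); wi(d)            # nstart, mx my mz
  wf(d * vol$voxel_size_nm * 10)      # cella (Angstrom)
  wf(c(90, 90, 90))                   # cellb
  wi(c(1L, 2L, 3L))                   # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))
  wi(c(1L, 0L))                       # ispg, nsymbt
  wi(rep(0L, 25L))                    # extra
  wf(vol$origin_nm * 10)              # origin (Angstrom)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(vol$data))
  wi(0L)                              # nlabl
  writeBin(raw(800L), con)            # labels
  writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a cryo-EM volume with its recommended isovalue
#'
#' Convenience wrapper over [read_mrc()] matching per-entry metadata files
#' (see [read_map_metadata()]).
#'
#' @param path map file.
#' @param isovalue recommended iso-contour level (stored with the grid).
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, isovalue = NULL) read_mrc(path, isovalue)

#' Read per-map metadata (accession, isovalue, helical parameters)
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) entry file with
#' fields `accession`, `isovalue`, `twist_deg`, `rise_nm` (or `rise_angstrom`),
#' `handedness` (+1/-1 or "right"/"left"), optional `symmetry_order`, `label`
#' and `map_path`.
#'
#' @param path metadata file.
#' @return a list with a `helical` element of class [helical_params()].
#' @export
read_map_metadata <- function(path) {
  ext <- tolower(tools::file_ext(path))
  meta <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package not available")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  rise <- meta$rise_nm
  if (is.null(rise) && !is.null(meta$rise_angstrom)) rise <- meta$rise_angstrom / 10
  hnd <- meta$handedness
  if (is.character(hnd)) hnd <- if (tolower(hnd) %in% c("left", "l")) -1 else 1
  if (is.null(hnd)) hnd <- sign(meta$twist_deg)
  twist <- abs(meta$twist_deg) * hnd   # normalize external sign conventions
  meta$helical <- helical_params(twist, rise, hnd,
                                 if (is.null(meta$symmetry_order)) 1L
                                 else meta$symmetry_order)
  meta
}

# ---- iso-surface extraction -------------------------------------------------

#' Extract an iso-surface from a density map
#'
#' Places a vertex at the linearly interpolated iso-crossing of every grid
#' edge spanning the isovalue (the marching-cubes vertex rule), in physical
#' nm coordinates (voxel centres, header origin honored). Faces are not
#' triangulated; all downstream analysis consumes the vertex cloud.
#'
#' @param volume a [volume_grid()].
#' @param isovalue contour level; default the grid's stored isovalue.
#' @return a [surface_cloud()] carrying the source voxel size.
#' @export
extract_isosurface <- function(volume, isovalue = volume$isovalue) {
  stopifnot(inherits(volume, "volume_grid"))
  if (is.null(isovalue)) stop("no isovalue given and none stored with the grid")
  f <- volume$data - isovalue
  if (min(volume$data) >= isovalue || max(volume$data) <= isovalue)
    stop("isovalue outside the data range")
  vx <- volume$voxel_size_nm
  d <- dim(f)
  verts <- list()
  for (ax in 1:3) {
    n <- d[ax]
    d1 <- d; d1[ax] <- d[ax] - 1L
    f1 <- array(f[make_slab_index(d, ax, 1L, n - 1L)], dim = d1)
    f2 <- array(f[make_slab_index(d, ax, 2L, n)], dim = d1)
    cross <- (f1 < 0) != (f2 < 0)
    if (!any(cross)) next
    ijk <- which(cross, arr.ind = TRUE)
    t <- f1[cross] / (f1[cross] - f2[cross])
    xyz <- (ijk - 1)
    xyz[, ax] <- xyz[, ax] + t
    verts[[ax]] <- xyz
  }
  verts <- do.call(rbind, verts)
  if (is.null(verts) || nrow(verts) < 4L)
    stop("iso-surface degenerate: fewer than 4 vertices")
  v <- sweep(verts * vx, 2L, volume$origin_nm, "+")
  surface_cloud(v, voxel_size_nm = vx)
}

# linear indices of the slab data[.., from:to, ..] along axis ax
make_slab_index <- function(d, ax, from, to) {
  idx <- slice.index(array(0, dim = d), ax)
  which(idx >= from & idx <= to)
}

# ---- denoising --------------------------------------------------------------

#' Denoise an iso-surface vertex cloud
#'
#' Two stages, mirroring common practice for noisy helical maps: (1) remove
#' vertices whose mean distance to their `k_neighbors` nearest neighbours
#' exceeds `dist_factor` times the median of that statistic; (2) keep only
#' the largest connected region of the cloud, where connectivity is assessed
#' on the cloud voxelized at `alpha_radius` (rolling-sphere semantics: gaps
#' wider than the alpha radius disconnect regions, narrower ones are bridged
#' and holes suppressed).
#'
#' @param surface a [surface_cloud()].
#' @param k_neighbors nearest-neighbour count (default 8).
#' @param dist_factor outlier threshold multiplier (default 3); both are
#'   map-noise dependent and intended to be tuned by inspection.
#' @param alpha_radius_nm connectivity radius, nm; default twice the source
#'   voxel size.
#' @return a denoised [surface_cloud()].
#' @export
denoise_surface <- function(surface, k_neighbors = 8L, dist_factor = 3,
                            alpha_radius_nm = NULL) {
  stopifnot(inherits(surface, "surface_cloud"))
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  if (is.null(alpha_radius_nm)) {
    if (is.null(surface$voxel_size_nm))
      stop("alpha_radius_nm required when the surface has no voxel size")
    alpha_radius_nm <- 2 * surface$voxel_size_nm
  }
  if (alpha_radius_nm <= 0) stop("alpha_radius_nm must be positive")
  v <- surface$vertices
  nnd <- cpp_knn_mean_dist(v, as.integer(k_neighbors))
  keep <- nnd <= dist_factor * stats::median(nnd)
  if (!any(keep)) stop("denoising removed all vertices")
  v <- v[keep, , drop = FALSE]
  vox <- floor(v / alpha_radius_nm)
  storage.mode(vox) <- "integer"
  uv <- unique(vox)
  lab <- cpp_voxel_components(uv)
  key <- paste(vox[, 1], vox[, 2], vox[, 3])
  ukey <- paste(uv[, 1], uv[, 2], uv[, 3])
  vlab <- lab[match(key, ukey)]
  v <- v[vlab == 1L, , drop = FALSE]
  if (nrow(v) < 4L) stop("denoising removed all vertices")
  surface_cloud(v, helical = surface$helical,
                voxel_size_nm = surface$voxel_size_nm)
}

# ---- axis alignment ---------------------------------------------------------

#' Align the fibril long axis with z
#'
#' Rotates the vertex cloud so its first principal axis lies along +z and
#' translates the centroid onto the z-axis. The z-flip ambiguity is resolved
#' deterministically by making the third central moment of the z coordinates
#' non-negative.
#'
#' @param surface a [surface_cloud()] with clearly anisotropic extent
#'   (longest principal extent at least twice the second).
#' @return the aligned [surface_cloud()] with attributes `rotation` (3 x 3
#'   matrix applied as `v %*% t(R)`) and `translation` (added after rotation).
#' @export
align_long_axis <- function(surface) {
  stopifnot(inherits(surface, "surface_cloud"))
  v <- surface$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  pc <- prcomp(vc, center = FALSE)
  ext <- apply(vc %*% pc$rotation, 2L, function(u) diff(range(u)))
  if (ext[1] < 2 * ext[2])
    stop("ambiguous axis: longest principal extent < 2x the second")
  # map PC1 -> z, PC2 -> x, PC3 -> y; force a proper rotation
  R <- rbind(pc$rotation[, 2], pc$rotation[, 3], pc$rotation[, 1])
  if (det(R) < 0) R[2, ] <- -R[2, ]
  vr <- vc %*% t(R)
  if (sum((vr[, 3] - mean(vr[, 3]))^3) < 0) {
    flip <- diag(c(1, -1, -1))  # 180 deg about x
    R <- flip %*% R
    vr <- vc %*% t(R)
  }
  out <- surface_cloud(vr, helical = surface$helical,
                       voxel_size_nm = surface$voxel_size_nm)
  attr(out, "rotation") <- R
  attr(out, "translation") <- -as.numeric(R %*% ctr)
  out
}
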