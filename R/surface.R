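#' Construct a surface point cloud
#'
#' A set of 3D vertices (nm) describing a map iso-surface or phantom surface,
#' optionally with triangle faces and attached helical parameters.
#'
#' @param vertices N x 3 numeric matrix of coordinates in nm (N >= 4).
#' @param faces optional integer matrix (M x 3) of 1-based vertex indices.
#' @param helical optional [helical_params()].
#' @param voxel_size_nm optional provenance: voxel size of the source map, nm.
#' @return an object of class `surface_cloud`.
#' @export
surface_cloud <- function(vertices, faces = NULL, helical = NULL,
                          voxel_size_nm = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (nrow(vertices) < 4L) stop("a surface needs at least 4 vertices")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face indices out of range")
  }
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, faces = faces, helical = helical,
                 voxel_size_nm = voxel_size_nm),
            class = "surface_cloud")
}

#' @export
print.surface_cloud <- function(x, ...) {
  ext <- apply(x$vertices, 2L, function(v) diff(range(v)))
  cat(sprintf("Surface cloud: %d vertices, extent %.3g x %.3g x %.3g nm\n",
              nrow(x$vertices), ext[1], ext[2], ext[3]))
  if (!is.null(x$helical)) print(x$helical)
  invisible(x)
}

#' Helical symmetry parameters
#'
#' Twist (degrees per subunit, signed), rise (nm per subunit) and handedness
#' of a helical filament, plus the rotational symmetry order of its
#' cross-section (C_n). Convention: a left-handed filament has negative twist;
#' `handedness` must agree with `sign(twist_deg)`.
#'
#' @param twist_deg degrees of rotation per subunit (signed; nonzero).
#' @param rise_nm axial rise per subunit, nm (> 0).
#' @param handedness +1 (right-handed) or -1 (left-handed); default inferred
#'   from the sign of `twist_deg`.
#' @param symmetry_order integer n >= 1, rotational symmetry C_n.
#' @return an object of class `helical_params`.
#' @export
helical_params <- function(twist_deg, rise_nm, handedness = sign(twist_deg),
                           symmetry_order = 1L) {
  if (!is.finite(twist_deg) || twist_deg == 0) stop("twist_deg must be nonzero")
  if (!is.finite(rise_nm) || rise_nm <= 0) stop("rise_nm must be positive")
  if (!handedness %in% c(-1, 1)) stop("handedness must be -1 or +1")
  if (sign(twist_deg) != handedness)
    stop("sign(twist_deg) inconsistent with handedness (left-handed => twist < 0)")
  symmetry_order <- as.integer(symmetry_order)
  if (symmetry_order < 1L) stop("symmetry_order must be >= 1")
  structure(list(twist_deg = twist_deg, rise_nm = rise_nm,
                 handedness = handedness, symmetry_order = symmetry_order),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("Helical params: twist %.4g deg, rise %.4g nm, %s-handed, C%d\n",
              x$twist_deg, x$rise_nm, if (x$handedness < 0) "left" else "right",
              x$symmetry_order))
  invisible(x)
}

#' Apparent cross-over distance implied by helical parameters
#'
#' A fibril whose cross-section has C_n symmetry repeats its appearance every
#' 360/n degrees of rotation, so the apparent cross-over distance is
#' `(360 / |twist|) * rise / n` (one n-th of the full helical pitch).
#'
#' @param helical a [helical_params()].
#' @return cross-over distance in nm.
#' @export
helical_cod <- function(helical) {
  stopifnot(inherits(helical, "helical_params"))
  360 / abs(helical$twist_deg) * helical$rise_nm / helical$symmetry_order
}

#' Export a surface cloud as PLY or OBJ
#'
#' ASCII export for inspection in external mesh viewers. Faces are written if
#' present.
#'
#' @param surface a [surface_cloud()].
#' @param path output file; format chosen from the extension (.ply / .obj).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "surface_cloud"))
  v <- surface$vertices
  f <- surface$faces
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", if (is.null(f)) 0L else nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    lines <- c(hdr, sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]))
    if (!is.null(f))
      lines <- c(lines, sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  } else if (ext == "obj") {
    lines <- sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])
    if (!is.null(f))
      lines <- c(lines, sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  } else stop("unsupported surface format: ", ext)
  writeLines(lines, path)
  invisible(path)
}
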