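# rotation about z by angle (radians), applied to N x 3 or N x 2 coords
rot_z <- function(v, ang) {
  ca <- cos(ang); sa <- sin(ang)
  out <- v
  out[, 1] <- ca * v[, 1] - sa * v[, 2]
  out[, 2] <- sa * v[, 1] + ca * v[, 2]
  out
}

# exact-integer voxel keys (coordinates must stay within +-2000 voxels)
voxel_keys <- function(v, voxel) {
  iv <- floor(v / voxel) + 2048
  if (any(iv < 0) || any(iv >= 4096)) stop("surface too large for voxel hashing")
  (iv[, 1] * 4096 + iv[, 2]) * 4096 + iv[, 3]
}

# Jaccard overlap of a cloud with its helically transformed copy, with the
# candidate screw axis at the (shifted, tilted) origin
helical_overlap <- function(v, twist_deg, rise_nm, voxel) {
  vt <- rot_z(v, twist_deg * pi / 180)
  vt[, 3] <- vt[, 3] + rise_nm
  zlo <- max(min(v[, 3]), min(vt[, 3]))
  zhi <- min(max(v[, 3]), max(vt[, 3]))
  a <- unique(voxel_keys(v[v[, 3] >= zlo & v[, 3] <= zhi, , drop = FALSE], voxel))
  b <- unique(voxel_keys(vt[vt[, 3] >= zlo & vt[, 3] <= zhi, , drop = FALSE], voxel))
  ni <- sum(a %in% b)
  ni / (length(a) + length(b) - ni)
}

apply_pose <- function(v, dx, dy, tx = 0, ty = 0) {
  out <- v
  out[, 1] <- out[, 1] - dx
  out[, 2] <- out[, 2] - dy
  if (tx != 0 || ty != 0) {
    cx <- cos(tx * pi / 180); sx <- sin(tx * pi / 180)
    cy <- cos(ty * pi / 180); sy <- sin(ty * pi / 180)
    y <- cx * out[, 2] - sx * out[, 3]
    z <- sx * out[, 2] + cx * out[, 3]
    out[, 2] <- y; out[, 3] <- z
    x <- cy * out[, 1] + sy * out[, 3]
    z <- -sy * out[, 1] + cy * out[, 3]
    out[, 1] <- x; out[, 3] <- z
  }
  out
}

#' Fit the screw-axis position of a helical surface
#'
#' Finds the in-plane axis offset (and residual axis tilt) that maximizes the
#' voxel-overlap (Jaccard index) between the voxelized surface and the same
#' surface rotated by the helical twist and translated by the rise about the
#' candidate axis. The surface must already be roughly axis-aligned (see
#' [align_long_axis()]). Deterministic: centre-of-mass initialization, coarse
#' grid search, Nelder-Mead polish, then a fine local grid.
#'
#' @param surface an axis-aligned [surface_cloud()].
#' @param helical a [helical_params()].
#' @param mode `"joint"` optimizes offset and tilt together after the grid
#'   stage; `"staged"` optimizes tilt first, then offset, then a joint polish.
#' @param voxel_size_nm voxelization size; default the surface's source voxel
#'   size.
#' @param search_radius_nm coarse-search half-width around the centre of mass
#'   (default 4 nm).
#' @return a `screw_axis_pose`: offset_xy (nm), tilt (deg), overlap_score,
#'   and `surface` re-centred so the screw axis is the z-axis.
#' @export
fit_screw_axis <- function(surface, helical, mode = c("joint", "staged"),
                           voxel_size_nm = NULL, search_radius_nm = 4) {
  stopifnot(inherits(surface, "surface_cloud"), inherits(helical, "helical_params"))
  mode <- match.arg(mode)
  if (is.null(voxel_size_nm)) voxel_size_nm <- surface$voxel_size_nm
  if (is.null(voxel_size_nm)) stop("voxel_size_nm required")
  v <- surface$vertices
  com <- colMeans(v)
  obj <- function(p) -helical_overlap(apply_pose(v, p[1], p[2], p[3], p[4]),
                                      helical$twist_deg, helical$rise_nm,
                                      voxel_size_nm)
  # coarse grid about the centre of mass, tilt = 0
  step <- max(voxel_size_nm / 2, search_radius_nm / 8)
  g <- expand.grid(dx = seq(com[1] - search_radius_nm, com[1] + search_radius_nm, by = step),
                   dy = seq(com[2] - search_radius_nm, com[2] + search_radius_nm, by = step))
  sc <- apply(g, 1L, function(r) obj(c(r[1], r[2], 0, 0)))
  p0 <- as.numeric(g[which.min(sc), ])
  if (mode == "staged") {
    ot <- stats::optim(c(0, 0), function(t) obj(c(p0, t)), method = "Nelder-Mead",
                       control = list(reltol = 1e-6, maxit = 200))
    oo <- stats::optim(p0, function(d) obj(c(d, ot$par)), method = "Nelder-Mead",
                       control = list(reltol = 1e-6, maxit = 200))
    start <- c(oo$par, ot$par)
  } else start <- c(p0, 0, 0)
  op <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-7, maxit = 400))
  # sub-voxel polish on a continuous objective: the correct screw axis is
  # the point about which untwisting collapses the surface into the
  # thinnest cross-section band (the Jaccard overlap is piecewise-constant
  # below the voxel scale)
  rate <- helical$twist_deg * pi / 180 / helical$rise_nm
  sub <- if (nrow(v) > 12000L) v[seq(1L, nrow(v), length.out = 12000L), ] else v
  polish_obj <- function(d) {
    vp <- apply_pose(sub, d[1], d[2], op$par[3], op$par[4])
    ang <- -rate * vp[, 3]
    ux <- cos(ang) * vp[, 1] - sin(ang) * vp[, 2]
    uy <- sin(ang) * vp[, 1] + cos(ang) * vp[, 2]
    r <- sqrt(ux^2 + uy^2)
    th <- atan2(uy, ux)
    bin <- floor((th + pi) / (2 * pi) * 72) + 1L
    agg <- rowsum(cbind(r, r^2, 1), bin)
    sum(agg[, 2] - agg[, 1]^2 / agg[, 3]) / nrow(vp)  # pooled within-bin var
  }
  po <- stats::optim(op$par[1:2], polish_obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-8, maxit = 300))
  best <- c(po$par, op$par[3], op$par[4])
  score <- -obj(best)
  if (score < 0.5)
    stop("no screw axis found: best overlap ", signif(score, 3),
         " < 0.5 (map and helical metadata likely inconsistent)")
  centred <- surface_cloud(apply_pose(v, best[1], best[2], best[3], best[4]),
                           helical = helical, voxel_size_nm = surface$voxel_size_nm)
  structure(list(offset_xy = best[1:2], tilt = best[3:4],
                 overlap_score = score, surface = centred,
                 com_offset_xy = best[1:2] - com[1:2]),
            class = "screw_axis_pose")
}

#' @export
print.screw_axis_pose <- function(x, ...) {
  cat(sprintf("Screw axis: offset (%.3f, %.3f) nm, tilt (%.2f, %.2f) deg, overlap %.3f\n",
              x$offset_xy[1], x$offset_xy[2], x$tilt[1], x$tilt[2], x$overlap_score))
  invisible(x)
}

#' Extend a helical segment to a target length
#'
#' Stacks helically transformed copies of the segment (rotation by the twist,
#' translation by the rise, about the z-axis) until the z-extent reaches
#' `target_length_nm`. Seam duplicates (vertices within a quarter voxel of an
#' existing vertex) are dropped.
#'
#' @param surface a [surface_cloud()] whose screw axis is the z-axis.
#' @param helical a [helical_params()].
#' @param target_length_nm desired z-extent, nm.
#' @return the extended [surface_cloud()].
#' @export
extend_helical <- function(surface, helical, target_length_nm) {
  stopifnot(inherits(surface, "surface_cloud"), inherits(helical, "helical_params"))
  if (helical$rise_nm <= 0) stop("rise must be positive")
  v <- surface$vertices
  zext <- diff(range(v[, 3]))
  if (target_length_nm <= zext) return(surface)
  m <- ceiling((target_length_nm - zext) / helical$rise_nm)
  tw <- helical$twist_deg * pi / 180
  tol <- if (!is.null(surface$voxel_size_nm)) 0.25 * surface$voxel_size_nm else 1e-6
  zmax <- max(v[, 3])
  # each copy contributes its top few-rise slice; consecutive copies overlap,
  # which is harmless (a helical surface agrees with itself under the screw
  # operation) and keeps the vertex sampling of the extension dense
  top <- v[v[, 3] > zmax - 3 * helical$rise_nm - tol, , drop = FALSE]
  parts <- vector("list", m + 1L)
  parts[[1L]] <- v
  for (j in seq_len(m)) {
    vj <- rot_z(top, j * tw)
    vj[, 3] <- vj[, 3] + j * helical$rise_nm
    parts[[j + 1L]] <- vj
  }
  allv <- do.call(rbind, parts)
  g <- round(sweep(allv, 2L, apply(allv, 2L, min)) / tol)
  key <- g[, 1] + 65536 * (g[, 2] + 65536 * g[, 3])  # exact in doubles
  allv <- allv[!duplicated(key), , drop = FALSE]
  surface_cloud(allv, helical = helical, voxel_size_nm = surface$voxel_size_nm)
}

#' Untwist helical coordinates onto one cross-sectional plane
#'
#' Rotates every vertex about z by `-twist * z / rise` and projects onto the
#' xy-plane, collapsing the whole filament onto the rotational cross-section.
#'
#' @param surface a [surface_cloud()] whose screw axis is the z-axis.
#' @param helical a [helical_params()].
#' @return an N x 2 matrix (nm) of cross-section points.
#' @export
untwist_to_plane <- function(surface, helical) {
  stopifnot(inherits(surface, "surface_cloud"), inherits(helical, "helical_params"))
  v <- surface$vertices
  ang <- -helical$twist_deg * pi / 180 * v[, 3] / helical$rise_nm
  ca <- cos(ang); sa <- sin(ang)
  cbind(x = ca * v[, 1] - sa * v[, 2],
        y = sa * v[, 1] + ca * v[, 2])
}
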