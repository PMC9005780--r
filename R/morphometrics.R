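#' Construct a cross-section curve
#'
#' A simple closed planar curve (ordered, counter-clockwise, nm), optionally
#' with percentile bound curves and a screw-axis position marker.
#'
#' @param curve N x 2 matrix, ordered boundary points (the closing edge from
#'   the last to the first point is implicit).
#' @param lo,hi optional percentile bound curves (same format).
#' @param axis_xy screw-axis position marker, nm.
#' @return an object of class `cross_section`.
#' @export
cross_section <- function(curve, lo = NULL, hi = NULL, axis_xy = c(0, 0)) {
  curve <- as.matrix(curve)
  if (ncol(curve) != 2L || nrow(curve) < 3L)
    stop("curve must be an N x 2 matrix with N >= 3")
  if (any(!is.finite(curve))) stop("curve coordinates must be finite")
  if (shoelace(curve) < 0) {  # enforce counter-clockwise order
    curve <- curve[nrow(curve):1, , drop = FALSE]
    if (!is.null(lo)) lo <- lo[nrow(lo):1, , drop = FALSE]
    if (!is.null(hi)) hi <- hi[nrow(hi):1, , drop = FALSE]
  }
  structure(list(curve = curve, lo = lo, hi = hi, axis_xy = as.numeric(axis_xy)),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("Cross-section: %d boundary points, area %.2f nm^2%s\n",
              nrow(x$curve), cross_section_area(x),
              if (!is.null(x$lo)) ", with percentile bounds" else ""))
  invisible(x)
}

#' @export
plot.cross_section <- function(x, ...) {
  rng <- range(rbind(x$curve, x$lo, x$hi))
  plot(rbind(x$curve, x$curve[1, ]), type = "l", lwd = 2, asp = 1,
       xlim = rng, ylim = rng, xlab = "x (nm)", ylab = "y (nm)", ...)
  if (!is.null(x$lo)) graphics::lines(rbind(x$lo, x$lo[1, ]), lty = 3)
  if (!is.null(x$hi)) graphics::lines(rbind(x$hi, x$hi[1, ]), lty = 3)
  graphics::points(x$axis_xy[1], x$axis_xy[2], pch = 3)
  invisible(x)
}

# signed shoelace area (positive = counter-clockwise)
shoelace <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

# resample a closed curve to n points uniformly by arc length
resample_closed_curve <- function(p, n = 360L) {
  p <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  tot <- s[length(s)]
  if (tot == 0) stop("degenerate curve: zero perimeter")
  so <- seq(0, tot, length.out = n + 1L)[-(n + 1L)]
  cbind(stats::approx(s, p[, 1], xout = so)$y,
        stats::approx(s, p[, 2], xout = so)$y)
}

#' Tip-accessible boundary of a 2D point cloud
#'
#' Traces a circle of the tip radius around the cross-section cloud: the
#' boundary of the morphological closing (dilation then erosion by a disc of
#' the tip radius) of the rasterized cloud, with interior holes suppressed.
#' Concavities narrower than the tip are bridged; wider ones are preserved -
#' the boundary an AFM probe of that radius can physically reach.
#'
#' @param points N x 2 matrix of cross-section points, nm (N >= 10).
#' @param tip_radius_nm probe apex radius, nm (> 0).
#' @param cell_nm raster cell size; default adapts to the cloud extent
#'   (extent/400, at most tip_radius/2).
#' @param n_out number of boundary points returned.
#' @return a [cross_section()] (axis marker at the origin of the input frame).
#' @export
tip_accessible_boundary <- function(points, tip_radius_nm, cell_nm = NULL,
                                    n_out = 360L) {
  points <- as.matrix(points)
  if (nrow(points) < 10L) stop("need at least 10 points")
  if (tip_radius_nm <= 0) stop("tip radius must be positive")
  sv <- svd(sweep(points, 2L, colMeans(points)))$d
  if (sv[2] < 1e-9 * sv[1]) stop("degenerate (collinear) point cloud")
  ext <- max(apply(points, 2L, function(v) diff(range(v))))
  if (is.null(cell_nm))  # keep the padded raster below ~1500^2 cells
    cell_nm <- max(min(ext / 400, tip_radius_nm / 2),
                   (ext + 2 * tip_radius_nm) / 1500)
  R <- tip_radius_nm / cell_nm  # radius in cells
  pad <- tip_radius_nm + 2 * cell_nm
  x0 <- min(points[, 1]) - pad
  y0 <- min(points[, 2]) - pad
  nxp <- ceiling((max(points[, 1]) + pad - x0) / cell_nm) + 1L
  nyp <- ceiling((max(points[, 2]) + pad - y0) / cell_nm) + 1L
  A <- matrix(0L, nxp, nyp)
  ij <- cbind(pmin(pmax(round((points[, 1] - x0) / cell_nm) + 1L, 1L), nxp),
              pmin(pmax(round((points[, 2] - y0) / cell_nm) + 1L, 1L), nyp))
  A[ij] <- 1L
  # dilation: distance-to-cloud <= R; closing: erosion of the dilation
  dist_to_A <- EBImage::distmap(1 - A)
  D <- (A == 1L) | (dist_to_A <= R)
  Dfill <- EBImage::fillHull(EBImage::Image(D * 1))
  C <- EBImage::distmap(Dfill) > R
  C <- EBImage::fillHull(EBImage::Image(C * 1))
  lab <- EBImage::bwlabel(C)
  if (max(lab) < 1L) stop("closing produced an empty region")
  sizes <- tabulate(as.integer(lab[lab > 0]))
  C <- EBImage::Image((lab == which.max(sizes)) * 1)
  oc <- EBImage::ocontour(C)[[1]]
  curve <- cbind(x0 + (oc[, 1] - 1) * cell_nm, y0 + (oc[, 2] - 1) * cell_nm)
  cross_section(resample_closed_curve(curve, n_out))
}

#' Cross-sectional area
#'
#' Area enclosed by the cross-section boundary (shoelace formula), nm^2.
#'
#' @param cs a [cross_section()] or N x 2 matrix.
#' @return area in nm^2.
#' @export
cross_section_area <- function(cs) {
  p <- if (inherits(cs, "cross_section")) cs$curve else as.matrix(cs)
  a <- shoelace(p)
  if (curve_self_intersects(p)) stop("self-intersecting curve")
  abs(a)
}

# conservative self-intersection test on a decimated copy (O(n^2) segments)
curve_self_intersects <- function(p, max_check = 200L) {
  n <- nrow(p)
  if (n > max_check) p <- p[unique(round(seq(1, n, length.out = max_check))), ]
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), ]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_cross(a[i, ], b[i, ], a[js, , drop = FALSE],
                           b[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  q1 <- matrix(q1, ncol = 2L); q2 <- matrix(q2, ncol = 2L)
  ex <- p2[1] - p1[1]; ey <- p2[2] - p1[2]
  d1 <- ex * (q1[, 2] - p1[2]) - ey * (q1[, 1] - p1[1])
  d2 <- ex * (q2[, 2] - p1[2]) - ey * (q2[, 1] - p1[1])
  fx <- q2[, 1] - q1[, 1]; fy <- q2[, 2] - q1[, 2]
  d3 <- fx * (p1[2] - q1[, 2]) - fy * (p1[1] - q1[, 1])
  d4 <- fx * (p2[2] - q1[, 2]) - fy * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Rotationally align two cross-sections
#'
#' Centroid-aligns both curves, resamples each to an equal point count by arc
#' length, then searches rotations of the first curve in 1-degree steps over
#' 360 degrees for the angle minimizing the RMSD (symmetrized mean
#' point-to-nearest-point distance). Ties break to the smallest angle.
#'
#' @param cs_a,cs_b [cross_section()]s (or N x 2 matrices).
#' @param n_points resampling count (default 360).
#' @return list with `angle_deg` (rotation applied to `cs_a`), `rmsd_nm`, and
#'   `aligned_a`/`aligned_b` (centroid-centred, resampled, `cs_a` rotated).
#' @export
align_cross_sections <- function(cs_a, cs_b, n_points = 360L) {
  pa <- if (inherits(cs_a, "cross_section")) cs_a$curve else as.matrix(cs_a)
  pb <- if (inherits(cs_b, "cross_section")) cs_b$curve else as.matrix(cs_b)
  pa <- resample_closed_curve(pa, n_points)
  pb <- resample_closed_curve(pb, n_points)
  pa <- sweep(pa, 2L, colMeans(pa))
  pb <- sweep(pb, 2L, colMeans(pb))
  best <- cpp_align_curves(pa, pb)
  ra <- rot2(pa, best[1] * pi / 180)
  list(angle_deg = best[1], rmsd_nm = best[2], aligned_a = ra, aligned_b = pb)
}

rot2 <- function(p, ang) {
  ca <- cos(ang); sa <- sin(ang)
  cbind(ca * p[, 1] - sa * p[, 2], sa * p[, 1] + ca * p[, 2])
}

# symmetrized RMSD of nearest-point distances between two point sets
curve_rmsd <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt((mean(apply(d2, 1L, min)) + mean(apply(d2, 2L, min))) / 2)
}

#' Cross-sectional difference area
#'
#' Area of the symmetric difference of the two enclosed regions,
#' `area(A union B) - area(A intersect B)`, after optional centroid +
#' best-rotation alignment ([align_cross_sections()]). Computed by
#' rasterization (even-odd point-in-polygon per cell).
#'
#' @param cs_a,cs_b [cross_section()]s (or N x 2 matrices).
#' @param align centroid-align and rotationally align first (default TRUE).
#' @param cell_nm raster cell size; default extent/400.
#' @return symmetric-difference area, nm^2.
#' @export
cross_section_difference <- function(cs_a, cs_b, align = TRUE, cell_nm = NULL) {
  pa <- if (inherits(cs_a, "cross_section")) cs_a$curve else as.matrix(cs_a)
  pb <- if (inherits(cs_b, "cross_section")) cs_b$curve else as.matrix(cs_b)
  if (curve_self_intersects(pa) || curve_self_intersects(pb))
    stop("self-intersecting curve")
  if (align) {
    al <- align_cross_sections(pa, pb)
    pa <- al$aligned_a
    pb <- al$aligned_b
  }
  both <- rbind(pa, pb)
  ext <- max(apply(both, 2L, function(v) diff(range(v))))
  if (is.null(cell_nm)) cell_nm <- ext / 400
  x0 <- min(both[, 1]) - cell_nm
  y0 <- min(both[, 2]) - cell_nm
  nxp <- ceiling((max(both[, 1]) + cell_nm - x0) / cell_nm) + 1L
  nyp <- ceiling((max(both[, 2]) + cell_nm - y0) / cell_nm) + 1L
  gx <- x0 + (seq_len(nxp) - 0.5) * cell_nm
  gy <- y0 + (seq_len(nyp) - 0.5) * cell_nm
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  ina <- mgcv::in.out(rbind(pa, pa[1, ]), grid)
  inb <- mgcv::in.out(rbind(pb, pb[1, ]), grid)
  sum(xor(ina, inb)) * cell_nm^2
}
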