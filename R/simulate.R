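#' Simulate an AFM topograph of a 3D surface
#'
#' Geometric contact-point imaging: the simulated image is the grey-scale
#' dilation of the sample's top surface by the reflected tip. For every pixel
#' the height is the maximum over surface points `p` of
#' `p_z - tip_height(tip, lateral distance p -> pixel)`, clamped at the
#' substrate (0). An axis-aligned filament (screw axis = z, see
#' [fit_screw_axis()]) is laid onto the substrate with its axis along the
#' image y direction (the conventional 90-degree rotation), the original -y
#' azimuth facing the substrate.
#'
#' @param surface a [surface_cloud()]; either already in image frame
#'   (`frame = "image"`: x lateral, y axial, z height >= 0) or axis-aligned
#'   (`frame = "axis"`, the default, converted as described).
#' @param tip a [build_tip()] model.
#' @param pixel_size_nm image pixel size, nm. Surface vertex spacing should
#'   be at most half the pixel size for full accuracy.
#' @param frame input coordinate convention, see above.
#' @param pad_nm lateral padding beyond the tip footprint (default 1 pixel).
#' @return a [height_map()] with `axis_height_nm` set to the height of the
#'   screw axis above the substrate (axis frame only) and attributes
#'   `x0_nm`/`y0_nm` (physical coordinates of pixel (1,1)) and `axis_x_nm`
#'   (lateral position of the axis).
#' @export
simulate_topograph <- function(surface, tip, pixel_size_nm,
                               frame = c("axis", "image"), pad_nm = NULL) {
  stopifnot(inherits(surface, "surface_cloud"), inherits(tip, "tip_model"))
  frame <- match.arg(frame)
  v <- surface$vertices
  if (nrow(v) < 1L) stop("empty surface")
  if (frame == "axis") {
    h0 <- -min(v[, 2])
    pts <- cbind(x = v[, 1], y = v[, 3], z = v[, 2] + h0)
    axis_h <- h0
    axis_x <- 0
  } else {
    pts <- v
    if (min(pts[, 3]) < -1e-6)
      stop("image-frame surface must rest on the substrate (z >= 0)")
    axis_h <- NULL
    axis_x <- NULL
  }
  hmax <- max(pts[, 3])
  foot <- tip_footprint(tip, hmax)
  if (is.null(pad_nm)) pad_nm <- pixel_size_nm
  # snap the grid origin to the pixel lattice so images of the same surface
  # (e.g. with different tips) sample identical physical positions
  x0 <- floor((min(pts[, 1]) - foot - pad_nm) / pixel_size_nm) * pixel_size_nm
  x1 <- max(pts[, 1]) + foot + pad_nm
  y0 <- floor(min(pts[, 2]) / pixel_size_nm) * pixel_size_nm
  y1 <- max(pts[, 2])
  nx <- max(2L, floor((x1 - x0) / pixel_size_nm) + 1L)
  ny <- max(2L, floor((y1 - y0) / pixel_size_nm) + 1L)
  img <- cpp_simulate_topograph(pts[, 1], pts[, 2], pts[, 3], x0, y0,
                                nx, ny, pixel_size_nm, tip$radius_nm,
                                tip$half_angle_deg * pi / 180)
  out <- height_map(img, pixel_size_nm, axis_h)
  attr(out, "x0_nm") <- x0
  attr(out, "y0_nm") <- y0
  attr(out, "axis_x_nm") <- axis_x
  out
}

#' Tip-deconvolve a height image
#'
#' Grey-scale erosion of the image by the reflected tip: recovers the deepest
#' surface consistent with the observed tip-convolved topograph (the
#' contact-point surface estimate).
#'
#' @param hm a [height_map()].
#' @param tip the [build_tip()] model used during imaging.
#' @return a [height_map()] of the deconvolved surface.
#' @export
deconvolve_topograph <- function(hm, tip) {
  stopifnot(inherits(hm, "height_map"), inherits(tip, "tip_model"))
  out <- hm
  out$heights <- cpp_erode_topograph(hm$heights, hm$pixel_size_nm,
                                     hm$pixel_size_nm, tip$radius_nm,
                                     tip$half_angle_deg * pi / 180)
  out
}

#' Estimate the tip radius from a straightened fibril image
#'
#' Least-squares fit of a tip-sample contact-point model to the mean
#' transverse cross-section of the straightened fibril: the fibril envelope
#' is modelled as a cylinder (radius = half the peak of the mean profile),
#' the candidate tip dilates it, and the apex radius minimizing the squared
#' residual against the observed mean profile is returned.
#'
#' @param straight_img a straightened [height_map()] (fibril along y).
#' @param half_angle_deg tip cone half-angle used in the model (deg).
#' @param bounds_nm search interval for the radius, nm.
#' @return estimated radius (nm), with attribute `rss`. Warns if the optimum
#'   sits at a search bound.
#' @export
estimate_tip_radius <- function(straight_img, half_angle_deg = 18,
                                bounds_nm = c(0.2, 60)) {
  stopifnot(inherits(straight_img, "height_map"))
  px <- straight_img$pixel_size_nm
  prof <- colMeans(straight_img$heights)
  a <- max(prof) / 2
  if (a <= 0) stop("flat image: no fibril present")
  x <- (seq_along(prof) - which.max(prof)) * px
  th <- seq(0, 2 * pi, length.out = 721L)[-721L]
  cu <- a * cos(th)
  cw <- a + a * sin(th)
  predict_profile <- function(R) {
    alpha <- half_angle_deg * pi / 180
    vapply(x, function(xi) {
      max(0, max(cw - cpp_tip_z(abs(xi - cu), R, alpha)))
    }, numeric(1))
  }
  rss <- function(R) sum((predict_profile(R) - prof)^2)
  op <- stats::optimize(rss, bounds_nm, tol = 1e-3)
  R <- op$minimum
  span <- diff(bounds_nm)
  if (R - bounds_nm[1] < 0.01 * span || bounds_nm[2] - R < 0.01 * span)
    warning("tip radius estimate at search bound; estimation may have failed")
  structure(R, rss = op$objective)
}

# Pearson NCC between two equal-size vectors; NA if degenerate
ncc <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# resample matrix rows at fractional row positions (linear), per column
resample_rows <- function(m, rows) {
  rows <- pmin(pmax(rows, 1), nrow(m))
  lo <- floor(rows); hi <- pmin(lo + 1L, nrow(m)); w <- rows - lo
  m[lo, , drop = FALSE] * (1 - w) + m[hi, , drop = FALSE] * w
}

# intensity-weighted lateral (column) centroid of the fibril footprint
footprint_centroid_col <- function(m, q = 0.1) {
  w <- pmax(m - q * max(m), 0)
  if (sum(w) == 0) return(ncol(m) / 2)
  sum(t(w) * seq_len(ncol(m))) / sum(w)
}

# shift/crop/pad sim columns so its footprint centroid lands on the data's
# footprint centroid and the widths agree
match_lateral_frame <- function(sim, data) {
  S <- sim$heights; D <- data$heights
  if (ncol(S) == ncol(D) &&
      abs(footprint_centroid_col(S) - footprint_centroid_col(D)) <= 0.5)
    return(sim)
  shift <- round(footprint_centroid_col(S) - footprint_centroid_col(D))
  out <- matrix(0, nrow(S), ncol(D))
  src <- seq_len(ncol(D)) + shift
  ok <- src >= 1L & src <= ncol(S)
  out[, which(ok)] <- S[, src[ok], drop = FALSE]
  height_map(out, sim$pixel_size_nm, sim$axis_height_nm)
}

#' Centre a height map laterally on its fibril footprint
#'
#' Recentres the columns so the footprint centroid sits at the middle of a
#' `width_px`-wide image (zero padding outside), used to bring simulated and
#' experimental images onto a common lateral frame before correlation.
#'
#' @param hm a [height_map()].
#' @param width_px output width in pixels.
#' @return a [height_map()] with `width_px` columns.
#' @export
center_on_footprint <- function(hm, width_px) {
  m <- hm$heights
  cc <- round(footprint_centroid_col(m))
  out <- matrix(0, nrow(m), width_px)
  half <- floor(width_px / 2)
  src <- (cc - half):(cc - half + width_px - 1L)
  ok <- src >= 1L & src <= ncol(m)
  out[, which(ok)] <- m[, src[ok], drop = FALSE]
  height_map(out, hm$pixel_size_nm, hm$axis_height_nm)
}

#' Optimize the periodicity of a simulated fibril image against data
#'
#' Helical twist varies between individual filaments, so the simulated image
#' is allowed to dilate or contract along the fibril axis (image y) by a
#' global scale factor bounded in [0.5, 2], chosen to maximize the normalized
#' cross-correlation with the data over the fibril footprint (an axial shift
#' is searched simultaneously so phase does not confound the scale).
#'
#' @param sim simulated [height_map()] (fibril along y).
#' @param data experimental/reference [height_map()], same pixel size.
#' @param scale_bounds search interval for the scale factor.
#' @param footprint_quantile pixels with data height above this fraction of
#'   the data maximum define the correlation footprint (default 0.1).
#' @return list with `scale`, `correlation`, `shift_px` and `image` (the
#'   resampled simulated map, cropped/padded to the data's row count). Warns
#'   when the optimum is clamped at a bound.
#' @export
optimize_periodicity <- function(sim, data, scale_bounds = c(0.5, 2),
                                 footprint_quantile = 0.1) {
  stopifnot(inherits(sim, "height_map"), inherits(data, "height_map"))
  if (abs(sim$pixel_size_nm - data$pixel_size_nm) > 1e-9 * data$pixel_size_nm)
    stop("pixel sizes differ")
  D <- data$heights
  if (max(D) == min(D)) stop("flat data image: correlation undefined")
  sim2 <- match_lateral_frame(sim, data)
  keep_col <- which(apply(D, 2L, max) > footprint_quantile * max(D))
  mask <- D[, keep_col, drop = FALSE] > footprint_quantile * max(D)
  ny <- nrow(D)
  S <- sim2$heights[, keep_col, drop = FALSE]
  shifts <- seq(-24L, 24L, by = 4L)
  Dm <- D[, keep_col][mask]
  score <- function(s, shift) {
    rows <- (seq_len(ny) - 1) / s + 1 + shift
    Ss <- resample_rows(S, rows)
    ncc(Ss[mask], Dm)
  }
  # 0.02 grid; the continuous polish below covers the inter-grid interval
  grid <- seq(scale_bounds[1], scale_bounds[2], by = 0.02)
  best <- c(NA, NA, -Inf)
  for (s in grid) {
    cs <- vapply(shifts, function(sh) score(s, sh), numeric(1))
    j <- which.max(cs)
    if (isTRUE(cs[j] > best[3])) best <- c(s, shifts[j], cs[j])
  }
  if (!is.finite(best[3])) stop("correlation undefined over the footprint")
  # refine shift then scale
  sh_fine <- (best[2] - 3):(best[2] + 3)
  cs <- vapply(sh_fine, function(sh) score(best[1], sh), numeric(1))
  best[2] <- sh_fine[which.max(cs)]
  op <- stats::optimize(function(s) -score(s, best[2]),
                        c(max(scale_bounds[1], best[1] - 0.025),
                          min(scale_bounds[2], best[1] + 0.025)), tol = 1e-4)
  scale <- op$minimum; corr <- -op$objective
  if (corr < best[3]) { scale <- best[1]; corr <- best[3] }
  span <- diff(scale_bounds)
  if (min(scale - scale_bounds[1], scale_bounds[2] - scale) < 0.005 * span)
    warning("periodicity scale clamped at search bound [",
            scale_bounds[1], ", ", scale_bounds[2], "]")
  rows <- (seq_len(ny) - 1) / scale + 1 + best[2]
  full <- resample_rows(sim$heights, rows)
  out <- height_map(full, sim$pixel_size_nm, sim$axis_height_nm)
  list(scale = scale, correlation = corr, shift_px = best[2], image = out)
}
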