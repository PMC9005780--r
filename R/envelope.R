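#' Reconstruct a 3D surface envelope from a straightened AFM topograph
#'
#' The reconstruction proceeds by (i) tip-deconvolving the straightened image
#' (grey-scale erosion by the reflected tip, [deconvolve_topograph()]) to
#' recover the contact-point surface; (ii) mapping each recovered surface
#' point to helix phase: a fibril whose cross-section has C_n symmetry
#' rotates by 2*pi/n per cross-over distance along the axis, so a point at
#' axial position z and lab azimuth phi (about the screw axis) has base
#' azimuth `phi - handedness * 2*pi * z / (n * cod)`; (iii) accumulating
#' radii into angular bins over one 2*pi/n sector across all periods;
#' (iv) averaging per (angle, axial) bin, with per-bin dispersion retained.
#'
#' Only the upper (tip-visible) part of the surface is observed per axial
#' slice; full angular coverage comes from phase accumulation over at least
#' one cross-over period, so shorter images are rejected.
#'
#' @param straight_img straightened [height_map()], fibril along y.
#' @param tip the [build_tip()] model used for imaging.
#' @param n symmetry order (C_n), 1-4.
#' @param cod_nm measured cross-over distance, nm (see
#'   [crossover_distance()]).
#' @param handedness +1 or -1 (left-handed = -1).
#' @param axis_col optional known lateral position of the screw axis (image
#'   column units, may be fractional); when NULL it is estimated from the
#'   image (footprint centroid over whole periods, refined by re-simulation
#'   agreement).
#' @param min_height_nm accumulation threshold: only pixels whose deconvolved
#'   height exceeds this are used. Default is the axis height itself - below
#'   it the deconvolved surface blends into the tip-inaccessible wedge
#'   between the fibril flank and the substrate, where the contact-point
#'   estimate no longer equals the true surface.
#' @param refine_axis refine the estimated axis position by re-simulation
#'   agreement (default TRUE; ignored when `axis_col` is given).
#' @return an `envelope3d`: radial matrix `r` (K angular bins x image rows,
#'   NA where unobserved), `theta` bin centres (radians, sector [0, 2*pi/n)),
#'   `z_nm`, `symmetry_order`, `cod_nm`, `handedness`, `axis_height_nm`.
#' @export
reconstruct_envelope <- function(straight_img, tip, n, cod_nm, handedness = -1,
                                 axis_col = NULL, min_height_nm = NULL,
                                 refine_axis = TRUE) {
  stopifnot(inherits(straight_img, "height_map"), inherits(tip, "tip_model"))
  n <- as.integer(n)
  if (!n %in% 1:4) stop("symmetry order must be 1, 2, 3 or 4")
  if (!handedness %in% c(-1, 1)) stop("handedness must be -1 or +1")
  if ((nrow(straight_img$heights) - 1L) * straight_img$pixel_size_nm < cod_nm)
    stop("image must span at least one full cross-over period")
  prep <- envelope_prep(straight_img, tip)
  if (is.null(axis_col) && isTRUE(refine_axis)) {
    # the intensity-weighted footprint centroid is biased for asymmetric
    # cross-sections (dilation is nonlinear); refine the axis position by
    # re-simulation agreement, which peaks at the true axis
    env0 <- envelope_accumulate(prep, n, cod_nm, handedness, NULL,
                                min_height_nm)
    px0 <- straight_img$pixel_size_nm
    len <- (nrow(straight_img$heights) - 1L) * px0
    score_at <- function(xc) {
      e <- envelope_accumulate(prep, n, cod_nm, handedness, xc, min_height_nm)
      sim <- simulate_topograph(envelope_to_surface(e, len), tip, px0)
      resimulation_score(sim, straight_img)[["direct"]]
    }
    offs <- c(-1, -0.5, 0, 0.5, 1)
    sc <- vapply(env0$axis_col + offs, score_at, numeric(1))
    k <- which.max(sc)
    # parabolic refinement on the top three scores where possible
    xc_best <- env0$axis_col + offs[k]
    if (k > 1L && k < length(offs)) {
      den <- sc[k - 1L] - 2 * sc[k] + sc[k + 1L]
      if (den < 0)
        xc_best <- xc_best + 0.5 * 0.5 * (sc[k - 1L] - sc[k + 1L]) / den
    }
    return(envelope_accumulate(prep, n, cod_nm, handedness, xc_best,
                               min_height_nm))
  }
  envelope_accumulate(prep, n, cod_nm, handedness, axis_col, min_height_nm)
}

# axis-independent part of the reconstruction: adaptive denoising, lateral
# upsampling, tip erosion, edge margins and the flattened sample arrays
envelope_prep <- function(straight_img, tip) {
  px <- straight_img$pixel_size_nm
  ny <- nrow(straight_img$heights)
  img <- straight_img
  # grey-scale erosion tracks noise minima, biasing the recovered surface
  # downward; smooth adaptively so residual noise stays ~2% of the peak
  sub_cols <- apply(img$heights, 2L, stats::median) < 0.1 * max(img$heights)
  noise_sd <- if (any(sub_cols)) stats::mad(img$heights[, sub_cols])
              else stats::mad(as.numeric(diff(img$heights))) / sqrt(2)
  hpk <- max(img$heights)
  if (hpk > 0 && noise_sd > 0.01 * hpk) {
    sigma <- min(1.5, noise_sd / (3.5 * 0.02 * hpk))
    img$heights <- gauss_blur2(img$heights, sigma)
  }
  # upsample the (smooth) tip-convolved image 4x laterally, then erode on
  # the fine grid: sampling the erosion minimum densely beats interpolating
  # the eroded surface afterwards, which has contact-switch kinks
  ups <- 4L
  nxs <- ncol(img$heights) * ups
  cols <- seq(1, ncol(img$heights), length.out = nxs)
  fine <- matrix(cpp_interp_bicubic(img$heights,
                                    rep(seq_len(ny), times = nxs) - 1,
                                    rep(cols, each = ny) - 1), ny, nxs)
  ero <- cpp_erode_topograph(fine, px * (cols[2] - cols[1]), px,
                             tip$radius_nm, tip$half_angle_deg * pi / 180)
  hmax <- max(ero)
  # exclude rows within one tip footprint of the image ends: there the
  # erosion window is truncated by the image boundary (and, for simulated
  # map segments, polluted by the segment end caps), so the recovered
  # surface is biased
  margin <- ceiling(tip_footprint(tip, hmax) / px)
  row_ok <- rep(FALSE, ny)
  if (ny - 2L * margin >= 2L)
    row_ok[(margin + 1L):(ny - margin)] <- TRUE
  else row_ok[] <- TRUE  # image too short to trim; keep everything
  list(ero = ero, cols = cols, ny = ny, nxs = nxs, px = px,
       h0 = hmax / 2,  # screw axis height: peaks reach 2 * max radius
       margin = margin, row_ok = row_ok)
}

# axis- and symmetry-dependent part: helical phase accumulation of the
# eroded surface samples into (theta, z) bins
envelope_accumulate <- function(prep, n, cod_nm, handedness, axis_col,
                                min_height_nm) {
  px <- prep$px; ny <- prep$ny; cols <- prep$cols
  h0 <- prep$h0
  ero <- prep$ero
  row_ok <- prep$row_ok
  if (is.null(min_height_nm)) min_height_nm <- h0
  if ((sum(row_ok) - 1L) * px < cod_nm)
    row_ok <- rep(TRUE, ny)  # trimming would drop below one period
  # lateral axis position: footprint centroid over an integer number of
  # cross-over periods, where the rotating (possibly asymmetric) section
  # averages exactly onto the screw axis; in fine-column units
  nper <- max(1L, floor((sum(row_ok) - 1L) * px / cod_nm))
  rows_int <- which(row_ok)[seq_len(min(sum(row_ok),
                                        floor(nper * cod_nm / px) + 1L))]
  if (is.null(axis_col)) {
    x0 <- footprint_centroid_col(ero[rows_int, , drop = FALSE])
  } else {
    # convert image-column units to fine-column units
    x0 <- (axis_col - cols[1]) / (cols[2] - cols[1]) + 1
  }
  K <- as.integer(round(360 / n))
  sector <- 2 * pi / n
  rmat <- matrix(NA_real_, K, ny)
  cnt <- matrix(0L, K, ny)
  # accumulate every fine-grid surface sample above the axis height; axial
  # sampling stays at the scan rows (the surface rotates between rows, so
  # interpolating across them would mix azimuths)
  rows_g <- rep(seq_len(ny), times = prep$nxs)
  cols_g <- rep(cols, each = ny)
  hv <- as.numeric(ero)
  keep <- hv > min_height_nm & row_ok[rows_g]
  if (!any(keep)) stop("no surface samples above the height threshold")
  xc <- (cols_g[keep] - 1) * px   # column 1 sits at 0 nm
  hk <- hv[keep]
  zrow <- rows_g[keep]
  z <- (zrow - 1L) * px
  psi <- handedness * 2 * pi * z / (n * cod_nm)
  x0_nm <- (cols[1] + (x0 - 1) * (cols[2] - cols[1]) - 1) * px
  u <- xc - x0_nm
  w <- hk - h0
  r <- sqrt(u^2 + w^2)
  phi <- atan2(w, u)
  theta <- (phi - psi) %% sector
  bin <- pmin(floor(theta / sector * K) + 1L, K)
  acc <- rowsum(cbind(r, 1), group = bin + K * (zrow - 1L))
  ids <- as.integer(rownames(acc))
  rmat[ids] <- acc[, 1] / acc[, 2]
  cnt[ids] <- as.integer(acc[, 2])
  cover <- rowSums(cnt) > 0L
  if (mean(!cover) > 0.10)
    stop(sprintf("insufficient angular coverage: %.0f%% of bins empty",
                 100 * mean(!cover)))
  structure(list(r = rmat, theta = (seq_len(K) - 0.5) * sector / K,
                 z_nm = (seq_len(ny) - 1L) * px, symmetry_order = as.integer(n),
                 cod_nm = cod_nm, handedness = handedness,
                 axis_height_nm = h0, axis_col = x0_nm / px + 1,
                 pixel_size_nm = px),
            class = "envelope3d")
}

#' @export
print.envelope3d <- function(x, ...) {
  cat(sprintf("3D envelope: C%d, cod %.1f nm, %s-handed, axis height %.2f nm, %d angular bins\n",
              x$symmetry_order, x$cod_nm,
              if (x$handedness < 0) "left" else "right",
              x$axis_height_nm, nrow(x$r)))
  invisible(x)
}

# mean radial profile over the sector, NA bins filled by circular
# linear interpolation
envelope_mean_radius <- function(env, fun = function(v) mean(v, na.rm = TRUE)) {
  prof <- apply(env$r, 1L, function(v) if (all(is.na(v))) NA_real_ else fun(v))
  fill_circular_na(prof)
}

fill_circular_na <- function(v) {
  if (!anyNA(v)) return(v)
  n <- length(v)
  ok <- which(!is.na(v))
  if (length(ok) == 0L) stop("no observed bins")
  x3 <- c(ok - n, ok, ok + n)
  y3 <- rep(v[ok], 3L)
  stats::approx(x3, y3, xout = seq_len(n))$y
}

#' Extract the cross-section of a reconstructed envelope
#'
#' Mean radius per angular bin over the axial direction, with lower/upper
#' percentile curves capturing the structural variation along the fibril,
#' replicated n-fold over the full 2*pi. The screw axis is at the origin.
#'
#' @param env an `envelope3d`.
#' @param probs percentile bounds (default 2.5 and 97.5).
#' @return a [cross_section()] with `lo`/`hi` percentile curves.
#' @export
envelope_cross_section <- function(env, probs = c(0.025, 0.975)) {
  stopifnot(inherits(env, "envelope3d"))
  m <- envelope_mean_radius(env)
  lo <- envelope_mean_radius(env, function(v) stats::quantile(v, probs[1], na.rm = TRUE))
  hi <- envelope_mean_radius(env, function(v) stats::quantile(v, probs[2], na.rm = TRUE))
  n <- env$symmetry_order
  th_full <- as.numeric(outer(env$theta, 2 * pi / n * (seq_len(n) - 1L), "+"))
  mk <- function(r) {
    r <- rep(r, n)
    cbind(x = r * cos(th_full), y = r * sin(th_full))
  }
  cross_section(mk(m), lo = mk(lo), hi = mk(hi), axis_xy = c(0, 0))
}

#' Rebuild a surface cloud from a reconstructed envelope
#'
#' Sweeps the envelope's mean cross-section helically (rotation of 2*pi/n per
#' cross-over distance, signed by handedness) to the requested length, in the
#' axis frame (screw axis = z).
#'
#' @param env an `envelope3d`.
#' @param length_nm axial length, nm.
#' @param axial_step_nm axial sampling (default the envelope's pixel pitch / 2).
#' @param n_theta angular samples per ring.
#' @return a [surface_cloud()].
#' @export
envelope_to_surface <- function(env, length_nm, axial_step_nm = NULL,
                                n_theta = 256L) {
  stopifnot(inherits(env, "envelope3d"))
  if (is.null(axial_step_nm)) axial_step_nm <- env$pixel_size_nm / 2
  n <- env$symmetry_order
  rm <- envelope_mean_radius(env)
  th_full <- as.numeric(outer(env$theta, 2 * pi / n * (seq_len(n) - 1L), "+"))
  ord <- order(th_full)
  thq <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  rq <- stats::approx(c(th_full[ord] - 2 * pi, th_full[ord], th_full[ord] + 2 * pi),
                      rep(rep(rm, n)[ord], 3L), xout = thq)$y
  rate <- env$handedness * 2 * pi / (n * env$cod_nm)
  zs <- seq(0, length_nm, by = axial_step_nm)
  ang <- outer(thq, zs * rate, "+")
  surface_cloud(cbind(as.numeric(rq * cos(ang)), as.numeric(rq * sin(ang)),
                      rep(zs, each = n_theta)),
                voxel_size_nm = env$pixel_size_nm / 2)
}

#' Export an envelope as PLY mesh + JSON grid
#' @param env an `envelope3d`.
#' @param path_prefix writes `<prefix>.ply` and `<prefix>.json`.
#' @return `path_prefix`, invisibly.
#' @export
write_envelope <- function(env, path_prefix) {
  surf <- envelope_to_surface(env, max(env$z_nm))
  write_surface(surf, paste0(path_prefix, ".ply"))
  jsonlite::write_json(list(theta_rad = env$theta, z_nm = env$z_nm,
                            r_nm = env$r, symmetry_order = env$symmetry_order,
                            cod_nm = env$cod_nm, handedness = env$handedness,
                            axis_height_nm = env$axis_height_nm),
                       paste0(path_prefix, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path_prefix)
}

# direct + Fourier-magnitude agreement between a re-simulated topograph and
# the input topograph
resimulation_score <- function(sim, data, footprint_quantile = 0.1) {
  sim <- match_lateral_frame(sim, data)
  ny <- min(nrow(sim$heights), nrow(data$heights))
  S <- sim$heights[seq_len(ny), , drop = FALSE]
  D <- data$heights[seq_len(ny), , drop = FALSE]
  keep <- which(apply(D, 2L, max) > footprint_quantile * max(D))
  S <- S[, keep, drop = FALSE]; D <- D[, keep, drop = FALSE]
  # remove the static transverse ridge profile so the score reflects the
  # axial twist-modulation pattern, not the (model-independent) mean shape
  Sm <- sweep(S, 2L, colMeans(S))
  Dm <- sweep(D, 2L, colMeans(D))
  direct <- ncc(as.numeric(Sm), as.numeric(Dm))
  fs <- Mod(stats::fft(Sm))
  fd <- Mod(stats::fft(Dm))
  fourier <- ncc(as.numeric(fs)[-1L], as.numeric(fd)[-1L])
  c(direct = direct, fourier = fourier, combined = (direct + fourier) / 2)
}

#' Identify the helical symmetry order from a fibril topograph
#'
#' For each candidate order n an envelope is reconstructed from the image, a
#' topograph is re-simulated from it, and the agreement with the input image
#' is scored in direct space (normalized cross-correlation over the fibril
#' footprint) and in Fourier space (correlation of the 2D spectral
#' magnitudes); the wrong order spreads the surface pattern at the wrong
#' twist angle and scores lower. Returns the best-scoring order.
#'
#' @param straight_img straightened [height_map()].
#' @param tip the imaging [build_tip()] model.
#' @param cod_nm measured cross-over distance, nm.
#' @param candidates candidate orders, subset of 1:4.
#' @param handedness twist handedness of the imaged fibril.
#' @return the selected order (integer) with attributes `scores` (combined
#'   per-candidate scores) and `ambiguous` (TRUE when the top two scores are
#'   within 1%, with a warning).
#' @export
detect_symmetry <- function(straight_img, tip, cod_nm, candidates = c(1L, 2L),
                            handedness = -1) {
  candidates <- sort(unique(as.integer(candidates)))
  if (!all(candidates %in% 1:4)) stop("candidates must be within 1..4")
  px <- straight_img$pixel_size_nm
  len <- (nrow(straight_img$heights) - 1L) * px
  if (len < cod_nm)
    stop("image must span at least one full cross-over period")
  prep <- envelope_prep(straight_img, tip)  # erosion shared across orders
  scores <- vapply(candidates, function(n) {
    env <- envelope_accumulate(prep, n, cod_nm, handedness, NULL, NULL)
    surf <- envelope_to_surface(env, len)
    sim <- simulate_topograph(surf, tip, px)
    resimulation_score(sim, straight_img)[["combined"]]
  }, numeric(1))
  names(scores) <- paste0("C", candidates)
  ord <- order(scores, decreasing = TRUE)
  best <- candidates[ord[1]]
  amb <- FALSE
  if (length(scores) > 1L &&
      (scores[ord[1]] - scores[ord[2]]) < 0.01 * abs(scores[ord[1]])) {
    amb <- TRUE
    warning("ambiguous symmetry: top two candidate scores within 1%")
  }
  structure(best, scores = scores, ambiguous = amb)
}
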