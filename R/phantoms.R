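# ---- parametric cross-sections ---------------------------------------------
# Phantom cross-sections are star-shaped about the screw axis (the origin) and
# described by a radial function r(theta) > 0, which keeps areas, unions and
# C_n replication exact and cheap.

#' Elliptical cross-section (C2)
#' @param a,b semi-axes, nm.
#' @return vectorized radial function r(theta).
#' @export
cs_ellipse <- function(a, b) {
  force(a); force(b)
  function(th) a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
}

#' Two-lobed cross-section (C2), the union of two circles straddling the axis
#' @param r_lobe lobe radius, nm.
#' @param sep centre-to-centre separation (< 2 r_lobe so the lobes fuse), nm.
#' @return vectorized radial function r(theta).
#' @export
cs_two_lobe <- function(r_lobe, sep) {
  force(r_lobe); force(sep)
  c2 <- sep / 2
  if (c2 >= r_lobe) stop("lobes must overlap (sep < 2 * r_lobe)")
  function(th) {
    s2 <- (c2 * sin(th))^2
    r1 <- c2 * cos(th) + sqrt(pmax(r_lobe^2 - s2, 0))
    r2 <- -c2 * cos(th) + sqrt(pmax(r_lobe^2 - s2, 0))
    pmax(r1, r2)
  }
}

#' Egg-shaped asymmetric cross-section (C1)
#'
#' `r(theta) = r0 (1 + e1 cos(theta) + e2 cos(2 theta + phase))`; with
#' `e1 != 0` the centroid lies off the screw axis.
#' @param r0 base radius, nm.
#' @param e1,e2 harmonic distortions (|e1| + |e2| < 1).
#' @param phase phase of the second harmonic, radians.
#' @return vectorized radial function r(theta).
#' @export
cs_egg <- function(r0, e1 = 0.25, e2 = 0.1, phase = 0) {
  force(r0); force(e1); force(e2); force(phase)
  if (abs(e1) + abs(e2) >= 1) stop("|e1| + |e2| must be < 1")
  function(th) r0 * (1 + e1 * cos(th) + e2 * cos(2 * th + phase))
}

# sample a radial function into a closed polygon (K x 2, CCW, open ring)
sample_radial <- function(r_fun, K = 360L) {
  th <- seq(0, 2 * pi, length.out = K + 1L)[-(K + 1L)]
  r <- r_fun(th)
  if (any(!is.finite(r)) || any(r <= 0)) stop("radial function must be positive")
  cbind(x = r * cos(th), y = r * sin(th))
}

# area enclosed by a radial function, 0.5 * integral r^2 dtheta
radial_area <- function(r_fun, K = 3600L) {
  th <- seq(0, 2 * pi, length.out = K + 1L)[-(K + 1L)]
  mean(r_fun(th)^2) * pi
}

#' Generate a helical phantom fibril with known ground truth
#'
#' Sweeps a star-shaped cross-section helically about the z-axis (the screw
#' axis), producing a surface point cloud, a voxelized density map (inside =
#' 1, outside = 0, smoothed by a 1-voxel Gaussian, recommended isovalue 0.5)
#' and a ground-truth record. The supplied cross-section must exhibit the
#' declared C_n symmetry.
#'
#' @param r_fun radial function of the cross-section (nm), e.g. [cs_ellipse()].
#' @param twist_deg,rise_nm,handedness,symmetry_order helical parameters
#'   (see [helical_params()]).
#' @param length_nm fibril length along z, nm.
#' @param voxel_nm voxel size of the phantom density map, nm.
#' @param axial_step_nm axial sampling of the surface cloud (default
#'   `voxel_nm / 2`).
#' @param n_theta angular samples per cross-section ring (default 256).
#' @param make_volume set `FALSE` to skip the (more expensive) density map.
#' @return list with `surface` ([surface_cloud()]), `volume`
#'   ([volume_grid()] or NULL) and `truth` (cod_nm, csa_nm2, axis_height_nm,
#'   max_radius_nm, helical parameters; the screw axis is the z-axis).
#' @export
make_phantom <- function(r_fun, twist_deg, rise_nm, handedness = sign(twist_deg),
                         symmetry_order = 1L, length_nm = 100, voxel_nm = 0.5,
                         axial_step_nm = NULL, n_theta = 256L,
                         make_volume = TRUE) {
  helical <- helical_params(twist_deg, rise_nm, handedness, symmetry_order)
  n <- helical$symmetry_order
  th <- seq(0, 2 * pi, length.out = 721L)[-721L]
  if (n > 1L && max(abs(r_fun(th) - r_fun((th + 2 * pi / n) %% (2 * pi)))) >
      1e-6 * max(r_fun(th)))
    warning("cross-section does not have the declared C", n, " symmetry")
  if (is.null(axial_step_nm)) axial_step_nm <- voxel_nm / 2
  thv <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  rv <- r_fun(thv)
  zs <- seq(0, length_nm, by = axial_step_nm)
  rate <- twist_deg * pi / 180 / rise_nm  # rad per nm of z
  ang <- outer(thv, zs * rate, "+")
  xs <- as.numeric(rv * cos(ang))
  ys <- as.numeric(rv * sin(ang))
  zz <- rep(zs, each = n_theta)
  surface <- surface_cloud(cbind(xs, ys, zz), helical = helical,
                           voxel_size_nm = voxel_nm)
  vol <- NULL
  if (make_volume) {
    rmax <- max(rv)
    half <- ceiling((rmax + 2 * voxel_nm) / voxel_nm)
    gx <- (-half:half) * voxel_nm
    nz <- floor(length_nm / voxel_nm) + 1L
    gz <- (seq_len(nz) - 1L) * voxel_nm
    poly <- cbind(rv * cos(thv), rv * sin(thv))
    grid_xy <- as.matrix(expand.grid(x = gx, y = gx))
    dat <- array(0, dim = c(length(gx), length(gx), nz))
    for (k in seq_len(nz)) {
      a <- gz[k] * rate
      p <- rot_z(grid_xy, -a)  # untwist the slice instead of rotating the polygon
      dat[, , k] <- matrix(as.numeric(mgcv::in.out(rbind(poly, poly[1, ]), p)),
                           length(gx), length(gx))
    }
    dat <- gauss_smooth3(dat, 1)
    vol <- volume_grid(dat, voxel_nm, origin_nm = c(gx[1], gx[1], 0),
                       isovalue = 0.5)
  }
  truth <- list(cod_nm = helical_cod(helical),
                csa_nm2 = radial_area(r_fun),
                axis_height_nm = max(rv),
                max_radius_nm = max(rv),
                twist_deg = twist_deg, rise_nm = rise_nm,
                handedness = helical$handedness, symmetry_order = n)
  list(surface = surface, volume = vol, truth = truth, helical = helical,
       r_fun = r_fun)
}

# separable 2D Gaussian blur, sigma in pixels
gauss_blur2 <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_filter <- function(v) stats::filter(c(rep(v[1], r), v, rep(v[length(v)], r)),
                                          k, sides = 2L)[(r + 1L):(r + length(v))]
  m <- apply(m, 2L, pad_filter)
  t(apply(m, 1L, pad_filter))
}

# separable 3D Gaussian smoothing, sigma in voxels, kernel +-3 sigma
gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(arr)
  smooth_dim <- function(a, ax) {
    m <- apply(a, setdiff(1:3, ax), function(v)
      stats::filter(c(rep(v[1], r), v, rep(v[length(v)], r)), k,
                    sides = 2L)[(r + 1L):(r + length(v))])
    aperm(array(m, dim = c(d[ax], d[setdiff(1:3, ax)])),
          order(c(ax, setdiff(1:3, ax))))
  }
  for (ax in 1:3) arr <- smooth_dim(arr, ax)
  arr
}

#' Simulate a noisy AFM image of a phantom surface
#'
#' [simulate_topograph()] plus additive Gaussian pixel noise and optional
#' line-wise (per-scanline) offset noise, reproducible via `seed`.
#'
#' @param surface a [surface_cloud()] (axis frame).
#' @param tip a [build_tip()] model.
#' @param pixel_nm pixel size, nm.
#' @param noise_sd_nm per-pixel Gaussian noise SD, nm.
#' @param seed RNG seed.
#' @param line_noise_sd_nm per-scanline offset SD, nm (default 0).
#' @return a [height_map()].
#' @export
simulate_noisy_afm <- function(surface, tip, pixel_nm, noise_sd_nm = 0,
                               seed = 1L, line_noise_sd_nm = 0) {
  hm <- simulate_topograph(surface, tip, pixel_nm)
  if (noise_sd_nm > 0 || line_noise_sd_nm > 0) {
    set.seed(seed)
    h <- hm$heights
    if (noise_sd_nm > 0)
      h <- h + matrix(stats::rnorm(length(h), sd = noise_sd_nm), nrow(h))
    if (line_noise_sd_nm > 0)
      h <- h + stats::rnorm(nrow(h), sd = line_noise_sd_nm)
    hm$heights <- h
  }
  hm
}

#' Generate a deterministic panel of decoy phantoms
#'
#' Phantoms spanning the morphometric space: C1 and C2 cross-section shapes
#' (ellipses, fused two-lobe, egg), cross-over distances across [30, 80] nm,
#' both handedness signs and at least a two-fold spread in cross-sectional
#' area. Deterministic for a given seed.
#'
#' @param n_decoys number of phantoms (>= 2).
#' @param seed RNG seed.
#' @param length_nm minimum fibril length; phantoms with long cross-over
#'   distances are extended so each spans at least ~2.3 apparent periods.
#' @param make_volume build density maps too (default FALSE; surfaces only).
#' @return list of phantom entries as returned by [make_phantom()], each with
#'   a `label`.
#' @export
decoy_panel <- function(n_decoys, seed = 1L, length_nm = 100,
                        make_volume = FALSE) {
  if (n_decoys < 2L) stop("need at least 2 decoys")
  set.seed(seed)
  out <- vector("list", n_decoys)
  # deterministically spaced size scales guarantee >= 2-fold spread in
  # cross-sectional area for any panel (order shuffled per seed)
  scales <- sample(seq(0.8, 1.6, length.out = n_decoys))
  for (i in seq_len(n_decoys)) {
    fam <- ((i - 1L) %% 4L) + 1L
    scale <- scales[i]
    # C1 shapes keep the first angular harmonic dominant: a cross-section
    # dominated by its second harmonic is visually near-C2 and its apparent
    # cross-over period is half its pitch, which makes the symmetry/cod
    # truth record ill-posed
    shape <- switch(fam,
      list(r = cs_ellipse(4 * scale, 2.2 * scale), n = 2L),
      list(r = cs_two_lobe(2.6 * scale, 2.8 * scale), n = 2L),
      list(r = cs_egg(3 * scale, 0.3, 0.12), n = 1L),
      list(r = cs_egg(3.2 * scale, 0.3, 0.15, phase = 1), n = 1L))
    cod <- stats::runif(1, 30, 80)
    hnd <- if (i %% 2L == 0L) -1 else 1
    rise <- 0.47
    twist <- hnd * 360 * rise / (cod * shape$n)
    # every phantom spans at least two apparent periods, the precondition
    # for measuring its cross-over distance
    out[[i]] <- make_phantom(shape$r, twist, rise, hnd, shape$n,
                             length_nm = max(length_nm, 2.3 * cod),
                             make_volume = make_volume)
    out[[i]]$label <- sprintf("decoy-%02d", i)
  }
  out
}
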