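#' Flatten an AFM image
#'
#' Removes scanner tilt and bow by fitting, per scan line (image row), a
#' polynomial background to the substrate pixels (those below a robust
#' threshold, median + 3 * MAD of the row) and subtracting it, leaving the
#' substrate mode at ~0. A stand-in for vendor flattening tools.
#'
#' @param img a [height_map()].
#' @param order polynomial order, 1-3.
#' @return the flattened [height_map()].
#' @export
flatten_image <- function(img, order = 2L) {
  stopifnot(inherits(img, "height_map"))
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  h <- img$heights
  x <- seq_len(ncol(h)) / ncol(h)
  X <- cbind(1, stats::poly(x, order, raw = TRUE))
  for (i in seq_len(nrow(h))) {
    row <- h[i, ]
    # two passes: the substrate selection threshold is applied to the
    # residual of the first fit, so it does not depend on the tilt itself
    res <- row
    for (pass in 1:2) {
      thr <- stats::median(res) + 3 * stats::mad(res)
      bg <- res <= thr
      if (sum(bg) <= order + 1L) bg <- rep(TRUE, length(row))
      fit <- stats::lm.fit(X[bg, , drop = FALSE], row[bg])
      res <- row - as.numeric(X %*% fit$coefficients)
    }
    h[i, ] <- res
  }
  out <- img
  out$heights <- h
  out
}

#' Trace and digitally straighten a fibril
#'
#' Follows the fibril ridge from one seed endpoint to the other with
#' sub-pixel, intensity-weighted lateral re-centring, smooths the centreline,
#' then resamples the image perpendicular to the local tangent (bicubic
#' interpolation) into a straightened strip with the fibril along the image
#' y-axis. Arc length is preserved.
#'
#' @param img a flattened [height_map()].
#' @param seed_px 2 x 2 matrix of approximate endpoints, pixel coordinates
#'   (col, row).
#' @param half_width_px half-width of the straightened strip; default 2x the
#'   apparent fibril half-width.
#' @param step_px tracing step along the ridge, pixels.
#' @return a `fibril_trace`: `centerline` (pixel coords), `straightened`
#'   ([height_map()]) and `length_nm`.
#' @export
trace_and_straighten <- function(img, seed_px, half_width_px = NULL,
                                 step_px = 2) {
  stopifnot(inherits(img, "height_map"))
  h <- img$heights
  px <- img$pixel_size_nm
  # noise from the row-to-row derivative (structure cancels, noise doubles)
  noise_sd <- stats::mad(as.numeric(diff(h))) / sqrt(2)
  if (max(h) < 5 * max(noise_sd, 1e-12))
    stop("fibril contrast too low to trace (peak < 5x noise SD)")
  thr <- max(h) * 0.3
  # apparent half width from the footprint area
  if (is.null(half_width_px)) {
    foot <- sum(h > thr)
    seedv <- seed_px[2, ] - seed_px[1, ]
    approx_len <- sqrt(sum(seedv^2))
    half_width_px <- max(4, round(2 * foot / (2 * approx_len)) * 2)
  }
  recentre <- function(pt, normal) {
    offs <- seq(-half_width_px, half_width_px, by = 0.5)
    xs <- pt[1] + offs * normal[1]
    ys <- pt[2] + offs * normal[2]
    v <- cpp_interp_bicubic(h, ys - 1, xs - 1)
    w <- pmax(v - thr, 0)
    if (sum(w) == 0) return(NULL)
    dc <- sum(offs * w) / sum(w)
    pt + dc * normal
  }
  trace_dir <- function(start, towards) {
    dirv <- towards - start
    dirv <- dirv / sqrt(sum(dirv^2))
    pt <- start
    path <- list(pt)
    for (it in seq_len(20000L)) {
      nrm <- c(-dirv[2], dirv[1])
      newpt <- recentre(pt + step_px * dirv, nrm)
      if (is.null(newpt)) break
      hgt <- cpp_interp_bicubic(h, newpt[2] - 1, newpt[1] - 1)
      if (hgt < thr) break
      dnew <- newpt - pt
      dnew <- dnew / sqrt(sum(dnew^2))
      dirv <- dirv + 0.7 * (dnew - dirv)
      dirv <- dirv / sqrt(sum(dirv^2))
      pt <- newpt
      path[[length(path) + 1L]] <- pt
      if (newpt[1] < 2 || newpt[2] < 2 || newpt[1] > ncol(h) - 1 ||
          newpt[2] > nrow(h) - 1) break
    }
    do.call(rbind, path)
  }
  p0 <- recentre(seed_px[1, ], {
    d <- seed_px[2, ] - seed_px[1, ]
    d <- d / sqrt(sum(d^2)); c(-d[2], d[1])
  })
  if (is.null(p0)) stop("trace failed: no ridge at the first seed point")
  cl <- trace_dir(p0, seed_px[2, ])
  if (is.null(cl) || nrow(cl) < 5L)
    stop("trace failed: ridge lost near the seed")
  # smooth the centreline against arc length
  t0 <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  sx <- stats::smooth.spline(t0, cl[, 1], spar = 0.4)
  sy <- stats::smooth.spline(t0, cl[, 2], spar = 0.4)
  # resample at 1 px arc-length steps
  tt <- seq(0, max(t0), by = 1)
  cx <- stats::predict(sx, tt)$y
  cy <- stats::predict(sy, tt)$y
  # re-measure arc length after smoothing
  seg <- sqrt(diff(cx)^2 + diff(cy)^2)
  arc <- c(0, cumsum(seg))
  tangent <- cbind(c(diff(cx), NA), c(diff(cy), NA))
  tangent[length(cx), ] <- tangent[length(cx) - 1L, ]
  tangent <- tangent / sqrt(rowSums(tangent^2))
  offs <- seq(-half_width_px, half_width_px, by = 1)
  strip <- matrix(0, length(cx), length(offs))
  for (i in seq_along(cx)) {
    nrm <- c(-tangent[i, 2], tangent[i, 1])
    xs <- cx[i] + offs * nrm[1]
    ys <- cy[i] + offs * nrm[2]
    strip[i, ] <- cpp_interp_bicubic(h, ys - 1, xs - 1)
  }
  structure(list(centerline = cbind(col = cx, row = cy),
                 straightened = height_map(pmax(strip, 0), px),
                 length_nm = max(arc) * px),
            class = "fibril_trace")
}

#' @export
print.fibril_trace <- function(x, ...) {
  cat(sprintf("Fibril trace: %.1f nm long, straightened strip %d x %d px\n",
              x$length_nm, nrow(x$straightened$heights),
              ncol(x$straightened$heights)))
  invisible(x)
}

#' Write a fibril trace (centerline JSON + straightened TSV)
#' @param trace a `fibril_trace`.
#' @param path_prefix output prefix: writes `<prefix>_centerline.json` and
#'   `<prefix>_straightened.tsv` (+ `.json` sidecar).
#' @return `path_prefix`, invisibly.
#' @export
write_fibril_trace <- function(trace, path_prefix) {
  jsonlite::write_json(list(centerline_px = trace$centerline,
                            length_nm = trace$length_nm),
                       paste0(path_prefix, "_centerline.json"),
                       auto_unbox = TRUE, digits = NA)
  write_height_tsv(trace$straightened, paste0(path_prefix, "_straightened.tsv"))
  invisible(path_prefix)
}

#' Centre-line height profile of a straightened fibril
#'
#' Heights along the central column of the straightened strip, sub-pixel
#' interpolated at the lateral footprint centroid.
#'
#' @param trace a `fibril_trace`, or a straightened [height_map()].
#' @return data.frame with `z_nm` (axial position) and `height_nm`.
#' @export
centerline_profile <- function(trace) {
  hm <- if (inherits(trace, "fibril_trace")) trace$straightened else trace
  stopifnot(inherits(hm, "height_map"))
  cc <- footprint_centroid_col(hm$heights)
  v <- cpp_interp_bicubic(hm$heights, seq_len(nrow(hm$heights)) - 1,
                          rep(cc - 1, nrow(hm$heights)))
  data.frame(z_nm = (seq_len(nrow(hm$heights)) - 1L) * hm$pixel_size_nm,
             height_nm = v)
}

#' Cross-over distance from a centre-line profile
#'
#' The average cross-over distance is the period of the dominant non-DC peak
#' of the profile's Fourier spectrum (quadratically interpolated between
#' frequency bins); per-period distances are the spacings of consecutive
#' profile minima. Invariant to the profile's mean and amplitude.
#'
#' @param profile data.frame from [centerline_profile()], or a numeric height
#'   vector (then `pixel_size_nm` must be given).
#' @param pixel_size_nm axial sample spacing, nm.
#' @return list with `cod_nm` (Fourier estimate), `periods_nm` (consecutive
#'   minima spacings) and `minima_nm` (minima positions).
#' @export
crossover_distance <- function(profile, pixel_size_nm = NULL) {
  if (is.data.frame(profile)) {
    v <- profile$height_nm
    pixel_size_nm <- profile$z_nm[2] - profile$z_nm[1]
  } else {
    v <- as.numeric(profile)
    if (is.null(pixel_size_nm)) stop("pixel_size_nm required for a bare vector")
  }
  n <- length(v)
  vc <- v - mean(v)
  sp <- (Mod(stats::fft(vc))^2)[2:floor(n / 2)]  # non-DC half-spectrum
  if (all(sp == 0)) stop("aperiodic profile: no non-DC spectral peak")
  k <- which.max(sp)
  bgr <- stats::median(sp)
  if (sp[k] < 3 * bgr)
    stop("aperiodic profile: dominant peak below 3x spectral background")
  # refine the peak frequency on an 8x zero-padded spectrum (finite profiles
  # of a couple of periods otherwise quantize the period badly)
  np <- 8L * n
  spp <- (Mod(stats::fft(c(vc, rep(0, np - n))))^2)[seq_len(floor(np / 2))]
  lo <- max(2L, (k - 1L) * 8L - 7L)
  hi <- min(floor(np / 2) - 1L, (k + 1L) * 8L + 9L)
  kp <- lo - 1L + which.max(spp[lo:hi])
  y1 <- log(spp[kp - 1L] + 1e-300); y2 <- log(spp[kp] + 1e-300)
  y3 <- log(spp[kp + 1L] + 1e-300)
  den <- y1 - 2 * y2 + y3
  delta <- if (den < 0) 0.5 * (y1 - y3) / den else 0
  freq <- (kp - 1L + delta) / (np * pixel_size_nm)
  cod <- 1 / freq
  # per-period: minima of the lightly smoothed profile
  sm <- stats::filter(vc, rep(1 / 5, 5), sides = 2L)
  sm[is.na(sm)] <- vc[is.na(sm)]
  mins <- which(diff(sign(diff(sm))) > 0) + 1L
  # keep minima separated by at least half the Fourier period
  if (length(mins) > 1L) {
    keep <- c(TRUE, diff(mins) * pixel_size_nm > cod / 2)
    while (!all(keep)) {
      mins <- mins[keep]
      keep <- c(TRUE, diff(mins) * pixel_size_nm > cod / 2)
    }
  }
  list(cod_nm = cod,
       periods_nm = diff(mins) * pixel_size_nm,
       minima_nm = (mins - 1L) * pixel_size_nm)
}
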