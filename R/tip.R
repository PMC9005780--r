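#' Build an AFM tip model
#'
#' Constructs a sphere-capped cone probe model: a spherical apex of radius
#' `radius_nm` joined tangent-continuously to a cone of half-angle
#' `half_angle_deg` (measured from the probe axis). The model is the height
#' profile `z(d)` of the tip surface above its apex at lateral distance `d`,
#' which is all that geometric contact-point imaging needs.
#'
#' @param radius_nm apex sphere radius in nm (> 0).
#' @param half_angle_deg cone half-angle in degrees, strictly between 0 and 90.
#'   The default (18 degrees) is typical of sharpened silicon-nitride probes.
#' @return an object of class `tip_model`.
#' @examples
#' tip <- build_tip(10)
#' tip_height(tip, 6) # 2 nm: spherical-cap geometry
#' @export
build_tip <- function(radius_nm, half_angle_deg = 18) {
  if (!is.numeric(radius_nm) || length(radius_nm) != 1L || !is.finite(radius_nm) ||
      radius_nm <= 0)
    stop("radius_nm must be a single positive number")
  if (!is.numeric(half_angle_deg) || length(half_angle_deg) != 1L ||
      half_angle_deg <= 0 || half_angle_deg >= 90)
    stop("half_angle_deg must lie strictly between 0 and 90 degrees")
  structure(list(radius_nm = radius_nm, half_angle_deg = half_angle_deg),
            class = "tip_model")
}

#' Tip height profile
#'
#' Vertical drop `z(d)` of the tip surface at lateral distance `d` from the
#' apex: `R - sqrt(R^2 - d^2)` within the spherical cap, continuing along the
#' tangent cone beyond `d = R cos(alpha)`.
#'
#' @param tip a [build_tip()] model.
#' @param d_nm lateral distance(s) from the apex, nm.
#' @return height(s) in nm; `z(0) = 0`.
#' @export
tip_height <- function(tip, d_nm) {
  stopifnot(inherits(tip, "tip_model"))
  cpp_tip_z(as.numeric(d_nm), tip$radius_nm, tip$half_angle_deg * pi / 180)
}

#' Tip footprint radius
#'
#' Lateral distance at which the tip profile first reaches height `h`: the
#' radius of the region of a flat substrate that a feature of height `h` can
#' influence through tip-sample contact.
#'
#' @param tip a [build_tip()] model.
#' @param h_nm feature height(s), nm.
#' @return footprint radius/radii in nm.
#' @export
tip_footprint <- function(tip, h_nm) {
  R <- tip$radius_nm
  a <- tip$half_angle_deg * pi / 180
  zt <- R * (1 - sin(a))
  ifelse(h_nm <= 0, 0,
         ifelse(h_nm <= zt, sqrt(h_nm * (2 * R - h_nm)),
                R * cos(a) + (h_nm - zt) * tan(a)))
}

#' @export
print.tip_model <- function(x, ...) {
  cat(sprintf("AFM tip model: sphere-capped cone, R = %.2f nm, half-angle = %.1f deg\n",
              x$radius_nm, x$half_angle_deg))
  invisible(x)
}
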