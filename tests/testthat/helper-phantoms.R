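# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

std_tip <- function() build_tip(5, 18)

# canonical C2 elliptical phantom, left-handed, cod 45 nm
c2_phantom <- function() fixture("c2", function() {
  make_phantom(cs_ellipse(4, 2.2), -360 * 0.47 / (45 * 2), 0.47, -1, 2L,
               length_nm = 100, voxel_nm = 0.5, make_volume = FALSE)
})

# asymmetric C1 phantom with off-centre centroid, cod 50 nm
c1_phantom <- function() fixture("c1", function() {
  make_phantom(cs_egg(3, 0.3, 0.12), -360 * 0.47 / 50, 0.47, -1, 1L,
               length_nm = 110, voxel_nm = 0.5, make_volume = FALSE)
})

# C2 phantom with a voxelized density map
c2_volume_phantom <- function() fixture("c2vol", function() {
  make_phantom(cs_ellipse(4, 2), -1.2, 0.47, -1, 2L, length_nm = 60,
               voxel_nm = 0.5)
})

# cylinder surface cloud along z (axis frame), axis on the z-axis
cylinder_surface <- function(radius, length_nm, axial_step = 0.25,
                             n_theta = 256L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(0, length_nm, by = axial_step)
  surface_cloud(cbind(rep(radius * cos(th), length(zs)),
                      rep(radius * sin(th), length(zs)),
                      rep(zs, each = n_theta)),
                voxel_size_nm = 0.5)
}

# closed C-shaped region outline: annular sector with mouth of given width
c_shape_cloud <- function(r_out = 4, r_in = 2.5, mouth_half_angle = 0.25) {
  th <- seq(mouth_half_angle, 2 * pi - mouth_half_angle, length.out = 300L)
  cap1 <- cbind(seq(r_in, r_out, length.out = 20) * cos(mouth_half_angle),
                seq(r_in, r_out, length.out = 20) * sin(mouth_half_angle))
  cap2 <- cbind(seq(r_out, r_in, length.out = 20) * cos(-mouth_half_angle),
                seq(r_out, r_in, length.out = 20) * sin(-mouth_half_angle))
  rbind(cap1, cbind(r_out * cos(th), r_out * sin(th)), cap2,
        cbind(r_in * cos(rev(th)), r_in * sin(rev(th))))
}

point_in_curve <- function(cs, pt) {
  p <- if (inherits(cs, "cross_section")) cs$curve else cs
  mgcv::in.out(rbind(p, p[1, ]), matrix(pt, nrow = 1L))
}
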