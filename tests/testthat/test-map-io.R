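test_that("MRC round trip preserves data, voxel size and origin", {
  set.seed(5)
  vol <- volume_grid(array(runif(12 * 10 * 8), c(12, 10, 8)), 0.5,
                     origin_nm = c(-3, -2.5, 0), isovalue = 0.5)
  f <- tempfile(fileext = ".mrc")
  write_mrc(vol, f)
  back <- read_mrc(f)
  expect_equal(back$data, vol$data, tolerance = 1e-7)  # float32 storage
  expect_equal(back$voxel_size_nm, 0.5, tolerance = 1e-7)
  expect_equal(back$origin_nm, c(-3, -2.5, 0), tolerance = 1e-6)
})

test_that("MRC header units convert Angstrom to nm and malformed maps fail", {
  # hand-written header with 2.5 Angstrom voxels -> 0.25 nm
  f <- tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(4L, 4L, 4L, 2L, 0L, 0L, 0L, 4L, 4L, 4L))
  wf(c(10, 10, 10, 90, 90, 90))       # cella 10 A / 4 voxels = 2.5 A
  wi(c(1L, 2L, 3L))
  wf(c(0, 1, 0.5))
  wi(c(1L, 0L)); wi(rep(0L, 25L)); wf(c(0, 0, 0))
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0.1); wi(0L); writeBin(raw(800L), con)
  writeBin(as.numeric(seq_len(64)), con, size = 4L, endian = "little")
  close(con)
  vol <- read_mrc(f)
  expect_equal(vol$voxel_size_nm, 0.25, tolerance = 1e-7)
  # zero-sized dimension
  z <- readBin(f, "raw", n = file.size(f))
  z[1:4] <- as.raw(c(0, 0, 0, 0))
  fz <- tempfile(fileext = ".mrc")
  writeBin(z, fz)
  expect_error(read_mrc(fz), "zero-sized")
  # missing MAP stamp
  b <- readBin(f, "raw", n = file.size(f))
  b[209:212] <- as.raw(0)
  fb <- tempfile(fileext = ".mrc")
  writeBin(b, fb)
  expect_error(read_mrc(fb), "malformed")
  # anisotropic voxels beyond 1%
  a <- readBin(f, "raw", n = file.size(f))
  a[41:44] <- writeBin(20, raw(), size = 4L, endian = "little")  # cella x
  fa <- tempfile(fileext = ".mrc")
  writeBin(a, fa)
  expect_error(read_mrc(fa), "anisotropic")
})

test_that("iso-surface of analytic solids has the right geometry", {
  # solid sphere radius 5 at half-max isovalue
  g <- seq(-8, 8, by = 0.5)
  d <- array(0, c(length(g), length(g), length(g)))
  for (k in seq_along(g))
    d[, , k] <- outer(g, g, function(x, y) 1 / (1 + exp(4 * (sqrt(x^2 + y^2 + g[k]^2) - 5))))
  vol <- volume_grid(d, 0.5, origin_nm = c(-8, -8, -8))
  surf <- extract_isosurface(vol, 0.5)
  r <- sqrt(rowSums(surf$vertices^2))
  expect_true(all(r > 4.5 & r < 5.5))
  # axis-aligned box: bounding box of the surface equals box extents +- 1 voxel
  b <- array(0, c(20, 16, 30))
  b[5:15, 4:12, 6:24] <- 1
  vb <- volume_grid(b, 0.5)
  sb <- extract_isosurface(vb, 0.5)
  bb <- apply(sb$vertices, 2L, range)
  expect_lt(max(abs(bb[, 1] - c(4, 14) * 0.5)), 0.51)
  expect_lt(max(abs(bb[, 2] - c(3, 11) * 0.5)), 0.51)
  expect_lt(max(abs(bb[, 3] - c(5, 23) * 0.5)), 0.51)
  expect_error(extract_isosurface(vol, 2), "outside the data range")
  expect_error(extract_isosurface(vol, -1), "outside the data range")
})

test_that("phantom voxelize/extract round trip stays within one voxel", {
  ph <- c2_volume_phantom()
  iso <- extract_isosurface(ph$volume)
  u <- untwist_to_plane(iso, ph$helical)
  r <- sqrt(rowSums(u^2))
  r_true <- ph$r_fun(atan2(u[, 2], u[, 1]))
  expect_lt(max(abs(r - r_true)), 0.5)   # <= 1 voxel
  expect_lt(mean(abs(r - r_true)), 0.15)
})

test_that("denoising removes planted outliers, keeps clean clouds, picks the largest region", {
  cyl <- cylinder_surface(3, 30, axial_step = 0.5, n_theta = 128L)
  n <- nrow(cyl$vertices)
  out_pts <- cbind(20 * cos(seq_len(10)), 20 * sin(seq_len(10)),
                   seq(2, 28, length.out = 10))
  noisy <- surface_cloud(rbind(cyl$vertices, out_pts), voxel_size_nm = 0.5)
  den <- denoise_surface(noisy, k_neighbors = 8, dist_factor = 3)
  expect_equal(nrow(den$vertices), n)
  expect_lt(max(sqrt(den$vertices[, 1]^2 + den$vertices[, 2]^2)), 3.01)
  # clean cloud unchanged
  den2 <- denoise_surface(cyl, 8, 3)
  expect_equal(nrow(den2$vertices), n)
  # idempotence
  den3 <- denoise_surface(den2, 8, 3)
  expect_equal(den3$vertices, den2$vertices)
  # two disconnected fragments: only the large one survives
  small <- cylinder_surface(3, 4, axial_step = 0.5, n_theta = 16L)
  sv <- small$vertices
  sv[, 3] <- sv[, 3] + 60
  both <- surface_cloud(rbind(cyl$vertices, sv), voxel_size_nm = 0.5)
  denb <- denoise_surface(both, 8, 6)  # keep all by distance, split by region
  expect_equal(nrow(denb$vertices), n)
  expect_lt(max(denb$vertices[, 3]), 31)
})

test_that("long-axis alignment is a deterministic projector", {
  set.seed(21)
  th <- runif(3000, 0, 2 * pi)
  z <- runif(3000, 0, 50)
  # cylinder along x
  cx <- surface_cloud(cbind(z, 3 * cos(th), 3 * sin(th)))
  al <- align_long_axis(cx)
  ext <- apply(al$vertices, 2L, function(v) diff(range(v)))
  expect_gt(ext[3] / max(ext[1:2]), 8)  # long axis now z
  # principal axis within 1 degree of z
  pc <- prcomp(al$vertices)$rotation[, 1]
  expect_lt(acos(min(1, abs(pc[3]))) * 180 / pi, 1)
  # cylinder already along z: rotation within 1 degree of identity (up to flip)
  cz <- surface_cloud(cbind(3 * cos(th), 3 * sin(th), z))
  alz <- align_long_axis(cz)
  R <- attr(alz, "rotation")
  expect_lt(acos(min(1, abs(R[3, 3]))) * 180 / pi, 1)
  # known 30 degree tilt in the xz-plane is recovered
  a <- 30 * pi / 180
  Rt <- rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  ct <- surface_cloud(t(Rt %*% t(cz$vertices)))
  alt <- align_long_axis(ct)
  Rrec <- attr(alt, "rotation")
  ang <- acos(min(1, abs((Rrec %*% Rt)[3, 3]))) * 180 / pi
  expect_lt(ang, 1)
  # applying alignment twice changes nothing (projector property)
  al2 <- align_long_axis(al)
  expect_equal(abs(al2$vertices[, 3]), abs(al$vertices[, 3]), tolerance = 1e-6)
  expect_lt(max(abs(attr(al2, "rotation") %*% t(attr(al2, "rotation")) -
                      diag(3))), 1e-8)
  # near-isotropic cloud is rejected
  iso_cloud <- surface_cloud(matrix(rnorm(300), ncol = 3))
  expect_error(align_long_axis(iso_cloud), "ambiguous axis")
})

test_that("map metadata files normalize units and handedness", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(accession = "TEST-1", isovalue = 0.5,
                            twist_deg = 1.2, rise_angstrom = 4.7,
                            handedness = "left", symmetry_order = 2),
                       f, auto_unbox = TRUE)
  m <- read_map_metadata(f)
  expect_s3_class(m$helical, "helical_params")
  expect_equal(m$helical$twist_deg, -1.2)   # left-handed => negative twist
  expect_equal(m$helical$rise_nm, 0.47)
  expect_equal(m$helical$symmetry_order, 2L)
})
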