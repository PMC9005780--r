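make_scene <- function() fixture("scene", function() {
  # C2 fibril bent along a sine, imaged with background tilt + bow
  tip <- std_tip()
  amp <- 25; per <- 500
  ph <- make_phantom(cs_ellipse(4, 2.2), -360 * 0.47 / (45 * 2), 0.47, -1, 2L,
                     length_nm = 390, voxel_nm = 0.5, make_volume = FALSE)
  v <- ph$surface$vertices
  pts <- cbind(v[, 1] + 80 + amp * sin(2 * pi * v[, 3] / per), v[, 3] + 5,
               v[, 2] - min(v[, 2]))
  img <- simulate_topograph(surface_cloud(pts), tip, 1, frame = "image")
  list(img = img, amp = amp, per = per,
       x0 = attr(img, "x0_nm"), y0 = attr(img, "y0_nm"))
})

test_that("flattening removes tilt and bow and is idempotent", {
  sc <- make_scene()
  h <- sc$img$heights
  nx <- ncol(h)
  tilt <- outer(rep(1, nrow(h)), 0.01 * seq_len(nx))
  fl <- flatten_image(height_map(h + tilt, 1), order = 1)
  base <- flatten_image(height_map(h, 1), order = 1)
  # the added tilt is removed: tilted and untilted inputs flatten alike
  expect_lt(sqrt(mean((fl$heights - base$heights)^2)), 0.01)
  # quadratic bow with order 2
  bow <- outer(rep(1, nrow(h)), 0.0003 * (seq_len(nx) - nx / 2)^2)
  fl2 <- flatten_image(height_map(h + bow, 1), order = 2)
  bg_res <- fl2$heights[, apply(h, 2, max) < 0.1]  # substrate columns
  expect_lt(sqrt(mean(bg_res^2)), 0.05)
  # an already-flat image is unchanged
  flat <- flatten_image(height_map(h, 1), 2)
  expect_lt(sqrt(mean((flatten_image(flat, 2)$heights - flat$heights)^2)), 1e-6)
})

test_that("straight fibrils trace straight and curved ones straighten", {
  tip <- std_tip()
  # straight cylinder along y: centreline deviation well below a pixel
  cyl <- cylinder_surface(3.5, 300)
  v <- cyl$vertices
  img <- simulate_topograph(surface_cloud(cbind(v[, 1], v[, 3], v[, 2] + 3.5)),
                            tip, 1, frame = "image")
  mid <- (0 - attr(img, "x0_nm")) / 1 + 1
  tr <- trace_and_straighten(img, rbind(c(mid, 8), c(mid, nrow(img$heights) - 8)))
  cl <- tr$centerline
  inner <- 10:(nrow(cl) - 10)
  expect_lt(max(abs(cl[inner, 1] - mid)), 0.3)
  # straightened strip of a straight fibril reproduces the input heights
  prof_in <- img$heights[40, ]
  j0 <- which.max(tr$straightened$heights[40, ])
  i0 <- which.max(prof_in)
  w <- 3
  expect_lt(max(abs(tr$straightened$heights[40, (j0 - w):(j0 + w)] -
                      prof_in[(i0 - w):(i0 + w)])), 0.05)
  # curved fibril: arc length preserved and strip self-centred within 1 px
  sc <- make_scene()
  toc <- function(xy) c((xy[1] - sc$x0) / 1 + 1, (xy[2] - sc$y0) / 1 + 1)
  seedA <- toc(c(80 + sc$amp * sin(2 * pi * 10 / sc$per), 15))
  seedB <- toc(c(80 + sc$amp * sin(2 * pi * 380 / sc$per), 385))
  tr2 <- trace_and_straighten(sc$img, rbind(seedA, seedB))
  # arc length of the analytic sine between the traced end rows
  y_lo <- (min(tr2$centerline[, 2]) - 1) * 1 + sc$y0
  y_hi <- (max(tr2$centerline[, 2]) - 1) * 1 + sc$y0
  ys <- seq(y_lo, y_hi, by = 0.25)
  arc_true <- sum(sqrt(1 + (2 * pi * sc$amp / sc$per *
                              cos(2 * pi * ys / sc$per))^2) * 0.25)
  expect_lt(abs(tr2$length_nm - arc_true) / arc_true, 0.01)
  st <- tr2$straightened$heights
  ctr <- apply(st, 1L, function(r) {
    w <- pmax(r - 0.3 * max(st), 0)
    if (sum(w) == 0) NA else sum(w * seq_along(r)) / sum(w)
  })
  midc <- (ncol(st) + 1) / 2
  expect_lt(max(abs(ctr[10:(nrow(st) - 10)] - midc), na.rm = TRUE), 1)
  # tracing noise-level images fails loudly
  set.seed(77)
  expect_error(trace_and_straighten(height_map(matrix(abs(rnorm(5000, 0, 0.1)),
                                                      100), 1),
                                    rbind(c(25, 5), c(25, 95))),
               "contrast|trace failed")
})

test_that("centre-line profiles reflect the surface geometry", {
  tip <- std_tip()
  # flat slab: constant profile
  g <- as.matrix(expand.grid(x = seq(0, 8, 0.25), y = seq(0, 60, 0.25)))
  slab <- simulate_topograph(surface_cloud(cbind(g, 3)), tip, 1, frame = "image")
  prof <- centerline_profile(slab)
  inner <- 8:(nrow(prof) - 8)
  expect_lt(diff(range(prof$height_nm[inner])), 1e-6)
  # C2 phantom: alternating peaks and grooves at the cross-over period
  ph <- c2_phantom()
  hm <- simulate_topograph(ph$surface, tip, 0.6)
  p2 <- centerline_profile(hm)
  expect_gt(diff(range(p2$height_nm)), 1)  # clear modulation
  cd <- crossover_distance(p2)
  expect_lt(abs(cd$cod_nm - 45), 1)
  expect_true(all(abs(cd$periods_nm - 45) < 3))
})

test_that("cross-over distance estimation matches constructed periods", {
  px <- 1.46
  z <- (0:339) * px
  prof <- 7 + 1.5 * cos(2 * pi * z / 47.7)
  cd <- crossover_distance(prof, px)
  expect_lt(abs(cd$cod_nm - 47.7), 47.7 / 340 * 2)  # within ~a frequency bin
  # invariance to mean and amplitude scaling
  cd2 <- crossover_distance(100 + 17 * (prof - 7), px)
  expect_equal(cd2$cod_nm, cd$cod_nm, tolerance = 1e-12)
  # constant profile has no period
  expect_error(crossover_distance(rep(5, 200), px), "aperiodic")
})
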