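test_that("image distance follows the correlation-distance contract", {
  set.seed(9)
  h <- matrix(runif(600, 0, 8), 30, 20)
  data <- height_map(h, 1, axis_height_nm = 3)
  expect_equal(image_distance(data, height_map(h, 1)), 0, tolerance = 1e-12)
  # mean-reflected image is perfectly anti-correlated
  refl <- height_map(2 * mean(h[h > 3]) - h, 1)
  expect_equal(image_distance(data, refl), 2, tolerance = 1e-9)
  # Pearson on a known masked vector pair, against a direct oracle
  d <- height_map(matrix(c(1, 2, 4), 1), 1, axis_height_nm = 0)
  s <- height_map(matrix(c(1, 2, 3), 1), 1)
  r_oracle <- {
    x <- c(1, 2, 4); y <- c(1, 2, 3)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(image_distance(d, s, axis_height_nm = 0), 1 - r_oracle,
               tolerance = 1e-12)
  expect_lt(abs(1 - r_oracle - 0.018), 1e-3)
  # empty mask and zero variance are errors
  expect_error(image_distance(height_map(h, 1, axis_height_nm = 100),
                              height_map(h, 1)), "empty mask")
  expect_error(image_distance(height_map(matrix(5, 5, 5), 1, 1),
                              height_map(matrix(5, 5, 5), 1)),
               "zero variance")
})

test_that("parameter distances are normalized absolute differences", {
  expect_equal(param_distance(5, 5, 10), 0)
  # opposite handedness with the theoretical norm of 2
  expect_equal(param_distance(1, -1, 2), 1)
  # cod example: candidates {40, 50, 70} vs reference 47.7
  ref <- 47.7
  cand <- c(40, 50, 70)
  nm <- max(abs(cand - ref))
  expect_equal(nm, 22.3)
  expect_equal(param_distance(50, ref, nm), 2.3 / 22.3, tolerance = 1e-12)
  expect_warning(d0 <- param_distance(c(3, 3), 3, 0), "norm_max is 0")
  expect_equal(d0, c(0, 0))
})

test_that("the combined score is a plain six-component sum", {
  expect_equal(combined_score(c(0, 0, 0, 0, 0, 0)), 0)
  expect_equal(combined_score(c(0.1, 0, 0, 0.2, 0.3, 0.4)), 1)
  expect_equal(combined_score(list(d_img = 0.5, d_sym = 0.1, d_hnd = 0,
                                   d_cod = 0.2, d_csa = 0.1, d_csd = 0.05)),
               0.95)
  expect_error(combined_score(c(0.1, 0.2)), "six")
  expect_error(combined_score(list(d_img = 1, d_sym = 0, d_hnd = 0,
                                   d_cod = 0, d_csa = 0)), "missing")
  expect_error(combined_score(c(0.1, NA, 0, 0, 0, 0)), "finite")
  expect_error(combined_score(c(-0.1, 0, 0, 0, 0, 0)), ">= 0")
})

test_that("score bounds hold over randomized inputs", {
  set.seed(23)
  for (i in 1:20) {
    h <- matrix(runif(400, 0, 8), 20)
    s <- h + matrix(rnorm(400, 0, runif(1, 0.1, 3)), 20)
    d <- image_distance(height_map(h, 1, axis_height_nm = 2),
                        height_map(pmax(s, 0), 1))
    expect_gte(d, 0); expect_lte(d, 2)
    dp <- param_distance(runif(1, 0, 100), runif(1, 0, 100), 100)
    expect_gte(dp, 0); expect_lte(dp, 1)
  }
})

test_that("a candidate identical to the reference scores zero and ranks first", {
  tip <- std_tip()
  ph <- c2_phantom()
  decoy <- c1_phantom()
  img <- simulate_topograph(ph$surface, tip, 0.6)
  env <- reconstruct_envelope(img, tip, 2L, 45, -1)
  img$axis_height_nm <- env$axis_height_nm
  pts <- untwist_to_plane(ph$surface, ph$helical)
  cs <- tip_accessible_boundary(pts, tip$radius_nm)
  reference <- list(image = img, envelope = env, cross_section = cs,
                    cod_nm = helical_cod(ph$helical), symmetry_order = 2L,
                    handedness = -1, csa_nm2 = cross_section_area(cs))
  rep <- rank_candidates(reference,
                         list(c(ph, list(label = "self")),
                              c(decoy, list(label = "decoy"))),
                         tip)
  self <- rep$table[rep$table$label == "self", ]
  expect_equal(self$rank, 1L)
  expect_lt(self$d_sum, 0.02)
  expect_lt(self$d_img, 0.01)
  expect_equal(self$d_sym + self$d_hnd + self$d_cod, 0)
})

test_that("ranking is deterministic with stable tie-breaks and logged exclusions", {
  tip <- std_tip()
  ph <- c2_phantom()
  img <- simulate_topograph(ph$surface, tip, 0.6)
  env <- reconstruct_envelope(img, tip, 2L, 45, -1)
  img$axis_height_nm <- env$axis_height_nm
  pts <- untwist_to_plane(ph$surface, ph$helical)
  cs <- tip_accessible_boundary(pts, tip$radius_nm)
  reference <- list(image = img, envelope = env, cross_section = cs,
                    cod_nm = helical_cod(ph$helical), symmetry_order = 2L,
                    handedness = -1, csa_nm2 = cross_section_area(cs))
  # two identical candidates: identical d_sum, ranks assigned by label
  twin <- list(c(ph, list(label = "twin-b")), c(ph, list(label = "twin-a")),
               list(label = "broken", surface = NULL, volume = NULL,
                    helical = ph$helical))
  expect_message(rep <- rank_candidates(reference, twin, tip), "excluded")
  tab <- rep$table
  expect_equal(sort(tab$rank), seq_len(nrow(tab)))
  expect_equal(tab$d_sum[tab$label == "twin-a"],
               tab$d_sum[tab$label == "twin-b"], tolerance = 1e-9)
  expect_equal(tab$label[tab$rank == 1], "twin-a")  # alphabetical tie-break
  expect_true("broken" %in% names(rep$excluded))
  # increasing one morphometric discrepancy never lowers d_sum
  base <- param_distance(50, 47.7, 30) + param_distance(30, 28, 10)
  worse <- param_distance(55, 47.7, 30) + param_distance(30, 28, 10)
  expect_gte(worse, base)
})

test_that("similarity reports serialize to TSV and JSON", {
  tip <- std_tip()
  ph <- c2_phantom()
  img <- simulate_topograph(ph$surface, tip, 0.6)
  env <- reconstruct_envelope(img, tip, 2L, 45, -1)
  img$axis_height_nm <- env$axis_height_nm
  cs <- tip_accessible_boundary(untwist_to_plane(ph$surface, ph$helical),
                                tip$radius_nm)
  reference <- list(image = img, envelope = env, cross_section = cs,
                    cod_nm = 45, symmetry_order = 2L, handedness = -1,
                    csa_nm2 = cross_section_area(cs))
  rep <- rank_candidates(reference,
                         list(c(ph, list(label = "a")),
                              c(c1_phantom(), list(label = "b"))), tip)
  pre <- file.path(tempdir(), "simrep")
  write_similarity_report(rep, pre)
  tsv <- utils::read.delim(paste0(pre, ".tsv"))
  expect_equal(nrow(tsv), 2L)
  expect_true(all(c("d_img", "d_sum", "rank") %in% names(tsv)))
  j <- jsonlite::read_json(paste0(pre, ".json"), simplifyVector = TRUE)
  expect_equal(j$reference$symmetry_order, 2L)
})
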