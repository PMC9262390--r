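test_that("contours validate vertex count, simplicity and bounds", {
  expect_error(cell_contour(matrix(c(0, 0, 1, 1), 2, 2)), "n >= 3")
  bowtie <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))
  expect_error(cell_contour(bowtie), "self-intersecting")
  sq <- cell_contour(cbind(c(5, 15, 15, 5), c(5, 5, 15, 15)))
  expect_s3_class(sq, "cell_contour")
  img <- matrix(1, 12, 12)
  expect_error(sample_perimeter_intensity(img, sq, 2), "outside the image")
})

test_that("a uniform ring is measured as a flat profile at the ring value", {
  cfg <- synth_config(n_cells_per_side = 1, image_size = 128,
                      membrane_cortex_intensity = 100,
                      cytoplasm_intensity = 10, gaussian_sd = 0, seed = 1)
  d <- single_cell_domain(crescent_angle = 0)
  img <- render_membrane_image(d, cfg)
  ct <- cell_contour(d$cells[[1]]$mitotic, side = "left")
  p <- sample_perimeter_intensity(img, ct, line_width = 2)
  # PSF mixing with cytoplasm/exterior lowers the absolute level; flatness
  # is the contract
  expect_lt(stats::sd(p$raw_intensity) / mean(p$raw_intensity), 0.03)
  expect_gt(mean(p$raw_intensity), 0.5 * 100)
})

test_that("wider transects reduce profile variance under noise", {
  d <- single_cell_domain(crescent_angle = 0)
  ct <- cell_contour(d$cells[[1]]$mitotic, side = "left")
  sds <- vapply(c(1, 3), function(w) {
    vv <- vapply(1:6, function(s) {
      cfg <- synth_config(n_cells_per_side = 1, image_size = 128,
                          gaussian_sd = 30, seed = s)
      img <- render_membrane_image(d, cfg)
      stats::sd(sample_perimeter_intensity(img, ct, w)$raw_intensity)
    }, numeric(1))
    mean(vv)
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})

test_that("orientation enforces cw-left / ccw-right and is idempotent", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ccw <- make_angular_profile(vals, dirn = 1, side = "left")
  expect_gt(spindlepol:::profile_signed_area(ccw), 0)
  fixed <- orient_profile(ccw, "left")
  expect_lt(spindlepol:::profile_signed_area(fixed), 0)
  # start sample unchanged, remainder reversed
  expect_equal(fixed$raw_intensity, c(1, 8, 7, 6, 5, 4, 3, 2))
  expect_equal(fixed$raw_intensity, orient_profile(fixed, "left")$raw_intensity)
  # right-side ccw profile is untouched
  right <- make_angular_profile(vals, dirn = 1, side = "right")
  expect_equal(orient_profile(right, "right")$raw_intensity, vals)
  expect_error(orient_profile(make_angular_profile(vals, side = "unassigned"),
                              "unassigned"), "left")
})

test_that("normalization divides by the cytoplasm mean and validates it", {
  p <- make_angular_profile(c(10, 20, 30, 10), normalized = FALSE)
  n1 <- normalize_profile(p, 10)
  expect_equal(n1$normalized_intensity, c(1, 2, 3, 1))
  expect_equal(n1$raw_intensity, c(10, 20, 30, 10))
  flat <- normalize_profile(make_angular_profile(rep(7, 8),
                                                 normalized = FALSE), 7)
  expect_equal(flat$normalized_intensity, rep(1, 8))
  expect_error(normalize_profile(p, 0), "positive")
  # renormalizing with cytoplasm mean 1 is the identity
  n2 <- normalize_profile(n1, 1)
  expect_equal(n2$normalized_intensity, n1$normalized_intensity)
})

test_that("resampling preserves constants and cosines on the circle", {
  const <- make_angular_profile(rep(3, 40))
  expect_equal(resample_profile(const, 16)$normalized_intensity, rep(3, 16))
  cosp <- cosine_profile(128)
  down_up <- resample_profile(resample_profile(cosp, 64), 128)
  expect_lt(max(abs(down_up$normalized_intensity -
                      cosp$normalized_intensity)), 0.01)
  # identity on an already-uniform grid
  same <- resample_profile(cosp, 128)
  expect_equal(same$normalized_intensity, cosp$normalized_intensity,
               tolerance = 1e-9)
  expect_error(resample_profile(cosp, 4), "n_points")
})

test_that("profile averaging weights embryos equally, not cells", {
  mk <- function(val, emb, id) {
    make_angular_profile(rep(val, 16), embryo_id = emb, cell_id = id)
  }
  profs <- c(lapply(1:3, function(i) mk(1, "e1", paste0("a", i))),
             list(mk(3, "e2", "b1")))
  avg <- average_profiles(profs)
  expect_equal(unname(avg$grand_mean), rep(2, 16))
  expect_equal(unname(avg$n_cells), c(3L, 1L))
  one <- average_profiles(list(mk(5, "e1", "a"), mk(5, "e1", "b")))
  expect_equal(unname(one$grand_mean), rep(5, 16))
  # mixed grids are rejected
  expect_error(average_profiles(list(mk(1, "e1", "a"),
                                     make_angular_profile(rep(1, 8)))),
               "grids")
  # mixed normalization state is rejected
  expect_error(
    average_profiles(list(mk(1, "e1", "a"),
                          make_angular_profile(rep(1, 16),
                                               normalized = FALSE))),
    "normaliz")
})

test_that("hierarchical averaging reduces variance below single cells", {
  set.seed(8)
  grand <- replicate(40, {
    profs <- unlist(lapply(1:3, function(e) {
      lapply(1:5, function(i) {
        make_angular_profile(rep(10, 16) + rnorm(16, sd = 2),
                             embryo_id = paste0("e", e),
                             cell_id = paste0("e", e, "c", i))
      })
    }), recursive = FALSE)
    mean(average_profiles(profs)$grand_mean)
  })
  single <- replicate(40, mean(10 + rnorm(16, sd = 2)))
  expect_lt(stats::var(grand), stats::var(single))
})
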