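test_that("config validation rejects impossible parameterizations", {
  expect_error(synth_config(n_cells_per_side = 0), "n_cells_per_side")
  expect_error(synth_config(crescent_concentration = 0), "concentration")
  expect_error(synth_config(crescent_contrast = -0.1), "contrast")
  expect_error(synth_config(anaphase_frame = 20, n_frames = 10), "anaphase")
})

test_that("identical config and seed reproduce the truth table exactly", {
  cfg <- synth_config(n_cells_per_side = 5, image_size = 256, seed = 42)
  d1 <- generate_domain(cfg)
  d2 <- generate_domain(cfg)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$cells, d2$cells)
  img1 <- render_polarity_image(d1, cfg)
  img2 <- render_polarity_image(d2, cfg)
  expect_identical(img1, img2)
})

test_that("domain layout gives the requested mirrored cell counts", {
  cfg <- synth_config(n_cells_per_side = 40, seed = 1)
  d <- generate_domain(cfg)
  expect_equal(nrow(d$truth), 80)
  expect_equal(unname(table(d$truth$side)["left"]), 40L)
  expect_equal(unname(table(d$truth$side)["right"]), 40L)
  # mirrored centroids about the vertical midline
  cl <- t(vapply(d$cells[d$truth$side == "left"],
                 function(c) c$centroid, numeric(2)))
  cr <- t(vapply(d$cells[d$truth$side == "right"],
                 function(c) c$centroid, numeric(2)))
  expect_equal(sort(cfg$image_size - cr[, "x"]), sort(cl[, "x"]),
               tolerance = 0.2)
})

test_that("degenerate noise collapses division angles onto the side means", {
  cfg <- synth_config(n_cells_per_side = 6, image_size = 256,
                      crescent_angle_sd = 0, division_coupling_sd = 0,
                      seed = 9)
  d <- generate_domain(cfg)
  expect_equal(d$truth$true_final_division_angle_signed,
               ifelse(d$truth$side == "left", 20, -20))
  expect_equal(d$truth$true_crescent_angle,
               ifelse(d$truth$side == "left", 20, -20))
})

test_that("truth angles stay in their declared ranges", {
  cfg <- synth_config(n_cells_per_side = 30, division_coupling_sd = 40,
                      crescent_angle_sd = 50, seed = 2)
  tr <- generate_domain(cfg)$truth
  expect_true(all(tr$true_final_division_angle_signed > -90 &
                    tr$true_final_division_angle_signed <= 90))
  expect_true(all(tr$true_crescent_angle > -180 &
                    tr$true_crescent_angle <= 180))
  expect_true(all(tr$interphase_aspect_ratio >= 1))
  expect_true(all(tr$true_rotation_direction %in% c("cw", "ccw", "none")))
})

test_that("zero-contrast polarity channel equals the membrane channel", {
  cfg <- synth_config(n_cells_per_side = 4, image_size = 200,
                      crescent_contrast = 0, gaussian_sd = 0, seed = 5)
  d <- generate_domain(cfg)
  expect_equal(render_polarity_image(d, cfg), render_membrane_image(d, cfg))
})

test_that("boundary intensity follows the closed-form crescent law pre-blur", {
  cfg <- synth_config(n_cells_per_side = 1, image_size = 128,
                      crescent_contrast = 1, crescent_concentration = 4,
                      gaussian_sd = 0, psf_sigma = 0, seed = 1)
  # vertex pixel exactly at (64, 64), at angle 0 from the centroid (64, 84)
  domain <- single_cell_domain(crescent_angle = 0, cx = 64, cy = 84, r = 20)
  img <- render_polarity_image(domain, cfg)
  expect_equal(img[64, 64], 2 * cfg$membrane_cortex_intensity,
               tolerance = 1e-9)
  mem <- render_membrane_image(domain, cfg)
  expect_equal(mem[64, 64], cfg$membrane_cortex_intensity, tolerance = 1e-9)
  expect_lte(max(mem), cfg$membrane_cortex_intensity + 1e-9)
})

test_that("rendered crescents are recovered by the profile pipeline", {
  cfg <- synth_config(n_cells_per_side = 1, image_size = 128,
                      gaussian_sd = 0, seed = 1)
  domain <- single_cell_domain(crescent_angle = 30)
  img <- render_polarity_image(domain, cfg)
  ct <- cell_contour(domain$cells[[1]]$mitotic, side = "left")
  p <- sample_perimeter_intensity(img, ct, line_width = 2)
  p <- resample_profile(orient_profile(normalize_profile(
    p, cfg$cytoplasm_intensity)), 128)
  pk <- find_peak(p)
  expect_lt(abs(wrap_angle(pk$peak_angle - 30)), 5)
})

test_that("membrane profiles approach ratio 1 as noise vanishes and smoothing grows", {
  d <- single_cell_domain(crescent_angle = 0)
  cfg0 <- synth_config(n_cells_per_side = 1, image_size = 128,
                       gaussian_sd = 0, seed = 2)
  measure <- function(cfg, w) {
    img <- render_membrane_image(d, cfg)
    ct <- cell_contour(d$cells[[1]]$mitotic, side = "left")
    p <- resample_profile(orient_profile(normalize_profile(
      sample_perimeter_intensity(img, ct, 2), cfg$cytoplasm_intensity)), 128)
    peak_to_trough_ratio(p, smooth_window = w)$peak_to_trough_ratio
  }
  expect_lt(measure(cfg0, 5), 1.05)
  cfgn <- synth_config(n_cells_per_side = 1, image_size = 128,
                       gaussian_sd = 20, seed = 2)
  r_narrow <- measure(cfgn, 3)
  r_wide <- measure(cfgn, 15)
  expect_gt(r_narrow, 1)
  expect_gt(r_wide, 1)
  expect_lt(r_wide, r_narrow)
})

test_that("measured polarity ratio increases monotonically with contrast", {
  ratios <- vapply(c(0.25, 0.5, 1, 2), function(a) {
    cfg <- synth_config(n_cells_per_side = 1, image_size = 128,
                        crescent_contrast = a, gaussian_sd = 0, seed = 1)
    d <- single_cell_domain(crescent_angle = 0)
    img <- render_polarity_image(d, cfg)
    ct <- cell_contour(d$cells[[1]]$mitotic, side = "left")
    p <- resample_profile(orient_profile(normalize_profile(
      sample_perimeter_intensity(img, ct, 2), cfg$cytoplasm_intensity)), 128)
    peak_to_trough_ratio(p)$peak_to_trough_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("spindle axis kinematics follow the shorter path and freeze at anaphase", {
  # no rotation needed
  s <- spindlepol:::spindle_axis_series(35, 35, 10, 8, 6)
  expect_equal(s, rep(35, 8))
  # 80 -> 0 at 10 deg/frame: reaches 0 at frame 9 and stays
  s2 <- spindlepol:::spindle_axis_series(80, 0, 10, 12, 10)
  expect_equal(s2[1], 80)
  expect_equal(s2[9], 0)
  expect_equal(s2[9:12], rep(0, 4))
  expect_equal(diff(s2[1:9]), rep(-10, 8))
  # shorter path crosses the axis wrap: 80 -> -80 goes through 90
  s3 <- spindlepol:::spindle_axis_series(80, -80, 10, 6, 6)
  expect_equal(s3[2], 90)
  expect_equal(s3[3], -80)  # 80 + 20 wrapped onto the axis range
  expect_equal(s3[4:6], rep(-80, 3))
})

test_that("image-free profile datasets honor the crescent law and hierarchy", {
  cfg <- synth_config(crescent_contrast = 0, gaussian_sd = 0, seed = 1)
  ds <- make_profile_dataset(cfg, n_cells = 4, n_embryos = 2)
  for (p in ds$profiles) {
    expect_equal(diff(range(p$raw_intensity)), 0)
  }
  cfg2 <- synth_config(gaussian_sd = 0, seed = 1)
  ds2 <- make_profile_dataset(cfg2, n_cells = 10, n_embryos = 3)
  expect_length(ds2$profiles, 30)
  expect_equal(nrow(ds2$truth), 30)
  expect_equal(length(unique(ds2$truth$embryo_id)), 3)
  expect_true(all(table(ds2$truth$embryo_id) == 10))
})

test_that("crescent half-width shrinks monotonically with concentration", {
  half_width <- function(kappa) {
    cfg <- synth_config(crescent_concentration = kappa, gaussian_sd = 0,
                        crescent_angle_sd = 0, seed = 1)
    ds <- make_profile_dataset(cfg, n_cells = 1, n_embryos = 1,
                               n_points = 720)
    p <- ds$profiles[[1]]
    base <- min(p$raw_intensity)
    thr <- base * (1 + cfg$crescent_contrast / 2)
    sum(p$raw_intensity > thr) * 360 / 720
  }
  widths <- vapply(c(1, 2, 4, 8, 16), half_width, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("angle datasets match their generating distribution", {
  u <- make_angle_dataset(5, 200, "uniform", seed = 4)
  expect_equal(mean(u$folded_angle), 45, tolerance = 3)
  w <- make_angle_dataset(2, 5, "wrapped_normal", mu = 20, sd = 0, seed = 4)
  expect_equal(w$folded_angle, rep(20, 10))
  expect_identical(make_angle_dataset(2, 5, "uniform", seed = 9),
                   make_angle_dataset(2, 5, "uniform", seed = 9))
})

test_that("oversized spindles are rejected at render time", {
  cfg <- synth_config(n_cells_per_side = 4, image_size = 128,
                      pole_separation = 40, seed = 1)
  d <- generate_domain(cfg)
  expect_error(render_spindle_timelapse(d, cfg), "pole_separation")
})
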