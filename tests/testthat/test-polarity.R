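test_that("peak finding returns the crescent angle and flags flat profiles", {
  p <- cosine_profile(360, peak_at = 90)
  pk <- find_peak(p)
  expect_false(pk$no_peak)
  expect_equal(pk$peak_angle, 90, tolerance = 1.5)
  flat <- make_angular_profile(rep(2, 64))
  expect_true(find_peak(flat)$no_peak)
  expect_true(is.na(find_peak(flat)$peak_angle))
})

test_that("plateau ties resolve to the circular plateau midpoint", {
  vals <- c(0, 0, 5, 5, 5, 0, 0, 0)
  p <- make_angular_profile(vals)
  pk <- find_peak(p, smooth_window = 1)
  expect_equal(pk$peak_index, 4L)
  # plateau wrapping across the start
  vals2 <- c(5, 0, 0, 0, 0, 0, 5, 5)
  pk2 <- find_peak(make_angular_profile(vals2), smooth_window = 1)
  expect_equal(pk2$peak_index, 8L)
})

test_that("peak-to-trough ratio matches closed forms", {
  flat <- make_angular_profile(rep(5, 64))
  m <- peak_to_trough_ratio(flat)
  expect_identical(m$peak_to_trough_ratio, 1)
  expect_true(m$no_peak)
  # 2 + cos(phi): peak 3, single trough 1 used for both sides -> P = 3
  m2 <- peak_to_trough_ratio(cosine_profile(360), smooth_window = 1)
  expect_equal(m2$peak_to_trough_ratio, 3, tolerance = 1e-9)
  expect_equal(m2$trough_values, c(1, 1), tolerance = 1e-9)
  # smoothing changes the value only marginally on a dense grid
  m3 <- peak_to_trough_ratio(cosine_profile(360), smooth_window = 5)
  expect_equal(m3$peak_to_trough_ratio, 3, tolerance = 0.01)
})

test_that("adjacent troughs are the nearest circular local minima", {
  p <- make_angular_profile(c(1, 4, 1, 2, 1, 2))
  m <- peak_to_trough_ratio(p, smooth_window = 1)
  expect_equal(m$peak_value, 4)
  expect_equal(sort(m$trough_values), c(1, 1))
  expect_equal(m$peak_to_trough_ratio, 4)
  # oracle: exhaustive scan of circular local minima adjacent to the max
  vals <- c(2, 1, 3, 8, 5, 6, 2, 4)
  n <- length(vals)
  is_min <- vapply(seq_len(n), function(i) {
    vals[i] <= vals[(i %% n) + 1] && vals[i] <= vals[((i - 2) %% n) + 1]
  }, logical(1))
  pk <- which.max(vals)
  fwd <- ((pk - 1 + seq_len(n - 1)) %% n) + 1
  bwd <- ((pk - 1 - seq_len(n - 1)) %% n) + 1
  expected <- c(vals[fwd[which(is_min[fwd])[1]]],
                vals[bwd[which(is_min[bwd])[1]]])
  m2 <- peak_to_trough_ratio(make_angular_profile(vals), smooth_window = 1)
  expect_equal(sort(m2$trough_values), sort(expected))
  expect_equal(m2$peak_to_trough_ratio, max(vals) / mean(expected))
})

test_that("polarity statistics are invariant to the profile start index", {
  set.seed(21)
  base <- 2 + cospi((0:119) * 3 / 180) + rnorm(120, sd = 0.05)
  p0 <- make_angular_profile(base)
  m0 <- peak_to_trough_ratio(p0)
  for (shift in c(13, 57, 101)) {
    rolled <- c(base[-seq_len(shift)], base[seq_len(shift)])
    phi <- spindlepol::wrap_angle((seq_len(120) - 1 + shift) * 3)
    uv <- cbind(-sinpi(phi / 180), -cospi(phi / 180))
    pr <- normalize_profile(cortical_profile(
      cell_id = "c", embryo_id = "e", side = "left", channel = "polarity",
      arclength_fraction = (seq_len(120) - 1) / 120,
      raw_intensity = rolled, xy = 10 * uv, centroid = c(x = 0, y = 0)), 1)
    mr <- peak_to_trough_ratio(pr)
    expect_equal(mr$peak_to_trough_ratio, m0$peak_to_trough_ratio,
                 tolerance = 1e-9)
    expect_equal(mr$peak_angle, m0$peak_angle, tolerance = 1e-9)
  }
})

test_that("ratio is monotone in contrast and reaches 1 exactly at a = 0", {
  ratio_at <- function(a) {
    cfg <- synth_config(crescent_contrast = a, gaussian_sd = 0,
                        crescent_angle_sd = 0, seed = 1)
    ds <- make_profile_dataset(cfg, n_cells = 1, n_embryos = 1)
    p <- normalize_profile(ds$profiles[[1]], cfg$cytoplasm_intensity)
    peak_to_trough_ratio(p)
  }
  rr <- vapply(c(0.2, 0.5, 1, 2, 4),
               function(a) ratio_at(a)$peak_to_trough_ratio, numeric(1))
  expect_true(all(diff(rr) > 0))
  at0 <- ratio_at(0)
  expect_identical(at0$peak_to_trough_ratio, 1)
  expect_true(at0$no_peak)
})

test_that("peak angle recovery under noise stays within 5 degrees", {
  cfg <- synth_config(crescent_contrast = 1, crescent_concentration = 4,
                      gaussian_sd = 0.05 * 200, seed = 31)
  ds <- make_profile_dataset(cfg, n_cells = 10, n_embryos = 1)
  errs <- vapply(seq_along(ds$profiles), function(i) {
    p <- normalize_profile(ds$profiles[[i]], cfg$cytoplasm_intensity)
    abs(wrap_angle(find_peak(p)$peak_angle - ds$truth$true_crescent_angle[i]))
  }, numeric(1))
  expect_lte(mean(errs), 5)
})

test_that("the polarity-vs-control contrast test uses exact inference", {
  mk <- function(vals, channel) {
    lapply(seq_along(vals), function(i) {
      structure(list(cell_id = paste0(channel, i),
                     embryo_id = paste0("e", (i - 1) %/% 5 + 1),
                     channel = channel, peak_angle = 0, peak_value = vals[i],
                     trough_values = c(1, 1),
                     peak_to_trough_ratio = vals[i], no_peak = FALSE),
                class = "polarity_measurement")
    })
  }
  pol <- mk(seq(1.3, 1.5, length.out = 10), "polarity")
  ctl <- mk(seq(1.00, 1.10, length.out = 10), "membrane")
  res <- polarity_contrast_test(pol, ctl)
  expect_equal(res$test$p_two_sided, 2 / choose(20, 10))
  expect_identical(res$test$method, "exact")
  expect_equal(nrow(res$cell_summary), 2)
  expect_equal(res$cell_summary$mean[res$cell_summary$group == "control"],
               mean(seq(1.00, 1.10, length.out = 10)))
  # embryo-level aggregation: one mean +/- SD row per group, n = 2 embryos
  expect_equal(nrow(res$embryo_summary), 2)
  expect_equal(res$embryo_summary$n, c(2L, 2L))
  expect_error(polarity_contrast_test(pol, list()), "non-empty")
})
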