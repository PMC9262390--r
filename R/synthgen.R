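# Synthetic mitotic-domain generator.
#
# Emulates the statistical structure of live imaging of an embryonic head
# mitotic domain: two mirrored clusters of polygonal epithelial cells, a
# uniform cortical membrane channel, a polarity channel carrying a single
# angular crescent of elevated cortical signal per cell, and a two-pole
# spindle that assembles at a random orientation and rotates by the shorter
# angular path to a final angle coupled to the crescent angle. Ground truth
# is recorded per cell so that downstream measurement modules can be tested
# for parameter recovery.

#' Configuration for the synthetic mitotic-domain generator
#'
#' @param n_cells_per_side cells per mirrored cluster (default 40, the size
#'   of the largest head mitotic domain).
#' @param image_size side of the square raster, pixels.
#' @param pixel_scale microns per pixel.
#' @param membrane_cortex_intensity cortical signal level, arbitrary units.
#' @param cytoplasm_intensity cytoplasmic fill level, a.u.
#' @param crescent_contrast fractional elevation `a >= 0` of the cortical
#'   polarity signal at the crescent center; the cortical intensity follows
#'   `I(phi) = base * (1 + a * exp(kappa * (cos(phi - phi_c) - 1)))`.
#' @param crescent_concentration von-Mises-like width parameter `kappa > 0`;
#'   larger values give narrower crescents.
#' @param crescent_center_mean named numeric `c(left=, right=)`: mean crescent
#'   angle per side, degrees from the AP axis (opposite signs model the
#'   mirror symmetry of the two clusters).
#' @param crescent_angle_sd per-cell SD of the crescent angle, degrees.
#' @param division_coupling_sd SD of the final division angle about the
#'   crescent-implied angle, degrees.
#' @param rotation_rate spindle rotation, degrees per frame.
#' @param n_frames frames in the spindle time-lapse.
#' @param anaphase_frame frame from which the spindle axis is fixed; choose
#'   `rotation_rate * (anaphase_frame - 1) >= 90` so any rotation completes.
#' @param pole_separation spindle pole-to-pole distance, microns.
#' @param pole_sigma Gaussian width of a rendered pole blob, microns.
#' @param gaussian_sd additive Gaussian read-noise SD, a.u. (0 = off).
#' @param poisson logical; apply Poisson shot noise before the Gaussian term.
#' @param psf_sigma isotropic Gaussian point-spread-function SD, pixels
#'   (0 = no blur).
#' @param double_sided_crescent logical; if `TRUE` the crescent is rendered
#'   at both `phi_c` and `phi_c + 180` (the imaging of the original domains
#'   cannot resolve one- vs two-sided crescents; single-sided is the
#'   default).
#' @param seed root integer seed; all randomness derives from it via
#'   deterministic per-cell streams.
#' @return an object of class `synth_config` (validated list).
#' @export
synth_config <- function(n_cells_per_side = 40,
                         image_size = 512,
                         pixel_scale = 0.2,
                         membrane_cortex_intensity = 200,
                         cytoplasm_intensity = 50,
                         crescent_contrast = 1,
                         crescent_concentration = 4,
                         crescent_center_mean = c(left = 20, right = -20),
                         crescent_angle_sd = 10,
                         division_coupling_sd = 10,
                         rotation_rate = 10,
                         n_frames = 12,
                         anaphase_frame = 10,
                         pole_separation = 6,
                         pole_sigma = 0.8,
                         gaussian_sd = 0,
                         poisson = FALSE,
                         psf_sigma = 1,
                         double_sided_crescent = FALSE,
                         seed = 1L) {
  cfg <- list(
    n_cells_per_side = as.integer(n_cells_per_side),
    image_size = as.integer(image_size),
    pixel_scale = pixel_scale,
    membrane_cortex_intensity = membrane_cortex_intensity,
    cytoplasm_intensity = cytoplasm_intensity,
    crescent_contrast = crescent_contrast,
    crescent_concentration = crescent_concentration,
    crescent_center_mean = crescent_center_mean,
    crescent_angle_sd = crescent_angle_sd,
    division_coupling_sd = division_coupling_sd,
    rotation_rate = rotation_rate,
    n_frames = as.integer(n_frames),
    anaphase_frame = as.integer(anaphase_frame),
    pole_separation = pole_separation,
    pole_sigma = pole_sigma,
    gaussian_sd = gaussian_sd,
    poisson = isTRUE(poisson),
    psf_sigma = psf_sigma,
    double_sided_crescent = isTRUE(double_sided_crescent),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  ok <- function(cond, msg) if (!cond) stop("invalid config: ", msg, call. = FALSE)
  ok(cfg$n_cells_per_side >= 1, "n_cells_per_side must be >= 1")
  ok(cfg$image_size >= 16, "image_size must be >= 16")
  ok(cfg$pixel_scale > 0, "pixel_scale must be > 0")
  ok(cfg$crescent_contrast >= 0, "crescent_contrast must be >= 0")
  ok(cfg$crescent_concentration > 0, "crescent_concentration must be > 0")
  ok(all(c("left", "right") %in% names(cfg$crescent_center_mean)),
     "crescent_center_mean needs named 'left' and 'right' entries")
  ok(cfg$crescent_angle_sd >= 0, "crescent_angle_sd must be >= 0")
  ok(cfg$division_coupling_sd >= 0, "division_coupling_sd must be >= 0")
  ok(cfg$rotation_rate > 0, "rotation_rate must be > 0")
  ok(cfg$n_frames >= 1, "n_frames must be >= 1")
  ok(cfg$anaphase_frame >= 1 && cfg$anaphase_frame <= cfg$n_frames,
     "anaphase_frame must be in 1..n_frames")
  ok(cfg$pole_separation > 0, "pole_separation must be > 0")
  ok(cfg$pole_sigma > 0, "pole_sigma must be > 0")
  ok(cfg$gaussian_sd >= 0, "gaussian_sd must be >= 0")
  ok(cfg$psf_sigma >= 0, "psf_sigma must be >= 0")
  invisible(cfg)
}

# Evaluate an expression with a deterministic per-cell RNG substream, then
# restore the caller's RNG state. Substreams are derived arithmetically from
# (root seed, cell index, stream id) so that adding cells never reshuffles
# the draws of existing ones.
with_substream <- function(seed, cell_index, stream, expr) {
  s <- (as.double(seed) * 48271 + cell_index * 75011 + stream * 131) %%
    2147483629
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(s))
  expr
}

# Hexagonal lattice centers for one elliptical cluster; returns exactly n
# centers closest (in elliptical radius) to the cluster center, in a
# deterministic order. Spacing is capped by `s_max` so small cohorts shrink
# toward the cluster center instead of spilling outside the frame.
hex_cluster_centers <- function(n, cx, cy, a, b, s_max = Inf) {
  area <- pi * a * b
  s <- min(sqrt(area / (n * sqrt(3) / 2)), s_max)
  jr <- ceiling(1.8 * b / (s * sqrt(3) / 2)) + 2
  ir <- ceiling(1.8 * a / s) + 2
  grid <- expand.grid(i = -ir:ir, j = -jr:jr)
  x <- cx + (grid$i + (grid$j %% 2) / 2) * s
  y <- cy + grid$j * s * sqrt(3) / 2
  re <- sqrt(((x - cx) / a)^2 + ((y - cy) / b)^2)
  ord <- order(re, y, x)
  idx <- ord[seq_len(n)]
  list(x = x[idx], y = y[idx], spacing = s)
}

# Regular polygon (n-gon) boundary as a (n x 2) matrix of (x, y).
regular_polygon <- function(cx, cy, radius, n_vertices, phase_deg = 0) {
  th <- (phase_deg + seq(0, 360, length.out = n_vertices + 1)[-(n_vertices + 1)]) *
    pi / 180
  cbind(x = cx + radius * cos(th), y = cy + radius * sin(th))
}

#' Generate a synthetic mitotic-domain geometry and ground truth
#'
#' Lays out `2 * n_cells_per_side` cells on jittered hexagonal lattices
#' clipped to two elliptical clusters mirrored about the vertical image
#' midline, and draws per-cell ground truth: crescent angle (per-side mean
#' plus Gaussian jitter), final division angle (crescent angle plus Gaussian
#' coupling noise, wrapped to the axis range), initial spindle angle
#' (uniform), rotation direction (shorter path), and interphase shape
#' (long-axis angle and aspect ratio).
#'
#' @param config a [synth_config()].
#' @param embryo_id identifier recorded in the truth table.
#' @return list with elements `cells` (list of per-cell geometry: `cell_id`,
#'   `side`, `centroid`, `mitotic` and `interphase` contour matrices) and
#'   `truth` (data.frame, one row per cell).
#' @export
generate_domain <- function(config, embryo_id = "embryo1") {
  validate_synth_config(config)
  w <- config$image_size
  n <- config$n_cells_per_side
  ell_a <- 0.20 * w; ell_b <- 0.34 * w
  left <- hex_cluster_centers(n, 0.27 * w, 0.5 * w, ell_a, ell_b,
                              s_max = 0.12 * w)
  centers <- data.frame(
    x = c(left$x, w - left$x),
    y = c(left$y, left$y),
    side = rep(c("left", "right"), each = n)
  )
  s <- left$spacing
  cells <- vector("list", nrow(centers))
  rows <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    side <- centers$side[i]
    draws <- with_substream(config$seed, i, 1, {
      list(
        jit = stats::runif(2, -0.04, 0.04) * s,
        vjit = stats::runif(24, -0.04, 0.04),
        phase = stats::runif(1, 0, 30),
        cres = stats::rnorm(1, 0, config$crescent_angle_sd),
        divn = stats::rnorm(1, 0, config$division_coupling_sd),
        init = stats::runif(1, -90, 90),
        ar = 1 + stats::rgamma(1, shape = 2, scale = 0.15),
        axang = stats::runif(1, -90, 90)
      )
    })
    cx <- centers$x[i] + draws$jit[1]
    cy <- centers$y[i] + draws$jit[2]
    mit <- regular_polygon(cx, cy, 0.43 * s, 24, draws$phase)
    mit[, 1] <- cx + (mit[, 1] - cx) * (1 + draws$vjit)
    mit[, 2] <- cy + (mit[, 2] - cy) * (1 + draws$vjit)
    # interphase cell: regular hexagon scaled by sqrt(AR) along the long
    # axis and 1/sqrt(AR) across it, so the moment aspect ratio equals AR
    hexp <- regular_polygon(0, 0, 0.52 * s, 6, draws$phase)
    k <- sqrt(draws$ar)
    u <- ap_unit_vector(draws$axang)       # long-axis direction (array coords)
    vx <- u[1, "d_col"]; vy <- u[1, "d_row"]
    px <- hexp[, 1] * vx + hexp[, 2] * vy  # component along axis
    qx <- -hexp[, 1] * vy + hexp[, 2] * vx # component across axis
    inter <- cbind(x = cx + (k * px) * vx - (qx / k) * vy,
                   y = cy + (k * px) * vy + (qx / k) * vx)
    theta_c <- wrap_angle(config$crescent_center_mean[[side]] + draws$cres)
    final <- wrap_axis_angle(theta_c + draws$divn)
    delta <- axis_angle_difference(draws$init, final)
    dir <- if (abs(delta) < 1) "none" else if (delta > 0) "ccw" else "cw"
    cell_id <- sprintf("%s_%s_c%03d", embryo_id, substr(side, 1, 1),
                       ((i - 1) %% n) + 1)
    cells[[i]] <- list(cell_id = cell_id, side = side,
                       centroid = c(x = cx, y = cy),
                       mitotic = mit, interphase = inter)
    rows[[i]] <- data.frame(
      cell_id = cell_id, embryo_id = embryo_id, side = side,
      true_crescent_angle = theta_c,
      true_final_division_angle_signed = final,
      true_initial_spindle_angle = draws$init,
      true_rotation_direction = dir,
      true_total_rotation = abs(delta),
      interphase_long_axis_angle = draws$axang,
      interphase_aspect_ratio = draws$ar,
      stringsAsFactors = FALSE
    )
  }
  list(cells = cells, truth = do.call(rbind, rows))
}

# Cortical crescent intensity law shared by the renderer and the image-free
# profile generator. phi and phi_c in degrees; vectorized over phi.
crescent_intensity <- function(phi, phi_c, base, a, kappa, double_sided = FALSE) {
  d <- (phi - phi_c) * pi / 180
  mod <- exp(kappa * (cos(d) - 1))
  if (double_sided) mod <- pmax(mod, exp(kappa * (cos(d + pi) - 1)))
  base * (1 + a * mod)
}

# Distance from points to a closed polygon outline (min over edges).
dist_to_outline <- function(px, py, poly) {
  v <- rbind(poly, poly[1, , drop = FALSE])
  d2 <- rep(Inf, length(px))
  for (e in seq_len(nrow(poly))) {
    ax <- v[e, 1]; ay <- v[e, 2]
    bx <- v[e + 1, 1]; by <- v[e + 1, 2]
    ex <- bx - ax; ey <- by - ay
    len2 <- ex^2 + ey^2
    t <- pmin(pmax(((px - ax) * ex + (py - ay) * ey) / len2, 0), 1)
    dd <- (px - ax - t * ex)^2 + (py - ay - t * ey)^2
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

# Paint the cortical band of one cell: pixels within `halfwidth` of the
# polygon outline take the angular intensity law f(phi), anti-aliased by
# supersampled coverage, composited over the existing image.
paint_boundary <- function(img, poly, centroid, f, halfwidth = 1,
                           supersample = 4) {
  pad <- ceiling(halfwidth) + 1
  xr <- max(1, floor(min(poly[, 1])) - pad):min(ncol(img), ceiling(max(poly[, 1])) + pad)
  yr <- max(1, floor(min(poly[, 2])) - pad):min(nrow(img), ceiling(max(poly[, 2])) + pad)
  g <- expand.grid(x = xr, y = yr)
  # coarse prefilter to keep the supersampling cheap
  d0 <- dist_to_outline(g$x, g$y, poly)
  near <- d0 <= halfwidth + 1
  if (!any(near)) return(img)
  gx <- g$x[near]; gy <- g$y[near]
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  cov <- numeric(length(gx))
  for (ox in offs) for (oy in offs) {
    d <- dist_to_outline(gx + ox, gy + oy, poly)
    cov <- cov + (d <= halfwidth)
  }
  cov <- cov / supersample^2
  hit <- cov > 0
  if (!any(hit)) return(img)
  gx <- gx[hit]; gy <- gy[hit]; cov <- cov[hit]
  phi <- angle_from_ap(gx - centroid[1], gy - centroid[2])
  val <- f(phi)
  idx <- (gx - 1) * nrow(img) + gy
  img[idx] <- pmax(img[idx], cov * val + (1 - cov) * img[idx])
  img
}

# Fill polygon interiors at a constant level (values only raised, never
# lowered, so cortical paint survives).
fill_polygons <- function(img, cells, level, which_poly = "mitotic") {
  for (cell in cells) {
    poly <- cell[[which_poly]]
    xr <- floor(min(poly[, 1])):ceiling(max(poly[, 1]))
    yr <- floor(min(poly[, 2])):ceiling(max(poly[, 2]))
    xr <- xr[xr >= 1 & xr <= ncol(img)]
    yr <- yr[yr >= 1 & yr <= nrow(img)]
    if (!length(xr) || !length(yr)) next
    g <- expand.grid(x = xr, y = yr)
    inside <- pracma::inpolygon(g$x, g$y, poly[, 1], poly[, 2])
    if (!any(inside)) next
    idx <- (g$x[inside] - 1) * nrow(img) + g$y[inside]
    img[idx] <- pmax(img[idx], level)
  }
  img
}

# PSF blur + noise, in that order (blur models optics, noise the detector).
# `stream` separates the noise streams of different channels/frames.
finish_image <- function(img, config, stream) {
  if (config$psf_sigma > 0) {
    img <- EBImage::gblur(img, sigma = config$psf_sigma)
  }
  if (config$poisson || config$gaussian_sd > 0) {
    img <- with_substream(config$seed, 0, stream, {
      out <- img
      if (config$poisson) {
        out <- matrix(stats::rpois(length(out), lambda = pmax(out, 0)),
                      nrow = nrow(out))
      }
      if (config$gaussian_sd > 0) {
        out <- out + stats::rnorm(length(out), sd = config$gaussian_sd)
      }
      out
    })
  }
  img
}

#' Render the polarity channel of a synthetic domain
#'
#' Cortical intensity along each mitotic cell boundary follows the crescent
#' law `I(phi) = base * (1 + a * exp(kappa * (cos(phi - phi_c) - 1)))` where
#' `phi` is the angular position of the boundary point about the cell
#' centroid and `phi_c` the cell's true crescent angle; the cytoplasm is
#' filled at `cytoplasm_intensity`; the image is then blurred by the PSF and
#' noise is applied last.
#'
#' @param domain output of [generate_domain()].
#' @param config the [synth_config()] used to generate it.
#' @return numeric matrix (`image_size` x `image_size`), row 1 = anterior.
#' @export
render_polarity_image <- function(domain, config) {
  render_channel(domain, config, polarity = TRUE, stream = 11)
}

#' Render the membrane (control) channel of a synthetic domain
#'
#' Identical pipeline to [render_polarity_image()] but with a uniform
#' cortical intensity, emulating an unpolarized membrane marker.
#'
#' @inheritParams render_polarity_image
#' @return numeric matrix.
#' @export
render_membrane_image <- function(domain, config) {
  render_channel(domain, config, polarity = FALSE, stream = 12)
}

render_channel <- function(domain, config, polarity, stream) {
  validate_synth_config(config)
  w <- config$image_size
  img <- matrix(0, w, w)
  img <- fill_polygons(img, domain$cells, config$cytoplasm_intensity)
  base <- config$membrane_cortex_intensity
  for (i in seq_along(domain$cells)) {
    cell <- domain$cells[[i]]
    if (polarity) {
      phi_c <- domain$truth$true_crescent_angle[i]
      f <- function(phi) crescent_intensity(
        phi, phi_c, base, config$crescent_contrast,
        config$crescent_concentration, config$double_sided_crescent)
    } else {
      f <- function(phi) rep(base, length(phi))
    }
    img <- paint_boundary(img, cell$mitotic, cell$centroid, f)
  }
  finish_image(img, config, stream)
}

# Spindle axis angle per frame: rotates from `initial` toward `final` along
# the shorter axis arc at `rate` degrees/frame, and is pinned to `final`
# from `anaphase_frame` onward.
spindle_axis_series <- function(initial, final, rate, n_frames, anaphase_frame) {
  delta <- axis_angle_difference(initial, final)
  f <- seq_len(n_frames)
  prog <- pmin(rate * (f - 1), abs(delta))
  ang <- wrap_axis_angle(initial + sign(delta) * prog)
  ang[f >= anaphase_frame] <- final
  ang
}

#' Render a synthetic spindle time-lapse stack
#'
#' Each cell contains two Gaussian pole blobs at `+/- pole_separation / 2`
#' along the current spindle axis; the axis rotates from the cell's initial
#' angle toward its final division angle by the shorter angular path at
#' `rotation_rate` degrees per frame and is constant from `anaphase_frame`
#' onward. Frames are PSF-blurred and noised like the other channels.
#'
#' @inheritParams render_polarity_image
#' @param pole_intensity peak amplitude of a pole blob, a.u.
#' @return numeric array `image_size x image_size x n_frames`.
#' @export
render_spindle_timelapse <- function(domain, config, pole_intensity = 200) {
  validate_synth_config(config)
  w <- config$image_size
  sep_px <- config$pole_separation / config$pixel_scale
  sig_px <- config$pole_sigma / config$pixel_scale
  for (cell in domain$cells) {
    r <- sqrt(rowSums((sweep(cell$mitotic, 2, cell$centroid))^2))
    if (sep_px / 2 > min(r)) {
      stop("pole_separation exceeds cell size: reduce pole_separation ",
           "or enlarge cells", call. = FALSE)
    }
  }
  stack <- array(0, dim = c(w, w, config$n_frames))
  halfw <- ceiling(4 * sig_px)
  for (i in seq_along(domain$cells)) {
    cell <- domain$cells[[i]]
    tr <- domain$truth[i, ]
    ang <- spindle_axis_series(tr$true_initial_spindle_angle,
                               tr$true_final_division_angle_signed,
                               config$rotation_rate, config$n_frames,
                               config$anaphase_frame)
    uv <- ap_unit_vector(ang)
    for (f in seq_len(config$n_frames)) {
      for (sgn in c(-1, 1)) {
        px <- cell$centroid["x"] + sgn * uv[f, "d_col"] * sep_px / 2
        py <- cell$centroid["y"] + sgn * uv[f, "d_row"] * sep_px / 2
        xr <- max(1, floor(px - halfw)):min(w, ceiling(px + halfw))
        yr <- max(1, floor(py - halfw)):min(w, ceiling(py + halfw))
        blob <- pole_intensity *
          exp(-(outer((yr - py)^2, (xr - px)^2, "+")) / (2 * sig_px^2))
        stack[yr, xr, f] <- stack[yr, xr, f] + blob
      }
    }
  }
  for (f in seq_len(config$n_frames)) {
    stack[, , f] <- finish_image(stack[, , f], config, stream = 100 + f)
  }
  stack
}

#' Generate cortical profiles directly from the crescent law (image-free)
#'
#' Bypasses rendering: samples `I(phi)` on a fixed angular grid for each
#' cell, adds Gaussian noise, and returns ready-made [cortical_profile]
#' objects plus their ground truth. Useful for unit-testing the polarity
#' statistics without the imaging pipeline.
#'
#' @param config a [synth_config()]; supplies the crescent law, intensities
#'   and noise.
#' @param n_cells cells per embryo.
#' @param n_embryos number of embryos.
#' @param n_points angular samples per profile.
#' @return list with `profiles` (list of `cortical_profile`) and `truth`
#'   (data.frame with `cell_id`, `embryo_id`, `side`,
#'   `true_crescent_angle`).
#' @export
make_profile_dataset <- function(config, n_cells = 10, n_embryos = 3,
                                 n_points = 128) {
  validate_synth_config(config)
  profiles <- list()
  rows <- list()
  idx <- 0L
  for (e in seq_len(n_embryos)) {
    for (i in seq_len(n_cells)) {
      idx <- idx + 1L
      side <- if (i %% 2 == 1) "left" else "right"
      draws <- with_substream(config$seed, idx, 7, {
        list(cres = stats::rnorm(1, 0, config$crescent_angle_sd),
             noise = stats::rnorm(n_points, 0, config$gaussian_sd))
      })
      phi_c <- wrap_angle(config$crescent_center_mean[[side]] + draws$cres)
      dirn <- if (side == "left") -1 else 1   # cw for left, ccw for right
      phi <- wrap_angle(dirn * (seq_len(n_points) - 1) * 360 / n_points)
      raw <- crescent_intensity(phi, phi_c, config$membrane_cortex_intensity,
                                config$crescent_contrast,
                                config$crescent_concentration,
                                config$double_sided_crescent)
      if (config$gaussian_sd > 0) raw <- raw + draws$noise
      uv <- ap_unit_vector(phi)
      cell_id <- sprintf("e%02d_c%03d", e, i)
      embryo_id <- sprintf("embryo%02d", e)
      profiles[[idx]] <- cortical_profile(
        cell_id = cell_id, embryo_id = embryo_id, side = side,
        channel = "polarity",
        arclength_fraction = (seq_len(n_points) - 1) / n_points,
        raw_intensity = raw,
        xy = cbind(x = 10 * uv[, "d_col"], y = 10 * uv[, "d_row"]),
        centroid = c(x = 0, y = 0),
        cytoplasm_mean = NA_real_, line_width = NA_real_
      )
      rows[[idx]] <- data.frame(cell_id = cell_id, embryo_id = embryo_id,
                                side = side, true_crescent_angle = phi_c,
                                stringsAsFactors = FALSE)
    }
  }
  list(profiles = profiles, truth = do.call(rbind, rows))
}

#' Generate a division-angle table from a stated distribution (image-free)
#'
#' Emulates the per-embryo folded division-angle tables that underlie rose
#' plots: angles drawn either from a wrapped normal about `mu` (wrapped to
#' the axis range, then folded) or uniformly on [0, 90].
#'
#' @param n_embryos,n_cells embryos and cells per embryo.
#' @param distribution `"wrapped_normal"` or `"uniform"`.
#' @param mu,sd mean and SD (degrees) for the wrapped normal.
#' @param seed integer seed.
#' @return data.frame with `embryo_id`, `cell_id`, `folded_angle`.
#' @export
make_angle_dataset <- function(n_embryos, n_cells,
                               distribution = c("wrapped_normal", "uniform"),
                               mu = 20, sd = 10, seed = 1L) {
  distribution <- match.arg(distribution)
  n <- n_embryos * n_cells
  ang <- with_substream(seed, 0, 13, {
    if (distribution == "uniform") {
      stats::runif(n, 0, 90)
    } else {
      fold_angle(wrap_axis_angle(stats::rnorm(n, mu, sd)))
    }
  })
  data.frame(
    embryo_id = sprintf("embryo%02d", rep(seq_len(n_embryos), each = n_cells)),
    cell_id = sprintf("e%02d_c%03d", rep(seq_len(n_embryos), each = n_cells),
                      rep(seq_len(n_cells), n_embryos)),
    folded_angle = ang,
    stringsAsFactors = FALSE
  )
}
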