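# Fixtures shared across test files; everything is built in code.

# cortical_profile with prescribed values on a uniform angular grid around a
# unit-ish circle; dirn = -1 traverses clockwise (left-side convention)
make_angular_profile <- function(values, channel = "polarity", dirn = 1,
                                 side = if (dirn < 0) "left" else "right",
                                 normalized = TRUE, cell_id = "cell",
                                 embryo_id = "embryo") {
  n <- length(values)
  phi <- spindlepol::wrap_angle(dirn * (seq_len(n) - 1) * 360 / n)
  uv <- cbind(-sinpi(phi / 180), -cospi(phi / 180))
  p <- spindlepol::cortical_profile(
    cell_id = cell_id, embryo_id = embryo_id, side = side,
    channel = channel, arclength_fraction = (seq_len(n) - 1) / n,
    raw_intensity = values,
    xy = cbind(x = 10 * uv[, 1], y = 10 * uv[, 2]),
    centroid = c(x = 0, y = 0)
  )
  if (normalized) p <- spindlepol::normalize_profile(p, 1)
  p
}

# profile following 2 + cos(phi - peak_at) on a dense circular grid
cosine_profile <- function(n = 360, peak_at = 0, ...) {
  phi <- (seq_len(n) - 1) * 360 / n
  make_angular_profile(2 + cospi((phi - peak_at) / 180), ...)
}

# near-circular polygon contour centered in a small image
circle_polygon <- function(cx, cy, r, n = 64, phase = 270) {
  spindlepol:::regular_polygon(cx, cy, r, n, phase)
}

# parametric ellipse boundary polygon: semi-axes (a, b), long axis at
# `angle` degrees from the AP axis (package convention), array coords
ellipse_polygon <- function(cx, cy, a, b, angle, n = 256) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ex <- a * cos(t); ey <- b * sin(t)
  th <- angle * pi / 180
  # long axis along the AP-relative direction `angle`
  ux <- -sin(th); uy <- -cos(th)   # array coords unit vector
  cbind(x = cx + ex * ux - ey * uy, y = cy + ex * uy + ey * ux)
}

# single-cell synthetic domain (bypasses the lattice) for rendering tests
single_cell_domain <- function(crescent_angle, cx = 64, cy = 64, r = 20,
                               final_angle = 0, initial_angle = 0) {
  poly <- circle_polygon(cx, cy, r)
  list(
    cells = list(list(cell_id = "c1", side = "left",
                      centroid = c(x = cx, y = cy),
                      mitotic = poly, interphase = poly)),
    truth = data.frame(
      cell_id = "c1", embryo_id = "e1", side = "left",
      true_crescent_angle = crescent_angle,
      true_final_division_angle_signed = final_angle,
      true_initial_spindle_angle = initial_angle,
      true_rotation_direction = "none", true_total_rotation = 0,
      interphase_long_axis_angle = 0, interphase_aspect_ratio = 1,
      stringsAsFactors = FALSE
    )
  )
}

# exact two-sided Mann-Whitney p by brute-force enumeration of all
# C(n1+n2, n1) label assignments (independent oracle)
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# permutations via a generator distinct from the package's (Heap's
# algorithm), used as the Spearman oracle
heap_perms <- function(n) {
  out <- list()
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1) {
      out[[length(out) + 1]] <<- a
      return()
    }
    for (i in seq_len(k)) {
      rec(k - 1)
      if (k %% 2 == 0) {
        tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp
      } else {
        tmp <- a[1]; a[1] <<- a[k]; a[k] <<- tmp
      }
    }
  }
  rec(n)
  do.call(rbind, out)
}

spearman_enum_oracle <- function(x, y) {
  n <- length(x)
  rho_obs <- stats::cor(rank(x), rank(y))
  perms <- heap_perms(n)
  rho_all <- apply(perms, 1, function(p) stats::cor(rank(x), rank(y[p])))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}
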