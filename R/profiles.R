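# Cortical intensity profiles along traced cell perimeters.
#
# Measurement conventions: the perimeter is traced from a reference start
# vertex (for these domains the anterior-most point of the mitotic cell);
# the trace direction is clockwise for cells in the left half of the domain
# and counterclockwise for cells in the right half (anterior-up view), so
# that mirrored cells are directly comparable; intensity at each perimeter
# sample is averaged over a short transect perpendicular to the boundary
# (line width, default 2 px); profiles are normalized to the mean
# cytoplasmic intensity; cells are averaged within an embryo and embryos
# averaged with equal weight.

#' Construct a cell contour
#'
#' @param vertices numeric matrix (n x 2) of ordered polygon vertices,
#'   columns x (column coordinate) and y (row coordinate, increasing
#'   downward). The polygon is closed implicitly; do not repeat the first
#'   vertex.
#' @param cell_id,embryo_id identifiers.
#' @param side `"left"`, `"right"` or `"unassigned"`.
#' @param reference_point index of the vertex where the trace starts; by
#'   default the anterior-most (smallest y) vertex.
#' @param phase `"interphase"`, `"mitotic_anaphase"` or `"other"`.
#' @return object of class `cell_contour`.
#' @export
cell_contour <- function(vertices, cell_id = "cell", embryo_id = "embryo",
                         side = c("unassigned", "left", "right"),
                         reference_point = NULL,
                         phase = c("mitotic_anaphase", "interphase", "other")) {
  side <- match.arg(side)
  phase <- match.arg(phase)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("vertices must be an (n x 2) matrix with n >= 3", call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("vertices must be finite", call. = FALSE)
  colnames(vertices) <- c("x", "y")
  if (!is_simple_polygon(vertices)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  if (is.null(reference_point)) {
    reference_point <- which.min(vertices[, "y"])
  }
  if (reference_point < 1 || reference_point > nrow(vertices)) {
    stop("reference_point out of range", call. = FALSE)
  }
  structure(
    list(cell_id = cell_id, embryo_id = embryo_id, side = side,
         vertices = vertices, reference_point = as.integer(reference_point),
         phase = phase),
    class = "cell_contour"
  )
}

# Simple-polygon check: no two non-adjacent edges intersect. O(n^2), fine
# for manual traces and synthetic polygons.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      if (j == i || j == (i %% n) + 1 || i == (j %% n) + 1) next
      if (seg_int(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

polygon_centroid <- function(v) {
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) {
    return(c(x = mean(x), y = mean(y)))
  }
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' Construct a cortical intensity profile
#'
#' Usually produced by [sample_perimeter_intensity()] or
#' [make_profile_dataset()]; exported so measured profiles (e.g. from
#' external tracing tools) can be brought into the package.
#'
#' @param cell_id,embryo_id,side,channel identity fields.
#' @param arclength_fraction strictly increasing positions in `[0, 1)`.
#' @param raw_intensity raw intensities, same length.
#' @param xy (n x 2) matrix of sample coordinates (for angular positions).
#' @param centroid length-2 named vector, the contour centroid.
#' @param normalized_intensity optional normalized intensities.
#' @param cytoplasm_mean cytoplasmic mean used for normalization (NA if
#'   not normalized yet).
#' @param line_width transect width used during sampling, px.
#' @return object of class `cortical_profile`.
#' @export
cortical_profile <- function(cell_id, embryo_id, side, channel,
                             arclength_fraction, raw_intensity, xy, centroid,
                             normalized_intensity = NULL,
                             cytoplasm_mean = NA_real_,
                             line_width = NA_real_) {
  n <- length(arclength_fraction)
  stopifnot(length(raw_intensity) == n, nrow(xy) == n)
  if (n < 4) stop("profile needs at least 4 samples", call. = FALSE)
  if (any(diff(arclength_fraction) <= 0) ||
      any(arclength_fraction < 0) || any(arclength_fraction >= 1)) {
    stop("arclength_fraction must be strictly increasing in [0, 1)",
         call. = FALSE)
  }
  if (!is.null(normalized_intensity) && length(normalized_intensity) != n) {
    stop("normalized_intensity length mismatch", call. = FALSE)
  }
  ang <- angle_from_ap(xy[, 1] - centroid["x"], xy[, 2] - centroid["y"])
  structure(
    list(cell_id = cell_id, embryo_id = embryo_id, side = side,
         channel = channel, arclength_fraction = arclength_fraction,
         angular_position = ang, raw_intensity = raw_intensity,
         normalized_intensity = normalized_intensity,
         cytoplasm_mean = cytoplasm_mean, line_width = line_width,
         xy = xy, centroid = centroid),
    class = "cortical_profile"
  )
}

#' @export
print.cortical_profile <- function(x, ...) {
  cat(sprintf("Cortical profile: cell %s (%s, %s side), channel %s, %d samples%s\n",
              x$cell_id, x$embryo_id, x$side, x$channel,
              length(x$raw_intensity),
              if (!is.null(x$normalized_intensity)) ", normalized" else ""))
  invisible(x)
}

#' Sample cortical intensity along a traced cell perimeter
#'
#' Walks the contour at approximately one sample per pixel of boundary
#' length starting at the reference vertex; at each sample the intensity is
#' the mean over a transect of length `line_width` centered on the boundary
#' and perpendicular to it (bilinear interpolation). A Gaussian smoothing
#' of the image (0.75 px kernel, the standard preprocessing for these
#' measurements) is applied first unless `presmooth = FALSE`.
#'
#' @param image numeric matrix (row 1 = anterior/top).
#' @param contour a [cell_contour()].
#' @param line_width transect length in pixels (>= 1, default 2).
#' @param presmooth logical; apply the 0.75 px Gaussian smoothing first.
#' @param smooth_sigma smoothing kernel SD in pixels (default 0.75).
#' @return a raw [cortical_profile] (not yet normalized).
#' @export
sample_perimeter_intensity <- function(image, contour, line_width = 2,
                                       presmooth = TRUE, smooth_sigma = 0.75) {
  stopifnot(inherits(contour, "cell_contour"))
  if (line_width < 1) stop("line_width must be >= 1", call. = FALSE)
  v <- contour$vertices
  margin <- line_width / 2 + 1
  if (min(v[, 1]) < 1 + margin || max(v[, 1]) > ncol(image) - margin ||
      min(v[, 2]) < 1 + margin || max(v[, 2]) > nrow(image) - margin) {
    stop("contour (plus transect width) extends outside the image",
         call. = FALSE)
  }
  if (presmooth && smooth_sigma > 0) {
    image <- EBImage::gblur(image, sigma = smooth_sigma)
  }
  # reorder vertices to start at the reference point
  n <- nrow(v)
  ord <- ((contour$reference_point - 1 + 0:(n - 1)) %% n) + 1
  v <- v[ord, , drop = FALSE]
  vc <- rbind(v, v[1, , drop = FALSE])
  seg_len <- sqrt(rowSums(diff(vc)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[n + 1]
  n_samp <- max(8L, round(total))
  s_pos <- (seq_len(n_samp) - 1) * total / n_samp
  seg <- findInterval(s_pos, cum, rightmost.closed = TRUE)
  seg[seg > n] <- n
  t <- (s_pos - cum[seg]) / seg_len[seg]
  xs <- vc[seg, 1] + t * (vc[seg + 1, 1] - vc[seg, 1])
  ys <- vc[seg, 2] + t * (vc[seg + 1, 2] - vc[seg, 2])
  # unit tangent, then inward-agnostic normal for the transect
  tx <- (vc[seg + 1, 1] - vc[seg, 1]) / seg_len[seg]
  ty <- (vc[seg + 1, 2] - vc[seg, 2]) / seg_len[seg]
  nx <- -ty; ny <- tx
  # transect sampled at ~0.5 px steps across the full line width
  n_off <- max(3L, 2L * ceiling(line_width) + 1L)
  offs <- seq(-line_width / 2, line_width / 2, length.out = n_off)
  acc <- matrix(0, length(xs), length(offs))
  for (k in seq_along(offs)) {
    acc[, k] <- pracma::interp2(seq_len(ncol(image)), seq_len(nrow(image)),
                                image, xs + offs[k] * nx, ys + offs[k] * ny)
  }
  raw <- rowMeans(acc)
  cortical_profile(
    cell_id = contour$cell_id, embryo_id = contour$embryo_id,
    side = contour$side, channel = "unknown",
    arclength_fraction = s_pos / total, raw_intensity = raw,
    xy = cbind(x = xs, y = ys), centroid = polygon_centroid(contour$vertices),
    line_width = line_width
  )
}

# Signed area in the anterior-up display frame (y up); positive area means
# the samples run counterclockwise in that view.
profile_signed_area <- function(profile) {
  x <- profile$xy[, 1]; y <- -profile$xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Enforce the per-side trace direction of a profile
#'
#' Reverses the sample order if needed so the traversal is clockwise for
#' left-side cells and counterclockwise for right-side cells in the
#' anterior-up view; the start sample is unchanged. Idempotent.
#'
#' @param profile a [cortical_profile].
#' @param side optional override of the profile's side label.
#' @return the profile, possibly with reversed sample order.
#' @export
orient_profile <- function(profile, side = profile$side) {
  if (!side %in% c("left", "right")) {
    stop("side must be 'left' or 'right' to orient a profile", call. = FALSE)
  }
  ccw <- profile_signed_area(profile) > 0
  want_ccw <- side == "right"
  if (ccw == want_ccw) {
    profile$side <- side
    return(profile)
  }
  n <- length(profile$raw_intensity)
  ord <- c(1L, rev(seq_len(n)[-1]))
  gaps <- diff(c(profile$arclength_fraction, 1))
  new_arc <- c(0, cumsum(rev(gaps))[-n])
  out <- profile
  out$side <- side
  out$raw_intensity <- profile$raw_intensity[ord]
  if (!is.null(profile$normalized_intensity)) {
    out$normalized_intensity <- profile$normalized_intensity[ord]
  }
  out$xy <- profile$xy[ord, , drop = FALSE]
  out$angular_position <- profile$angular_position[ord]
  out$arclength_fraction <- new_arc
  out
}

#' Normalize a profile to the cytoplasmic mean
#'
#' @param profile a [cortical_profile].
#' @param cytoplasm either a positive scalar (pre-measured cytoplasmic mean
#'   gray value) or a polygon matrix delimiting a cytoplasmic region, in
#'   which case `image` must be supplied and the mean is measured there.
#' @param image image matrix, required when `cytoplasm` is a polygon.
#' @return the profile with `normalized_intensity = raw / cytoplasm_mean`;
#'   raw intensities are retained.
#' @export
normalize_profile <- function(profile, cytoplasm, image = NULL) {
  if (is.matrix(cytoplasm)) {
    if (is.null(image)) {
      stop("image required to measure a cytoplasm polygon", call. = FALSE)
    }
    xr <- floor(min(cytoplasm[, 1])):ceiling(max(cytoplasm[, 1]))
    yr <- floor(min(cytoplasm[, 2])):ceiling(max(cytoplasm[, 2]))
    g <- expand.grid(x = xr, y = yr)
    inside <- pracma::inpolygon(g$x, g$y, cytoplasm[, 1], cytoplasm[, 2])
    cyto_mean <- mean(image[cbind(g$y[inside], g$x[inside])])
  } else {
    cyto_mean <- as.numeric(cytoplasm)
  }
  if (!is.finite(cyto_mean) || cyto_mean <= 0) {
    stop("cytoplasm mean must be positive", call. = FALSE)
  }
  if (!is.null(profile$normalized_intensity)) {
    # renormalization: rescale the normalized curve (so a second pass with
    # cytoplasm mean 1 is the identity); the cumulative factor is recorded
    profile$normalized_intensity <- profile$normalized_intensity / cyto_mean
    profile$cytoplasm_mean <- profile$cytoplasm_mean * cyto_mean
  } else {
    profile$cytoplasm_mean <- cyto_mean
    profile$normalized_intensity <- profile$raw_intensity / cyto_mean
  }
  profile
}

#' Resample a profile onto a uniform circular arclength grid
#'
#' Linear interpolation onto `n_points` equally spaced arclength fractions,
#' circular at the wrap point; angular positions are recomputed from the
#' interpolated coordinates.
#'
#' @param profile a [cortical_profile].
#' @param n_points number of output samples (>= 8).
#' @return resampled profile.
#' @export
resample_profile <- function(profile, n_points = 128) {
  if (n_points < 8) stop("n_points must be >= 8", call. = FALSE)
  s <- profile$arclength_fraction
  grid <- (seq_len(n_points) - 1) / n_points
  interp_circ <- function(vals) {
    stats::approx(x = c(s, 1), y = c(vals, vals[1]), xout = grid,
                  method = "linear", rule = 2)$y
  }
  out <- profile
  out$arclength_fraction <- grid
  out$raw_intensity <- interp_circ(profile$raw_intensity)
  if (!is.null(profile$normalized_intensity)) {
    out$normalized_intensity <- interp_circ(profile$normalized_intensity)
  }
  out$xy <- cbind(x = interp_circ(profile$xy[, 1]),
                  y = interp_circ(profile$xy[, 2]))
  out$angular_position <- angle_from_ap(out$xy[, 1] - out$centroid["x"],
                                        out$xy[, 2] - out$centroid["y"])
  out
}

#' Average profiles per embryo and across embryos
#'
#' Per-embryo curve = pointwise mean over that embryo's cells; grand curve =
#' pointwise mean of the per-embryo curves, so embryos with different cell
#' counts contribute equally (the standard hierarchical averaging for
#' biological replicates).
#'
#' @param profiles list of [cortical_profile] objects, all resampled to the
#'   same grid and in the same normalization state.
#' @param use `"normalized"` (default) or `"raw"`.
#' @return list with `embryo_curves` (matrix, one row per embryo),
#'   `grand_mean` (numeric vector), `arclength_fraction` and `n_cells`
#'   (named count per embryo).
#' @export
average_profiles <- function(profiles, use = c("normalized", "raw")) {
  use <- match.arg(use)
  if (!length(profiles)) stop("no profiles supplied", call. = FALSE)
  lens <- vapply(profiles, function(p) length(p$raw_intensity), integer(1))
  if (length(unique(lens)) != 1) {
    stop("profiles are on different grids; resample first", call. = FALSE)
  }
  grids <- vapply(profiles, function(p) p$arclength_fraction[2], numeric(1))
  if (diff(range(grids)) > 1e-9) {
    stop("profiles are on different grids; resample first", call. = FALSE)
  }
  get_vals <- function(p) {
    if (use == "normalized") {
      if (is.null(p$normalized_intensity)) {
        stop("mixed normalization state: profile ", p$cell_id,
             " is not normalized", call. = FALSE)
      }
      p$normalized_intensity
    } else p$raw_intensity
  }
  emb <- vapply(profiles, function(p) p$embryo_id, character(1))
  groups <- split(profiles, emb)
  curves <- t(vapply(groups, function(g) {
    rowMeans(vapply(g, get_vals, numeric(lens[1])))
  }, numeric(lens[1])))
  list(
    embryo_curves = curves,
    grand_mean = colMeans(curves),
    arclength_fraction = profiles[[1]]$arclength_fraction,
    n_cells = vapply(groups, length, integer(1))
  )
}
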