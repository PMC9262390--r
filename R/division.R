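# Division-angle analysis: spindle pole detection, signed and folded
# division angles, rotation tracking, rose histograms and per-embryo means.
#
# Conventions: the AP axis is the image vertical (anterior up); a division
# angle of 0 means alignment with the AP axis and 90 alignment with the DV
# axis; the sign of an axis angle is positive for counterclockwise tilt
# from AP in the anterior-up view; angles are measured at anaphase or
# later, when spindle orientation is fixed.

#' Detect the two spindle poles inside a cell contour
#'
#' Smooths the frame, masks it to the contour interior, finds local
#' intensity maxima above a relative threshold and returns sub-pixel pole
#' positions as intensity-weighted centroids around the two strongest
#' maxima.
#'
#' @param frame numeric image matrix.
#' @param contour a [cell_contour()] (or plain vertex matrix) bounding the
#'   cell.
#' @param smooth_sigma Gaussian smoothing SD in pixels before maximum
#'   detection (0 if `frame` is already smoothed).
#' @param rel_threshold local maxima below
#'   `background + rel_threshold * (max - background)` are ignored.
#' @param centroid_radius radius (px) of the window for the sub-pixel
#'   intensity-weighted centroid.
#' @param mask_dilate the contour mask is expanded outward by this many
#'   pixels, so poles grazing the cell boundary are not clipped (default 2).
#' @return 2 x 2 matrix with rows `pole_a`, `pole_b` and columns `x`, `y`.
#' @export
detect_poles <- function(frame, contour, smooth_sigma = 1,
                         rel_threshold = 0.2, centroid_radius = 5,
                         mask_dilate = 2) {
  v <- if (inherits(contour, "cell_contour")) contour$vertices else as.matrix(contour)
  pad <- centroid_radius + ceiling(3 * max(smooth_sigma, 1))
  x0 <- max(1, floor(min(v[, 1])) - pad); x1 <- min(ncol(frame), ceiling(max(v[, 1])) + pad)
  y0 <- max(1, floor(min(v[, 2])) - pad); y1 <- min(nrow(frame), ceiling(max(v[, 2])) + pad)
  crop <- frame[y0:y1, x0:x1, drop = FALSE]
  if (smooth_sigma > 0) crop <- EBImage::gblur(crop, sigma = smooth_sigma)
  g <- expand.grid(x = x0:x1, y = y0:y1)
  in_poly <- pracma::inpolygon(g$x, g$y, v[, 1], v[, 2])
  if (mask_dilate > 0) {
    in_poly <- in_poly | dist_to_outline(g$x, g$y, v) <= mask_dilate
  }
  inside <- matrix(in_poly, nrow = nrow(crop), byrow = TRUE)
  vals <- crop
  vals[!inside] <- -Inf
  nr <- nrow(vals); nc <- ncol(vals)
  if (nr < 3 || nc < 3) stop("contour region too small", call. = FALSE)
  core <- vals[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > -Inf
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- vals[2:(nr - 1) + dy, 2:(nc - 1) + dx]
    # a true maximum needs all its neighbors inside the mask: pixels on the
    # mask rim lie on a gradient and are not genuine extrema
    is_max <- is_max & is.finite(nb) & (core >= nb)
  }
  bg <- min(crop[inside])
  mx <- max(vals[is.finite(vals)])
  thr <- bg + rel_threshold * (mx - bg)
  idx <- which(is_max & core > thr, arr.ind = TRUE)
  if (nrow(idx) < 1) stop("no spindle poles detected", call. = FALSE)
  peaks <- data.frame(row = idx[, 1] + 1, col = idx[, 2] + 1,
                      val = core[idx])
  peaks <- peaks[order(-peaks$val), ]
  # merge maxima closer than 2 px (plateaus), keep the stronger
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    d <- sqrt((peaks$row - peaks$row[i])^2 + (peaks$col - peaks$col[i])^2)
    keep[d < 2 & seq_len(nrow(peaks)) > i] <- FALSE
  }
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) < 2) {
    stop("fewer than two spindle poles detected", call. = FALSE)
  }
  # sub-pixel refinement: 3-point parabola on log intensity at the pixel
  # maximum (exact for a Gaussian blob and insensitive to distant signal);
  # falls back to a windowed intensity-weighted centroid if ill-conditioned
  refine <- function(r0, c0) {
    if (r0 > 1 && r0 < nr && c0 > 1 && c0 < nc &&
        all(crop[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1)] > bg)) {
      lf <- log(crop[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1)] - bg + 1e-12)
      den_r <- 2 * lf[2, 2] - lf[1, 2] - lf[3, 2]
      den_c <- 2 * lf[2, 2] - lf[2, 1] - lf[2, 3]
      if (den_r > 0 && den_c > 0) {
        dr <- (lf[3, 2] - lf[1, 2]) / (2 * den_r)
        dc <- (lf[2, 3] - lf[2, 1]) / (2 * den_c)
        if (abs(dr) <= 1 && abs(dc) <= 1) {
          return(c(x = c0 + dc + x0 - 1, y = r0 + dr + y0 - 1))
        }
      }
    }
    rr <- max(1, r0 - centroid_radius):min(nr, r0 + centroid_radius)
    cc <- max(1, c0 - centroid_radius):min(nc, c0 + centroid_radius)
    wgt <- pmax(crop[rr, cc, drop = FALSE] - bg, 0)
    wsum <- sum(wgt)
    ry <- sum(outer(rr, rep(1, length(cc))) * wgt) / wsum
    cx <- sum(outer(rep(1, length(rr)), cc) * wgt) / wsum
    c(x = cx + x0 - 1, y = ry + y0 - 1)
  }
  p1 <- refine(peaks$row[1], peaks$col[1])
  p2 <- refine(peaks$row[2], peaks$col[2])
  out <- rbind(pole_a = p1, pole_b = p2)
  colnames(out) <- c("x", "y")
  out
}

#' Signed spindle-axis angle relative to the AP axis
#'
#' The pole-to-pole axis is undirected, as is the AP axis: the result is
#' the axis angle in `(-90, 90]`, positive when the axis is rotated
#' counterclockwise from AP in the anterior-up view.
#'
#' @param pole_a,pole_b length-2 vectors `(x, y)` in pixel coordinates
#'   (y increasing downward).
#' @return signed angle in degrees.
#' @export
spindle_axis_angle <- function(pole_a, pole_b) {
  d <- c(pole_b[1] - pole_a[1], pole_b[2] - pole_a[2])
  if (sqrt(sum(d^2)) < 1e-9) {
    stop("spindle poles are coincident", call. = FALSE)
  }
  unname(wrap_axis_angle(angle_from_ap(d[1], d[2])))
}

#' Track spindle rotation over a time-lapse and build a division record
#'
#' Consecutive-frame angle differences are unwrapped with the shorter-path
#' rule on the axis circle; the net signed displacement from the first
#' frame to anaphase defines the rotation direction (|net| < 1 degree is
#' classified as "none") and the total rotation. The final angle is the
#' angle at the first frame at or after `anaphase_frame`.
#'
#' @param observations data.frame with columns `frame` and `signed_angle`
#'   (one cell), ordered or orderable by frame; duplicate frames are an
#'   error.
#' @param anaphase_frame frame index at which orientation is fixed.
#' @param cell_id,embryo_id,domain_id,side identity fields for the record.
#' @return object of class `division_record`: list with
#'   `final_signed_angle`, `folded_angle`, `rotation_direction`,
#'   `total_rotation` plus the identity fields.
#' @export
track_rotation <- function(observations, anaphase_frame,
                           cell_id = "cell", embryo_id = "embryo",
                           domain_id = "MD1", side = "unassigned") {
  if (nrow(observations) < 2) stop("need at least 2 frames", call. = FALSE)
  if (is.unsorted(observations$frame, strictly = TRUE)) {
    stop("frames must be strictly increasing", call. = FALSE)
  }
  if (anaphase_frame < min(observations$frame) ||
      anaphase_frame > max(observations$frame)) {
    stop("anaphase_frame outside the observed frame range", call. = FALSE)
  }
  ang <- observations$signed_angle
  pre <- observations$frame <= anaphase_frame
  steps <- axis_angle_difference(ang[-length(ang)], ang[-1])
  net <- sum(steps[which(pre)[-1] - 1])
  final_idx <- which(observations$frame >= anaphase_frame)[1]
  final <- ang[final_idx]
  dir <- if (abs(net) < 1) "none" else if (net > 0) "ccw" else "cw"
  structure(
    list(cell_id = cell_id, embryo_id = embryo_id, domain_id = domain_id,
         side = side, final_signed_angle = final,
         folded_angle = fold_angle(final), rotation_direction = dir,
         total_rotation = abs(net)),
    class = "division_record"
  )
}

#' Measure all spindles of a synthetic time-lapse stack
#'
#' Smooths each frame once, detects the two poles of every cell in every
#' frame and returns the per-frame signed axis angles.
#'
#' @param stack array `H x W x n_frames`.
#' @param domain output of [generate_domain()] (cell contours and ids).
#' @param smooth_sigma per-frame Gaussian smoothing SD, px.
#' @return data.frame with `cell_id`, `frame`, pole coordinates and
#'   `signed_angle`.
#' @export
measure_spindle_stack <- function(stack, domain, smooth_sigma = 1) {
  n_frames <- dim(stack)[3]
  rows <- vector("list", length(domain$cells) * n_frames)
  k <- 0L
  for (f in seq_len(n_frames)) {
    frame <- stack[, , f]
    if (smooth_sigma > 0) frame <- EBImage::gblur(frame, sigma = smooth_sigma)
    for (cell in domain$cells) {
      poles <- detect_poles(frame, cell$mitotic, smooth_sigma = 0)
      k <- k + 1L
      rows[[k]] <- data.frame(
        cell_id = cell$cell_id, frame = f,
        ax = poles["pole_a", "x"], ay = poles["pole_a", "y"],
        bx = poles["pole_b", "x"], by = poles["pole_b", "y"],
        signed_angle = spindle_axis_angle(poles["pole_a", ],
                                          poles["pole_b", ]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Tabulate division records
#'
#' @param records list of `division_record` objects.
#' @return data.frame, one row per division.
#' @export
division_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(cell_id = r$cell_id, embryo_id = r$embryo_id,
               domain_id = r$domain_id, side = r$side,
               final_signed_angle = r$final_signed_angle,
               folded_angle = r$folded_angle,
               rotation_direction = r$rotation_direction,
               total_rotation = r$total_rotation, stringsAsFactors = FALSE)
  }))
}

#' Rose histogram of division angles
#'
#' Bins angles on the declared range and reports the percentage of
#' spindles per bin (the radial axis of a rose plot).
#'
#' @param angles numeric vector of angles in degrees.
#' @param bin_width bin width in degrees; must divide the range.
#' @param range `"folded"` for [0, 90] or `"signed"` for (-90, 90].
#' @return object of class `rose_histogram`: list with `bin_edges`,
#'   `percentages`, `n`, `range`.
#' @export
rose_histogram <- function(angles, bin_width = 15,
                           range = c("folded", "signed")) {
  range <- match.arg(range)
  if (!length(angles)) stop("no angles supplied", call. = FALSE)
  lo <- if (range == "folded") 0 else -90
  hi <- 90
  span <- hi - lo
  if (abs(span / bin_width - round(span / bin_width)) > 1e-9) {
    stop("bin_width must divide the angular range", call. = FALSE)
  }
  if (any(angles < lo - 1e-9) || any(angles > hi + 1e-9)) {
    stop("angles outside the declared range", call. = FALSE)
  }
  edges <- seq(lo, hi, by = bin_width)
  # right-open bins except the last, which is closed at 90
  bin <- pmin(floor((angles - lo) / bin_width) + 1, length(edges) - 1)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  structure(
    list(bin_edges = edges, percentages = 100 * counts / length(angles),
         n = length(angles), range = range),
    class = "rose_histogram"
  )
}

#' Rose plot of a division-angle histogram
#'
#' @param rose a [rose_histogram()].
#' @return a ggplot object (percentage on the radial axis).
#' @export
plot_rose <- function(rose) {
  mids <- (rose$bin_edges[-1] + rose$bin_edges[-length(rose$bin_edges)]) / 2
  df <- data.frame(mid = mids, pct = rose$percentages)
  full <- if (rose$range == "folded") c(0, 360) else c(-90, 270)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$pct)) +
    ggplot2::geom_col(width = diff(rose$bin_edges)[1],
                      fill = "grey40", colour = "white") +
    ggplot2::coord_polar(theta = "x", start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = full,
                                breaks = rose$bin_edges) +
    ggplot2::labs(x = "division angle (deg)", y = "% of spindles",
                  title = sprintf("n = %d divisions", rose$n)) +
    ggplot2::theme_minimal()
}

#' Per-embryo mean folded division angles
#'
#' Each embryo contributes one row regardless of its cell count; these
#' per-embryo means are the units of between-group inference.
#'
#' @param records data.frame from [division_table()] (needs `embryo_id` and
#'   `folded_angle`).
#' @return data.frame with `embryo_id`, `n_cells`, `mean_folded_angle`.
#' @export
embryo_mean_angles <- function(records) {
  if (!nrow(records)) stop("no records supplied", call. = FALSE)
  g <- split(records$folded_angle, records$embryo_id)
  data.frame(
    embryo_id = names(g),
    n_cells = vapply(g, length, integer(1)),
    mean_folded_angle = vapply(g, mean, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
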