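# Cell-shape analysis: moment-equivalent ellipse fits and the long-axis
# (Hertwig) rule test.
#
# The fit matches region-based "Fit Ellipse" semantics: the ellipse has the
# same area and the same second central area moments as the filled polygon,
# computed with the exact polygon-moment formulas (not a boundary-point
# least-squares fit). For an ellipse the moment eigenvalues are a^2/4 and
# b^2/4, so semi-axes are twice the square roots of the covariance
# eigenvalues.

#' Fit the moment-equivalent ellipse of a cell contour
#'
#' @param contour a [cell_contour()] or plain (n x 2) vertex matrix
#'   (x = column, y = row increasing downward).
#' @param ar_flag_threshold aspect ratios below this are flagged
#'   `unreliable_axis` (near-circular cells have ill-defined axes).
#' @return object of class `shape_fit`: list with `cell_id`, `centroid`,
#'   `major_axis_length`, `minor_axis_length`, `orientation` (degrees from
#'   the AP axis in (-90, 90]), `aspect_ratio`, `unreliable_axis`.
#' @export
fit_ellipse <- function(contour, ar_flag_threshold = 1.02) {
  if (inherits(contour, "cell_contour")) {
    v <- contour$vertices
    cell_id <- contour$cell_id
  } else {
    v <- as.matrix(contour)
    cell_id <- "cell"
  }
  if (nrow(v) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  # work in the anterior-up display frame (y up) so orientation signs match
  # the package convention
  x <- v[, 1]; y <- -v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a6 <- sum(cr)
  area <- a6 / 2
  if (abs(area) < 1e-9) stop("degenerate (zero-area) polygon", call. = FALSE)
  cx <- sum((x + xn) * cr) / (3 * a6)
  cy <- sum((y + yn) * cr) / (3 * a6)
  sxx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  syy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  cov_xx <- sxx / area - cx^2
  cov_yy <- syy / area - cy^2
  cov_xy <- sxy / area - cx * cy
  ev <- eigen(matrix(c(cov_xx, cov_xy, cov_xy, cov_yy), 2, 2),
              symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  if (lam[2] <= 0) stop("degenerate polygon: zero minor axis", call. = FALSE)
  major <- 4 * sqrt(lam[1])
  minor <- 4 * sqrt(lam[2])
  ar <- major / minor
  vec <- ev$vectors[, 1]                     # display coords (x right, y up)
  orientation <- wrap_axis_angle(atan2(-vec[1], vec[2]) * 180 / pi)
  structure(
    list(cell_id = cell_id,
         centroid = c(x = cx, y = -cy),      # back to array coords
         major_axis_length = major, minor_axis_length = minor,
         orientation = orientation, aspect_ratio = ar,
         unreliable_axis = ar < ar_flag_threshold),
    class = "shape_fit"
  )
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf(
    "Ellipse fit: cell %s, AR = %.3f, orientation = %.1f deg%s\n",
    x$cell_id, x$aspect_ratio, x$orientation,
    if (x$unreliable_axis) " (axis unreliable: near-circular)" else ""))
  invisible(x)
}

#' Aspect ratio of a shape fit
#'
#' @param fit a [fit_ellipse()] result.
#' @return major / minor axis ratio (>= 1).
#' @export
aspect_ratio <- function(fit) {
  if (fit$minor_axis_length <= 0) {
    stop("degenerate fit: zero minor axis", call. = FALSE)
  }
  fit$major_axis_length / fit$minor_axis_length
}

#' Tabulate shape fits
#'
#' @param fits list of `shape_fit` objects.
#' @return data.frame, one row per cell.
#' @export
shape_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(cell_id = f$cell_id, centroid_x = f$centroid["x"],
               centroid_y = f$centroid["y"],
               major_axis_length = f$major_axis_length,
               minor_axis_length = f$minor_axis_length,
               orientation = f$orientation, aspect_ratio = f$aspect_ratio,
               unreliable_axis = f$unreliable_axis,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Test the long-axis (Hertwig) rule
#'
#' Correlates the interphase long-axis angle with the final division angle
#' across cells (joined on `cell_id`), both folded to [0, 90]. Reports the
#' Spearman coefficient with its p-value (null: no correlation) plus the
#' Pearson r and R-squared; the same statistics on the signed angles are
#' reported alongside, since either convention is defensible.
#'
#' @param fits data.frame from [shape_table()] (or list of fits) with
#'   interphase orientations.
#' @param divisions data.frame from [division_table()].
#' @return list with `folded` and `signed` correlation results (each as
#'   returned by [spearman_cor()] plus `pearson_r`, `r_squared`) and
#'   `n_matched`.
#' @export
long_axis_rule_test <- function(fits, divisions) {
  if (!is.data.frame(fits)) fits <- shape_table(fits)
  m <- merge(fits[, c("cell_id", "orientation")],
             divisions[, c("cell_id", "final_signed_angle")],
             by = "cell_id")
  if (nrow(m) < 3) {
    stop("fewer than 3 cells with both a shape fit and a division record",
         call. = FALSE)
  }
  run <- function(xx, yy) {
    sp <- spearman_cor(xx, yy)
    pe <- pearson_r2(xx, yy)
    list(spearman_rho = sp$spearman_rho, p_two_sided = sp$p_two_sided,
         method = sp$method, pearson_r = pe$pearson_r,
         r_squared = pe$r_squared, n = sp$n)
  }
  list(
    folded = run(fold_angle(m$orientation), fold_angle(m$final_signed_angle)),
    signed = run(m$orientation, m$final_signed_angle),
    n_matched = nrow(m)
  )
}
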