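# Per-cell polarity statistics: angle of maximum cortical intensity and the
# peak-to-trough ratio, plus the polarity-vs-membrane-control comparison.
#
# The peak-to-trough ratio divides the global circular maximum of the
# (smoothed) normalized profile by the mean of the two nearest local minima
# flanking it; an unpolarized signal gives a ratio near 1. "Adjacent
# troughs" are found by walking from the peak in each circular direction
# until the smoothed profile first rises; if only one distinct local
# minimum exists it serves as both troughs.

# circular moving mean with an odd window
circular_smooth <- function(v, window) {
  window <- as.integer(window)
  if (window <= 1) return(v)
  if (window %% 2 == 0) window <- window + 1L
  h <- (window - 1L) %/% 2L
  n <- length(v)
  ext <- c(v[(n - h + 1):n], v, v[1:h])
  out <- stats::filter(ext, rep(1 / window, window), sides = 2)
  as.numeric(out[(h + 1):(h + n)])
}

profile_values <- function(profile) {
  if (!is.null(profile$normalized_intensity)) {
    profile$normalized_intensity
  } else {
    profile$raw_intensity
  }
}

# index of the circular-midpoint of the tied plateau containing the argmax
plateau_peak_index <- function(s, tol = 1e-12) {
  n <- length(s)
  m <- max(s)
  tied <- which(s >= m - tol)
  i0 <- tied[1]
  # contiguous circular run containing i0
  run <- i0
  j <- i0
  repeat {
    k <- (j %% n) + 1
    if (k %in% tied && k != i0) { run <- c(run, k); j <- k } else break
  }
  j <- i0
  repeat {
    k <- ((j - 2) %% n) + 1
    if (k %in% tied && k != i0 && !(k %in% run)) { run <- c(k, run); j <- k } else break
  }
  run[ceiling(length(run) / 2)]
}

#' Angle of maximum cortical intensity
#'
#' Returns the angular position of the global maximum of the circularly
#' smoothed profile. Plateau ties resolve to the circular midpoint of the
#' plateau. A constant profile has no defined peak and is flagged.
#'
#' @param profile a normalized, resampled [cortical_profile].
#' @param smooth_window circular moving-mean window in samples (odd;
#'   default 5; 1 = no smoothing).
#' @return list with `peak_angle` (degrees from the AP axis, `NA` if
#'   no peak), `peak_value`, `peak_index` and `no_peak` flag.
#' @export
find_peak <- function(profile, smooth_window = 5) {
  v <- profile_values(profile)
  s <- circular_smooth(v, smooth_window)
  rng <- max(s) - min(s)
  if (rng <= 1e-9 * max(abs(s), 1)) {
    return(list(peak_angle = NA_real_, peak_value = s[1],
                peak_index = NA_integer_, no_peak = TRUE))
  }
  i <- plateau_peak_index(s)
  list(peak_angle = profile$angular_position[i], peak_value = s[i],
       peak_index = i, no_peak = FALSE)
}

#' Peak-to-trough polarity ratio of a cortical profile
#'
#' Smooths the profile with a circular moving mean, locates the global
#' maximum, walks in both circular directions to the nearest local minima
#' (the "adjacent troughs") and returns peak / mean(troughs). Peak and
#' trough values are both read from the smoothed curve. Constant profiles
#' get ratio 1 with the `no_peak` flag set.
#'
#' @param profile a normalized [cortical_profile].
#' @param smooth_window circular moving-mean window (default 5 samples;
#'   1 = no smoothing).
#' @return object of class `polarity_measurement`: list with `cell_id`,
#'   `embryo_id`, `channel`, `peak_angle`, `peak_value`, `trough_values`
#'   (length 2), `peak_to_trough_ratio`, `no_peak`.
#' @export
peak_to_trough_ratio <- function(profile, smooth_window = 5) {
  v <- profile_values(profile)
  s <- circular_smooth(v, smooth_window)
  pk <- find_peak(profile, smooth_window)
  if (pk$no_peak) {
    return(structure(
      list(cell_id = profile$cell_id, embryo_id = profile$embryo_id,
           channel = profile$channel, peak_angle = NA_real_,
           peak_value = s[1], trough_values = c(s[1], s[1]),
           peak_to_trough_ratio = 1, no_peak = TRUE),
      class = "polarity_measurement"
    ))
  }
  n <- length(s)
  walk <- function(from, step) {
    j <- from
    for (iter in seq_len(n)) {
      k <- ((j - 1 + step) %% n) + 1
      if (s[k] <= s[j]) j <- k else break
    }
    j
  }
  t1 <- walk(pk$peak_index, +1L)
  t2 <- walk(pk$peak_index, -1L)
  troughs <- c(s[t1], s[t2])
  structure(
    list(cell_id = profile$cell_id, embryo_id = profile$embryo_id,
         channel = profile$channel, peak_angle = pk$peak_angle,
         peak_value = s[pk$peak_index], trough_values = troughs,
         peak_to_trough_ratio = s[pk$peak_index] / mean(troughs),
         no_peak = FALSE),
    class = "polarity_measurement"
  )
}

#' @export
print.polarity_measurement <- function(x, ...) {
  cat(sprintf("Polarity measurement: cell %s (%s), P = %.3f, peak angle = %s\n",
              x$cell_id, x$channel, x$peak_to_trough_ratio,
              if (x$no_peak) "no peak" else sprintf("%.1f deg", x$peak_angle)))
  invisible(x)
}

#' Tabulate polarity measurements
#'
#' @param measurements list of `polarity_measurement` objects.
#' @return data.frame, one row per cell.
#' @export
polarity_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m) {
    data.frame(cell_id = m$cell_id, embryo_id = m$embryo_id,
               channel = m$channel, peak_angle = m$peak_angle,
               peak_value = m$peak_value,
               peak_to_trough_ratio = m$peak_to_trough_ratio,
               no_peak = m$no_peak, stringsAsFactors = FALSE)
  }))
}

#' Compare polarity ratios against a membrane control
#'
#' Two-sided Mann-Whitney test of per-cell peak-to-trough ratios, polarity
#' channel versus membrane-control channel, with mean +/- SD per channel at
#' both the cell and the embryo level.
#'
#' @param polarity_cells,control_cells lists of `polarity_measurement`
#'   objects (or data.frames from [polarity_table()]).
#' @param exact_threshold passed to [mann_whitney()].
#' @return list with the `mw_test` in `$test`, `cell_summary` and
#'   `embryo_summary` data.frames.
#' @export
polarity_contrast_test <- function(polarity_cells, control_cells,
                                   exact_threshold = 20) {
  as_tab <- function(x) if (is.data.frame(x)) x else polarity_table(x)
  pol <- as_tab(polarity_cells); ctl <- as_tab(control_cells)
  if (is.null(pol) || is.null(ctl) || nrow(pol) == 0 || nrow(ctl) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  test <- mann_whitney(pol$peak_to_trough_ratio, ctl$peak_to_trough_ratio,
                       exact_threshold = exact_threshold)
  both <- rbind(cbind(pol, group = "polarity"), cbind(ctl, group = "control"))
  cell_summary <- group_summary(both$peak_to_trough_ratio, both$group)
  per_embryo <- stats::aggregate(
    peak_to_trough_ratio ~ embryo_id + group, data = both, FUN = mean)
  embryo_summary <- group_summary(per_embryo$peak_to_trough_ratio,
                                  per_embryo$group)
  list(test = test, cell_summary = cell_summary,
       embryo_summary = embryo_summary)
}
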