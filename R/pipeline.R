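# End-to-end analysis pipeline on synthetic cohorts: generation ->
# measurement -> statistics -> report bundle. Each stage is also exposed as
# a standalone function, so the pipeline is just their composition.

#' Configuration for the end-to-end pipeline
#'
#' @param synth a [synth_config()]; the generative parameters (the embedded
#'   seed drives all randomness).
#' @param n_embryos embryos to simulate.
#' @param n_profile_cells cells per embryo measured for cortical profiles.
#' @param line_width profile transect width, px.
#' @param smooth_window circular smoothing window for polarity statistics,
#'   samples.
#' @param resample_points common profile grid size.
#' @param rose_bin_width rose-histogram bin width, degrees.
#' @param exact_threshold exact-test threshold for [mann_whitney()].
#' @param alpha significance level echoed into the report.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(image_size = 256,
                                                 n_cells_per_side = 10,
                                                 pole_separation = 3,
                                                 gaussian_sd = 2),
                            n_embryos = 3,
                            n_profile_cells = 10,
                            line_width = 2,
                            smooth_window = 5,
                            resample_points = 128,
                            rose_bin_width = 15,
                            exact_threshold = 20,
                            alpha = 0.05) {
  structure(
    list(synth = synth, n_embryos = as.integer(n_embryos),
         n_profile_cells = as.integer(n_profile_cells),
         line_width = line_width, smooth_window = as.integer(smooth_window),
         resample_points = as.integer(resample_points),
         rose_bin_width = rose_bin_width,
         exact_threshold = as.integer(exact_threshold), alpha = alpha),
    class = "pipeline_config"
  )
}

# contour object for the i-th cell of a generated domain
domain_contour <- function(domain, i, embryo_id, phase = "mitotic_anaphase") {
  cell <- domain$cells[[i]]
  poly <- if (phase == "interphase") cell$interphase else cell$mitotic
  cell_contour(poly, cell_id = cell$cell_id, embryo_id = embryo_id,
               side = cell$side, phase = phase)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' For each simulated embryo: generates a mirrored mitotic domain, renders
#' the polarity and membrane channels, measures cortical profiles
#' (oriented, cytoplasm-normalized, resampled) for a subset of cells,
#' computes per-cell polarity measurements in both channels, renders and
#' measures the spindle time-lapse, tracks rotation into division records,
#' and fits interphase ellipses. Then: the polarity-vs-membrane contrast
#' test, the correlation of peak angle with division angle, the long-axis
#' rule test, rose histograms and per-embryo mean angles. All tables, the
#' configuration, plots and a run log are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return (invisibly) list with all tables and test results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$synth
  profiles_pol <- list(); profiles_mem <- list()
  division_records <- list(); shape_fits <- list()
  truth_all <- list(); contours_all <- list()
  for (e in seq_len(config$n_embryos)) {
    embryo_id <- sprintf("embryo%02d", e)
    sc_e <- sc
    sc_e$seed <- as.integer((sc$seed + 7919 * e) %% 2147483647)
    domain <- generate_domain(sc_e, embryo_id = embryo_id)
    truth_all[[e]] <- domain$truth
    img_pol <- render_polarity_image(domain, sc_e)
    img_mem <- render_membrane_image(domain, sc_e)
    n_cells <- length(domain$cells)
    measured <- seq_len(min(config$n_profile_cells, n_cells))
    for (i in measured) {
      ct <- domain_contour(domain, i, embryo_id)
      contours_all[[length(contours_all) + 1]] <- ct
      cyto <- cytoplasm_mean_at(img_pol, domain$cells[[i]]$centroid)
      cyto_m <- cytoplasm_mean_at(img_mem, domain$cells[[i]]$centroid)
      pp <- sample_perimeter_intensity(img_pol, ct, config$line_width)
      pp$channel <- "polarity"
      pp <- resample_profile(orient_profile(normalize_profile(pp, cyto)),
                             config$resample_points)
      pm <- sample_perimeter_intensity(img_mem, ct, config$line_width)
      pm$channel <- "membrane"
      pm <- resample_profile(orient_profile(normalize_profile(pm, cyto_m)),
                             config$resample_points)
      profiles_pol[[length(profiles_pol) + 1]] <- pp
      profiles_mem[[length(profiles_mem) + 1]] <- pm
    }
    stack <- render_spindle_timelapse(domain, sc_e)
    obs <- measure_spindle_stack(stack, domain)
    for (cell in domain$cells) {
      co <- obs[obs$cell_id == cell$cell_id, ]
      division_records[[length(division_records) + 1]] <- track_rotation(
        co[, c("frame", "signed_angle")], sc_e$anaphase_frame,
        cell_id = cell$cell_id, embryo_id = embryo_id, side = cell$side)
    }
    for (i in seq_len(n_cells)) {
      f <- fit_ellipse(domain_contour(domain, i, embryo_id, "interphase"))
      f$embryo_id <- embryo_id
      shape_fits[[length(shape_fits) + 1]] <- f
    }
  }
  truth <- do.call(rbind, truth_all)
  divisions <- division_table(division_records)
  meas_pol <- lapply(profiles_pol, peak_to_trough_ratio,
                     smooth_window = config$smooth_window)
  meas_mem <- lapply(profiles_mem, peak_to_trough_ratio,
                     smooth_window = config$smooth_window)
  contrast <- polarity_contrast_test(meas_pol, meas_mem,
                                     exact_threshold = config$exact_threshold)
  pol_tab <- polarity_table(meas_pol)
  # peak angle vs division angle, folded to the axis range
  pk <- merge(pol_tab[!pol_tab$no_peak, c("cell_id", "peak_angle")],
              divisions[, c("cell_id", "final_signed_angle")],
              by = "cell_id")
  angle_corr <- if (nrow(pk) >= 3) {
    xx <- fold_angle(wrap_axis_angle(pk$peak_angle))
    yy <- fold_angle(pk$final_signed_angle)
    c(spearman_cor(xx, yy), pearson_r2(xx, yy)[c("pearson_r", "r_squared")])
  } else NULL
  shapes <- shape_table(shape_fits)
  long_axis <- long_axis_rule_test(shapes, divisions)
  rose <- rose_histogram(divisions$folded_angle,
                         bin_width = config$rose_bin_width)
  embryo_means <- embryo_mean_angles(divisions)
  prof_avg <- average_profiles(profiles_pol)
  results <- list(
    truth = truth, divisions = divisions,
    polarity = rbind(pol_tab, polarity_table(meas_mem)),
    contrast = contrast, angle_correlation = angle_corr,
    shapes = shapes, long_axis = long_axis, rose = rose,
    embryo_means = embryo_means, profile_average = prof_avg,
    profiles = c(profiles_pol, profiles_mem),
    config = config
  )
  if (!is.null(out_dir)) write_report_bundle(results, contours_all, out_dir)
  invisible(results)
}

# mean intensity in a small disk at the cell centroid (cytoplasmic region)
cytoplasm_mean_at <- function(image, centroid, radius = 3) {
  xr <- round(centroid["x"]) + (-radius:radius)
  yr <- round(centroid["y"]) + (-radius:radius)
  g <- expand.grid(x = xr, y = yr)
  g <- g[(g$x - centroid["x"])^2 + (g$y - centroid["y"])^2 <= radius^2, ]
  mean(image[cbind(g$y, g$x)])
}

write_report_bundle <- function(results, contours, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_table_csv(results$truth, fp("ground_truth.csv"))
  write_table_csv(results$divisions, fp("division_records.csv"))
  write_table_csv(results$polarity, fp("polarity_measurements.csv"))
  write_table_csv(results$shapes, fp("shape_fits.csv"))
  write_table_csv(results$embryo_means, fp("embryo_mean_angles.csv"))
  write_profiles_csv(results$profiles, fp("cortical_profiles.csv"))
  write_contours_csv(contours, fp("contours.csv"))
  write_config_file(results$config$synth, fp("config.yml"))
  stats_rows <- data.frame(
    comparison = c("polarity_vs_membrane_ratio", "peak_angle_vs_division",
                   "long_axis_vs_division_folded"),
    statistic = c(results$contrast$test$U,
                  if (is.null(results$angle_correlation)) NA else
                    results$angle_correlation$spearman_rho,
                  results$long_axis$folded$spearman_rho),
    p_two_sided = c(results$contrast$test$p_two_sided,
                    if (is.null(results$angle_correlation)) NA else
                      results$angle_correlation$p_two_sided,
                    results$long_axis$folded$p_two_sided),
    method = c(results$contrast$test$method,
               if (is.null(results$angle_correlation)) NA else
                 results$angle_correlation$method,
               results$long_axis$folded$method)
  )
  write_table_csv(stats_rows, fp("statistics.csv"))
  g <- plot_rose(results$rose)
  ggplot2::ggsave(fp("rose_divisions.png"), g, width = 5, height = 5,
                  dpi = 150)
  pa <- results$profile_average
  pdf_df <- data.frame(
    arclength = rep(pa$arclength_fraction, nrow(pa$embryo_curves) + 1),
    intensity = c(as.vector(t(pa$embryo_curves)), pa$grand_mean),
    curve = rep(c(rownames(pa$embryo_curves), "grand mean"),
                each = length(pa$arclength_fraction))
  )
  gp <- ggplot2::ggplot(pdf_df,
                        ggplot2::aes(x = arclength, y = intensity,
                                     group = curve, colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arclength fraction from anterior-most point",
                  y = "normalized intensity") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(fp("mean_profiles.png"), gp, width = 6, height = 4,
                  dpi = 150)
  log_lines <- c(
    sprintf("spindlepol %s", as.character(utils::packageVersion("spindlepol"))),
    sprintf("R %s", R.version.string),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed: %d", results$config$synth$seed),
    "parameters:",
    utils::capture.output(utils::str(unclass(results$config), give.attr = FALSE))
  )
  writeLines(log_lines, fp("run_log.txt"))
  invisible(out_dir)
}
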