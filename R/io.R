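# File I/O: contour/profile/division/shape CSV tables with documented
# schemas, 16-bit TIFF stacks, and flat key-value config files.

#' Write cell contours to CSV
#'
#' Long format, one row per vertex: `cell_id, embryo_id, side, phase,
#' vertex_index, x, y`.
#'
#' @param contours list of [cell_contour()] objects.
#' @param path output file.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- do.call(rbind, lapply(contours, function(ct) {
    data.frame(cell_id = ct$cell_id, embryo_id = ct$embryo_id,
               side = ct$side, phase = ct$phase,
               vertex_index = seq_len(nrow(ct$vertices)),
               x = ct$vertices[, 1], y = ct$vertices[, 2],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read cell contours from CSV
#'
#' Expects the schema written by [write_contours_csv()]; polygons are
#' validated (at least 3 vertices, simple).
#'
#' @param path CSV file.
#' @return list of [cell_contour()] objects.
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "embryo_id", "side", "vertex_index", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("contour CSV is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$phase)) df$phase <- "mitotic_anaphase"
  keys <- unique(df[, c("cell_id", "embryo_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$cell_id == keys$cell_id[i] & df$embryo_id == keys$embryo_id[i], ]
    sub <- sub[order(sub$vertex_index), ]
    cell_contour(cbind(sub$x, sub$y), cell_id = keys$cell_id[i],
                 embryo_id = keys$embryo_id[i], side = sub$side[1],
                 phase = sub$phase[1])
  })
}

#' Write cortical profiles to long-format CSV
#'
#' One row per sample: `cell_id, embryo_id, side, channel,
#' arclength_fraction, angular_position, raw, normalized, cytoplasm_mean,
#' line_width`.
#'
#' @param profiles list of [cortical_profile] objects.
#' @param path output file.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(cell_id = p$cell_id, embryo_id = p$embryo_id, side = p$side,
               channel = p$channel,
               arclength_fraction = p$arclength_fraction,
               angular_position = p$angular_position,
               raw = p$raw_intensity,
               normalized = if (is.null(p$normalized_intensity)) NA_real_
                            else p$normalized_intensity,
               cytoplasm_mean = p$cytoplasm_mean,
               line_width = p$line_width, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write any result table to CSV
#'
#' @param table data.frame.
#' @param path output file.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a result table from CSV
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an image or stack as 16-bit TIFF
#'
#' Intensities are rounded to integers and stored as 16-bit samples on a
#' fixed 0..65535 scale, so the round trip through [read_image_tiff()] is
#' lossless for integer-valued images in that range. Stacks are written as
#' multi-page TIFFs, one page per frame.
#'
#' @param img numeric matrix or `H x W x n_frames` array.
#' @param path output file.
#' @export
write_image_tiff <- function(img, path) {
  to_page <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  if (length(dim(img)) == 3) {
    pages <- lapply(seq_len(dim(img)[3]), function(f) to_page(img[, , f]))
  } else {
    pages <- list(to_page(img))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read an image or stack written by [write_image_tiff()]
#'
#' @param path TIFF file.
#' @return numeric matrix (single page) or array (multi-page), on the
#'   original 0..65535 integer scale.
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) round(p * 65535))
  if (length(pages) == 1) return(pages[[1]])
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write a configuration as a flat key-value text file
#'
#' @param config a [synth_config()] or [pipeline_config()] (any named list).
#' @param path output file (YAML-formatted key: value lines).
#' @export
write_config_file <- function(config, path) {
  # named atomic vectors become maps so their names survive the round trip
  flat <- lapply(unclass(config), function(x) {
    if (is.atomic(x) && !is.null(names(x)) && length(x) > 1) as.list(x) else x
  })
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read a configuration file written by [write_config_file()]
#'
#' @param path config file.
#' @return named list.
#' @export
read_config_file <- function(path) {
  yaml::read_yaml(path)
}
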