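#' Extract per-cell mean RGB from a chip image
#'
#' For every cell of the layout, averages each 8-bit channel over the
#' centered `roi_side x roi_side` square of the cell (the ~1000-pixel
#' averaging window of the colorimetric signal). Means are kept at full
#' floating precision.
#'
#' @param image Integer array `h x w x 3` in `[0, 255]`.
#' @param layout A `"chip_layout"` matching the image dimensions.
#' @return Numeric matrix, one row per cell (named `cell{row}{col}`),
#'   columns `R`, `G`, `B`.
#' @examples
#' lay <- chip_layout()
#' img <- render_chip_image(lay, matrix(100L, 9, 3), noise_sd = 0)
#' extract_cell_means(img, lay)
#' @export
extract_cell_means <- function(image, layout) {
  validate_layout(layout)
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop_csa("image must be an h x w x 3 array", class = "layout_error")
  if (d[1] != layout$image_height || d[2] != layout$image_width)
    stop_csa("image dimensions do not match layout", class = "layout_error")
  cells <- layout$cells
  roi <- layout$roi_side
  out <- matrix(NA_real_, nrow(cells), 3,
                dimnames = list(cell_names(layout), c("R", "G", "B")))
  for (i in seq_len(nrow(cells))) {
    rx0 <- cells$x0[i] + (cells$width[i] - roi) %/% 2L
    ry0 <- cells$y0[i] + (cells$height[i] - roi) %/% 2L
    if (rx0 < 0 || ry0 < 0 || rx0 + roi > d[2] || ry0 + roi > d[1])
      stop_csa("ROI of cell ", i, " out of image bounds",
               class = "layout_error")
    block <- image[(ry0 + 1L):(ry0 + roi), (rx0 + 1L):(rx0 + roi), ,
                   drop = FALSE]
    out[i, ] <- apply(block, 3, mean)
  }
  out
}

#' Form a delta-RGB response pattern from paired means
#'
#' The sensor's signal is the signed change of each cell's mean 8-bit
#' channel values between the pre-exposure and post-exposure images of the
#' same chip: `delta = post - pre`, per cell, per channel. Signs are kept
#' (they encode the direction of the spectral shift); set
#' `absolute = TRUE` to fold them, e.g. for display.
#'
#' @param pre_means,post_means Numeric cell x RGB matrices with identical
#'   row order (as from [extract_cell_means()]).
#' @param analyte_id Analyte label for the pattern.
#' @param temperature_c Temperature of the exposure in degrees C.
#' @param absolute Use `|post - pre|` instead of signed differences.
#' @return An object of class `"response_pattern"` with fields
#'   `analyte_id`, `temperature_c` and `bins` (cells x 3 matrix of
#'   delta-R/G/B).
#' @export
compute_delta_pattern <- function(pre_means, post_means, analyte_id,
                                  temperature_c, absolute = FALSE) {
  pre_means <- as.matrix(pre_means); post_means <- as.matrix(post_means)
  if (!all(dim(pre_means) == dim(post_means)))
    stop_csa("pre/post cell counts differ", class = "pairing_error")
  if (!is.null(rownames(pre_means)) && !is.null(rownames(post_means)) &&
      !identical(rownames(pre_means), rownames(post_means)))
    stop_csa("pre/post cell order differs", class = "pairing_error")
  bins <- post_means - pre_means
  if (absolute) bins <- abs(bins)
  colnames(bins) <- c("R", "G", "B")
  structure(list(analyte_id = analyte_id,
                 temperature_c = temperature_c, bins = bins),
            class = "response_pattern")
}

#' @export
print.response_pattern <- function(x, ...) {
  cat(sprintf("response_pattern: %s at %g C, %d bins\n",
              x$analyte_id, x$temperature_c, nrow(x$bins)))
  print(round(x$bins, 2))
  invisible(x)
}

# Flatten a pattern's bins to the canonical feature vector:
# cell-major, channels R,G,B within each cell.
pattern_vector <- function(bins) {
  v <- as.vector(t(bins))
  names(v) <- paste0(rep(rownames(bins), each = 3), "_",
                     rep(c("R", "G", "B"), nrow(bins)))
  v
}

#' Assemble response patterns into feature tables
#'
#' Combines a collection of [compute_delta_pattern()] results into the
#' table(s) fed to the distance stage. Every analyte must be present at
#' every temperature. In `"concatenated"` mode (the default) the per-
#' temperature patterns of an analyte are concatenated temperature-major
#' into one long feature vector (9 cells x 4 temperatures = 36 bins in the
#' default design), giving one table with one row per analyte. In
#' `"per_temperature"` mode one table per temperature is returned, each
#' with the plain 9-cell bins.
#'
#' @param patterns List of `"response_pattern"` objects.
#' @param mode `"concatenated"` or `"per_temperature"`.
#' @return A data frame (`analyte_id` + numeric bin columns) in
#'   concatenated mode, or a named list of such data frames (with an
#'   additional `temperature_c` column) keyed by temperature. The mode is
#'   stored in attribute `"mode"`.
#' @export
assemble_feature_table <- function(patterns,
                                   mode = c("concatenated",
                                            "per_temperature")) {
  mode <- match.arg(mode)
  stopifnot(length(patterns) > 0,
            all(vapply(patterns, inherits, TRUE, "response_pattern")))
  analytes <- unique(vapply(patterns, `[[`, "", "analyte_id"))
  temps <- sort(unique(vapply(patterns, `[[`, 0, "temperature_c")))
  key <- function(a, t) paste(a, t, sep = "@")
  idx <- setNames(seq_along(patterns),
                  vapply(patterns, function(p)
                    key(p$analyte_id, p$temperature_c), ""))
  want <- as.vector(outer(analytes, temps, key))
  missing <- setdiff(want, names(idx))
  if (length(missing) || length(patterns) != length(want))
    stop_csa("incomplete analyte x temperature design; missing: ",
             paste(missing, collapse = ", "), class = "completeness_error")
  nbins <- unique(vapply(patterns, function(p) nrow(p$bins), 0L))
  if (length(nbins) != 1)
    stop_csa("patterns disagree on bin count", class = "completeness_error")
  one_row <- function(p) as.data.frame(t(pattern_vector(p$bins)))
  if (mode == "per_temperature") {
    out <- lapply(temps, function(t) {
      rows <- lapply(analytes, function(a) one_row(patterns[[idx[key(a, t)]]]))
      cbind(data.frame(analyte_id = analytes, temperature_c = t),
            do.call(rbind, rows))
    })
    names(out) <- as.character(temps)
    attr(out, "mode") <- mode
    return(out)
  }
  rows <- lapply(analytes, function(a) {
    parts <- lapply(temps, function(t) {
      r <- one_row(patterns[[idx[key(a, t)]]])
      names(r) <- sprintf("t%03d_%s", t, names(r))
      r
    })
    do.call(cbind, parts)
  })
  out <- cbind(data.frame(analyte_id = analytes), do.call(rbind, rows))
  attr(out, "mode") <- mode
  out
}

# Numeric bin matrix of a feature table, rownames = analyte ids.
feature_matrix <- function(features) {
  stopifnot(is.data.frame(features), "analyte_id" %in% names(features))
  num <- features[, setdiff(names(features),
                            c("analyte_id", "temperature_c")),
                  drop = FALSE]
  m <- as.matrix(num)
  rownames(m) <- features$analyte_id
  m
}

#' Read / write a feature table as CSV
#'
#' @param features Feature table from [assemble_feature_table()] (a single
#'   data frame).
#' @param path CSV path.
#' @return `read_feature_csv()` returns the feature table;
#'   `write_feature_csv()` returns `path` invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
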