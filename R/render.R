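#' Render a chip image from per-cell colors
#'
#' Paints each cell rectangle of the layout with its 8-bit RGB color on a
#' mid-grey background, then (optionally) adds i.i.d. Gaussian noise per
#' pixel per channel, rounded and clipped to `[0, 255]`. Rendering is fully
#' deterministic for a given seed.
#'
#' @param layout A `"chip_layout"`.
#' @param cell_rgbs Integer matrix, one row per layout cell, columns R, G,
#'   B in `[0, 255]`.
#' @param noise_sd Per-channel pixel noise standard deviation in counts.
#' @param seed Seed for the noise draws (ignored when `noise_sd = 0`).
#' @param background Background grey level.
#' @return Integer array `image_height x image_width x 3` with values in
#'   `[0, 255]`.
#' @examples
#' img <- render_chip_image(chip_layout(), simulate_response(
#'   synthetic_scenario(), "E1", 120)$post, noise_sd = 0)
#' @export
render_chip_image <- function(layout, cell_rgbs, noise_sd = 0, seed = NULL,
                              background = 128L) {
  validate_layout(layout)
  cell_rgbs <- as.matrix(cell_rgbs)
  if (nrow(cell_rgbs) != nrow(layout$cells) || ncol(cell_rgbs) != 3)
    stop_csa("cell_rgbs must be one RGB row per layout cell",
             class = "layout_error")
  if (noise_sd < 0)
    stop_csa("noise_sd must be >= 0", class = "invalid_parameter")
  h <- layout$image_height; w <- layout$image_width
  img <- array(as.numeric(background), dim = c(h, w, 3))
  cells <- layout$cells
  for (i in seq_len(nrow(cells))) {
    rows <- (cells$y0[i] + 1L):(cells$y0[i] + cells$height[i])
    cols <- (cells$x0[i] + 1L):(cells$x0[i] + cells$width[i])
    for (ch in 1:3) img[rows, cols, ch] <- cell_rgbs[i, ch]
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, array(rnorm(length(img), 0, noise_sd),
                                       dim = dim(img)))
  }
  array(as.integer(pmin(pmax(round(img), 0), 255)), dim = dim(img))
}

#' Write / read an 8-bit RGB chip image as PNG
#'
#' Thin wrappers around the `png` package keeping the package's integer
#' 0-255 convention: `write_chip_image()` stores the array losslessly;
#' `read_chip_image()` returns an integer array in `[0, 255]`.
#'
#' @param image Integer array `h x w x 3` in `[0, 255]`.
#' @param path PNG file path.
#' @return `read_chip_image()` returns the integer image array;
#'   `write_chip_image()` returns `path` invisibly.
#' @export
write_chip_image <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname write_chip_image
#' @export
read_chip_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 1))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  array(as.integer(round(img * 255)), dim = dim(img))
}

#' Generate a complete synthetic chip-image dataset
#'
#' Drives [simulate_response()] and [render_chip_image()] over every
#' (analyte, temperature) combination of the scenario, writing one
#' pre-exposure and one post-exposure PNG per combination plus a manifest
#' (`manifest.csv`: analyte, class, temperature, file names, per-image
#' seed), the ground-truth cell colors and deltas (`ground_truth.csv`), and
#' a scenario snapshot (`scenario.yaml`). Per-image noise seeds are derived
#' deterministically from the scenario seed, so regenerating with the same
#' scenario reproduces byte-identical files.
#'
#' @param scenario A `"synthetic_scenario"`.
#' @param output_dir Writable output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(scenario, output_dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir))
    stop_csa("cannot create output directory: ", output_dir,
             class = "io_error")
  combos <- expand.grid(temperature_c = scenario$temperatures_c,
                        analyte_id = scenario$analyte_ids,
                        stringsAsFactors = FALSE)[, 2:1]
  seeds <- derive_seeds(scenario$seed, 2L * nrow(combos))
  nms <- cell_names(scenario$layout)
  manifest <- data.frame(
    analyte_id = combos$analyte_id,
    class_label = scenario$class_labels[combos$analyte_id],
    temperature_c = combos$temperature_c,
    pre_image = sprintf("pre_%s_%03d.png", combos$analyte_id,
                        combos$temperature_c),
    post_image = sprintf("post_%s_%03d.png", combos$analyte_id,
                         combos$temperature_c),
    seed = seeds[seq_len(nrow(combos)) * 2L - 1L],
    row.names = NULL)
  truth <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    resp <- simulate_response(scenario, combos$analyte_id[i],
                              combos$temperature_c[i])
    pre_img <- render_chip_image(scenario$layout, resp$pre,
                                 scenario$noise_sd, seeds[2L * i - 1L])
    post_img <- render_chip_image(scenario$layout, resp$post,
                                  scenario$noise_sd, seeds[2L * i])
    write_chip_image(pre_img, file.path(output_dir, manifest$pre_image[i]))
    write_chip_image(post_img, file.path(output_dir, manifest$post_image[i]))
    truth[[i]] <- data.frame(
      analyte_id = combos$analyte_id[i],
      temperature_c = combos$temperature_c[i],
      cell = nms,
      swelling = resp$swelling,
      pre_R = resp$pre[, 1], pre_G = resp$pre[, 2], pre_B = resp$pre[, 3],
      post_R = resp$post[, 1], post_G = resp$post[, 2],
      post_B = resp$post[, 3],
      delta_R = resp$post[, 1] - resp$pre[, 1],
      delta_G = resp$post[, 2] - resp$pre[, 2],
      delta_B = resp$post[, 3] - resp$pre[, 3],
      row.names = NULL)
  }
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, truth),
                   file.path(output_dir, "ground_truth.csv"),
                   row.names = FALSE)
  write_scenario_config(scenario, file.path(output_dir, "scenario.yaml"))
  invisible(manifest)
}
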