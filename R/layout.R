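#' Define the sensor-cell grid of a chip image
#'
#' Geometry and identity of the unit cells on a chip image. The default is
#' the 3 x 3 design: one row of cells per engineered phage type (wild, RGD,
#' EEEE) and one column per film color (red, green, blue, set by the film
#' pulling speed). Pixel coordinates are 0-based with x to the right and y
#' down; each cell occupies the half-open rectangle
#' `[x0, x0 + width) x [y0, y0 + height)`. The response of a cell is read
#' from a centered square region of interest of side `roi_side` (default
#' 32 px, i.e. 1024 pixels, matching the ~1000-pixel averaging square used
#' for the colorimetric signal).
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_w,cell_h Cell size in pixels.
#' @param gap Gap between adjacent cells in pixels.
#' @param margin Margin around the grid in pixels.
#' @param roi_side Side of the centered averaging square in pixels.
#' @param phage_types Phage type per row.
#' @param film_colors Film color per column.
#' @param cells Optional custom cell table (columns `row`, `col`, `x0`,
#'   `y0`, `width`, `height`); overrides the regular grid.
#' @param image_width,image_height Image size in pixels; computed from the
#'   grid when omitted.
#' @return An object of class `"chip_layout"`.
#' @examples
#' chip_layout()
#' @export
chip_layout <- function(n_rows = 3, n_cols = 3, cell_w = 48, cell_h = 48,
                        gap = 8, margin = 8, roi_side = 32,
                        phage_types = c("wild", "RGD", "EEEE"),
                        film_colors = c("red", "green", "blue"),
                        cells = NULL, image_width = NULL,
                        image_height = NULL) {
  if (is.null(cells)) {
    grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
    cells <- data.frame(
      row = grid$row, col = grid$col,
      x0 = margin + (grid$col - 1L) * (cell_w + gap),
      y0 = margin + (grid$row - 1L) * (cell_h + gap),
      width = cell_w, height = cell_h)
  }
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL
  if (is.null(image_width))
    image_width <- max(cells$x0 + cells$width) + margin
  if (is.null(image_height))
    image_height <- max(cells$y0 + cells$height) + margin
  if (length(phage_types) != max(cells$row) ||
      length(film_colors) != max(cells$col))
    stop_csa("phage_types/film_colors must match grid rows/cols",
             class = "layout_error")
  layout <- structure(
    list(image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         cells = cells, roi_side = as.integer(roi_side),
         phage_types = phage_types, film_colors = film_colors),
    class = "chip_layout")
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  cells <- layout$cells
  if (any(cells$x0 < 0) || any(cells$y0 < 0) ||
      any(cells$x0 + cells$width > layout$image_width) ||
      any(cells$y0 + cells$height > layout$image_height))
    stop_csa("cell rectangles extend outside the image",
             class = "layout_error")
  if (layout$roi_side < 1 ||
      any(layout$roi_side > cells$width) ||
      any(layout$roi_side > cells$height))
    stop_csa("roi_side must fit inside every cell", class = "layout_error")
  n <- nrow(cells)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (cells$x0[i] < cells$x0[j] + cells$width[j] &&
        cells$x0[j] < cells$x0[i] + cells$width[i] &&
        cells$y0[i] < cells$y0[j] + cells$height[j] &&
        cells$y0[j] < cells$y0[i] + cells$height[i])
      stop_csa("cells ", i, " and ", j, " overlap", class = "layout_error")
  }
  invisible(layout)
}

#' Canonical cell names of a layout
#'
#' Row-major names `cell{row}{col}` fixing the bin order of every response
#' pattern extracted with this layout.
#'
#' @param layout A `"chip_layout"`.
#' @return Character vector, one name per cell.
#' @export
cell_names <- function(layout) {
  paste0("cell", layout$cells$row, layout$cells$col)
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("chip_layout: %d cells on %d x %d px image, roi %d x %d\n",
              nrow(x$cells), x$image_width, x$image_height,
              x$roi_side, x$roi_side))
  cat("rows:", paste(x$phage_types, collapse = ", "),
      "| cols:", paste(x$film_colors, collapse = ", "), "\n")
  invisible(x)
}
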