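test_that("cell means are exact on constant images and recover known fills", {
  lay <- chip_layout()
  img <- array(0L, dim = c(lay$image_height, lay$image_width, 3))
  img[, , 1] <- 100L; img[, , 2] <- 150L; img[, , 3] <- 200L
  means <- extract_cell_means(img, lay)
  expect_equal(unname(means),
               matrix(rep(c(100, 150, 200), each = 9), 9, 3))

  rgbs <- matrix(sample(0:255, 27), 9, 3)
  img2 <- render_chip_image(lay, rgbs, noise_sd = 0)
  expect_equal(unname(extract_cell_means(img2, lay)), unname(rgbs) * 1.0)

  # half 0 / half 255 in one channel averages to 127.5
  img3 <- render_chip_image(lay, matrix(0L, 9, 3), noise_sd = 0)
  cell <- lay$cells[1, ]
  rows <- (cell$y0 + 1):(cell$y0 + cell$height)
  cols <- (cell$x0 + 1):(cell$x0 + cell$width)
  img3[rows, cols[seq_len(cell$width / 2)], 1] <- 255L
  expect_equal(extract_cell_means(img3, lay)[1, "R"], 127.5)

  bad <- array(0L, dim = c(10, 10, 3))
  expect_error(extract_cell_means(bad, lay), class = "layout_error")
})

test_that("delta patterns are signed post-minus-pre differences", {
  pre <- matrix(c(200, 50, 100), 1, 3,
                dimnames = list("cell11", c("R", "G", "B")))
  post <- matrix(c(180, 80, 100), 1, 3,
                 dimnames = list("cell11", c("R", "G", "B")))
  p <- compute_delta_pattern(pre, post, "X", 30)
  expect_equal(unname(p$bins), matrix(c(-20, 30, 0), 1, 3))
  expect_equal(unname(compute_delta_pattern(pre, post, "X", 30,
                                            absolute = TRUE)$bins),
               matrix(c(20, 30, 0), 1, 3))
  expect_equal(unname(compute_delta_pattern(pre, pre, "X", 30)$bins),
               matrix(0, 1, 3))
  p2 <- compute_delta_pattern(matrix(0, 1, 3), matrix(255, 1, 3), "X", 30)
  expect_equal(unname(p2$bins), matrix(255, 1, 3))
  expect_error(compute_delta_pattern(matrix(0, 2, 3), matrix(0, 1, 3),
                                     "X", 30),
               class = "pairing_error")
})

test_that("noiseless simulate -> render -> extract round-trips exactly", {
  sc <- tiny_scenario(noise_sd = 0)
  dir <- withr::local_tempdir()
  generate_dataset(sc, dir)
  truth <- read.csv(file.path(dir, "ground_truth.csv"))
  ex <- extract_dataset(dir, sc$layout, mode = "concatenated")
  for (p in ex$patterns) {
    tr <- truth[truth$analyte_id == p$analyte_id &
                  truth$temperature_c == p$temperature_c, ]
    expect_equal(unname(p$bins),
                 unname(as.matrix(tr[, c("delta_R", "delta_G", "delta_B")])))
  }
})

test_that("feature assembly produces the documented shapes and fails on gaps", {
  mk <- function(a, t) compute_delta_pattern(
    matrix(0, 9, 3, dimnames = list(paste0("cell", rep(1:3, each = 3),
                                           rep(1:3, 3)), NULL)),
    matrix(seq_len(27), 9, 3), a, t)
  analytes <- c("a1", "a2", "a3")
  temps <- c(30, 60)
  patterns <- unlist(lapply(analytes, function(a)
    lapply(temps, function(t) mk(a, t))), recursive = FALSE)

  conc <- assemble_feature_table(patterns, "concatenated")
  expect_equal(dim(conc), c(3, 1 + 9 * 3 * 2))
  expect_true(all(startsWith(names(conc)[2:28], "t030_")))

  per <- assemble_feature_table(patterns, "per_temperature")
  expect_equal(names(per), c("30", "60"))
  expect_equal(dim(per[["30"]]), c(3, 2 + 27))

  single <- assemble_feature_table(list(mk("a1", 30)), "concatenated")
  expect_equal(dim(single), c(1, 1 + 27))

  expect_error(assemble_feature_table(patterns[-2]),
               class = "completeness_error")
})

test_that("extracted-mean spread across seeds matches sigma over sqrt(N)", {
  lay <- chip_layout()
  rgbs <- matrix(128L, 9, 3)
  sd_px <- 6
  means <- vapply(1:200, function(seed) {
    img <- render_chip_image(lay, rgbs, noise_sd = sd_px, seed = seed)
    extract_cell_means(img, lay)[1, "R"]
  }, 0)
  expect_equal(sd(means), sd_px / sqrt(lay$roi_side^2), tolerance = 0.2)
})

test_that("consistently permuting bins leaves downstream distances unchanged", {
  set.seed(99)
  a <- random_bins(9); b <- random_bins(9)
  perm <- sample(9)
  expect_equal(color_distance(a, b),
               color_distance(a[perm, ], b[perm, ]))
  expect_equal(color_distance(a, b, "euclidean"),
               color_distance(a[perm, ], b[perm, ], "euclidean"))
})
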