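test_that("zero swelling capacity or infinite affinity gives a null response", {
  sc0 <- synthetic_scenario(s_max = 0, noise_sd = 0)
  r <- simulate_response(sc0, "E1", 120)
  expect_identical(r$pre, r$post)
  expect_equal(unname(r$swelling), rep(0, 9))

  aff <- default_affinity() * 1e12  # affinity >> exposure: saturation -> 0
  sc_sat <- synthetic_scenario(affinity = aff, noise_sd = 0)
  r2 <- simulate_response(sc_sat, "TET", 90)
  expect_identical(r2$pre, r2$post)

  expect_error(simulate_response(sc0, "nope", 120), class = "lookup_error")
  expect_error(simulate_response(sc0, "E1", 45), class = "lookup_error")
})

test_that("swelling fractions respect [0, s_max] and temperature gain ordering", {
  sc <- synthetic_scenario()
  for (t in sc$temperatures_c) {
    s <- csaclust:::swelling_fractions(sc, "E2", t)
    expect_true(all(s >= 0 & s <= sc$s_max))
  }
  # hotter exposure swells at least as much (gains increase with temperature)
  s30 <- csaclust:::swelling_fractions(sc, "AMX", 30)
  s120 <- csaclust:::swelling_fractions(sc, "AMX", 120)
  expect_true(all(s120 >= s30))
})

test_that("noiseless rendering fills each cell ROI exactly and is reproducible", {
  lay <- chip_layout()
  rgbs <- matrix(rep(c(10L, 20L, 30L), each = 9), 9, 3)
  img <- render_chip_image(lay, rgbs, noise_sd = 0)
  expect_equal(dim(img), c(lay$image_height, lay$image_width, 3))
  cell <- lay$cells[5, ]
  block <- img[(cell$y0 + 1):(cell$y0 + cell$height),
               (cell$x0 + 1):(cell$x0 + cell$width), ]
  expect_true(all(block[, , 1] == 10L))
  expect_true(all(block[, , 2] == 20L))
  expect_true(all(block[, , 3] == 30L))
  # background untouched
  expect_equal(img[1, 1, ], rep(128L, 3))

  a <- render_chip_image(lay, rgbs, noise_sd = 5, seed = 7)
  b <- render_chip_image(lay, rgbs, noise_sd = 5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, render_chip_image(lay, rgbs, noise_sd = 5,
                                              seed = 8)))
})

test_that("noisy ROI means stay within 3 sigma of the mean of the true value", {
  lay <- chip_layout()
  rgbs <- matrix(100L, 9, 3)
  sd_px <- 5
  tol <- 3 * sd_px / sqrt(lay$roi_side^2)  # 3 sigma of a 1024-px mean
  n_bad <- 0L
  for (seed in 1:100) {
    img <- render_chip_image(lay, rgbs, noise_sd = sd_px, seed = seed)
    means <- extract_cell_means(img, lay)
    n_bad <- n_bad + sum(abs(means - 100) > tol)
  }
  # 900 channel-means x 100 seeds at 3 sigma: expect ~0.3% outliers
  expect_lt(n_bad / (900 * 100), 0.01)
})

test_that("generate_dataset writes the full design deterministically", {
  sc <- tiny_scenario(noise_sd = 2, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(sc, d1)
  m2 <- generate_dataset(sc, d2)
  expect_equal(nrow(m1), 4)  # 2 analytes x 2 temperatures
  expect_true(all(file.exists(file.path(d1, m1$pre_image))))
  expect_true(all(file.exists(file.path(d1, m1$post_image))))
  pngs <- sort(c(m1$pre_image, m1$post_image))
  expect_identical(unname(tools::md5sum(file.path(d1, pngs))),
                   unname(tools::md5sum(file.path(d2, pngs))))
  # scenario snapshot round-trips
  sc2 <- read_scenario_config(file.path(d1, "scenario.yaml"))
  expect_equal(sc2$affinity, sc$affinity)
  expect_equal(sc2$noise_sd, sc$noise_sd)
  expect_equal(sc2$layout$cells, sc$layout$cells)
})

test_that("overlapping cells are rejected as a layout error", {
  cells <- data.frame(row = c(1, 1), col = c(1, 2),
                      x0 = c(0, 10), y0 = c(0, 0),
                      width = 20, height = 20)
  expect_error(chip_layout(cells = cells, roi_side = 10,
                           phage_types = "wild",
                           film_colors = c("red", "green"),
                           image_width = 40, image_height = 30),
               class = "layout_error")
})
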