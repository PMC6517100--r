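test_that("empty and degenerate specs produce consistent images and truth", {
  spec0 <- image_spec(width_px = 120, height_px = 100, n_cells = 0, seed = 1)
  gen0 <- generate_if_image(spec0)
  expect_equal(nrow(gen0$truth$cells), 0)
  expect_true(is.na(gen0$truth$content_pct))
  # pure background + noise: nothing near the signal level
  expect_lt(max(gen0$image$data[, , "nuclear"]), spec0$signal_level / 2)

  spec1 <- image_spec(width_px = 300, height_px = 240, n_cells = 40,
                      frac_iba1 = 1, marker_pos_frac = 1, seed = 2)
  gen1 <- generate_if_image(spec1)
  expect_true(all(gen1$truth$cells$iba1_positive))
  expect_true(all(gen1$truth$cells$marker_positive))
  expect_equal(gen1$truth$content_pct, 100)
  expect_equal(gen1$truth$marker_freq_pct, 100)
})

test_that("fixed seed fixes every output bit-for-bit", {
  spec <- image_spec(width_px = 200, height_px = 160, n_cells = 25, seed = 5)
  a <- generate_if_image(spec)
  b <- generate_if_image(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("Iba1-positive counts follow the configured binomial fraction", {
  # mean Iba1+ count over repeated seeds within 3 SE of n * p
  n <- 200; p <- 0.4; n_seeds <- 50
  counts <- vapply(seq_len(n_seeds), function(s) {
    gen <- generate_if_image(std_image_spec(seed = 3000 + s, n_cells = n,
                                            frac_iba1 = p))
    sum(gen$truth$cells$iba1_positive)
  }, numeric(1))
  se <- sqrt(n * p * (1 - p)) / sqrt(n_seeds)
  expect_lt(abs(mean(counts) - n * p), 3 * se)
})

test_that("generated quantities respect their physical bounds", {
  for (s in 1:5) {
    gen <- generate_if_image(std_image_spec(seed = 400 + s, n_cells = 100,
                                            frac_iba1 = 0.3,
                                            marker_pos_frac = 0.5))
    tr <- gen$truth
    expect_true(all(tr$cells$marker_positive <= tr$cells$iba1_positive))
    expect_true(all(tr$cells$true_area_um2 > 0))
    expect_gte(tr$content_pct, 0); expect_lte(tr$content_pct, 100)
    expect_true(all(gen$image$data >= 0 & gen$image$data <= 1))
  }
})

test_that("overcrowded specs are rejected", {
  expect_error(generate_if_image(
    image_spec(width_px = 100, height_px = 100, n_cells = 500, seed = 1)),
    "overcrowded")
})

test_that("no-primary control shares unblanked channels with its image", {
  spec <- std_image_spec(seed = 9, n_cells = 60)
  gen <- generate_if_image(spec)
  ctrl <- generate_no_primary_control(spec)
  expect_identical(ctrl$data[, , "nuclear"], gen$image$data[, , "nuclear"])
  expect_identical(ctrl$data[, , "iba1"], gen$image$data[, , "iba1"])
  expect_false(identical(ctrl$data[, , "marker"], gen$image$data[, , "marker"]))

  # with autofluorescence and noise off, the blanked channel is exactly zero
  flat <- image_spec(width_px = 150, height_px = 120, n_cells = 10,
                     autofluor_level = 0, noise_sd = 0, seed = 3)
  ctrl0 <- generate_no_primary_control(flat)
  expect_true(all(ctrl0$data[, , "marker"] == 0))
})

test_that("control marker intensities sit below specific-signal levels", {
  spec <- std_image_spec(seed = 21, n_cells = 150, autofluor_level = 0.15)
  ctrl <- generate_no_primary_control(spec)
  cells <- ctrl$data[, , "marker"]
  # per-cell mean marker intensity over the true soma/nucleus footprint
  px <- spec$pixel_size_um
  tr <- generate_if_image(spec)$truth$cells
  means <- vapply(seq_len(nrow(tr)), function(i) {
    r <- (if (tr$iba1_positive[i]) tr$cell_radius_um[i]
          else tr$nuclear_radius_um[i]) / px
    xs <- pmax(1, floor(tr$x[i] - r)):pmin(nrow(cells), ceiling(tr$x[i] + r))
    ys <- pmax(1, floor(tr$y[i] - r)):pmin(ncol(cells), ceiling(tr$y[i] + r))
    inside <- outer((xs - tr$x[i])^2, (ys - tr$y[i])^2, "+") <= r^2
    mean(cells[xs, ys][inside])
  }, numeric(1))
  expect_lt(stats::quantile(means, 0.95), spec$signal_level)
})
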