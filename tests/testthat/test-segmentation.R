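make_disc <- function(w, h, cx, cy, r, bg = 0.05, fg = 0.6) {
  m <- matrix(bg, w, h)
  xs <- seq_len(w); ys <- seq_len(h)
  inside <- outer((xs - cx)^2, (ys - cy)^2, "+") <= r^2
  m[inside] <- fg
  m
}

test_that("nucleus detection finds isolated nuclei at their true positions", {
  expect_equal(max(detect_nuclei(matrix(0, 80, 80), segmentation_params())), 0)

  # 100 nuclei strictly inside the size filter
  spec <- std_image_spec(seed = 31, n_cells = 100, frac_iba1 = 0,
                         nuclear_diam_um = c(6, 8))
  gen <- generate_if_image(spec)
  labels <- detect_nuclei(gen$image$data[, , "nuclear"], segmentation_params())
  expect_equal(max(labels), 100)

  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  cx <- tapply(idx[, 1], lab, mean); cy <- tapply(idx[, 2], lab, mean)
  tr <- gen$truth$cells
  d <- vapply(seq_len(nrow(tr)), function(i)
    sqrt(min((cx - tr$x[i])^2 + (cy - tr$y[i])^2)), numeric(1))
  expect_true(all(d <= 2))
})

test_that("objects outside the nuclear diameter range are discarded", {
  params <- segmentation_params(nuclear_diam_um = c(5, 9))
  # diameter twice the max (18 um = 36 px at 0.5 um/px)
  big <- make_disc(120, 120, 60, 60, r = 18)
  expect_equal(max(detect_nuclei(big, params)), 0)
  # and one comfortably inside the range survives
  ok <- make_disc(120, 120, 60, 60, r = 7)
  expect_equal(max(detect_nuclei(ok, params)), 1)
})

test_that("cells without Iba1 signal keep their nucleus as the region", {
  spec <- std_image_spec(seed = 32, n_cells = 50, frac_iba1 = 0)
  gen <- generate_if_image(spec)
  params <- segmentation_params()
  nuclei <- detect_nuclei(gen$image$data[, , "nuclear"], params)
  cells <- segment_cells(nuclei, gen$image$data[, , "iba1"], params,
                         iba1_threshold = 0.3)
  rec <- measure_cells(cells, nuclei, gen$image, params, 0.3, 0.3)
  expect_equal(rec$cell_area_um2, rec$nucleus_area_um2)
})

test_that("cell regions are disjoint, contain their nucleus, and recover soma area", {
  f <- std_quant()
  nuclei <- f$q$nuclei; cells <- f$q$cells
  # every nucleus pixel belongs to the cell with the same label
  expect_true(all(cells[nuclei > 0] == nuclei[nuclei > 0]))
  # labels partition the foreground (disjoint by construction); every
  # detected nucleus has a cell
  expect_setequal(unique(as.vector(cells[cells > 0])),
                  unique(as.vector(nuclei[nuclei > 0])))

  # per-cell area recovery for Iba1+ cells, matched to truth by centroid
  rec <- f$q$records[f$q$records$iba1_positive, ]
  tr <- f$gen$truth$cells[f$gen$truth$cells$iba1_positive, ]
  nearest <- vapply(seq_len(nrow(rec)), function(i)
    which.min((tr$x - rec$x[i])^2 + (tr$y - rec$y[i])^2), integer(1))
  rel_err <- abs(rec$cell_area_um2 - tr$true_area_um2[nearest]) /
    tr$true_area_um2[nearest]
  expect_lt(stats::median(rel_err), 0.15)
  expect_lt(abs(mean(rec$cell_area_um2) - mean(tr$true_area_um2)) /
              mean(tr$true_area_um2), 0.15)
})

test_that("mean intensities are measured exactly on constant channels", {
  f <- std_quant()
  img <- f$gen$image
  img$data[, , "marker"] <- 0.37
  rec <- measure_cells(f$q$cells, f$q$nuclei, img, f$params, 0.3, 0.3)
  expect_true(all(abs(rec$marker_mean_intensity - 0.37) < 1e-12))
  # per-image mean Iba1 intensity of Iba1+ cells tracks the generator signal
  pos <- f$q$records[f$q$records$iba1_positive, ]
  expect_lt(abs(mean(pos$iba1_mean_intensity) - 0.5) / 0.5, 0.10)
})

test_that("stained area follows marker geometry", {
  f <- std_quant()
  img <- f$gen$image
  half <- matrix(0, nrow(img$data[, , 1]), ncol(img$data[, , 1]))
  half[seq_len(nrow(half) / 2), ] <- 0.9
  img$data[, , "marker"] <- half
  rec <- measure_cells(f$q$cells, f$q$nuclei, img, f$params, 0.3, 0.5)
  # cells fully on the stained side are fully stained; fully off, zero
  w <- nrow(half); px <- f$params$pixel_size_um
  rmax <- f$params$cell_diam_um[2] / 2 / px
  left <- rec$x < w / 2 - rmax
  right <- rec$x > w / 2 + rmax
  expect_true(all(abs(rec$marker_stained_area_um2[left] -
                        rec$cell_area_um2[left]) < 1e-9))
  expect_true(all(rec$marker_stained_area_um2[right] == 0))
})

test_that("mismatched shapes are rejected", {
  params <- segmentation_params()
  expect_error(segment_cells(matrix(0L, 50, 50), matrix(0, 60, 50),
                             params, 0.3), "different shapes")
})

test_that("positivity is monotone in both thresholds", {
  f <- std_quant()
  rec <- f$q$records
  params <- f$params
  for (mult in c(1.5, 3, 10)) {
    lo <- call_positivity(rec, f$cal$iba1$threshold, f$cal$marker$threshold,
                          params)
    hi <- call_positivity(rec, f$cal$iba1$threshold * mult,
                          f$cal$marker$threshold * mult, params)
    expect_true(all(hi$iba1_positive <= lo$iba1_positive))
    expect_true(all(hi$marker_positive <= lo$marker_positive))
    expect_true(all(hi$marker_positive <= hi$iba1_positive))
  }
  inf <- call_positivity(rec, Inf, Inf, params)
  expect_equal(sum(inf$iba1_positive), 0)
})

test_that("label maps are deterministic given image and parameters", {
  f <- std_quant()
  again <- detect_nuclei(f$gen$image$data[, , "nuclear"], f$params)
  expect_identical(again, f$q$nuclei)
})
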