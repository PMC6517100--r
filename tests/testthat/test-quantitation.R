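records_of <- function(iba1, marker) {
  data.frame(cell_id = seq_along(iba1), iba1_positive = iba1,
             marker_positive = marker)
}

test_that("content and marker frequency implement the counting formulas", {
  none <- records_of(rep(FALSE, 500), rep(FALSE, 500))
  expect_equal(compute_content(none, 500), 0)
  all_pos <- records_of(rep(TRUE, 500), rep(FALSE, 500))
  expect_equal(compute_content(all_pos, 500), 100)
  expect_error(compute_content(records_of(logical(0), logical(0)), 0),
               "no cells")

  r <- records_of(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(compute_content(r, 4), 75)
  expect_equal(compute_marker_frequency(r), 100 * 2 / 3)
  expect_equal(compute_marker_frequency(records_of(rep(TRUE, 3),
                                                   rep(TRUE, 3))), 100)
  expect_equal(compute_marker_frequency(records_of(rep(TRUE, 3),
                                                   rep(FALSE, 3))), 0)
  expect_warning(out <- compute_marker_frequency(
    records_of(rep(FALSE, 5), rep(FALSE, 5))), "undefined")
  expect_true(is.na(out))
})

test_that("formulas agree exactly with brute-force counts on ground truth", {
  for (s in c(11, 12)) {
    gen <- generate_if_image(std_image_spec(seed = s, n_cells = 150,
                                            frac_iba1 = 0.45,
                                            marker_pos_frac = 0.6))
    rec <- truth_records(gen$truth)
    tr <- gen$truth$cells
    # brute-force loop count
    n_iba1 <- 0; n_both <- 0
    for (i in seq_len(nrow(tr))) {
      if (tr$iba1_positive[i]) n_iba1 <- n_iba1 + 1
      if (tr$iba1_positive[i] && tr$marker_positive[i]) n_both <- n_both + 1
    }
    expect_identical(compute_content(rec, nrow(tr)),
                     100 * n_iba1 / nrow(tr))
    expect_identical(compute_marker_frequency(rec), 100 * n_both / n_iba1)
    expect_identical(compute_content(rec, nrow(tr)), gen$truth$content_pct)
  }
})

test_that("section summaries give mean and sample SD, ordered-invariantly", {
  s3 <- summarize_tumor(data.frame(content = c(10, 20, 30)))
  expect_equal(unname(s3$mean), 20)
  expect_equal(unname(s3$sd), 10)
  expect_false(s3$single_section)

  perm <- summarize_tumor(data.frame(content = c(30, 10, 20)))
  expect_equal(perm$mean, s3$mean)
  expect_equal(perm$sd, s3$sd)

  s1 <- summarize_tumor(data.frame(content = 42))
  expect_equal(unname(s1$sd), 0)
  expect_true(s1$single_section)

  same <- summarize_tumor(data.frame(content = c(7, 7, 7)))
  expect_equal(unname(same$sd), 0)
})

test_that("modality correlation matches closed-form Pearson computation", {
  expect_equal(correlate_modalities(c(1, 2, 3, 4), c(1, 2, 3, 4))$r, 1)
  expect_equal(correlate_modalities(c(1, 2, 3), c(-1, -2, -3))$r, -1)
  expect_error(correlate_modalities(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate_modalities(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlate_modalities(c(1, NA, 3), c(1, 2, 3)), "missing")

  x <- c(2.5, 7.1, 4.4); y <- c(1.0, 6.2, 2.2)
  out <- correlate_modalities(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(1 / (1 - r_hand^2))  # df = n - 2 = 1
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 1)
  expect_equal(out$r, r_hand, tolerance = 1e-10)
  expect_equal(out$p, p_hand, tolerance = 1e-10)
})

test_that("estimated content and marker frequency recover planted truth", {
  spec <- std_image_spec(seed = 61, n_cells = 500, frac_iba1 = 0.4,
                         marker_pos_frac = 0.6,
                         width_px = 700, height_px = 520)
  f <- calibrated_quant(spec)
  est_c <- compute_content(f$q$records, f$q$n_nuclei)
  est_f <- compute_marker_frequency(f$q$records)
  expect_lt(abs(est_c - f$gen$truth$content_pct), 5)
  expect_lt(abs(est_f - f$gen$truth$marker_freq_pct), 5)
})
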