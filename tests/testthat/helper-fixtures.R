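# shared fixtures; expensive segmentations are cached per session

fixture_cache <- new.env(parent = emptyenv())

std_image_spec <- function(seed, n_cells = 200, width_px = 450L,
                           height_px = 340L, ...) {
  image_spec(width_px = width_px, height_px = height_px, n_cells = n_cells,
             seed = seed, ...)
}

# generate image + matched controls, calibrate thresholds, quantify
calibrated_quant <- function(spec, params = segmentation_params()) {
  gen <- generate_if_image(spec)
  cal <- calibrate_site_thresholds(
    generate_no_primary_control(spec, c("iba1", "marker")),
    generate_no_primary_control(spec), params)
  q <- quantify_image(gen$image, params, cal$iba1$threshold,
                      cal$marker$threshold, cal$grow)
  list(gen = gen, cal = cal, q = q, params = params)
}

std_quant <- function() {
  if (is.null(fixture_cache$std)) {
    fixture_cache$std <- calibrated_quant(std_image_spec(seed = 7))
  }
  fixture_cache$std
}

# Rand index between two partitions
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  npairs <- choose(n, 2)
  (npairs + 2 * sum_ij - sum_i - sum_j) / npairs
}

# upper-tail hypergeometric probability by direct enumeration of draw
# counts: P(overlap >= q) drawing k from a universe of N with m successes
hyper_tail_oracle <- function(N, m, k, q) {
  if (q <= 0) return(1)
  js <- q:min(m, k)
  js <- js[js >= max(0, k - (N - m))]
  if (length(js) == 0) return(0)
  sum(choose(m, js) * choose(N - m, k - js)) / choose(N, k)
}

# map estimated cluster ids onto planted truth by majority vote
majority_map <- function(labels, truth) {
  vapply(sort(unique(labels)), function(cl) {
    as.integer(names(which.max(table(truth[labels == cl]))))
  }, integer(1))
}

# cell records reconstructed directly from generator ground truth
# (GroundTruth-perfect records)
truth_records <- function(truth) {
  cells <- truth$cells
  data.frame(cell_id = cells$cell_id,
             iba1_positive = cells$iba1_positive,
             marker_positive = cells$marker_positive)
}
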