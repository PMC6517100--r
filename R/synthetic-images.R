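#' Specification for one synthetic immunofluorescence site image
#'
#' Describes a three-channel (nuclear counterstain / Iba1 / inflammatory
#' marker) widefield site of fixed physical size, populated with
#' non-overlapping synthetic cells. Iba1-positive cells carry an Iba1-bright
#' soma; a configurable fraction of those additionally carry marker signal
#' co-located with the soma. Intensities are on a unit scale where 1.0 is
#' 16-bit detector saturation.
#'
#' Defaults emulate one microscope site of roughly 300 x 225 um at
#' 0.5 um/px with microglia-scale cells (nuclei 5-9 um, somata 8-16 um).
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param n_cells number of cells to place (non-overlapping).
#' @param frac_iba1 fraction of cells that are Iba1-positive.
#' @param marker_pos_frac fraction of Iba1-positive cells that are positive
#'   for the marker channel. Marker positivity is only defined within
#'   Iba1-positive cells.
#' @param nuclear_diam_um,cell_diam_um length-2 vectors (min, max) of
#'   nuclear and cell (soma) diameters in micrometres.
#' @param signal_level specific-stain intensity added on stained structures.
#' @param background_level camera/stain background of the nuclear and Iba1
#'   channels.
#' @param noise_sd standard deviation of additive Gaussian noise (clipped
#'   at 0 and at saturation).
#' @param autofluor_level tissue autofluorescence forming the background of
#'   the marker channel.
#' @param vessel_frac fraction of the image area covered by a bright
#'   vessel-like ellipse painted into all channels (0 disables).
#' @param seed integer seed; fixing it fixes every output bit-for-bit.
#' @return an object of class `image_spec`.
#' @export
image_spec <- function(width_px = 600L, height_px = 450L, pixel_size_um = 0.5,
                       n_cells = 300L, frac_iba1 = 0.4, marker_pos_frac = 0.5,
                       nuclear_diam_um = c(5, 9), cell_diam_um = c(8, 16),
                       signal_level = 0.5, background_level = 0.05,
                       noise_sd = 0.02, autofluor_level = 0.1,
                       vessel_frac = 0, seed = 1L) {
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
    frac_iba1 = frac_iba1, marker_pos_frac = marker_pos_frac,
    nuclear_diam_um = as.numeric(nuclear_diam_um),
    cell_diam_um = as.numeric(cell_diam_um),
    signal_level = signal_level, background_level = background_level,
    noise_sd = noise_sd, autofluor_level = autofluor_level,
    vessel_frac = vessel_frac, seed = as.integer(seed)
  )
  class(spec) <- "image_spec"
  validate_image_spec(spec)
  spec
}

validate_image_spec <- function(spec) {
  stopifnot(
    spec$width_px > 0, spec$height_px > 0, spec$pixel_size_um > 0,
    spec$n_cells >= 0,
    spec$frac_iba1 >= 0, spec$frac_iba1 <= 1,
    spec$marker_pos_frac >= 0, spec$marker_pos_frac <= 1,
    length(spec$nuclear_diam_um) == 2, length(spec$cell_diam_um) == 2,
    spec$nuclear_diam_um[1] > 0, spec$cell_diam_um[1] > 0,
    spec$nuclear_diam_um[1] < spec$nuclear_diam_um[2],
    spec$cell_diam_um[1] < spec$cell_diam_um[2],
    spec$signal_level > spec$background_level,
    spec$noise_sd >= 0, spec$autofluor_level >= 0,
    spec$vessel_frac >= 0, spec$vessel_frac <= 1
  )
  invisible(spec)
}

#' @rdname image_spec
#' @param x object to test / print.
#' @param ... unused.
#' @export
print.image_spec <- function(x, ...) {
  cat(sprintf(
    "<image_spec> %d x %d px @ %.3g um/px, %d cells (Iba1+ %.0f%%, marker+|Iba1+ %.0f%%), seed %d\n",
    x$width_px, x$height_px, x$pixel_size_um, x$n_cells,
    100 * x$frac_iba1, 100 * x$marker_pos_frac, x$seed))
  invisible(x)
}

CHANNEL_NAMES <- c("nuclear", "iba1", "marker")

new_if_image <- function(data, pixel_size_um) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == 3)
  dimnames(data) <- list(NULL, NULL, CHANNEL_NAMES)
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 channels = CHANNEL_NAMES),
            class = "if_image")
}

#' @export
print.if_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<if_image> %d x %d px, 3 channels (%s), %.3g um/px\n",
              d[1], d[2], paste(x$channels, collapse = "/"), x$pixel_size_um))
  invisible(x)
}

# Place n non-overlapping discs by rejection sampling. radii_px includes the
# desired clearance. Largest discs are placed first to ease packing.
place_cells <- function(n, radii_px, width, height, max_attempts = 8000L) {
  ord <- order(radii_px, decreasing = TRUE)
  xs <- ys <- numeric(n)
  rs <- radii_px[ord]
  for (i in seq_len(n)) {
    r <- rs[i]
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- stats::runif(1, r + 1, width - r - 1)
      y <- stats::runif(1, r + 1, height - r - 1)
      if (i == 1L ||
          all((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2 >
              (rs[seq_len(i - 1)] + r + 1)^2)) {
        xs[i] <- x; ys[i] <- y; placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping cells; image overcrowded")
  }
  inv <- order(ord)
  data.frame(x = xs[inv], y = ys[inv])
}

# Add `value` over a disc of radius r (px) centred at (cx, cy) into matrix m.
paint_disc <- function(m, cx, cy, r, value) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(nrow(m), ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(ncol(m), ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  inside <- outer((xs - cx)^2, (ys - cy)^2, "+") <= r^2
  m[xs, ys][inside] <- m[xs, ys][inside] + value
  m
}

paint_ellipse <- function(m, cx, cy, a, b, theta, value) {
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  m[inside] <- m[inside] + value
  m
}

# Shared generator behind generate_if_image() / generate_no_primary_control().
# `blank` names fluorophore channels whose specific staining is omitted;
# everything else, including the RNG stream, is identical, so matched
# image/control pairs share all unblanked channels bit-for-bit.
generate_site <- function(spec, blank = character(0)) {
  validate_image_spec(spec)
  w <- spec$width_px; h <- spec$height_px; px <- spec$pixel_size_um

  set.seed(spec$seed)

  n <- spec$n_cells
  nuc <- matrix(spec$background_level, w, h)
  iba <- matrix(spec$background_level, w, h)
  mrk <- matrix(spec$autofluor_level, w, h)

  if (n > 0) {
    nuc_r_um <- stats::runif(n, spec$nuclear_diam_um[1], spec$nuclear_diam_um[2]) / 2
    cel_r_um <- stats::runif(n, spec$cell_diam_um[1], spec$cell_diam_um[2]) / 2
    # a soma always envelops its nucleus
    cel_r_um <- pmax(cel_r_um, nuc_r_um + 0.25)
    iba1_pos <- stats::runif(n) < spec$frac_iba1
    marker_pos <- iba1_pos & (stats::runif(n) < spec$marker_pos_frac)
    bright <- stats::runif(n, 0.8, 1.2)  # per-cell staining heterogeneity

    foot_r_px <- ifelse(iba1_pos, cel_r_um, nuc_r_um) / px
    expected_area <- sum(pi * foot_r_px^2)
    if (expected_area > 0.5 * w * h)
      stop("expected cell footprint (", round(expected_area), " px) exceeds ",
           "half the image area (", w * h, " px); image overcrowded")

    pos <- place_cells(n, foot_r_px, w, h)

    for (i in seq_len(n)) {
      nr <- nuc_r_um[i] / px
      nuc <- paint_disc(nuc, pos$x[i], pos$y[i], nr, spec$signal_level * bright[i])
      if (iba1_pos[i]) {
        cr <- cel_r_um[i] / px
        if (!("iba1" %in% blank))
          iba <- paint_disc(iba, pos$x[i], pos$y[i], cr,
                            spec$signal_level * bright[i])
        if (marker_pos[i] && !("marker" %in% blank))
          mrk <- paint_disc(mrk, pos$x[i], pos$y[i], cr,
                            spec$signal_level * bright[i])
      }
    }
    truth_cells <- data.frame(
      cell_id = seq_len(n),
      x = pos$x, y = pos$y,
      nuclear_radius_um = nuc_r_um, cell_radius_um = cel_r_um,
      iba1_positive = iba1_pos, marker_positive = marker_pos,
      true_area_um2 = pi * ifelse(iba1_pos, cel_r_um, nuc_r_um)^2
    )
  } else {
    truth_cells <- data.frame(
      cell_id = integer(), x = numeric(), y = numeric(),
      nuclear_radius_um = numeric(), cell_radius_um = numeric(),
      iba1_positive = logical(), marker_positive = logical(),
      true_area_um2 = numeric()
    )
  }

  if (spec$vessel_frac > 0) {
    area <- spec$vessel_frac * w * h
    aspect <- stats::runif(1, 1.5, 3)
    b <- sqrt(area / (pi * aspect)); a <- aspect * b
    cx <- stats::runif(1, 0.25 * w, 0.75 * w)
    cy <- stats::runif(1, 0.25 * h, 0.75 * h)
    theta <- stats::runif(1, 0, pi)
    nuc <- paint_ellipse(nuc, cx, cy, a, b, theta, 1.5 * spec$signal_level)
    iba <- paint_ellipse(iba, cx, cy, a, b, theta, 1.5 * spec$signal_level)
    mrk <- paint_ellipse(mrk, cx, cy, a, b, theta, 1.5 * spec$signal_level)
  }

  if (spec$noise_sd > 0) {
    nuc <- nuc + stats::rnorm(w * h, 0, spec$noise_sd)
    iba <- iba + stats::rnorm(w * h, 0, spec$noise_sd)
    mrk <- mrk + stats::rnorm(w * h, 0, spec$noise_sd)
  }

  arr <- array(0, dim = c(w, h, 3))
  arr[, , 1] <- pmin(pmax(nuc, 0), 1)
  arr[, , 2] <- pmin(pmax(iba, 0), 1)
  arr[, , 3] <- pmin(pmax(mrk, 0), 1)

  img <- new_if_image(arr, px)

  n_iba1 <- sum(truth_cells$iba1_positive)
  truth <- list(
    cells = truth_cells,
    content_pct = if (n > 0) 100 * n_iba1 / n else NA_real_,
    marker_freq_pct = if (n_iba1 > 0)
      100 * sum(truth_cells$marker_positive) / n_iba1 else NA_real_
  )
  class(truth) <- "ground_truth"
  list(image = img, truth = truth)
}

#' Generate a synthetic immunofluorescence site with known ground truth
#'
#' Produces a three-channel image (nuclear / Iba1 / marker) in which every
#' cell's position, size and positivity status is recorded, so segmentation
#' and quantitation can be validated against the truth. Cells are
#' non-overlapping discs placed by rejection sampling; noise is additive
#' Gaussian clipped to the valid intensity range.
#'
#' @param spec an [image_spec()].
#' @return a list with elements `image` (an `if_image`) and `truth`
#'   (a `ground_truth` with per-cell assignments plus image-level true
#'   Iba1 content and marker frequency in percent).
#' @export
generate_if_image <- function(spec) {
  generate_site(spec)
}

#' Generate a matched no-primary-antibody control image
#'
#' Same nuclear and Iba1 channels as [generate_if_image()] run with the same
#' spec (identical seed, identical pixels), but the marker channel carries
#' only autofluorescence background and noise — no specific staining. Used
#' to calibrate the marker positivity threshold so that at most a set
#' fraction of control cells score falsely positive.
#'
#' @param spec an [image_spec()]; use the same seed as the matched image.
#' @param channels which fluorophore channels to blank. The default
#'   (`"marker"`) reproduces the usual control in which only the marker
#'   primary is omitted; `c("iba1", "marker")` also omits the Iba1
#'   primary, for calibrating the Iba1 threshold.
#' @return an `if_image`.
#' @export
generate_no_primary_control <- function(spec, channels = "marker") {
  stopifnot(length(channels) >= 1, all(channels %in% c("iba1", "marker")))
  generate_site(spec, blank = channels)$image
}
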