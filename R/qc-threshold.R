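#' Calibrate a positivity threshold from a no-primary control
#'
#' Sets the intensity threshold of one fluorophore from the per-cell mean
#' intensities measured on a matched no-primary-antibody control, following
#' the rule that at most `max_fp` (default 5%) of control cells may score
#' falsely positive. The threshold is the smallest measured candidate value
#' at which the fraction of control cells at or above it drops to
#' `max_fp` or less; when no measured value qualifies (e.g. all intensities
#' tie) the threshold is placed just above the control maximum and the
#' achieved false-positive fraction is 0.
#'
#' Calibration operates on per-cell mean intensities; the minimum
#' stained-area rule applied later at positivity calling can only remove
#' further positives, so the achieved false-positive bound is conservative.
#'
#' @param control_records cell records measured on the control image
#'   (from [measure_cells()]); at least 20 cells are required.
#' @param channel `"marker"` or `"iba1"` — which fluorophore to calibrate.
#' @param max_fp maximum tolerated false-positive fraction of control
#'   cells (default 0.05).
#' @return a `threshold_set` entry: list with `threshold`,
#'   `control_n_cells`, and `achieved_false_positive_frac`.
#' @export
calibrate_threshold <- function(control_records, channel = c("marker", "iba1"),
                                max_fp = 0.05) {
  channel <- match.arg(channel)
  stopifnot(max_fp >= 0, max_fp <= 1)
  x <- control_records[[paste0(channel, "_mean_intensity")]]
  n <- length(x)
  if (n < 20)
    stop("under-powered control: ", n, " cells (need >= 20)")

  candidates <- sort(unique(x))
  fp <- vapply(candidates, function(t) mean(x >= t), numeric(1))
  ok <- which(fp <= max_fp)
  if (length(ok) > 0) {
    thr <- candidates[ok[1]]
    achieved <- fp[ok[1]]
  } else {
    thr <- max(x) * (1 + 1e-9) + 1e-12  # just above the highest control cell
    achieved <- 0
  }
  structure(list(threshold = thr, control_n_cells = n,
                 achieved_false_positive_frac = achieved),
            class = "threshold_set")
}

#' Region-growing threshold from a no-primary control's background
#'
#' Cell regions must be delineated by a threshold that excludes background
#' pixels outright, otherwise region growing selectively collects
#' supra-threshold noise and biases per-cell mean intensities upward. The
#' grow threshold is set from the pixel population of a control channel
#' carrying no specific signal: median + 5 MAD, far in the background
#' tail yet well below specific staining.
#'
#' @param control an `if_image` whose named channel carries no specific
#'   signal (e.g. an Iba1-blanked no-primary control).
#' @param channel channel name, default `"iba1"`.
#' @return the grow threshold (intensity units).
#' @export
background_grow_threshold <- function(control, channel = "iba1") {
  ch <- get_channel(control, channel)
  stats::median(ch) + 5 * stats::mad(ch)
}

#' Calibrate all thresholds for one tumor from its no-primary controls
#'
#' Performs the full per-fluorophore calibration for one tumor/marker
#' pairing: the region-growing threshold comes from the Iba1-blanked
#' control's background pixels, then the Iba1 and marker scoring
#' thresholds are calibrated at the cell level on controls segmented with
#' that same grow threshold (so control and sample cells are measured
#' identically and the false-positive bound carries over).
#'
#' @param control_iba1 no-primary control with both Iba1 and marker
#'   blanked (`generate_no_primary_control(spec, c("iba1", "marker"))`).
#' @param control_marker no-primary control with only the marker blanked.
#' @param params a [segmentation_params()].
#' @param max_fp maximum tolerated false-positive fraction.
#' @return list with `grow` (grow threshold), `iba1` and `marker`
#'   (`threshold_set` entries from [calibrate_threshold()]).
#' @export
calibrate_site_thresholds <- function(control_iba1, control_marker, params,
                                      max_fp = 0.05) {
  grow <- background_grow_threshold(control_iba1, "iba1")
  nuc_i <- detect_nuclei(control_iba1$data[, , "nuclear"], params)
  cells_i <- segment_cells(nuc_i, control_iba1$data[, , "iba1"], params, grow)
  rec_i <- measure_cells(cells_i, nuc_i, control_iba1, params, grow, grow)
  thr_iba <- calibrate_threshold(rec_i, "iba1", max_fp = max_fp)

  nuc_m <- detect_nuclei(control_marker$data[, , "nuclear"], params)
  cells_m <- segment_cells(nuc_m, control_marker$data[, , "iba1"], params, grow)
  rec_m <- measure_cells(cells_m, nuc_m, control_marker, params,
                         thr_iba$threshold, grow)
  thr_mrk <- calibrate_threshold(rec_m, "marker", max_fp = max_fp)
  list(grow = grow, iba1 = thr_iba, marker = thr_mrk)
}

#' Site-level quality rules
#'
#' Sites are excluded when a vessel-like bright structure covers more than
#' `max_vessel_frac` of the site area (strictly greater than, default 25%),
#' when the focus metric falls below `min_focus_metric`, or when more than
#' `max_saturated_frac` of pixels are saturated.
#'
#' @param max_vessel_frac maximum tolerated vessel area fraction (strict).
#' @param min_focus_metric minimum variance-of-Laplacian focus metric; 0
#'   disables the check. See [default_focus_cutoff()].
#' @param max_saturated_frac maximum tolerated fraction of saturated
#'   pixels.
#' @return an object of class `site_qc_rules`.
#' @export
site_qc_rules <- function(max_vessel_frac = 0.25, min_focus_metric = 0,
                          max_saturated_frac = 0.1) {
  r <- list(max_vessel_frac = max_vessel_frac,
            min_focus_metric = min_focus_metric,
            max_saturated_frac = max_saturated_frac)
  stopifnot(r$max_vessel_frac >= 0, r$max_vessel_frac <= 1,
            r$min_focus_metric >= 0,
            r$max_saturated_frac >= 0, r$max_saturated_frac <= 1)
  class(r) <- "site_qc_rules"
  r
}

#' Compute per-site QC statistics
#'
#' Vessel fraction: pixels simultaneously bright in all three channels
#' (above each channel's median + 5 MAD — vessels are autofluorescent
#' across channels, cells are bright in individual channels only), after
#' morphological closing. Focus: variance of the Laplacian of the nuclear
#' channel. Saturation: fraction of pixels at the top of the intensity
#' range in any channel.
#'
#' @param image an `if_image`.
#' @return one-row data.frame with `vessel_frac`, `focus`,
#'   `saturated_frac`.
#' @export
site_qc_stats <- function(image) {
  stopifnot(inherits(image, "if_image"))
  arr <- image$data
  bright <- matrix(TRUE, dim(arr)[1], dim(arr)[2])
  for (c in 1:3) {
    ch <- arr[, , c]
    thr <- stats::median(ch) + 5 * stats::mad(ch)
    bright <- bright & (ch > thr)
  }
  if (any(bright)) {
    brush <- EBImage::makeBrush(5, shape = "disc")
    bright <- EBImage::imageData(
      EBImage::closing(EBImage::Image(bright * 1), brush)) > 0
  }
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  hp <- EBImage::imageData(EBImage::filter2(EBImage::Image(arr[, , 1]), lap))
  saturated <- (arr[, , 1] >= 0.999) | (arr[, , 2] >= 0.999) |
    (arr[, , 3] >= 0.999)
  data.frame(vessel_frac = mean(bright),
             focus = stats::var(as.vector(hp)),
             saturated_frac = mean(saturated))
}

#' Default focus cutoff for a run
#'
#' Poorly focused sites are flagged relative to the run itself: the default
#' cutoff is 10% of the median focus metric across the run's sites.
#'
#' @param focus_values numeric vector of per-site focus metrics.
#' @return a cutoff usable as `min_focus_metric` in [site_qc_rules()].
#' @export
default_focus_cutoff <- function(focus_values) {
  0.1 * stats::median(focus_values)
}

#' Apply site-level quality filters
#'
#' A site is excluded iff its vessel fraction strictly exceeds the maximum,
#' its focus metric falls below the minimum, or its saturated-pixel
#' fraction exceeds the maximum. Exclusion reasons are logged per site.
#' The filter is idempotent and order-independent.
#'
#' @param site_stats data.frame with one row per site and columns
#'   `site_id`, `vessel_frac`, `focus`, `saturated_frac`.
#' @param rules a [site_qc_rules()].
#' @return list with `kept` (site ids) and `log` (data.frame site_id,
#'   kept, reason — comma-joined reasons, empty when kept).
#' @export
filter_sites <- function(site_stats, rules) {
  stopifnot(inherits(rules, "site_qc_rules"),
            all(c("site_id", "vessel_frac", "focus", "saturated_frac") %in%
                  names(site_stats)))
  reasons <- lapply(seq_len(nrow(site_stats)), function(i) {
    r <- character(0)
    if (site_stats$vessel_frac[i] > rules$max_vessel_frac) r <- c(r, "vessel")
    if (site_stats$focus[i] < rules$min_focus_metric) r <- c(r, "focus")
    if (site_stats$saturated_frac[i] > rules$max_saturated_frac)
      r <- c(r, "saturation")
    r
  })
  kept <- vapply(reasons, length, integer(1)) == 0
  list(
    kept = site_stats$site_id[kept],
    log = data.frame(
      site_id = site_stats$site_id,
      kept = kept,
      reason = vapply(reasons, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
  )
}
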