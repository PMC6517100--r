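#' Segmentation parameters
#'
#' User-defined parameters of the automated per-cell scoring step: pixel
#' size, the minimum and maximum nuclear and cell diameter, and the minimum
#' stained area a cell must exceed to count as positively stained.
#'
#' @param pixel_size_um micrometres per pixel.
#' @param nuclear_diam_um,cell_diam_um length-2 `(min, max)` diameters, um.
#'   Detected nuclei outside the nuclear range are discarded; cell regions
#'   are capped at a radius of `max(cell_diam_um)/2` around their nucleus.
#' @param min_stained_area_um2 minimum supra-threshold stained area (um^2)
#'   required for a positivity call. Should exceed the area that background
#'   noise can push over the calibrated threshold inside a bare nucleus
#'   footprint (roughly half the largest nuclear area) while staying below
#'   the smallest genuine soma (`pi * (min cell diameter / 2)^2`); the
#'   default 30 does both for the default diameter ranges.
#' @param nuclear_threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_nuclear_threshold intensity threshold used when
#'   `nuclear_threshold_method = "fixed"`.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(pixel_size_um = 0.5,
                                nuclear_diam_um = c(5, 9),
                                cell_diam_um = c(8, 16),
                                min_stained_area_um2 = 30,
                                nuclear_threshold_method = c("otsu", "fixed"),
                                fixed_nuclear_threshold = NULL) {
  nuclear_threshold_method <- match.arg(nuclear_threshold_method)
  p <- list(pixel_size_um = pixel_size_um,
            nuclear_diam_um = as.numeric(nuclear_diam_um),
            cell_diam_um = as.numeric(cell_diam_um),
            min_stained_area_um2 = min_stained_area_um2,
            nuclear_threshold_method = nuclear_threshold_method,
            fixed_nuclear_threshold = fixed_nuclear_threshold)
  stopifnot(p$pixel_size_um > 0,
            p$nuclear_diam_um[1] > 0, p$nuclear_diam_um[1] < p$nuclear_diam_um[2],
            p$cell_diam_um[1] > 0, p$cell_diam_um[1] < p$cell_diam_um[2],
            p$min_stained_area_um2 > 0,
            p$min_stained_area_um2 < pi * (p$cell_diam_um[2] / 2)^2)
  if (nuclear_threshold_method == "fixed" && is.null(fixed_nuclear_threshold))
    stop("fixed_nuclear_threshold required when nuclear_threshold_method = 'fixed'")
  class(p) <- "segmentation_params"
  p
}

# channel extractor tolerating either an if_image or a bare matrix
get_channel <- function(image, channel) {
  if (inherits(image, "if_image")) image$data[, , channel]
  else image
}

#' Detect nuclei in the nuclear counterstain channel
#'
#' Thresholds the nuclear channel (Otsu by default), splits touching
#' nuclei by watershed on the distance transform, and discards objects
#' whose equivalent diameter falls outside the configured nuclear range.
#'
#' @param nuclear 2-D nuclear-channel matrix, or an `if_image` (its
#'   nuclear channel is used).
#' @param params a [segmentation_params()].
#' @return integer label matrix, same size as the input; 0 is background.
#'   Labels are sequential and deterministic given image and parameters.
#' @export
detect_nuclei <- function(nuclear, params) {
  x <- get_channel(nuclear, "nuclear")
  stopifnot(is.matrix(x), inherits(params, "segmentation_params"))
  thr <- if (params$nuclear_threshold_method == "fixed") {
    params$fixed_nuclear_threshold
  } else {
    rng <- range(x)
    if (rng[1] == rng[2]) return(matrix(0L, nrow(x), ncol(x)))
    EBImage::otsu(EBImage::Image(x), range = rng, levels = 256L)
  }
  mask <- x > thr
  if (!any(mask)) return(matrix(0L, nrow(x), ncol(x)))
  dm <- EBImage::distmap(EBImage::Image(mask))
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  storage.mode(labels) <- "integer"

  # size filter on equivalent diameter
  px2 <- params$pixel_size_um^2
  if (max(labels) > 0) {
    areas_px <- tabulate(labels[labels > 0], nbins = max(labels))
    eq_diam_um <- 2 * sqrt(areas_px * px2 / pi)
    keep <- which(eq_diam_um >= params$nuclear_diam_um[1] &
                    eq_diam_um <= params$nuclear_diam_um[2])
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  labels
}

label_centroids <- function(labels) {
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  if (length(lab) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  cx <- rowsum(as.numeric(idx[, 1]), lab) / rowsum(rep(1, length(lab)), lab)
  cy <- rowsum(as.numeric(idx[, 2]), lab) / rowsum(rep(1, length(lab)), lab)
  out <- cbind(x = cx[, 1], y = cy[, 1])
  rownames(out) <- rownames(cx)
  out
}

#' Grow cell regions from nuclear seeds into Iba1 staining
#'
#' Each detected nucleus seeds one cell region grown into contiguous
#' Iba1-above-threshold pixels. Pixels reachable from several seeds are
#' assigned to the nearest one (regions stay disjoint). Growth is capped
#' at a radius of half the maximum cell diameter around the nucleus
#' centroid; a cell with no supra-threshold Iba1 beyond its nucleus keeps
#' the nucleus as its whole region.
#'
#' @param nuclei integer nucleus label matrix from [detect_nuclei()].
#' @param iba1 Iba1-channel matrix (or an `if_image`).
#' @param params a [segmentation_params()].
#' @param iba1_threshold calibrated Iba1 intensity threshold.
#' @return integer cell label matrix; labels match the nucleus labels.
#' @export
segment_cells <- function(nuclei, iba1, params, iba1_threshold) {
  x <- get_channel(iba1, "iba1")
  stopifnot(is.matrix(x), is.matrix(nuclei))
  if (!all(dim(x) == dim(nuclei)))
    stop("iba1 channel and nucleus label map have different shapes: ",
         paste(dim(x), collapse = "x"), " vs ",
         paste(dim(nuclei), collapse = "x"))
  if (max(nuclei) == 0) return(matrix(0L, nrow(x), ncol(x)))

  mask <- (x >= iba1_threshold) | (nuclei > 0)
  cells <- EBImage::imageData(EBImage::propagate(
    x = EBImage::Image(x), seeds = EBImage::Image(nuclei),
    mask = EBImage::Image(mask), lambda = 1e4))
  storage.mode(cells) <- "integer"

  # cap each region at max cell radius from its nucleus centroid
  cent <- label_centroids(nuclei)
  max_r_px <- params$cell_diam_um[2] / 2 / params$pixel_size_um
  idx <- which(cells > 0, arr.ind = TRUE)
  lab <- cells[cells > 0]
  ci <- match(as.character(lab), rownames(cent))
  d2 <- (idx[, 1] - cent[ci, "x"])^2 + (idx[, 2] - cent[ci, "y"])^2
  too_far <- d2 > max_r_px^2 & nuclei[idx] == 0L
  if (any(too_far)) cells[idx[too_far, , drop = FALSE]] <- 0L
  cells
}

#' Measure per-cell areas and channel intensities
#'
#' Produces one record per segmented cell: centroid, nucleus and cell area
#' (um^2), mean Iba1 and marker intensity over the cell region, and the
#' stained area (pixels at or above the channel threshold) for each of the
#' two stains. Positivity flags are left unset; see [call_positivity()].
#'
#' @param cells cell label matrix from [segment_cells()].
#' @param nuclei nucleus label matrix from [detect_nuclei()].
#' @param image an `if_image` (channels nuclear / iba1 / marker).
#' @param params a [segmentation_params()].
#' @param iba1_threshold,marker_threshold intensity thresholds used for
#'   the stained-area measurements.
#' @return data.frame of cell records.
#' @export
measure_cells <- function(cells, nuclei, image, params,
                          iba1_threshold, marker_threshold) {
  iba <- get_channel(image, "iba1")
  mrk <- get_channel(image, "marker")
  stopifnot(all(dim(cells) == dim(iba)), all(dim(cells) == dim(nuclei)))
  px2 <- params$pixel_size_um^2
  n <- max(cells)
  if (n == 0) return(empty_cell_records())

  sel <- cells > 0
  lab <- cells[sel]
  idx <- which(sel, arr.ind = TRUE)
  ones <- rep(1, length(lab))

  agg <- function(v) rowsum(v, lab)[, 1]
  npix <- agg(ones)
  ids <- as.integer(names(npix))

  cx <- agg(as.numeric(idx[, 1])) / npix
  cy <- agg(as.numeric(idx[, 2])) / npix
  iba_v <- iba[sel]; mrk_v <- mrk[sel]
  iba_mean <- agg(iba_v) / npix
  mrk_mean <- agg(mrk_v) / npix
  iba_stained <- agg(as.numeric(iba_v >= iba1_threshold))
  mrk_stained <- agg(as.numeric(mrk_v >= marker_threshold))

  nuc_npix <- tabulate(nuclei[nuclei > 0], nbins = max(n, max(nuclei)))

  data.frame(
    cell_id = ids,
    x = cx, y = cy,
    nucleus_area_um2 = nuc_npix[ids] * px2,
    cell_area_um2 = npix * px2,
    iba1_mean_intensity = iba_mean,
    marker_mean_intensity = mrk_mean,
    iba1_stained_area_um2 = iba_stained * px2,
    marker_stained_area_um2 = mrk_stained * px2,
    iba1_positive = NA,
    marker_positive = NA,
    row.names = NULL
  )
}

empty_cell_records <- function() {
  data.frame(cell_id = integer(), x = numeric(), y = numeric(),
             nucleus_area_um2 = numeric(), cell_area_um2 = numeric(),
             iba1_mean_intensity = numeric(), marker_mean_intensity = numeric(),
             iba1_stained_area_um2 = numeric(),
             marker_stained_area_um2 = numeric(),
             iba1_positive = logical(), marker_positive = logical())
}

#' Call per-cell Iba1 and marker positivity
#'
#' A cell is Iba1-positive when its mean Iba1 intensity reaches the Iba1
#' threshold and its Iba1-stained area reaches the minimum stained area.
#' It is marker-positive when it is Iba1-positive and the marker channel
#' passes the same two rules with the marker threshold. Marker positivity
#' is only ever called within Iba1-positive cells.
#'
#' @param records cell records from [measure_cells()].
#' @param iba1_threshold,marker_threshold calibrated intensity thresholds
#'   (see [calibrate_threshold()]).
#' @param params a [segmentation_params()] (supplies the minimum stained
#'   area).
#' @return `records` with `iba1_positive` / `marker_positive` set.
#' @export
call_positivity <- function(records, iba1_threshold, marker_threshold, params) {
  min_area <- params$min_stained_area_um2
  records$iba1_positive <-
    records$iba1_mean_intensity >= iba1_threshold &
    records$iba1_stained_area_um2 >= min_area
  records$marker_positive <-
    records$iba1_positive &
    records$marker_mean_intensity >= marker_threshold &
    records$marker_stained_area_um2 >= min_area
  records
}

#' Segment and measure one site image in a single call
#'
#' Convenience wrapper: nucleus detection, cell segmentation, measurement
#' and positivity calling on one three-channel site image.
#'
#' The region-growing (delineation) threshold and the positivity-scoring
#' thresholds serve different purposes and may differ: growing regions at
#' the scoring threshold would selectively include supra-threshold noise
#' pixels and bias every cell's mean intensity upward. `grow_threshold`
#' should exclude background pixels outright (see
#' [background_grow_threshold()]); the scoring thresholds are calibrated
#' on a no-primary control measured with the same `grow_threshold`.
#'
#' @inheritParams measure_cells
#' @param image an `if_image`.
#' @param grow_threshold Iba1 threshold used to delineate cell regions
#'   (defaults to `iba1_threshold`).
#' @return list with `records` (positivity called), `n_nuclei` (nuclei
#'   passing the size filter), `nuclei` and `cells` label matrices.
#' @export
quantify_image <- function(image, params, iba1_threshold, marker_threshold,
                           grow_threshold = iba1_threshold) {
  nuclei <- detect_nuclei(image$data[, , "nuclear"], params)
  cells <- segment_cells(nuclei, image$data[, , "iba1"], params, grow_threshold)
  rec <- measure_cells(cells, nuclei, image, params,
                       iba1_threshold, marker_threshold)
  rec <- call_positivity(rec, iba1_threshold, marker_threshold, params)
  list(records = rec, n_nuclei = max(nuclei), nuclei = nuclei, cells = cells)
}
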