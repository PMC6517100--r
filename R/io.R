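#' Write a three-channel site image as a multi-page TIFF
#'
#' One 16-bit grayscale page per channel in the order nuclear, Iba1,
#' marker. Channel order and pixel size are recorded in a YAML sidecar
#' (`<path>.yaml`) since baseline TIFF tags cannot carry them.
#'
#' @param image an `if_image` (unit intensity scale, 1.0 = saturation).
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "if_image"))
  pages <- lapply(seq_len(3), function(c) t(image$data[, , c]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(channels = image$channels,
                        pixel_size_um = image$pixel_size_um),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a three-channel site image from a multi-page TIFF
#'
#' Expects exactly three grayscale pages (nuclear, Iba1, marker). Pixel
#' size is taken from the YAML sidecar written by [write_image_tiff()],
#' or from `pixel_size_um` when there is no sidecar.
#'
#' @param path TIFF file path.
#' @param pixel_size_um fallback pixel size when no sidecar exists.
#' @return an `if_image`.
#' @export
read_image_tiff <- function(path, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 3)
    stop("'", path, "' has ", length(pages),
         " page(s); expected 3 channels (nuclear, iba1, marker)")
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    pixel_size_um <- meta$pixel_size_um
    if (!identical(unlist(meta$channels), CHANNEL_NAMES))
      stop("'", path, "' sidecar declares channels (",
           paste(meta$channels, collapse = ", "),
           "); expected nuclear, iba1, marker")
  }
  if (is.null(pixel_size_um))
    stop("pixel size unknown: no sidecar for '", path,
         "' and pixel_size_um not given")
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[2], d[1], 3))
  for (c in seq_len(3)) arr[, , c] <- t(pages[[c]])
  new_if_image(arr, pixel_size_um)
}

#' Read curated gene lists from a GMT file
#'
#' Standard GMT (one list per line: name, description, genes). Duplicate
#' genes within a list are removed on read.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gene_lists <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: '", path, "'")
  lists <- fgsea::gmtPathways(path)
  if (length(lists) == 0) stop("'", path, "': no gene lists")
  lapply(lists, unique)
}

#' Write gene lists as GMT
#'
#' @param lists named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_lists <- function(lists, path) {
  stopifnot(!is.null(names(lists)), all(nzchar(names(lists))))
  lines <- vapply(names(lists), function(n) {
    paste(c(n, "synthetic", unique(lists[[n]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Force the six scored markers into the curated lists
#'
#' The gene-list curation step guarantees that the genes of the six
#' immunofluorescence markers (CD68, HLA-A/-B/-C, TNF for the
#' pro-inflammatory panel; CD163, IL10, TGFB2 for the anti-inflammatory
#' panel) are present after assembly: each panel's genes are appended to
#' the matching polarity list if absent, then lists are deduplicated.
#'
#' @param lists named list with `pro_inflammatory` and `anti_inflammatory`
#'   entries (other lists pass through untouched).
#' @return the augmented list set.
#' @export
augment_gene_lists <- function(lists) {
  stopifnot(all(c("pro_inflammatory", "anti_inflammatory") %in% names(lists)))
  pro_genes <- c("CD68", "HLA-A", "HLA-B", "HLA-C", "TNF")
  anti_genes <- c("CD163", "IL10", "TGFB2")
  lists$pro_inflammatory <- union(lists$pro_inflammatory, pro_genes)
  lists$anti_inflammatory <- union(lists$anti_inflammatory, anti_genes)
  lapply(lists, unique)
}

#' Built-in synthetic curated gene lists
#'
#' A small synthetic stand-in for curated microglia / macrophage /
#' pro-inflammatory / anti-inflammatory gene lists, shipped as
#' `synthetic_gamm_gene_lists.gmt`. Gene symbols are real markers commonly
#' used for these populations, but the membership was assembled for
#' testing, not curated from the literature. The six scored markers are
#' guaranteed present via [augment_gene_lists()].
#'
#' @return named list of four character vectors.
#' @export
example_gene_lists <- function() {
  path <- system.file("extdata", "synthetic_gamm_gene_lists.gmt",
                      package = "gammscope")
  augment_gene_lists(read_gene_lists(path))
}

#' Write / read a log-expression matrix as MTX + TSV
#'
#' MatrixMarket file plus `genes.tsv` and `cells.tsv` in the same
#' directory, the common exchange layout for expression matrices.
#'
#' @param matrix genes x cells matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(matrix, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(matrix), file.path(dir, "genes.tsv"))
  writeLines(colnames(matrix), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_expression
#' @export
read_expression <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx in '", dir, "'")
  m <- as.matrix(Matrix::readMM(mtx))
  if (ncol(m) == 0) stop("'", mtx, "': no cells")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  if (length(genes) != nrow(m))
    stop("'", dir, "': genes.tsv has ", length(genes), " entries for ",
         nrow(m), " matrix rows")
  if (length(cells) != ncol(m))
    stop("'", dir, "': cells.tsv has ", length(cells), " entries for ",
         ncol(m), " matrix columns")
  dimnames(m) <- list(genes, cells)
  m
}

#' Read / write per-tumor cohort tables as CSV
#'
#' UTF-8, comma-separated, header row, missing values as empty fields.
#'
#' @param tumors data.frame to write.
#' @param path CSV path.
#' @return the table (read) or `path` invisibly (write).
#' @export
write_cohort_csv <- function(tumors, path) {
  utils::write.csv(tumors, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort CSV not found: '", path, "'")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("'", path, "': empty cohort table")
  out
}
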