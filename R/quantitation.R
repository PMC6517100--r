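#' GAMM content of a site or section
#'
#' Microglia/macrophage content as a percentage of all cells:
#' `100 * (number of Iba1+ cells) / (total nuclei)`.
#'
#' @param records cell records with positivity called.
#' @param total_nuclei total number of nuclei passing the size filter in
#'   kept sites (defaults to the number of records). Must be at least the
#'   number of records.
#' @return content in percent.
#' @export
compute_content <- function(records, total_nuclei = nrow(records)) {
  if (total_nuclei == 0) stop("no cells: total_nuclei is 0")
  stopifnot(total_nuclei >= nrow(records))
  100 * sum(records$iba1_positive) / total_nuclei
}

#' Marker frequency within Iba1-positive cells
#'
#' Frequency of an inflammatory marker within GAMMs:
#' `100 * (marker and Iba1 double-positive cells) / (Iba1+ cells)`.
#' With zero Iba1+ cells the ratio is undefined; `NA` is returned with a
#' warning so the tumor drops out of that marker's statistics rather than
#' biasing them towards 0.
#'
#' @param records cell records with positivity called.
#' @return marker frequency in percent, or `NA`.
#' @export
compute_marker_frequency <- function(records) {
  n_iba1 <- sum(records$iba1_positive)
  if (n_iba1 == 0) {
    warning("no Iba1+ cells: marker frequency undefined")
    return(NA_real_)
  }
  100 * sum(records$marker_positive) / n_iba1
}

#' Aggregate per-section values into a per-tumor summary
#'
#' Arithmetic mean and sample SD across consecutive sections of one tumor
#' (three sections in the reference protocol). With a single section the
#' SD is undefined and reported as 0 with `single_section = TRUE`.
#'
#' @param sections data.frame (or named list coercible to one) with one
#'   row per section and one numeric column per measured field.
#' @return list with `mean` and `sd` (named numeric vectors),
#'   `n_sections`, and `single_section` flag.
#' @export
summarize_tumor <- function(sections) {
  sections <- as.data.frame(sections)
  stopifnot(nrow(sections) >= 1)
  m <- vapply(sections, mean, numeric(1))
  s <- if (nrow(sections) == 1) {
    stats::setNames(rep(0, ncol(sections)), names(sections))
  } else {
    vapply(sections, stats::sd, numeric(1))
  }
  list(mean = m, sd = s, n_sections = nrow(sections),
       single_section = nrow(sections) == 1)
}

#' Correlate flow-cytometry and immunofluorescence content estimates
#'
#' Pearson product-moment correlation (two-tailed) between the two
#' modalities' per-tumor GAMM content estimates.
#'
#' @param flow_pct,if_content_pct paired per-tumor percentages, no missing
#'   values, at least 3 pairs.
#' @return list with `r`, `p` and `n`.
#' @export
correlate_modalities <- function(flow_pct, if_content_pct) {
  stopifnot(length(flow_pct) == length(if_content_pct))
  if (length(flow_pct) < 3) stop("need at least 3 paired tumors")
  if (anyNA(flow_pct) || anyNA(if_content_pct))
    stop("missing values in paired content estimates")
  if (stats::sd(flow_pct) == 0 || stats::sd(if_content_pct) == 0)
    stop("zero variance: constant content vector")
  ct <- stats::cor.test(flow_pct, if_content_pct, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(flow_pct))
}
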