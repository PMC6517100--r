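#' Inflammatory profile of one tumor
#'
#' Pro- minus anti-inflammatory marker frequency: the mean of the three
#' pro-inflammatory marker frequencies (CD68, HLA-A/-B/-C, TNF) minus the
#' mean of the three anti-inflammatory ones (CD163, IL10, TGFB2), in
#' percentage points (range -100 to 100). Using means rather than sums
#' keeps the profile on an interpretable scale; the downstream min-max
#' scaling makes the two choices equivalent.
#'
#' @param marker_freq_pct named numeric vector (or one-row data.frame)
#'   with all six marker frequencies in percent.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @param pro,anti the pro- and anti-inflammatory panels to aggregate;
#'   default the canonical three markers each. Runs that stained only a
#'   subset may pass reduced panels (at least one marker per side).
#' @return the inflammatory profile.
#' @export
inflammatory_profile <- function(marker_freq_pct, aggregate = c("mean", "sum"),
                                 pro = PRO_MARKERS, anti = ANTI_MARKERS) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(pro) >= 1, length(anti) >= 1,
            all(pro %in% PRO_MARKERS), all(anti %in% ANTI_MARKERS))
  v <- unlist(marker_freq_pct)
  need <- c(pro, anti)
  if (!all(need %in% names(v)))
    stop("missing marker frequencies: ",
         paste(setdiff(need, names(v)), collapse = ", "))
  if (anyNA(v[need]))
    stop("missing marker frequencies: ",
         paste(need[is.na(v[need])], collapse = ", "))
  f <- if (aggregate == "mean") mean else sum
  f(v[pro]) - f(v[anti])
}

#' Min-max scale a cohort measurement to 0-100
#'
#' Linear rescaling that maps the cohort minimum to 0 and the cohort
#' maximum to 100: `100 * (v - min) / (max - min)`.
#'
#' @param values numeric vector with at least two distinct values.
#' @return rescaled values in `[0, 100]`.
#' @export
minmax_scale <- function(values) {
  stopifnot(!anyNA(values))
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("degenerate scale: all values equal (", rng[1], ")")
  # ratio first: the extremes then map to exactly 0 and 100 in floating point
  ((values - rng[1]) / (rng[2] - rng[1])) * 100
}

#' Composite pro-inflammatory activation score
#'
#' The three activation indicators chosen a priori — inflammatory profile,
#' Iba1 intensity, and mean cell surface area — are each min-max scaled to
#' 0-100 across the whole cohort (both genotypes pooled) and summed into a
#' score in 0-300 "pro-inflammatory units". Tumors are then dichotomized
#' at the cohort median (ties and the median itself go to the low group).
#'
#' Tumors missing any marker frequency are excluded from scoring and
#' listed in the `excluded` attribute of the result.
#'
#' @param summaries data.frame with one row per tumor and columns
#'   `tumor_id`, `genotype`, the six marker frequencies, `iba1_intensity`,
#'   an area column (`area_um2` or `mean_area_um2`), and optionally
#'   `survival_days` and `lost_to_followup`.
#' @param aggregate profile aggregation, `"mean"` or `"sum"`.
#' @inheritParams inflammatory_profile
#' @return a `score_table` data.frame with the raw profile, the three
#'   scaled components, the composite `score`, and the median-split
#'   `group`.
#' @export
composite_score <- function(summaries, aggregate = c("mean", "sum"),
                            pro = PRO_MARKERS, anti = ANTI_MARKERS) {
  aggregate <- match.arg(aggregate)
  markers <- c(pro, anti)
  stopifnot(nrow(summaries) >= 2,
            all(c("tumor_id", "iba1_intensity") %in% names(summaries)),
            all(markers %in% names(summaries)))
  area_col <- intersect(c("area_um2", "mean_area_um2"), names(summaries))[1]
  if (is.na(area_col)) stop("no area column (area_um2 or mean_area_um2)")

  complete <- stats::complete.cases(summaries[, c(markers,
                                                  "iba1_intensity", area_col)])
  excluded <- summaries$tumor_id[!complete]
  if (length(excluded) > 0)
    message("excluded from scoring (incomplete fields): ",
            paste(excluded, collapse = ", "))
  s <- summaries[complete, , drop = FALSE]
  if (nrow(s) < 2) stop("fewer than 2 tumors with complete fields")

  profile <- apply(s[, markers, drop = FALSE], 1, inflammatory_profile,
                   aggregate = aggregate, pro = pro, anti = anti)
  scaled_profile <- minmax_scale(profile)
  scaled_intensity <- minmax_scale(s$iba1_intensity)
  scaled_area <- minmax_scale(s[[area_col]])
  score <- scaled_profile + scaled_intensity + scaled_area

  out <- data.frame(
    tumor_id = s$tumor_id,
    genotype = if ("genotype" %in% names(s)) s$genotype else NA_character_,
    inflammatory_profile = profile,
    scaled_profile = scaled_profile,
    scaled_intensity = scaled_intensity,
    scaled_area = scaled_area,
    score = score,
    group = median_split(score),
    survival_days = if ("survival_days" %in% names(s)) s$survival_days
    else NA_real_,
    lost_to_followup = if ("lost_to_followup" %in% names(s))
      s$lost_to_followup else FALSE,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_table", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

#' Median split of composite scores
#'
#' Scores strictly above the cohort median go to the `high` group; scores
#' at or below it to `low`. Assigning the median itself (odd cohorts) and
#' ties to the low group is deterministic and conservative for the claim
#' that high scorers survive longer. When all scores are equal every tumor
#' is `low` and a warning is raised.
#'
#' @param scores numeric vector of composite scores (>= 2 values).
#' @return character vector `"high"` / `"low"`.
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 2, !anyNA(scores))
  med <- stats::median(scores)
  if (all(scores == med)) {
    warning("all scores equal: every tumor assigned to the low group")
    return(rep("low", length(scores)))
  }
  ifelse(scores > med, "high", "low")
}

#' Compare overall survival between median-split groups
#'
#' Excludes lost-to-follow-up tumors, then compares survival (days) of the
#' high- vs low-score groups with a two-tailed Student's t-test.
#'
#' @param scores a `score_table` from [composite_score()].
#' @param var_equal equal-variance Student's t (default, matching the
#'   reference analysis); `FALSE` for Welch.
#' @return list with per-group means, SDs, sizes and the p-value.
#' @export
compare_survival <- function(scores, var_equal = TRUE) {
  s <- scores[!scores$lost_to_followup & !is.na(scores$survival_days), ,
              drop = FALSE]
  hi <- s$survival_days[s$group == "high"]
  lo <- s$survival_days[s$group == "low"]
  if (length(hi) < 2 || length(lo) < 2)
    stop("each median-split group needs >= 2 tumors with survival ",
         "(high: ", length(hi), ", low: ", length(lo), ")")
  cmp <- compare_groups(hi, lo, var_equal = var_equal)
  list(mean_high = cmp$mean_a, sd_high = cmp$sd_a, n_high = length(hi),
       mean_low = cmp$mean_b, sd_low = cmp$sd_b, n_low = length(lo),
       p = cmp$p)
}

#' Two-group comparison by two-tailed Student's t-test
#'
#' Used for every wild-type vs mutant comparison (content, each marker,
#' intensity, area, composite score) and the survival comparison. Returns
#' group means and sample SDs alongside the two-tailed p-value. When both
#' groups are constant and equal, p is 1 by convention (no evidence of
#' difference; the t statistic is 0/0).
#'
#' @param values_a,values_b numeric vectors, each with >= 2 values.
#' @param var_equal equal-variance Student's t (default) or Welch.
#' @return list with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `p`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("insufficient n: each group needs >= 2 values")
  out <- list(mean_a = mean(values_a), sd_a = stats::sd(values_a),
              mean_b = mean(values_b), sd_b = stats::sd(values_b))
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    out$p <- if (out$mean_a == out$mean_b) 1 else 0
  } else {
    out$p <- stats::t.test(values_a, values_b, var.equal = var_equal,
                           alternative = "two.sided")$p.value
  }
  out
}

#' Wild-type vs mutant comparison across measured fields
#'
#' Runs [compare_groups()] for each requested field of a per-tumor table,
#' optionally applying a Holm correction across the fields (off by
#' default: each marker is tested at the nominal level, as in the
#' reference analysis).
#'
#' @param tumors data.frame with a `genotype` column (`IDH_WT` /
#'   `IDH_MUT`) and the fields to compare.
#' @param fields character vector of column names.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @param var_equal passed to [compare_groups()].
#' @return data.frame with per-field WT / MUT means, SDs and p-values.
#' @export
wt_mut_comparison <- function(tumors, fields = c("if_content_pct", ALL_MARKERS,
                                                 "iba1_intensity", "area_um2"),
                              p_adjust = c("none", "holm"), var_equal = TRUE) {
  p_adjust <- match.arg(p_adjust)
  stopifnot("genotype" %in% names(tumors), all(fields %in% names(tumors)))
  wt <- tumors$genotype == "IDH_WT"
  rows <- lapply(fields, function(f) {
    ok <- !is.na(tumors[[f]])
    cmp <- compare_groups(tumors[[f]][wt & ok], tumors[[f]][!wt & ok],
                          var_equal = var_equal)
    data.frame(field = f, wt_mean = cmp$mean_a, wt_sd = cmp$sd_a,
               mut_mean = cmp$mean_b, mut_sd = cmp$sd_b, p = cmp$p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  out
}
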