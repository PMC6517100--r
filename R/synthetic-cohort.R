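#' Marker panels
#'
#' The six inflammatory markers scored in GAMMs: three pro-inflammatory
#' (CD68 phagocytosis, HLA-A/-B/-C antigen presentation, TNF) and three
#' anti-inflammatory (CD163, IL10, TGFB2).
#' @export
PRO_MARKERS <- c("CD68", "HLA_ABC", "TNF")

#' @rdname PRO_MARKERS
#' @export
ANTI_MARKERS <- c("CD163", "IL10", "TGFB2")

#' @rdname PRO_MARKERS
#' @export
ALL_MARKERS <- c(PRO_MARKERS, ANTI_MARKERS)

default_marker_params <- function() {
  data.frame(
    marker   = ALL_MARKERS,
    wt_mean  = c(51.2, 66.4, 19.7, 48.4, 38.4, 35.4),
    wt_sd    = c(9.4, 6.9, 6.1, 8.9, 8.7, 9.7),
    mut_mean = c(23.1, 55.0, 39.4, 21.6, 29.6, 44.5),
    mut_sd   = c(8.2, 13.8, 6.6, 9.9, 13.3, 11.3)
  )
}

#' Configuration of a synthetic GBM cohort
#'
#' Per-genotype (IDH-wild type vs IDH-mutant) means and SDs of the
#' quantities the imaging pipeline measures: GAMM content (% Iba1+ of all
#' nuclei), the six marker frequencies (% of Iba1+ cells), mean Iba1
#' intensity (relative fluorescence units) and mean cell area (um^2).
#' Defaults are the cohort-level values reported for 9 wild-type and 4
#' mutant glioblastomas: mutants have far fewer GAMMs but higher TNF,
#' Iba1 intensity and cell area.
#'
#' A flow-cytometry GAMM percentage is generated as the immunofluorescence
#' content plus Gaussian error, with the error SD chosen so the population
#' flow-vs-IF Pearson correlation equals `flow_r`.
#'
#' Survival is a linear function of the tumor's (unscaled) activation
#' latent — inflammatory profile + Iba1 intensity + area — plus Gaussian
#' noise, floored at 1 day:
#' `survival_days = baseline_days + effect_per_score_unit * latent + noise`.
#'
#' @param n_wt,n_mut number of wild-type / mutant tumors (n_wt + n_mut >= 4).
#' @param marker_params data.frame with columns marker, wt_mean, wt_sd,
#'   mut_mean, mut_sd for the six markers (percent scale).
#' @param content_wt,content_mut,iba1_wt,iba1_mut,area_wt,area_mut
#'   length-2 `(mean, sd)` vectors for content %, Iba1 intensity and area.
#' @param flow_r target population Pearson correlation between the
#'   flow-cytometry and immunofluorescence content estimates.
#' @param baseline_days,effect_per_score_unit,noise_sd_days survival model.
#' @param frac_lost_to_followup fraction of tumors flagged lost to
#'   follow-up (their survival is excluded from survival comparisons).
#' @param marker_cor common correlation between the six markers'
#'   within-tumor deviations; 0 (default) draws them independently.
#' @param seed integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_wt = 9L, n_mut = 4L,
                          marker_params = default_marker_params(),
                          content_wt = c(37.2, 7.3), content_mut = c(4.9, 1.4),
                          iba1_wt = c(60.0, 19.4), iba1_mut = c(112.7, 23.5),
                          area_wt = c(40.5, 3.6), area_mut = c(53.3, 8.9),
                          flow_r = 0.73,
                          baseline_days = -200, effect_per_score_unit = 6,
                          noise_sd_days = 150,
                          frac_lost_to_followup = 1 / 13,
                          marker_cor = 0, seed = 1L) {
  cfg <- list(n_wt = as.integer(n_wt), n_mut = as.integer(n_mut),
              marker_params = marker_params,
              content_wt = content_wt, content_mut = content_mut,
              iba1_wt = iba1_wt, iba1_mut = iba1_mut,
              area_wt = area_wt, area_mut = area_mut,
              flow_r = flow_r, baseline_days = baseline_days,
              effect_per_score_unit = effect_per_score_unit,
              noise_sd_days = noise_sd_days,
              frac_lost_to_followup = frac_lost_to_followup,
              marker_cor = marker_cor, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_wt >= 1, cfg$n_mut >= 1, cfg$n_wt + cfg$n_mut >= 4,
    identical(sort(cfg$marker_params$marker), sort(ALL_MARKERS)),
    all(cfg$marker_params$wt_mean >= 0), all(cfg$marker_params$wt_mean <= 100),
    all(cfg$marker_params$mut_mean >= 0), all(cfg$marker_params$mut_mean <= 100),
    cfg$flow_r > 0, cfg$flow_r <= 1,
    cfg$frac_lost_to_followup >= 0, cfg$frac_lost_to_followup <= 1,
    cfg$marker_cor >= 0, cfg$marker_cor < 1,
    cfg$noise_sd_days >= 0
  )
  invisible(cfg)
}

clip01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# Equicorrelated normal deviations: z_ij = sqrt(rho) * shared_i + sqrt(1-rho) * own_ij
rmarker_dev <- function(n, k, rho) {
  shared <- stats::rnorm(n)
  own <- matrix(stats::rnorm(n * k), n, k)
  sqrt(rho) * shared + sqrt(1 - rho) * own
}

#' Generate a synthetic per-tumor cohort table
#'
#' One row per tumor, carrying the *true* underlying measurements the
#' imaging pipeline would estimate: genotype, the six marker frequencies
#' (clipped to 0-100%), Iba1 intensity, mean cell area, immunofluorescence
#' GAMM content, a flow-cytometry content estimate correlated with it,
#' the activation latent, survival days and a lost-to-follow-up flag.
#'
#' @param config a [cohort_config()].
#' @return a data.frame of class `cohort_table`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_wt + config$n_mut
  genotype <- c(rep("IDH_WT", config$n_wt), rep("IDH_MUT", config$n_mut))
  mp <- config$marker_params
  mp <- mp[match(ALL_MARKERS, mp$marker), ]

  dev <- rmarker_dev(n, length(ALL_MARKERS), config$marker_cor)
  freqs <- matrix(NA_real_, n, length(ALL_MARKERS),
                  dimnames = list(NULL, ALL_MARKERS))
  for (j in seq_along(ALL_MARKERS)) {
    mu <- ifelse(genotype == "IDH_WT", mp$wt_mean[j], mp$mut_mean[j])
    sd <- ifelse(genotype == "IDH_WT", mp$wt_sd[j], mp$mut_sd[j])
    freqs[, j] <- clip01(mu + sd * dev[, j])
  }

  draw <- function(par_wt, par_mut, lo = 0, hi = Inf) {
    mu <- ifelse(genotype == "IDH_WT", par_wt[1], par_mut[1])
    sd <- ifelse(genotype == "IDH_WT", par_wt[2], par_mut[2])
    pmin(pmax(stats::rnorm(n, mu, sd), lo), hi)
  }
  content <- draw(config$content_wt, config$content_mut, 0, 100)
  iba1 <- draw(config$iba1_wt, config$iba1_mut, 0)
  area <- draw(config$area_wt, config$area_mut, 0)

  # error SD giving the target population flow-vs-IF correlation for the
  # genotype mixture (law of total variance)
  p_wt <- config$n_wt / n
  mix_mean <- p_wt * config$content_wt[1] + (1 - p_wt) * config$content_mut[1]
  mix_var <- p_wt * config$content_wt[2]^2 + (1 - p_wt) * config$content_mut[2]^2 +
    p_wt * (config$content_wt[1] - mix_mean)^2 +
    (1 - p_wt) * (config$content_mut[1] - mix_mean)^2
  flow_err_sd <- sqrt(mix_var) * sqrt(1 / config$flow_r^2 - 1)
  flow <- clip01(content + stats::rnorm(n, 0, flow_err_sd))

  profile <- rowMeans(freqs[, PRO_MARKERS, drop = FALSE]) -
    rowMeans(freqs[, ANTI_MARKERS, drop = FALSE])
  latent <- profile + iba1 + area
  survival <- pmax(1, config$baseline_days +
                     config$effect_per_score_unit * latent +
                     stats::rnorm(n, 0, config$noise_sd_days))
  lost <- stats::runif(n) < config$frac_lost_to_followup

  out <- data.frame(
    tumor_id = sprintf("T%02d", seq_len(n)),
    genotype = genotype,
    freqs,
    iba1_intensity = iba1,
    area_um2 = area,
    if_content_pct = content,
    flow_content_pct = flow,
    activation_latent = latent,
    survival_days = survival,
    lost_to_followup = lost,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_table", "data.frame")
  out
}
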