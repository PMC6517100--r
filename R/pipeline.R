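#' Pipeline run configuration
#'
#' Bundles every knob of a full run: simulation settings (or input paths),
#' segmentation parameters, site QC rules, scoring and enrichment options,
#' the master seed and the output directory. Every source of randomness in
#' a run flows from `seed`.
#'
#' @param output_dir directory for all outputs (created if needed).
#' @param seed master integer seed.
#' @param simulate generate the cohort, images and expression matrix
#'   in-run (`TRUE`, default) instead of reading them from paths.
#' @param cohort a [cohort_config()]; default `cohort_config(seed = seed)`.
#' @param image an [image_spec()] template for simulated sites; per-tumor
#'   content, marker frequency, intensity and cell size are filled in from
#'   the cohort row, and seeds are derived per tumor/marker/section.
#' @param n_sections consecutive sections imaged per tumor (default 3).
#' @param markers inflammatory markers to stain/score (default all six).
#' @param cohort_csv,images_manifest input paths for `simulate = FALSE`:
#'   the per-tumor table and a CSV with columns tumor_id, marker, section,
#'   image, control (TIFF paths).
#' @param expression an [expr_config()] for the simulated expression
#'   matrix, or `NULL` to skip enrichment in simulate mode.
#' @param expression_dir MTX directory for `simulate = FALSE`.
#' @param gmt GMT path of curated gene lists; `NULL` uses the packaged
#'   synthetic lists in simulate mode, and skips enrichment otherwise.
#' @param segmentation a [segmentation_params()].
#' @param qc a [site_qc_rules()]; a `min_focus_metric` of 0 is replaced at
#'   run time by [default_focus_cutoff()] over the run's sites.
#' @param scoring list: `aggregate` ("mean"/"sum"), `var_equal`,
#'   `p_adjust` ("none"/"holm").
#' @param enrichment list: `n_clusters`, `fdr_cut`, `min_fc`,
#'   `fdr_threshold`.
#' @param write_images also write every simulated site as TIFF.
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L, simulate = TRUE,
                       cohort = NULL, image = NULL, n_sections = 3L,
                       markers = ALL_MARKERS,
                       cohort_csv = NULL, images_manifest = NULL,
                       expression = NULL, expression_dir = NULL, gmt = NULL,
                       segmentation = segmentation_params(),
                       qc = site_qc_rules(),
                       scoring = list(aggregate = "mean", var_equal = TRUE,
                                      p_adjust = "none"),
                       enrichment = list(n_clusters = 7L, fdr_cut = 1e-20,
                                         min_fc = 2, fdr_threshold = 0.05),
                       write_images = FALSE) {
  seed <- as.integer(seed)
  if (simulate && is.null(cohort)) cohort <- cohort_config(seed = seed)
  if (simulate && is.null(image)) image <- image_spec(seed = seed)
  # in simulate mode the tree is cut at the number of planted clusters
  # unless the caller overrides it
  if (simulate && !is.null(expression) && missing(enrichment))
    enrichment$n_clusters <- expression$n_clusters
  cfg <- list(output_dir = output_dir, seed = seed, simulate = simulate,
              cohort = cohort, image = image,
              n_sections = as.integer(n_sections), markers = markers,
              cohort_csv = cohort_csv, images_manifest = images_manifest,
              expression = expression, expression_dir = expression_dir,
              gmt = gmt, segmentation = segmentation, qc = qc,
              scoring = scoring, enrichment = enrichment,
              write_images = write_images)
  stopifnot(all(markers %in% ALL_MARKERS), cfg$n_sections >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Nested sections `cohort`, `image`, `segmentation`, `qc`, `expression`
#' are passed to the matching constructors; everything else maps directly
#' onto [run_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("cohort", "image", "segmentation", "qc", "expression")) {
    if (!is.null(y[[nm]])) {
      ctor <- switch(nm, cohort = cohort_config, image = image_spec,
                     segmentation = segmentation_params, qc = site_qc_rules,
                     expression = expr_config)
      y[[nm]] <- do.call(ctor, y[[nm]])
    }
  }
  do.call(run_config, y)
}

# deterministic per-(tumor, marker, section) seed derived from the master
# seed; stays within 32-bit integer range
derive_seed <- function(seed, i, j = 0L, k = 0L) {
  as.integer((abs(seed) * 1009 + i * 10007 + j * 101 + k) %% 2147483646 + 1)
}

# Image spec for one simulated tumor/marker/section, derived from the
# tumor's true measurements. Simulated somata live on a physical scale
# above the largest nucleus (so every soma envelops its nucleus and clears
# the minimum-stained-area rule); the tumor's nominal mean area maps onto
# the soma diameter monotonically, which is all the min-max-scaled score
# downstream requires.
tumor_image_spec <- function(template, tumor, marker, seed) {
  diam <- 2 * sqrt(tumor$area_um2 / pi)
  soma <- template$nuclear_diam_um[2] + 0.5 + 2 * pmax(0, diam - 7)
  spec <- template
  spec$frac_iba1 <- tumor$if_content_pct / 100
  spec$marker_pos_frac <- tumor[[marker]] / 100
  spec$signal_level <- max(tumor$iba1_intensity / 255,
                           template$background_level * 2)
  spec$cell_diam_um <- c(0.95, 1.05) * soma
  spec$seed <- seed
  validate_image_spec(spec)
  spec
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> segmentation -> threshold
#' calibration and site QC -> per-tumor quantitation -> composite scoring
#' and median-split survival -> flow-vs-IF correlation -> gene-list
#' enrichment, writing per-cell records, the tumor summary, the score
#' table, enrichment results, an exclusion log, and a JSON run manifest
#' under `config$output_dir`. Any stage error aborts the run with the
#' stage name. Reruns with the same config and seed are byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the cohort, tumor summary, score table,
#'   comparisons, survival and correlation results, enrichment table and
#'   exclusion log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("cohort", {
    if (config$simulate) generate_cohort(config$cohort)
    else read_cohort_csv(config$cohort_csv)
  })

  imaging <- stage("imaging", {
    if (config$simulate) simulate_imaging_inputs(config, cohort)
    else load_imaging_inputs(config)
  })

  quant <- stage("quantitation", quantify_cohort(config, imaging, cohort))

  summary_df <- quant$summary
  pro_panel <- intersect(PRO_MARKERS, config$markers)
  anti_panel <- intersect(ANTI_MARKERS, config$markers)
  score_tab <- stage("scoring", {
    composite_score(summary_df, aggregate = config$scoring$aggregate,
                    pro = pro_panel, anti = anti_panel)
  })
  surv <- stage("survival", {
    tryCatch(compare_survival(score_tab, var_equal = config$scoring$var_equal),
             error = function(e) {
               warning("survival comparison skipped: ", conditionMessage(e))
               NULL
             })
  })
  corr <- stage("correlation", {
    if ("flow_content_pct" %in% names(summary_df) &&
        !anyNA(summary_df$flow_content_pct)) {
      correlate_modalities(summary_df$flow_content_pct,
                           summary_df$content_pct)
    } else NULL
  })
  comparisons <- stage("comparisons", {
    wt_mut_comparison(summary_df,
                      fields = c("content_pct", config$markers,
                                 "iba1_intensity", "mean_area_um2"),
                      p_adjust = config$scoring$p_adjust,
                      var_equal = config$scoring$var_equal)
  })

  enr <- stage("enrichment", run_enrichment(config))

  stage("write", {
    out <- function(f) file.path(config$output_dir, f)
    write_cohort_csv(quant$cells, out("cell_records.csv"))
    write_cohort_csv(summary_df, out("tumor_summary.csv"))
    write_cohort_csv(as.data.frame(score_tab), out("score_table.csv"))
    write_cohort_csv(quant$exclusion_log, out("site_exclusions.csv"))
    write_cohort_csv(comparisons, out("wt_mut_comparisons.csv"))
    if (!is.null(enr))
      write_cohort_csv(as.data.frame(enr$enrichments), out("enrichment.csv"))
    cfg_yaml <- out("config.yaml")
    yaml::write_yaml(serializable_config(config), cfg_yaml)
    manifest <- list(
      package = "gammscope",
      package_version = as.character(utils::packageVersion("gammscope")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_yaml)),
      outputs = c("cell_records.csv", "tumor_summary.csv", "score_table.csv",
                  "site_exclusions.csv", "wt_mut_comparisons.csv",
                  if (!is.null(enr)) "enrichment.csv")
    )
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  })

  invisible(list(cohort = cohort, summary = summary_df, scores = score_tab,
                 survival = surv, correlation = corr,
                 comparisons = comparisons, enrichment = enr,
                 cells = quant$cells, exclusion_log = quant$exclusion_log))
}

# Cluster the expression matrix, detect per-cluster upregulated genes,
# enrich against the curated lists and designate each cluster. Returns
# NULL (with a warning) when inputs are missing so the other stages can
# complete.
run_enrichment <- function(config) {
  lists <- if (!is.null(config$gmt)) {
    if (!file.exists(config$gmt)) {
      warning("enrichment skipped: GMT file not found ('", config$gmt, "')")
      return(NULL)
    }
    augment_gene_lists(read_gene_lists(config$gmt))
  } else if (config$simulate) {
    example_gene_lists()
  } else {
    warning("enrichment skipped: no GMT file configured")
    return(NULL)
  }

  if (config$simulate) {
    if (is.null(config$expression)) {
      warning("enrichment skipped: no expression configuration")
      return(NULL)
    }
    sim <- generate_expression_matrix(config$expression, lists)
    mat <- sim$matrix
    truth <- sim$truth
  } else {
    if (is.null(config$expression_dir)) {
      warning("enrichment skipped: no expression matrix configured")
      return(NULL)
    }
    mat <- read_expression(config$expression_dir)
    truth <- NULL
  }

  k <- config$enrichment$n_clusters
  labels <- cluster_cells(mat, k)
  ups <- lapply(seq_len(k), function(cl)
    find_upregulated(mat, labels, cl, fdr_cut = config$enrichment$fdr_cut,
                     min_fc = config$enrichment$min_fc))
  universe <- ups[[1]]$universe
  gene_sets <- stats::setNames(lapply(ups, `[[`, "genes"),
                               paste0("cluster", seq_len(k)))
  enr <- enrich_all(gene_sets, lists, universe)
  designations <- vapply(paste0("cluster", seq_len(k)), function(cl)
    label_cluster(enr[enr$cluster == cl, ],
                  fdr_threshold = config$enrichment$fdr_threshold),
    character(1))
  list(enrichments = enr,
       designations = data.frame(cluster = names(designations),
                                 designation = unname(designations),
                                 stringsAsFactors = FALSE),
       cluster_labels = labels, truth = truth)
}

# strip non-scalar members so the config can round-trip through YAML for
# hashing and the manifest
serializable_config <- function(config) {
  strip <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x) || !is.list(x)) return(unclass(x))
    lapply(unclass(x), strip)
  }
  strip(config)
}

# Generate per-tumor/marker/section images and matched controls. Returns a
# flat list of units: tumor_id, marker, section, image, plus per-(tumor,
# marker) calibration controls.
simulate_imaging_inputs <- function(config, cohort) {
  units <- list()
  for (i in seq_len(nrow(cohort))) {
    tumor <- cohort[i, ]
    for (j in seq_along(config$markers)) {
      m <- config$markers[j]
      for (s in seq_len(config$n_sections)) {
        sd_ <- derive_seed(config$seed, i, j, s)
        spec <- tumor_image_spec(config$image, tumor, m, sd_)
        gen <- generate_if_image(spec)
        unit <- list(tumor_id = tumor$tumor_id, marker = m, section = s,
                     image = gen$image, truth = gen$truth, spec = spec)
        if (s == 1) {
          unit$control_marker <- generate_no_primary_control(spec)
          unit$control_iba1 <- generate_no_primary_control(
            spec, channels = c("iba1", "marker"))
        }
        if (config$write_images) {
          img_dir <- file.path(config$output_dir, "images")
          dir.create(img_dir, showWarnings = FALSE)
          write_image_tiff(gen$image, file.path(
            img_dir, sprintf("%s_%s_s%d.tif", tumor$tumor_id, m, s)))
        }
        units[[length(units) + 1]] <- unit
      }
    }
  }
  units
}

load_imaging_inputs <- function(config) {
  man <- read_cohort_csv(config$images_manifest)
  need <- c("tumor_id", "marker", "section", "image", "control",
            "control_iba1")
  stopifnot(all(need %in% names(man)))
  given <- function(x) !is.na(x) && nzchar(x)
  lapply(seq_len(nrow(man)), function(i) {
    unit <- list(tumor_id = man$tumor_id[i], marker = man$marker[i],
                 section = man$section[i],
                 image = read_image_tiff(man$image[i]))
    if (given(man$control[i]))
      unit$control_marker <- read_image_tiff(man$control[i])
    if (given(man$control_iba1[i]))
      unit$control_iba1 <- read_image_tiff(man$control_iba1[i])
    unit
  })
}

# Segment, QC-filter and measure every imaging unit; aggregate per tumor.
quantify_cohort <- function(config, units, cohort) {
  params <- config$segmentation

  # site QC first so the focus cutoff can be set run-wide
  stats_df <- do.call(rbind, lapply(seq_along(units), function(i) {
    st <- site_qc_stats(units[[i]]$image)
    st$site_id <- sprintf("%s_%s_s%d", units[[i]]$tumor_id,
                          units[[i]]$marker, units[[i]]$section)
    st$unit <- i
    st
  }))
  rules <- config$qc
  if (rules$min_focus_metric == 0)
    rules$min_focus_metric <- default_focus_cutoff(stats_df$focus)
  filt <- filter_sites(stats_df, rules)
  kept_units <- stats_df$unit[stats_df$site_id %in% filt$kept]

  # per-(tumor, marker) thresholds from the no-primary controls
  thresholds <- list()
  for (u in units) {
    if (is.null(u$control_marker)) next
    key <- paste(u$tumor_id, u$marker, sep = "|")
    if (is.null(u$control_iba1))
      stop("missing Iba1-blanked control for ", key)
    cal <- calibrate_site_thresholds(u$control_iba1, u$control_marker, params)
    thresholds[[key]] <- list(grow = cal$grow, iba1 = cal$iba1$threshold,
                              marker = cal$marker$threshold)
  }

  all_cells <- list()
  section_rows <- list()
  for (i in kept_units) {
    u <- units[[i]]
    key <- paste(u$tumor_id, u$marker, sep = "|")
    thr <- thresholds[[key]]
    if (is.null(thr)) stop("no calibration control for ", key)
    q <- quantify_image(u$image, params, thr$iba1, thr$marker,
                        grow_threshold = thr$grow)
    rec <- q$records
    if (nrow(rec) > 0) {
      rec$tumor_id <- u$tumor_id; rec$marker <- u$marker
      rec$section <- u$section
      all_cells[[length(all_cells) + 1]] <- rec
    }
    iba1_rec <- rec[rec$iba1_positive, , drop = FALSE]
    section_rows[[length(section_rows) + 1]] <- data.frame(
      tumor_id = u$tumor_id, marker = u$marker, section = u$section,
      content_pct = compute_content(rec, q$n_nuclei),
      marker_freq_pct = suppressWarnings(compute_marker_frequency(rec)),
      iba1_intensity = if (nrow(iba1_rec) > 0)
        mean(iba1_rec$iba1_mean_intensity) * 255 else NA_real_,
      mean_area_um2 = if (nrow(iba1_rec) > 0)
        mean(iba1_rec$cell_area_um2) else NA_real_
    )
  }
  sections <- do.call(rbind, section_rows)

  tumor_ids <- unique(vapply(units, function(u) u$tumor_id, character(1)))
  summary_df <- do.call(rbind, lapply(tumor_ids, function(tid) {
    st <- sections[sections$tumor_id == tid, , drop = FALSE]
    if (nrow(st) == 0)
      stop("every site of tumor ", tid, " was excluded by QC")
    base <- summarize_tumor(st[stats::complete.cases(
      st[, c("content_pct", "iba1_intensity", "mean_area_um2")]),
      c("content_pct", "iba1_intensity", "mean_area_um2"), drop = FALSE])
    row <- data.frame(tumor_id = tid,
                      content_pct = unname(base$mean["content_pct"]),
                      content_sd = unname(base$sd["content_pct"]),
                      iba1_intensity = unname(base$mean["iba1_intensity"]),
                      mean_area_um2 = unname(base$mean["mean_area_um2"]),
                      n_sections = base$n_sections,
                      stringsAsFactors = FALSE)
    for (m in config$markers) {
      v <- st$marker_freq_pct[st$marker == m]
      row[[m]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    row
  }))
  rownames(summary_df) <- NULL

  # attach cohort metadata (genotype, survival, follow-up) for scoring
  meta_cols <- intersect(c("tumor_id", "genotype", "survival_days",
                           "lost_to_followup", "flow_content_pct"),
                         names(cohort))
  summary_df <- merge(summary_df, cohort[, meta_cols, drop = FALSE],
                      by = "tumor_id", sort = FALSE)
  summary_df <- summary_df[match(tumor_ids, summary_df$tumor_id), ]
  rownames(summary_df) <- NULL

  list(summary = summary_df,
       cells = if (length(all_cells) > 0) do.call(rbind, all_cells)
       else empty_cell_records(),
       exclusion_log = filt$log)
}
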