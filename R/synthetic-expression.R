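#' Configuration of a synthetic single-cell log-expression matrix
#'
#' Describes a genes x cells matrix of log2 read counts with `n_clusters`
#' planted cell groups. Each cluster upregulates a fraction of the curated
#' gene list(s) assigned to it by `logfc` log2 units; all other expression
#' is baseline plus Gaussian dispersion. Defaults give a cohort-scale
#' matrix (about a thousand cells in seven clusters) with an upregulated
#' slice of each list comparable to the enrichment fractions seen in
#' immune clusters of glioblastoma single-cell data.
#'
#' @param n_genes number of genes (must cover the union of supplied lists).
#' @param n_cells_per_cluster cells per planted cluster.
#' @param n_clusters number of planted clusters (>= 2).
#' @param planted_list_frac fraction of each assigned curated list that is
#'   actually upregulated in the target cluster.
#' @param logfc log2 fold-change applied to planted genes.
#' @param dispersion SD of the per-cell Gaussian noise on log2 expression.
#' @param frac_background_de fraction of genes forming each cluster's
#'   cell-type-specific expression program: drawn disjointly per cluster
#'   from genes outside every curated list and upregulated by `logfc`.
#'   Real cell types differ over many genes beyond any curated list; this
#'   is what makes the clusters recoverable by expression clustering
#'   without touching the enrichment ground truth. Kept small relative to
#'   the gene universe (default 2%) so that, as in real data, a cluster's
#'   upregulated set is a sparse slice of the tested genes.
#' @param seed integer seed.
#' @return an object of class `expr_config`.
#' @export
expr_config <- function(n_genes = 2000L, n_cells_per_cluster = 150L,
                        n_clusters = 7L, planted_list_frac = 0.12,
                        logfc = 2, dispersion = 1,
                        frac_background_de = 0.02, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_cluster = as.integer(n_cells_per_cluster),
              n_clusters = as.integer(n_clusters),
              planted_list_frac = planted_list_frac,
              logfc = logfc, dispersion = dispersion,
              frac_background_de = frac_background_de,
              seed = as.integer(seed))
  class(cfg) <- "expr_config"
  stopifnot(cfg$n_genes > 0, cfg$n_cells_per_cluster > 0, cfg$n_clusters >= 2,
            cfg$planted_list_frac >= 0, cfg$planted_list_frac <= 1,
            cfg$logfc >= 0, cfg$dispersion > 0,
            cfg$frac_background_de >= 0, cfg$frac_background_de <= 1)
  cfg
}

# Default plan for which curated lists each cluster upregulates: alternate
# pro-inflammatory microglia, anti-inflammatory macrophage, and unplanted
# (non-immune) clusters when the four canonical lists are present.
default_cluster_assignments <- function(n_clusters, lists) {
  canonical <- c("microglia", "macrophage", "pro_inflammatory", "anti_inflammatory")
  if (all(canonical %in% names(lists))) {
    cycle <- list(c("microglia", "pro_inflammatory"),
                  c("macrophage", "anti_inflammatory"),
                  character(0))
  } else {
    cycle <- c(as.list(names(lists)), list(character(0)))
  }
  lapply(seq_len(n_clusters), function(j) cycle[[(j - 1) %% length(cycle) + 1]])
}

#' Generate a log-expression matrix with planted, list-enriched clusters
#'
#' Builds a genes x cells log2 expression matrix whose cell clusters each
#' upregulate a known subset of the supplied curated gene lists, so that
#' clustering, marker detection and gene-list enrichment can all be
#' validated against planted truth. Planted genes are drawn without
#' replacement from each assigned list.
#'
#' @param config an [expr_config()].
#' @param lists named list of character vectors of gene symbols (e.g. the
#'   microglia / macrophage / pro- / anti-inflammatory lists).
#' @param assignments optional list of length `n_clusters`; element j is a
#'   character vector of list names upregulated by cluster j (may be empty
#'   for a non-immune cluster). Defaults to alternating pro-inflammatory
#'   microglia / anti-inflammatory macrophage / unplanted clusters.
#' @return a list with `matrix` (genes x cells, log2 scale), `cell_meta`
#'   (data.frame cell_id, cluster) and `truth` (cluster labels, the
#'   assignment plan, and the planted gene sets per cluster).
#' @export
generate_expression_matrix <- function(config, lists, assignments = NULL) {
  stopifnot(inherits(config, "expr_config"), length(lists) > 0,
            !is.null(names(lists)), all(nzchar(names(lists))))
  lists <- lapply(lists, unique)
  all_list_genes <- unique(unlist(lists))
  if (config$n_genes < length(all_list_genes))
    stop("n_genes (", config$n_genes, ") is smaller than the union of the ",
         "supplied gene lists (", length(all_list_genes), ")")
  if (is.null(assignments))
    assignments <- default_cluster_assignments(config$n_clusters, lists)
  stopifnot(length(assignments) == config$n_clusters,
            all(unlist(assignments) %in% names(lists)))

  set.seed(config$seed)
  n_fill <- config$n_genes - length(all_list_genes)
  genes <- c(all_list_genes,
             if (n_fill > 0) sprintf("GENE%05d", seq_len(n_fill)))
  n_cells <- config$n_clusters * config$n_cells_per_cluster
  cluster <- rep(seq_len(config$n_clusters), each = config$n_cells_per_cluster)
  cell_id <- sprintf("cell%04d", seq_len(n_cells))

  baseline <- stats::runif(config$n_genes, 1, 6)
  mat <- matrix(stats::rnorm(config$n_genes * n_cells, 0, config$dispersion),
                config$n_genes, n_cells) + baseline
  dimnames(mat) <- list(genes, cell_id)

  # disjoint cluster-specific programs from genes outside every list
  n_bg <- round(config$frac_background_de * config$n_genes)
  non_list <- setdiff(genes, all_list_genes)
  if (n_bg * config$n_clusters > length(non_list))
    stop("not enough non-list genes (", length(non_list), ") for ",
         config$n_clusters, " background programs of ", n_bg, " genes")
  bg_pool <- sample(non_list, n_bg * config$n_clusters)
  background <- split(bg_pool, rep(seq_len(config$n_clusters), each = n_bg))

  planted <- vector("list", config$n_clusters)
  for (j in seq_len(config$n_clusters)) {
    pg <- character(0)
    for (ln in assignments[[j]]) {
      lg <- lists[[ln]]
      n_plant <- round(config$planted_list_frac * length(lg))
      if (n_plant < 1)
        stop("planted_list_frac * |", ln, "| < 1: no gene would be planted")
      pg <- union(pg, sample(lg, n_plant))
    }
    planted[[j]] <- pg
    up <- c(pg, if (n_bg > 0) background[[j]])
    if (length(up) > 0 && config$logfc > 0)
      mat[up, cluster == j] <- mat[up, cluster == j] + config$logfc
  }

  list(
    matrix = mat,
    cell_meta = data.frame(cell_id = cell_id, cluster = cluster,
                           stringsAsFactors = FALSE),
    truth = list(cluster = cluster, assignments = assignments,
                 planted = planted,
                 background = if (n_bg > 0) background else NULL)
  )
}
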