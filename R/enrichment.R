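#' Hierarchically cluster cells by log expression
#'
#' Agglomerative clustering of cells (columns) under the Ward D2 criterion
#' on Euclidean distances between log-expression profiles, with the tree
#' cut at a configured number of clusters.
#'
#' @param matrix genes x cells numeric matrix of log read counts.
#' @param n_clusters number of clusters (>= 2, <= number of cells).
#' @return integer cluster labels named by cell id.
#' @export
cluster_cells <- function(matrix, n_clusters) {
  n_cells <- ncol(matrix)
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (n_clusters > n_cells)
    stop("fewer cells (", n_cells, ") than clusters (", n_clusters, ")")
  hc <- stats::hclust(stats::dist(t(matrix)), method = "ward.D2")
  stats::cutree(hc, k = n_clusters)
}

#' Upregulated marker genes of one cluster
#'
#' One-vs-rest Welch t-test per gene on log2 expression, Benjamini-
#' Hochberg FDR across all tested genes, keeping genes that pass the FDR
#' cutoff and are upregulated at least `min_fc`-fold in the cluster
#' (a difference of `log2(min_fc)` on the log2 scale). Genes constant
#' across all cells cannot be tested and are skipped (listed in
#' `skipped`). The default FDR cutoff is the stringent 1e-20 used for
#' marker detection in well-powered single-cell comparisons.
#'
#' @param matrix genes x cells log2 expression matrix.
#' @param labels cluster labels (length = number of cells).
#' @param cluster the cluster id to contrast against all other cells.
#' @param fdr_cut BH-adjusted p-value cutoff (default 1e-20).
#' @param min_fc minimum fold-change, must be >= 1 (default 2).
#' @return list with `genes` (upregulated set), `universe` (all testable
#'   genes), `stats` (per-gene log2 fold-change, p, FDR) and `skipped`
#'   (constant genes).
#' @export
find_upregulated <- function(matrix, labels, cluster, fdr_cut = 1e-20,
                             min_fc = 2) {
  stopifnot(length(labels) == ncol(matrix))
  if (min_fc < 1)
    stop("min_fc must be >= 1: marker genes are upregulated")
  in_cl <- labels == cluster
  if (!any(in_cl)) stop("cluster ", cluster, " is empty")
  if (all(in_cl)) stop("cluster ", cluster, " contains every cell")
  n1 <- sum(in_cl); n2 <- sum(!in_cl)
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 cells in the cluster and its complement")

  x1 <- matrix[, in_cl, drop = FALSE]
  x2 <- matrix[, !in_cl, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)

  constant <- v1 == 0 & v2 == 0
  skipped <- rownames(matrix)[constant & (m1 == m2)]
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # groups internally constant but different: infinitely strong evidence
  p[constant & (m1 != m2)] <- 0
  testable <- !(constant & (m1 == m2))

  fdr <- rep(NA_real_, length(p))
  fdr[testable] <- stats::p.adjust(p[testable], method = "BH")
  lfc <- m1 - m2

  universe <- rownames(matrix)[testable]
  genes <- rownames(matrix)[testable & !is.na(fdr) & fdr < fdr_cut &
                              lfc >= log2(min_fc)]
  list(
    genes = genes,
    universe = universe,
    stats = data.frame(gene = rownames(matrix), log2fc = lfc, p = p,
                       fdr = fdr, row.names = NULL)[testable, ],
    skipped = skipped
  )
}

#' Hypergeometric enrichment of a gene set against one curated list
#'
#' Upper-tail hypergeometric probability of observing at least the
#' realized overlap between a cluster's upregulated gene set and a curated
#' list, conditioning on the universe of genes that could have been
#' detected (all testable genes). The percentage of the curated list
#' represented in the set is reported alongside.
#'
#' @param gene_set character vector of upregulated genes.
#' @param list_genes character vector, one curated list.
#' @param universe character vector of all tested genes.
#' @return one-row data.frame: `overlap`, `pct_of_list`, `p`.
#' @export
enrich <- function(gene_set, list_genes, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  list_in_u <- intersect(unique(list_genes), universe)
  if (length(list_in_u) == 0)
    stop("gene list has no overlap with the tested universe")
  set_in_u <- intersect(unique(gene_set), universe)
  overlap <- length(intersect(set_in_u, list_in_u))
  p <- stats::phyper(overlap - 1, m = length(list_in_u),
                     n = length(universe) - length(list_in_u),
                     k = length(set_in_u), lower.tail = FALSE)
  data.frame(overlap = overlap,
             pct_of_list = 100 * overlap / length(list_in_u),
             p = p)
}

#' Enrichment of every cluster against every curated list
#'
#' Runs [enrich()] for each (cluster, list) pair and applies a single
#' Benjamini-Hochberg FDR correction across all pairs of the run.
#'
#' @param gene_sets named list: per cluster, the upregulated gene set.
#' @param lists named list of curated gene lists.
#' @param universe character vector of all tested genes.
#' @return an `enrichment_result` data.frame: cluster, list_name, overlap,
#'   pct_of_list, p, fdr.
#' @export
enrich_all <- function(gene_sets, lists, universe) {
  stopifnot(length(gene_sets) > 0, length(lists) > 0,
            !is.null(names(gene_sets)), !is.null(names(lists)))
  rows <- list()
  for (cl in names(gene_sets)) {
    for (ln in names(lists)) {
      r <- enrich(gene_sets[[cl]], lists[[ln]], universe)
      r$cluster <- cl
      r$list_name <- ln
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("cluster", "list_name", "overlap", "pct_of_list", "p", "fdr")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Designate a cluster from its four list enrichments
#'
#' A cluster is immune when its microglia or macrophage list enrichment is
#' significant (FDR below `fdr_threshold`); its cell type is the more
#' significant of the two, its polarity the more significant of the pro-
#' vs anti-inflammatory lists. When both polarity FDRs are significant and
#' within `mixed_orders` orders of magnitude of each other the polarity is
#' ambiguous and the cluster is designated `mixed`. Non-immune clusters
#' are designated `non_immune`.
#'
#' @param enrichments data.frame of this cluster's enrichments with
#'   columns `list_name` (microglia, macrophage, pro_inflammatory,
#'   anti_inflammatory) and `fdr`.
#' @param fdr_threshold significance threshold (default 0.05).
#' @param mixed_orders closeness band, in orders of magnitude, within
#'   which two significant polarity FDRs count as mixed (default 5).
#' @return one of `"pro_microglia"`, `"anti_microglia"`,
#'   `"pro_macrophage"`, `"anti_macrophage"`, `"mixed"`, `"non_immune"`.
#' @export
label_cluster <- function(enrichments, fdr_threshold = 0.05, mixed_orders = 5) {
  need <- c("microglia", "macrophage", "pro_inflammatory", "anti_inflammatory")
  stopifnot(all(need %in% enrichments$list_name))
  fdr <- stats::setNames(enrichments$fdr, enrichments$list_name)[need]

  if (min(fdr["microglia"], fdr["macrophage"]) >= fdr_threshold)
    return("non_immune")
  cell_type <- if (fdr["microglia"] <= fdr["macrophage"]) "microglia"
  else "macrophage"

  pro <- fdr["pro_inflammatory"]; anti <- fdr["anti_inflammatory"]
  both_sig <- pro < fdr_threshold && anti < fdr_threshold
  if (both_sig && abs(log10(pmax(pro, 1e-300)) -
                        log10(pmax(anti, 1e-300))) <= mixed_orders)
    return("mixed")
  polarity <- if (pro <= anti) "pro" else "anti"
  paste(polarity, cell_type, sep = "_")
}
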