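test_that("Ward clustering recovers well-separated planted clusters", {
  lists <- example_gene_lists()
  cfg <- expr_config(n_genes = 650, n_cells_per_cluster = 50, n_clusters = 2,
                     logfc = 4, dispersion = 0.5, seed = 3)
  sim <- generate_expression_matrix(cfg, lists)
  lab <- cluster_cells(sim$matrix, 2)
  expect_gt(rand_index(lab, sim$truth$cluster), 0.95)

  # duplicated cells always co-cluster
  m <- sim$matrix[, c(1:20, 60:79)]
  m <- cbind(m, dup = m[, 1])
  colnames(m)[ncol(m)] <- "dup"
  lab2 <- cluster_cells(m, 2)
  expect_equal(unname(lab2["dup"]), unname(lab2[1]))

  expect_error(cluster_cells(sim$matrix[, 1:3], 5), "fewer cells")
  expect_error(cluster_cells(sim$matrix, 1), ">= 2")
})

test_that("null expression matrices cluster at chance", {
  lists <- example_gene_lists()
  ris <- vapply(1:5, function(s) {
    cfg <- expr_config(n_genes = 650, n_cells_per_cluster = 30,
                       n_clusters = 3, logfc = 0, seed = s)
    sim <- generate_expression_matrix(cfg, lists)
    # adjusted Rand index against truth should hover near zero
    ri <- rand_index(cluster_cells(sim$matrix, 3), sim$truth$cluster)
    ri
  }, numeric(1))
  # raw Rand index for random 3-way partitions concentrates near ~0.6;
  # genuine recovery would push it near 1
  expect_lt(mean(ris), 0.8)
})

test_that("upregulated-gene detection recovers planted genes under the filters", {
  lists <- example_gene_lists()
  cfg <- expr_config(n_genes = 1200, n_cells_per_cluster = 120,
                     n_clusters = 3, logfc = 3, seed = 9)
  sim <- generate_expression_matrix(cfg, lists)
  up <- find_upregulated(sim$matrix, sim$truth$cluster, 1)
  planted <- c(sim$truth$planted[[1]], sim$truth$background[[1]])
  expect_true(all(planted %in% up$genes))
  # false discoveries are rare at FDR < 1e-20
  expect_lte(length(setdiff(up$genes, planted)), 2)

  expect_length(find_upregulated(sim$matrix, sim$truth$cluster, 1,
                                 fdr_cut = 0)$genes, 0)
  expect_error(find_upregulated(sim$matrix, sim$truth$cluster, 1,
                                min_fc = 0.5), "min_fc")

  # constant genes are skipped and logged
  m2 <- sim$matrix[1:50, ]
  m2[1, ] <- 7
  rownames(m2)[1] <- "CONSTANT"
  up2 <- find_upregulated(m2, sim$truth$cluster, 1)
  expect_true("CONSTANT" %in% up2$skipped)
  expect_false("CONSTANT" %in% up2$universe)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # spec example: universe 20, list 5, set 5, overlap 3
  universe <- sprintf("g%02d", 1:20)
  lst <- universe[1:5]
  set <- c(universe[1:3], universe[6:7])
  out <- enrich(set, lst, universe)
  expect_equal(out$overlap, 3)
  p_oracle <- sum(choose(5, 3:5) * choose(15, 5 - (3:5))) / choose(20, 5)
  expect_equal(out$p, p_oracle, tolerance = 1e-12)

  # full-enumeration agreement across universes up to 25 genes
  set.seed(17)
  for (N in c(5, 9, 14, 20, 25)) {
    uni <- sprintf("u%03d", seq_len(N))
    for (rep in 1:6) {
      m <- sample.int(N - 1, 1)
      k <- sample.int(N, 1)
      lst <- sample(uni, m)
      st <- sample(uni, k)
      got <- enrich(st, lst, uni)
      want <- hyper_tail_oracle(N, m, k, got$overlap)
      expect_equal(got$p, want, tolerance = 1e-12)
    }
  }

  # boundary behaviour
  lst <- universe[1:5]
  expect_equal(enrich(universe, lst, universe)$pct_of_list, 100)
  disj <- enrich(universe[6:10], lst, universe)
  expect_equal(disj$overlap, 0)
  expect_equal(disj$p, 1)
  expect_error(enrich(set, character(0), universe), "no overlap")
  expect_error(enrich(set, lst, character(0)), "empty universe")
})

test_that("per-run FDR correction spans all cluster-list pairs", {
  universe <- sprintf("g%02d", 1:30)
  sets <- list(c1 = universe[1:6], c2 = universe[25:30])
  lists <- list(la = universe[1:6], lb = universe[7:12])
  out <- enrich_all(sets, lists, universe)
  expect_equal(nrow(out), 4)
  expect_equal(out$fdr, stats::p.adjust(out$p, "BH"))
  expect_true(all(out$pct_of_list >= 0 & out$pct_of_list <= 100))
  # gene order never matters
  out2 <- enrich_all(lapply(sets, rev), lapply(lists, sample), universe)
  expect_equal(out2$p, out$p)
})

test_that("cluster designation follows the significance rules", {
  enr <- function(mic, mac, pro, anti) {
    data.frame(list_name = c("microglia", "macrophage", "pro_inflammatory",
                             "anti_inflammatory"),
               fdr = c(mic, mac, pro, anti))
  }
  expect_equal(label_cluster(enr(1e-8, 0.5, 1e-4, 0.9)), "pro_microglia")
  expect_equal(label_cluster(enr(0.4, 1e-10, 0.8, 1e-6)), "anti_macrophage")
  expect_equal(label_cluster(enr(0.9, 0.6, 1e-30, 1e-40)), "non_immune")
  # both polarities significant and within five orders: mixed
  expect_equal(label_cluster(enr(1e-9, 0.2, 1e-6, 1e-8)), "mixed")
  # both significant but far apart: the stronger wins
  expect_equal(label_cluster(enr(1e-9, 0.2, 1e-20, 1e-3)), "pro_microglia")
})

test_that("planted immune clusters are designated correctly end to end", {
  lists <- example_gene_lists()
  cfg <- expr_config(n_genes = 1500, n_cells_per_cluster = 100,
                     n_clusters = 4, logfc = 2, seed = 23)
  sim <- generate_expression_matrix(cfg, lists)
  lab <- cluster_cells(sim$matrix, 4)
  ups <- lapply(1:4, function(cl) find_upregulated(sim$matrix, lab, cl))
  sets <- stats::setNames(lapply(ups, `[[`, "genes"), paste0("c", 1:4))
  enr <- enrich_all(sets, lists, ups[[1]]$universe)
  truth_map <- majority_map(lab, sim$truth$cluster)
  for (cl in 1:4) {
    got <- label_cluster(enr[enr$cluster == paste0("c", cl), ])
    planted <- sim$truth$assignments[[truth_map[cl]]]
    want <- if (length(planted) == 0) "non_immune"
    else if ("microglia" %in% planted) "pro_microglia" else "anti_macrophage"
    expect_equal(got, want)
  }
})
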