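test_that("dispersion selection finds structured genes, monotone in quantile", {
  set.seed(19)
  n <- 200
  counts <- matrix(rpois(60 * n, 2), 60, n)
  counts[1, ] <- c(rep(0, n / 2), rep(50, n / 2))  # bimodal gene
  counts[2, ] <- 3                                  # constant gene
  cm <- cm_from(counts)
  norm <- normalize_counts(cm, rep(1, n))
  sel <- select_genes_by_dispersion(norm)
  expect_true("g1" %in% sel)
  expect_false("g2" %in% sel)
  # raising the quantile never enlarges the set
  prev <- sel
  for (q in c(0.8, 0.9, 0.95)) {
    cur <- suppressWarnings(
      select_genes_by_dispersion(norm, dispersion_quantile = q))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("embedding is deterministic and separates planted populations", {
  set.seed(23)
  mu <- cbind(matrix(5, 20, 1) %*% rep(1, 40),
              matrix(0.2, 20, 1) %*% rep(1, 40))
  mu <- rbind(mu, mu[, c(41:80, 1:40)])
  counts <- matrix(rpois(length(mu), as.numeric(mu)), nrow(mu))
  cm <- cm_from(counts)
  norm <- normalize_counts(cm)
  emb <- embed_cells(norm, n_pcs = 2)
  expect_identical(emb, embed_cells(norm, n_pcs = 2))
  grp <- rep(1:2, each = 40)
  cents <- rbind(colMeans(emb[grp == 1, ]), colMeans(emb[grp == 2, ]))
  between <- sqrt(sum((cents[1, ] - cents[2, ])^2))
  within <- mean(c(sqrt(rowSums(sweep(emb[grp == 1, ], 2, cents[1, ])^2)),
                   sqrt(rowSums(sweep(emb[grp == 2, ], 2, cents[2, ])^2))))
  expect_gt(between, 5 * within)
  expect_error(embed_cells(norm, n_pcs = 1000), "exceeds")
  # duplicated cell gets identical coordinates
  dup <- cm_from(cbind(counts, counts[, 1]),
                 cells = c(paste0("c", 1:80), "dup"))
  edup <- embed_cells(normalize_counts(dup, rep(1, 81)), n_pcs = 2)
  expect_equal(unname(edup["dup", ]), unname(edup["c1", ]), tolerance = 1e-9)
})

test_that("clustering recovers planted populations and orders labels by size", {
  cfg <- small_sim_config(seed = 29)
  sim <- simulate_counts(cfg)
  norm <- normalize_counts(sim$counts)
  sel <- select_genes_by_dispersion(norm)
  emb <- embed_cells(norm, sel, n_pcs = 10)
  cl <- cluster_cells(emb, seed = 1)
  expect_gte(ari(cl, sim$truth$cells$cell_type), 0.9)
  sizes <- as.numeric(table(cl))
  expect_true(all(diff(sizes) <= 0))
  # a single tight blob is one cluster
  set.seed(2)
  blob <- matrix(rnorm(60 * 2, sd = 0.05), 60, 2,
                 dimnames = list(paste0("c", 1:60), NULL))
  expect_equal(length(unique(cluster_cells(blob, seed = 1))), 1)
  expect_error(cluster_cells(blob[1:2, ]), "at least 3")
  # permuting cell order changes labels only through the size rule
  perm <- sample(nrow(emb))
  clp <- cluster_cells(emb[perm, ], seed = 1)
  expect_gte(ari(cl[rownames(emb)[perm]], clp), 0.999)
})

test_that("pseudotime on a noiseless line equals normalized position", {
  pos <- seq(0, 1, length.out = 80)
  emb <- cbind(pos * 10, 0)
  rownames(emb) <- paste0("c", 1:80)
  tr <- learn_pseudotime(emb, root_barcode = "c1", n_centers = 6, seed = 1)
  expect_equal(unname(tr$pseudotime["c1"]), 0)
  expect_equal(max(tr$pseudotime), 1)
  expect_equal(cor(tr$pseudotime, pos, method = "spearman"), 1)
  # uniform scaling of the embedding leaves pseudotime unchanged
  tr2 <- learn_pseudotime(emb * 37, root_barcode = "c1", n_centers = 6,
                          seed = 1)
  expect_equal(tr2$pseudotime, tr$pseudotime, tolerance = 1e-9)
  expect_error(learn_pseudotime(emb, root_barcode = "nope"), "not found")
  expect_error(learn_pseudotime(emb), "root_score or root_barcode")
})

test_that("pseudotime recovers the planted latent time", {
  cfg <- sim_config(seed = 37)
  sim <- simulate_counts(cfg)
  norm <- normalize_counts(sim$counts)
  sel <- select_genes_by_dispersion(norm)
  emb <- embed_cells(norm, sel, n_pcs = 10)
  root <- geneset_score(norm, cfg$genes$markers$arterial_EC)
  tr <- learn_pseudotime(emb, root_score = root, seed = 1)
  expect_equal(unname(tr$pseudotime[tr$root]), 0)
  expect_gte(cor(tr$pseudotime, sim$truth$cells$latent_time,
                 method = "spearman"), 0.9)
})

test_that("Moran's I matches the closed form and the naive double loop", {
  w4 <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0))
  g4 <- neighbor_graph(w4)
  expect_equal(morans_i(c(1, -1, 1, -1), g4), -1)

  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    w <- random_graph_adjacency(n)
    x <- rnorm(n)
    expect_equal(morans_i(x, neighbor_graph(w)), naive_morans_i(x, w),
                 tolerance = 1e-12)
  }
  expect_error(morans_i(rep(2, 4), g4), "zero variance")
  expect_error(neighbor_graph(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("Moran's I permutation null has mean -1/(N-1)", {
  set.seed(43)
  n <- 10
  w <- random_graph_adjacency(n)
  g <- neighbor_graph(w)
  x <- rnorm(n)
  vals <- vapply(1:10000, function(i) morans_i(sample(x), g), numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - (-1 / (n - 1))), 3 * se)
})

test_that("trajectory DE applies the strict detection filter and finds planted genes", {
  cfg <- small_sim_config(seed = 47)
  sim <- simulate_counts(cfg)
  norm <- normalize_counts(sim$counts)
  sel <- select_genes_by_dispersion(norm)
  emb <- embed_cells(norm, sel, n_pcs = 10)
  g <- knn_graph(emb, 15)
  root <- geneset_score(norm, cfg$genes$markers$arterial_EC)
  tr <- learn_pseudotime(emb, root_score = root, seed = 1)
  de <- trajectory_de(sim$counts, norm, g, tr$pseudotime,
                      n_permutations = 199, seed = 1)
  # strict ">": a gene detected in exactly 5% of cells is excluded
  n <- ncol(sim$counts)
  frac <- Matrix::rowMeans(sim$counts >= 1)
  exact5 <- names(frac)[abs(frac - 0.05) < 1e-9]
  expect_false(any(exact5 %in% de$gene))
  expect_true(all(de$detected_fraction > 0.05))
  # planted monotone genes called, with the planted sign
  truth <- sim$truth$genes
  up <- truth$gene[truth$trajectory_sign == 1]
  dn <- truth$gene[truth$trajectory_sign == -1]
  dir_up <- de$direction[match(up, de$gene)]
  dir_dn <- de$direction[match(dn, de$gene)]
  expect_gte(mean(de$significant[match(c(up, dn), de$gene)]), 0.9)
  expect_gte(mean(dir_up == "late", na.rm = TRUE), 0.9)
  expect_gte(mean(dir_dn == "early", na.rm = TRUE), 0.9)
  # q-values equal the independently coded BH step-up
  expect_equal(de$q_value, bh_step_up(de$p_value), tolerance = 1e-12)
  expect_error(trajectory_de(sim$counts, norm, g, tr$pseudotime,
                             n_permutations = 50), "at least 100")
})

test_that("cluster markers obey the specificity definition and thresholds", {
  set.seed(53)
  clusters <- rep(1:4, each = 20)
  counts <- matrix(rpois(30 * 80, 1), 30, 80)
  counts[1, clusters == 2] <- counts[1, clusters == 2] + 20
  counts[2, ] <- rpois(80, 5)
  counts[3, ] <- 0
  counts[3, clusters == 3] <- rpois(20, 10)  # exclusive to cluster 3
  cm <- cm_from(counts)
  norm <- normalize_counts(cm, rep(1, 80))
  emb <- embed_cells(norm, n_pcs = 5)
  g <- knn_graph(emb, 10)
  mk <- cluster_markers(cm, norm, g, clusters)
  # exclusive gene: specificity 1 for its cluster
  expect_equal(mk$specificity[mk$gene == "g3"], 1)
  expect_equal(mk$cluster[mk$gene == "g3"], 3)
  # naive two-loop specificity recomputation
  for (gene in paste0("g", 1:10)) {
    means <- sapply(1:4, function(k) mean(norm[gene, clusters == k]))
    expect_equal(mk$specificity[mk$gene == gene],
                 max(means) / sum(means), tolerance = 1e-12)
  }
  # equal means across 4 clusters can never pass 0.75
  expect_lt(mk$specificity[mk$gene == "g2"], 0.75)
  expect_false(mk$is_marker[mk$gene == "g2"])
  # raising either threshold never adds markers
  stricter <- cluster_markers(cm, norm, g, clusters, morans_min = 0.5,
                              specificity_min = 0.9)
  expect_true(all(stricter$gene[stricter$is_marker] %in%
                    mk$gene[mk$is_marker]))
  expect_error(cluster_markers(cm, norm, g, rep(1, 80)), "at least 2")
  expect_error(cluster_markers(cm, norm, g,
                               factor(rep(1, 80), levels = c(1, 2))),
               "empty cluster")
})

test_that("pseudotime enrichment splits at the median pseudotime", {
  n <- 40
  pt <- seq(0, 1, length.out = n)
  m <- rbind(dec = round(seq(20, 0, length.out = n)),
             inc = round(seq(0, 20, length.out = n)))
  cm <- count_matrix(m, gene_symbols = c("dec", "inc"),
                     barcodes = paste0("c", 1:n))
  norm <- normalize_counts(cm, rep(1, n))
  mask <- rep(TRUE, n)
  expect_equal(pseudotime_enrichment("dec", norm, pt, mask), "early")
  expect_equal(pseudotime_enrichment("inc", norm, pt, mask), "late")
  expect_equal(pseudotime_enrichment("inc", norm, pt, mask,
                                     significant = FALSE), "ns")
  expect_error(pseudotime_enrichment("inc", norm, pt, rep(c(TRUE, FALSE),
                                                          c(5, n - 5))),
               "at least 10")
})
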