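test_that("gene-set scores are log1p sums of normalized expression", {
  m <- matrix(c(3, 6, 0,
                0, 0, 0), nrow = 3)
  cm <- cm_from(m, genes = c("A", "B", "C"))
  norm <- normalize_counts(cm, c(1, 1))
  sc <- geneset_score(norm, c("A", "B"))
  expect_equal(unname(sc), c(log(10), 0))
  # additive identity: a zero-expression member leaves scores unchanged
  expect_equal(geneset_score(norm, c("A", "B", "C")), sc)
  expect_warning(sc2 <- geneset_score(norm, c("A", "Zzz")), "missing")
  expect_equal(unname(sc2), c(log(4), 0))
  expect_warning(z <- geneset_score(norm, "Nope"), "all zero")
  expect_equal(unname(z), c(0, 0))
  # configurable base
  expect_equal(unname(geneset_score(norm, c("A", "B"), base = 2))[1],
               log2(10))
})

test_that("score monotonicity: adding a gene never lowers a score", {
  set.seed(21)
  cm <- cm_from(matrix(rpois(40 * 15, 2), 40, 15))
  norm <- normalize_counts(cm)
  genes <- rownames(cm)
  for (i in 1:20) {
    base_set <- sample(genes, 5)
    extra <- sample(setdiff(genes, base_set), 1)
    s0 <- geneset_score(norm, base_set)
    s1 <- geneset_score(norm, c(base_set, extra))
    expect_true(all(s1 >= s0 - 1e-12))
  }
})

test_that("rank-sum comparison: exact enumeration and symmetry", {
  same <- compare_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  sep <- compare_scores(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)  # 2 of the 20 assignments as extreme

  a <- c(0.3, 1.2, 2.2, 0.9); b <- c(2.5, 3.1, 1.9)
  expect_equal(compare_scores(a, b)$p_value, compare_scores(b, a)$p_value)

  expect_error(compare_scores(numeric(), 1:3), "non-empty")
})

test_that("rank-sum agrees with the reference implementation", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(25, mean = runif(1, -1, 1))
    ours <- compare_scores(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # exact path against wilcox.test's exact p (tie-free)
  for (i in 1:10) {
    x <- sample(100, 6); y <- sample(200, 7) + 0.5
    expect_equal(compare_scores(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("classification follows the published strict marker logic", {
  genes <- c("Gfi1", "Mycn", "Pdzk1ip1", "Procr", "Dll4", "Vwf", "Cdkn1c",
             "Pbx1", "Mllt3", "Flt3", "Il7r", "Fcgr3", "Csf3r", "Runx1",
             "Cdh5", "Efnb2", "Hey1", "Nr2f2", "Nrp2", "Cd48", "Itgal")
  mk <- function(on) {
    v <- integer(length(genes)); names(v) <- genes
    v[on] <- 1L
    v
  }
  cells <- cbind(
    precursor = mk(c("Gfi1", "Mycn", "Pdzk1ip1", "Procr", "Dll4", "Vwf",
                     "Cdkn1c", "Pbx1", "Mllt3")),
    progenitor = mk(c("Runx1", "Flt3")),
    hsc = mk(c("Runx1", "Pdzk1ip1", "Vwf")),
    hpc = mk(c("Runx1", "Pdzk1ip1", "Vwf", "Cd48")),
    nothing = mk(character()))
  cm <- count_matrix(cells, gene_symbols = genes,
                     barcodes = colnames(cells))
  res <- classify_cells(cm, default_marker_rules("all"))
  expect_equal(res$cell_type,
               c("HSC_precursor", "progenitor", "HSC_type", "HPC_type",
                 "unclassified"))
  # rule referencing an absent gene errors, naming the gene
  bad <- marker_rule("bad", required_all = "NotAGene")
  expect_error(classify_cells(cm, list(bad)), "NotAGene")
  # multi-rule matches are reported as ambiguous
  r1 <- marker_rule("t1", required_all = "Runx1")
  r2 <- marker_rule("t2", required_all = "Flt3")
  amb <- classify_cells(cm, list(r1, r2))
  expect_equal(amb$cell_type[2], "ambiguous")
  expect_equal(amb$matched_types[2], "t1;t2")
})

test_that("classification matches a boolean oracle on all detection patterns", {
  rules <- default_marker_rules("all")
  for (rule in rules) {
    genes <- unique(c(rule$required_all, rule$required_any, rule$forbidden))
    k <- length(genes)
    patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
    colnames(patterns) <- genes
    cm <- count_matrix(t(patterns), gene_symbols = genes,
                       barcodes = sprintf("p%04d", seq_len(nrow(patterns))))
    res <- classify_cells(cm, list(rule))
    want <- apply(patterns == 1, 1, rule_oracle, rule = rule)
    expect_identical(res$cell_type == rule$type_name, unname(want))
  }
})

test_that("HSC precursor and progenitor rules are provably disjoint", {
  rules <- default_marker_rules("agm")
  genes <- unique(unlist(lapply(rules, function(r)
    c(r$required_all, r$required_any, r$forbidden))))
  set.seed(13)
  patterns <- matrix(rbinom(2000 * length(genes), 1, 0.5),
                     ncol = length(genes), dimnames = list(NULL, genes))
  cm <- count_matrix(t(patterns), gene_symbols = genes,
                     barcodes = sprintf("p%04d", 1:2000))
  res <- classify_cells(cm, rules)
  both <- grepl("HSC_precursor", res$matched_types) &
    grepl("progenitor", res$matched_types)
  expect_false(any(both))
})

test_that("the HE subset is the three-gene negative predicate", {
  genes <- c("Itga2b", "Spn", "Ptprc", "Other")
  m <- rbind(Itga2b = c(0, 0, 2), Spn = c(0, 0, 0), Ptprc = c(0, 1, 0),
             Other = c(5, 5, 5))
  cm <- count_matrix(m, gene_symbols = genes, barcodes = c("a", "b", "c"))
  he <- he_subset(cm, rep("HSC_precursor", 3))
  expect_equal(unname(he), c(TRUE, FALSE, FALSE))
  expect_error(he_subset(cm, c("HSC_precursor", "HSC_precursor", "other")),
               "labeled")
  # predicate oracle on a random fixture
  set.seed(31)
  r <- matrix(rbinom(4 * 50, 1, 0.3), 4, 50, dimnames = list(genes, NULL))
  rcm <- count_matrix(r, gene_symbols = genes,
                      barcodes = sprintf("c%02d", 1:50))
  he2 <- he_subset(rcm, rep("HSC_precursor", 50))
  want <- apply(r[c("Itga2b", "Spn", "Ptprc"), ] >= 1, 2, function(d) !any(d))
  expect_equal(unname(he2), unname(want))
})

test_that("classification recovers simulated true types", {
  cfg <- small_sim_config(seed = 17)
  sim <- simulate_counts(cfg)
  res <- classify_cells(sim$counts, sim_marker_rules(cfg))
  expect_gte(mean(res$cell_type == sim$truth$cells$cell_type), 0.95)
})
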