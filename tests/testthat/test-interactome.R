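test_that("expression calling uses inclusive detection-fraction thresholds", {
  m <- matrix(0, 2, 20, dimnames = list(c("A", "B"), paste0("c", 1:20)))
  m["A", 1:2] <- 1  # detected in 2 of 20 cells = 10%
  cm <- count_matrix(m, gene_symbols = c("A", "B"),
                     barcodes = paste0("c", 1:20))
  calls <- call_expressed(cm, rep(TRUE, 20), 0.10)
  expect_true(calls$called[calls$gene == "A"])   # 0.10 >= 0.10
  expect_false(calls$called[calls$gene == "B"])
  # threshold 0: every gene with at least one detection, never all-zero genes
  calls0 <- call_expressed(cm, rep(TRUE, 20), 0)
  expect_true(calls0$called[calls0$gene == "A"])
  expect_false(calls0$called[calls0$gene == "B"])
  # monotonicity: raising the threshold never adds called genes
  prev <- calls0$gene[calls0$called]
  for (thr in c(0.05, 0.1, 0.2, 0.5)) {
    cur <- call_expressed(cm, rep(TRUE, 20), thr)
    expect_true(all(cur$gene[cur$called] %in% prev))
    prev <- cur$gene[cur$called]
  }
  expect_error(call_expressed(cm, rep(FALSE, 20), 0.1), "empty")
  expect_error(call_expressed(cm, rep(TRUE, 20), 1.5), "threshold")
})

test_that("human symbols map to mouse by title case with overrides", {
  mp <- map_symbols(c("CXCL12", "VCAM1", "DLL4"))
  expect_equal(mp$mouse, c("Cxcl12", "Vcam1", "Dll4"))
  ov <- data.frame(human = "IL3", mouse = "Il3x")
  mp2 <- map_symbols(c("IL3", "TPO"), ov)
  expect_equal(mp2$mouse, c("Il3x", "Tpo"))
  expect_equal(mp2$overridden, c(TRUE, FALSE))
  packaged <- utils::read.table(
    system.file("extdata", "lr_symbol_overrides.tsv", package = "agmniche"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(map_symbols("KITLG", packaged)$mouse, "Kitl")
})

test_that("the atlas is the database cross-join of called ligands/receptors", {
  db <- data.frame(ligand_human = c("A", "B", "C"),
                   receptor_human = c("R1", "R2", "R3"),
                   stringsAsFactors = FALSE)
  call_tbl <- function(called, genes = c("A", "B", "C", "R1", "R2", "R3")) {
    data.frame(gene = map_symbols(genes)$mouse,
               detection_fraction = ifelse(genes %in% called, 0.5, 0),
               threshold = 0.1, called = genes %in% called,
               stringsAsFactors = FALSE)
  }
  lig <- list(primary_arterial_EC = call_tbl(c("A")),
              cultured_AGM_EC = call_tbl(c("A", "B")))
  rec <- list(HSC_precursor = call_tbl(c("R1", "R3")))
  atlas <- build_interactome(lig, rec, db, exogenous = character())
  expect_equal(nrow(atlas), 1)
  expect_equal(atlas$ligand_mouse, "A")
  expect_equal(atlas$ligand_sources, "primary_arterial_EC;cultured_AGM_EC")
  # empty calls and no exogenous set -> empty atlas
  none <- list(primary_arterial_EC = call_tbl(character()))
  expect_equal(nrow(build_interactome(none, rec, db,
                                      exogenous = character())), 0)
  # exogenous cytokine: record present at 0% ligand detection
  ex <- build_interactome(none, rec, db, exogenous = "A")
  expect_equal(nrow(ex), 1)
  expect_equal(ex$ligand_sources, "exogenous_cytokine")
  expect_error(build_interactome(lig, list(bogus = call_tbl("R1")), db),
               "unknown receptor population")
})

test_that("the atlas equals a brute-force triple-loop oracle", {
  set.seed(59)
  genes_l <- paste0("L", 1:12); genes_r <- paste0("R", 1:12)
  db <- data.frame(
    ligand_human = toupper(sample(genes_l, 40, replace = TRUE)),
    receptor_human = toupper(sample(genes_r, 40, replace = TRUE)),
    stringsAsFactors = FALSE)
  db <- db[!duplicated(db), ]
  mk_calls <- function(p) {
    g <- c(genes_l, genes_r)
    data.frame(gene = g, detection_fraction = runif(length(g)),
               threshold = p, called = NA, stringsAsFactors = FALSE) |>
      transform(called = detection_fraction >= p)
  }
  lig <- list(primary_arterial_EC = mk_calls(0.10),
              cultured_AGM_EC = list(mk_calls(0.10), mk_calls(0.10)))
  rec <- list(HSC_precursor = mk_calls(0.05), HSC = mk_calls(0.20))
  sup <- sample(genes_l, 3)
  atlas <- build_interactome(lig, rec, db, exogenous = c("L1", "L2"),
                             supportive_de_genes = sup)
  # oracle: loop over db pairs x populations x sources
  lig_called <- list(
    primary_arterial_EC =
      lig$primary_arterial_EC$gene[lig$primary_arterial_EC$called],
    cultured_AGM_EC = intersect(
      lig$cultured_AGM_EC[[1]]$gene[lig$cultured_AGM_EC[[1]]$called],
      lig$cultured_AGM_EC[[2]]$gene[lig$cultured_AGM_EC[[2]]$called]))
  want <- list()
  mouse <- function(s) paste0(substr(s, 1, 1),
                              tolower(substr(s, 2, nchar(s))))
  for (pop in names(rec)) {
    rc <- rec[[pop]]$gene[rec[[pop]]$called]
    for (i in seq_len(nrow(db))) {
      L <- mouse(db$ligand_human[i]); R <- mouse(db$receptor_human[i])
      if (!(R %in% rc)) next
      srcs <- if (L %in% c("L1", "L2")) "exogenous_cytokine" else
        names(lig_called)[vapply(lig_called, function(s) L %in% s,
                                 logical(1))]
      if (!length(srcs)) next
      want[[length(want) + 1]] <- data.frame(
        ligand_mouse = L, receptor_mouse = R,
        ligand_sources = paste(srcs, collapse = ";"),
        receptor_population = pop, receptor_pseudotime = "not_tested",
        supportive_enriched = L %in% sup, stringsAsFactors = FALSE)
    }
  }
  want <- do.call(rbind, want)
  rownames(want) <- NULL
  expect_equal(atlas, want)
  # atlas is a subset of the database
  key <- paste(atlas$ligand_mouse, atlas$receptor_mouse)
  dbkey <- paste(mouse(db$ligand_human), mouse(db$receptor_human))
  expect_true(all(key %in% dbkey))
})

test_that("atlas thresholds are elementwise monotone", {
  cfg <- small_sim_config(seed = 61)
  sim <- simulate_counts(cfg)
  niche <- simulate_niche_panel(cfg)
  db <- make_toy_lr_db(cfg)$db
  lab <- sample_labels(niche$counts)
  types <- sim$truth$cells$cell_type
  atlas_at <- function(lt, rt) {
    lig <- list(
      primary_arterial_EC = call_expressed(sim$counts,
                                           types == "arterial_EC", lt),
      cultured_AGM_EC = lapply(unique(lab[niche$supportive]), function(p)
        call_expressed(niche$counts, lab == p, lt)))
    rec <- list(HSC_precursor = call_expressed(
      sim$counts, types %in% c("HE", "pre_HSC"), rt))
    a <- build_interactome(lig, rec, db, exogenous = character())
    paste(a$ligand_mouse, a$receptor_mouse, a$receptor_population)
  }
  base <- atlas_at(0.10, 0.05)
  for (g in list(c(0.10, 0.20), c(0.25, 0.05), c(0.3, 0.3)))
    expect_true(all(atlas_at(g[1], g[2]) %in% base))
})

test_that("supportive-ligand DE recovers planted enrichment, one-directional", {
  cfg <- small_sim_config(seed = 67, niche_n_cells = 300L)
  panel <- simulate_niche_panel(cfg)
  de <- supportive_de_ligands(panel$counts, panel$supportive)
  expect_true(all(panel$truth$gene %in% de$gene[de$enriched]))
  # genes higher in non-supportive cells are never flagged
  expect_false(any(de$enriched & de$log2_fold_change <= 0))
  expect_error(supportive_de_ligands(panel$counts, rep(TRUE,
                                                       ncol(panel$counts))),
               "non-supportive")
  # null panel: flags at most ~5% of genes
  cfg0 <- small_sim_config(seed = 71, n_supportive_de = 0L)
  p0 <- simulate_niche_panel(cfg0)
  de0 <- supportive_de_ligands(p0$counts, p0$supportive)
  expect_lte(mean(de0$enriched), 0.05)
})
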