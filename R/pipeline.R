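# Configuration-driven end-to-end run: simulate -> normalize -> score ->
# classify -> trajectory -> markers -> interactome -> cfc. Stages exchange
# data through files in the output directory, so each enabled stage checks
# that its upstream outputs exist; a run manifest records config hash,
# output checksums and wall-clock per stage.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "pipeline_out",
    stages = list(simulate = TRUE, normalize = TRUE, score = TRUE,
                  classify = TRUE, trajectory = TRUE, markers = TRUE,
                  interactome = TRUE, cfc = TRUE),
    simulation = list(n_genes = 200L, n_cells_per_type = 125L,
                      nb_dispersion = 10, size_factor_sigma = 0.3,
                      niche_n_cells = 300L, n_supportive = 3L,
                      supportive_lfc = 2, n_planted_lr_pairs = 8L,
                      n_decoy_pairs = 5L),
    classification = list(detect_min = 1),
    trajectory = list(n_pcs = 10L, k_neighbors = 15L, resolution = 1,
                      dispersion_quantile = 0.75, min_detect_frac = 0.05,
                      q_max = 0.01, n_permutations = 999L, n_centers = 10L),
    markers = list(morans_min = 0.25, specificity_min = 0.75),
    interactome = list(ligand_threshold = 0.10,
                       precursor_receptor_threshold = 0.05,
                       hsc_receptor_threshold = 0.20,
                       exogenous = c("Il3", "Kitl", "Thpo"),
                       supportive_rule = "all",
                       supportive_q_max = 0.05),
    cfc = list(n_wells = 480L, p_hsc_cfc = 0.05, p_non_hsc_cfc = 0.25,
               embryo_equivalents = 10, fraction_sorted = 0.25,
               stage_tag = "E10-E11"))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), merges it over the
#' documented defaults, and collects every validation error at once:
#' unknown keys, out-of-range thresholds, and inter-stage dependency
#' violations (e.g. interactome enabled without trajectory).
#'
#' @param config Path to a YAML file, or a (possibly partial) config list.
#' @return A validated `pipeline_config` list, or an error listing all
#'   problems.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- pipeline_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, paste0("unknown key: ", unknown))
  merged <- defaults
  for (k in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[k]])) {
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(bad))
        errors <- c(errors, paste0("unknown key: ", k, ".", bad))
      for (kk in intersect(names(config[[k]]), names(defaults[[k]])))
        merged[[k]][[kk]] <- config[[k]][[kk]]
    } else merged[[k]] <- config[[k]]
  }
  thr <- merged$interactome
  for (t in c("ligand_threshold", "precursor_receptor_threshold",
              "hsc_receptor_threshold"))
    if (!is.numeric(thr[[t]]) || thr[[t]] < 0 || thr[[t]] > 1)
      errors <- c(errors, paste0("interactome.", t, " must be in [0, 1]"))
  if (!merged$interactome$supportive_rule %in% c("all", "any"))
    errors <- c(errors, "interactome.supportive_rule must be 'all' or 'any'")
  if (merged$cfc$p_hsc_cfc < 0 || merged$cfc$p_non_hsc_cfc < 0 ||
      merged$cfc$p_hsc_cfc + merged$cfc$p_non_hsc_cfc > 1)
    errors <- c(errors, "cfc outcome probabilities invalid")
  if (merged$cfc$fraction_sorted <= 0 || merged$cfc$fraction_sorted > 1)
    errors <- c(errors, "cfc.fraction_sorted must be in (0, 1]")
  if (!is.numeric(merged$seed) || merged$seed != round(merged$seed))
    errors <- c(errors, "seed must be an integer")
  st <- merged$stages
  if (isTRUE(st$interactome) && !isTRUE(st$trajectory))
    errors <- c(errors,
                paste0("dependency error: interactome's pseudotime ",
                       "annotation requires the trajectory stage"))
  if (isTRUE(st$markers) && !isTRUE(st$trajectory))
    errors <- c(errors, "dependency error: markers requires trajectory")
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "pipeline_config")
}

pipeline_paths <- function(cfg) {
  d <- cfg$out_dir
  list(dir = d,
       counts_mtx = file.path(d, "matrix.mtx"),
       niche_mtx = file.path(d, "niche_matrix.mtx"),
       truth_cells = file.path(d, "truth_cells.csv"),
       truth_genes = file.path(d, "truth_genes.csv"),
       truth_pairs = file.path(d, "truth_lr_pairs.csv"),
       niche_labels = file.path(d, "niche_labels.csv"),
       lr_db = file.path(d, "lr_database.tsv"),
       clone_table = file.path(d, "clone_table.csv"),
       cell_table = file.path(d, "cell_table.csv"),
       scores = file.path(d, "scores.csv"),
       types = file.path(d, "cell_types.csv"),
       embedding = file.path(d, "embedding.csv"),
       trajectory = file.path(d, "trajectory.csv"),
       traj_de = file.path(d, "trajectory_de.csv"),
       markers = file.path(d, "cluster_markers.csv"),
       supportive_de = file.path(d, "supportive_de.csv"),
       atlas = file.path(d, "interactome_atlas.csv"),
       cfc = file.path(d, "cfc_summary.csv"),
       manifest = file.path(d, "manifest.csv"))
}

require_inputs <- function(stage, paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("dependency error: stage '", stage, "' needs missing input(s): ",
         paste(missing, collapse = ", "))
}

read_counts_dir <- function(dir, prefix = "") {
  read_count_matrix(file.path(dir, paste0(prefix, "matrix.mtx")),
                    file.path(dir, paste0(prefix, "features.tsv")),
                    file.path(dir, paste0(prefix, "barcodes.tsv")))
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order, writing all outputs as
#' headered CSV/TSV/MTX under `config$out_dir`, and returns (and writes) a
#' run manifest with the config hash, per-output MD5 checksums and
#' wall-clock seconds per stage. With fixed seeds two runs produce
#' byte-identical outputs; completed stages are skipped on re-run unless
#' `force = TRUE`.
#'
#' @param config A `pipeline_config` ([validate_config()]), a path to a YAML
#'   config, or a partial config list.
#' @param force Re-run stages whose outputs already exist.
#' @return data.frame manifest (invisibly written to `manifest.csv`).
#' @export
run_pipeline <- function(config = list(), force = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  p <- pipeline_paths(cfg)
  dir.create(p$dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  stage_outputs <- list(
    simulate = c(p$counts_mtx, p$niche_mtx, p$truth_cells, p$truth_genes,
                 p$truth_pairs, p$niche_labels, p$lr_db, p$clone_table),
    normalize = p$cell_table,
    score = p$scores,
    classify = p$types,
    trajectory = c(p$embedding, p$trajectory, p$traj_de),
    markers = p$markers,
    interactome = c(p$supportive_de, p$atlas),
    cfc = p$cfc)
  run_stage <- function(name, inputs, fun) {
    if (!isTRUE(cfg$stages[[name]]))
      return(invisible(NULL))
    outs <- stage_outputs[[name]]
    if (!force && all(file.exists(outs))) {
      manifest[[name]] <<- data.frame(stage = name, file = basename(outs),
                                      md5 = unname(tools::md5sum(outs)),
                                      seconds = 0, skipped = TRUE,
                                      stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    require_inputs(name, inputs)
    t0 <- proc.time()["elapsed"]
    ok <- tryCatch({fun(); TRUE},
                   error = function(e)
                     stop("stage '", name, "' failed: ",
                          conditionMessage(e), call. = FALSE))
    el <- as.numeric(proc.time()["elapsed"] - t0)
    manifest[[name]] <<- data.frame(stage = name, file = basename(outs),
                                    md5 = unname(tools::md5sum(outs)),
                                    seconds = round(el, 3), skipped = FALSE,
                                    stringsAsFactors = FALSE)
    invisible(NULL)
  }

  scfg <- do.call(sim_config, c(list(seed = cfg$seed),
                                cfg$simulation[setdiff(names(cfg$simulation),
                                                       "n_decoy_pairs")]))

  run_stage("simulate", character(), function() {
    sim <- simulate_counts(scfg)
    write_count_matrix(sim$counts, p$dir)
    niche <- simulate_niche_panel(scfg)
    write_count_matrix(niche$counts, p$dir, prefix = "niche_")
    write_table_csv(sim$truth$cells, p$truth_cells)
    write_table_csv(sim$truth$genes, p$truth_genes)
    write_table_csv(sim$truth$lr_pairs, p$truth_pairs)
    write_table_csv(data.frame(barcode = colnames(niche$counts),
                               population = sample_labels(niche$counts),
                               supportive = niche$supportive),
                    p$niche_labels)
    db <- make_toy_lr_db(scfg, cfg$simulation$n_decoy_pairs)
    write_lr_database(db$db, p$lr_db)
    ct <- simulate_clone_table(cfg$cfc$n_wells, cfg$cfc$p_hsc_cfc,
                               cfg$cfc$p_non_hsc_cfc,
                               cfg$cfc$embryo_equivalents,
                               cfg$cfc$fraction_sorted,
                               seed = cfg$seed,
                               stage = cfg$cfc$stage_tag)
    ct$embryo_equivalents <- attr(ct, "embryo_equivalents")
    ct$fraction_sorted <- attr(ct, "fraction_sorted")
    write_table_csv(ct, p$clone_table)
  })

  run_stage("normalize", p$counts_mtx, function() {
    counts <- read_counts_dir(p$dir)
    sf <- compute_size_factors(counts)
    qc <- qc_summary(counts)
    tab <- qc$cells
    tab$size_factor <- as.numeric(sf[tab$barcode])
    write_table_csv(tab, p$cell_table)
  })

  run_stage("score", c(p$counts_mtx, p$cell_table), function() {
    counts <- read_counts_dir(p$dir)
    tab <- read_table_csv(p$cell_table)
    norm <- normalize_counts(counts, tab$size_factor)
    sets <- lapply(scfg$genes$markers, identity)
    names(sets) <- paste0(names(sets), "_signature")
    write_table_csv(score_table(norm, sets), p$scores)
  })

  run_stage("classify", p$counts_mtx, function() {
    counts <- read_counts_dir(p$dir)
    types <- classify_cells(counts, sim_marker_rules(scfg),
                            detect_min = cfg$classification$detect_min)
    write_table_csv(types, p$types)
  })

  run_stage("trajectory", c(p$counts_mtx, p$cell_table, p$scores), function() {
    counts <- read_counts_dir(p$dir)
    tab <- read_table_csv(p$cell_table)
    norm <- normalize_counts(counts, tab$size_factor)
    genes <- select_genes_by_dispersion(
      norm, dispersion_quantile = cfg$trajectory$dispersion_quantile)
    emb <- embed_cells(norm, genes, n_pcs = cfg$trajectory$n_pcs,
                       seed = cfg$seed)
    clusters <- cluster_cells(emb, k_neighbors = cfg$trajectory$k_neighbors,
                              resolution = cfg$trajectory$resolution,
                              seed = cfg$seed)
    scores <- read_table_csv(p$scores)
    root_col <- grep("arterial", names(scores), value = TRUE)[1]
    traj <- learn_pseudotime(emb, root_score = scores[[root_col]],
                             n_centers = cfg$trajectory$n_centers,
                             seed = cfg$seed)
    graph <- knn_graph(emb, k = cfg$trajectory$k_neighbors)
    de <- trajectory_de(counts, norm, graph, traj$pseudotime,
                        min_detect_frac = cfg$trajectory$min_detect_frac,
                        q_max = cfg$trajectory$q_max,
                        n_permutations = cfg$trajectory$n_permutations,
                        seed = cfg$seed)
    emb_df <- data.frame(barcode = rownames(emb), emb, row.names = NULL)
    write_table_csv(emb_df, p$embedding)
    write_table_csv(data.frame(barcode = names(traj$pseudotime),
                               cluster = as.integer(clusters),
                               pseudotime = as.numeric(traj$pseudotime)),
                    p$trajectory)
    write_table_csv(de, p$traj_de)
  })

  run_stage("markers", c(p$counts_mtx, p$cell_table, p$embedding,
                         p$trajectory), function() {
    counts <- read_counts_dir(p$dir)
    tab <- read_table_csv(p$cell_table)
    norm <- normalize_counts(counts, tab$size_factor)
    emb_df <- read_table_csv(p$embedding)
    emb <- as.matrix(emb_df[, -1, drop = FALSE])
    rownames(emb) <- emb_df$barcode
    tr <- read_table_csv(p$trajectory)
    graph <- knn_graph(emb, k = cfg$trajectory$k_neighbors)
    mk <- cluster_markers(counts, norm, graph, tr$cluster,
                          morans_min = cfg$markers$morans_min,
                          specificity_min = cfg$markers$specificity_min)
    write_table_csv(mk, p$markers)
  })

  run_stage("interactome", c(p$counts_mtx, p$niche_mtx, p$types,
                             p$niche_labels, p$lr_db, p$traj_de,
                             p$trajectory), function() {
    counts <- read_counts_dir(p$dir)
    niche <- read_counts_dir(p$dir, prefix = "niche_")
    types <- read_table_csv(p$types)
    nl <- read_table_csv(p$niche_labels)
    db <- read_lr_database(p$lr_db)
    de <- read_table_csv(p$traj_de)
    tr <- read_table_csv(p$trajectory)
    # ligand sources: arterial EC cells in the primary data; each
    # supportive AGM-EC line separately (all-of rule by default)
    arterial <- types$cell_type == "arterial_EC"
    lig_thr <- cfg$interactome$ligand_threshold
    sup_pops <- unique(nl$population[nl$supportive])
    lig_sources <- list(
      primary_arterial_EC = call_expressed(counts, arterial, lig_thr),
      cultured_AGM_EC = lapply(sup_pops, function(pp)
        call_expressed(niche, nl$population == pp, lig_thr)))
    precursor <- types$cell_type %in% c("HE", "pre_HSC")
    rec_calls <- list(
      HSC_precursor = call_expressed(
        counts, precursor, cfg$interactome$precursor_receptor_threshold))
    # pseudotime categories for significant receptors in the precursor mask
    tab <- read_table_csv(p$cell_table)
    norm <- normalize_counts(counts, tab$size_factor)
    sig <- de$gene[de$significant]
    ptcat <- vapply(sig, function(g)
      pseudotime_enrichment(g, norm, tr$pseudotime, precursor,
                            significant = TRUE), character(1))
    sup_de <- supportive_de_ligands(niche, nl$supportive,
                                    q_max = cfg$interactome$supportive_q_max)
    write_table_csv(sup_de, p$supportive_de)
    atlas <- build_interactome(
      lig_sources, rec_calls, db,
      exogenous = cfg$interactome$exogenous,
      supportive_de_genes = sup_de$gene[sup_de$enriched],
      pseudotime_categories = list(HSC_precursor = ptcat),
      supportive_rule = cfg$interactome$supportive_rule)
    write_table_csv(atlas, p$atlas)
  })

  run_stage("cfc", p$clone_table, function() {
    ct <- read_table_csv(p$clone_table)
    out <- cfc_frequencies_by_stage(ct)
    out$hsc_cfc_per_agm <- vapply(seq_len(nrow(out)), function(i)
      cfc_per_agm(round(out$pct_hsc_cfc[i] / 100 * out$n_wells[i]),
                  ct$embryo_equivalents[1], ct$fraction_sorted[1]),
      numeric(1))
    write_table_csv(out, p$cfc)
  })

  man <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(stage = character(), file = character(), md5 = character(),
               seconds = numeric(), skipped = logical())
  man <- cbind(config_hash = config_hash(cfg), man)
  rownames(man) <- NULL
  write_table_csv(man, p$manifest)
  invisible(man)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}
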