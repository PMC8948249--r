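# Deterministic scRNA-seq simulator with planted ground truth.
#
# Counts are negative binomial with fixed (shared) dispersion theta and
# variance mu + mu^2/theta; per-cell size-factor variation is log-normal.
# Dropout is implicit in NB sampling (no extra zero inflation). Discrete cell
# types are defined by marker-gene detection patterns; trajectory types
# occupy contiguous sub-intervals of a latent maturation time t in [0,1]
# that drives monotone expression gradients.

#' Simulation configuration
#'
#' Builds the declarative configuration consumed by [simulate_counts()],
#' [simulate_niche_panel()] and [make_toy_lr_db()]. Defaults define the
#' package's reference fixture: four trajectory populations (arterial EC ->
#' hemogenic endothelium -> pre-HSC -> progenitor, 125 cells each, 500 cells
#' total) over a 200-gene universe containing type markers, monotone
#' trajectory genes, receptors detectable in HSC-precursor populations,
#' niche ligands, pan-endothelial markers and null background genes.
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output
#'   (R's default Mersenne-Twister integer stream).
#' @param n_genes Total gene universe size (>= the structured genes).
#' @param n_cells_per_type Cells simulated per cell type.
#' @param nb_dispersion NB dispersion theta (variance mu + mu^2/theta);
#'   shared across genes.
#' @param size_factor_sigma Log-normal sigma of per-cell size factors.
#' @param cell_types Optional list of type specs (name, n_cells, markers,
#'   t_interval or NULL, receptor_mean). Defaults to the four trajectory
#'   populations; see [colony_cell_types()] for the in vitro HSC/HPC panel.
#' @param n_markers_per_type,marker_mean,marker_offtype_mean Marker-gene
#'   block: own-type mean gives >= 90\% detection, off-type mean <= 2\%.
#' @param baseline_mean Mean scale of null background genes.
#' @param n_trajectory_genes_up,n_trajectory_genes_down,trajectory_fold,trajectory_peak_mean
#'   Monotone activation/deactivation genes: increasing genes have
#'   mean(t) = trajectory_peak_mean * fold^(t - 1) (near-silent early, peak
#'   late), decreasing genes the mirror image. The default 30-fold
#'   silent-to-high span mirrors hematopoietic fate genes switching on (and
#'   endothelial genes switching off) across the endothelial-to-hematopoietic
#'   transition, and satisfies the >= 2x planted effect-size convention.
#' @param n_receptors,receptor_mean Receptor genes expressed (at
#'   `receptor_mean`) in types whose spec sets `receptor_mean`.
#' @param n_ligands,ligand_mean,n_silent_ligands Ligand genes expressed in
#'   the niche panel; the last `n_silent_ligands` stay near zero there to
#'   exercise the detection threshold.
#' @param n_pan_ec,pan_ec_mean Pan-endothelial markers detected in every
#'   niche population.
#' @param niche_n_cells,n_supportive Niche panel: cells per population and
#'   number of HSC-supportive lines (plus one non-supportive line).
#' @param supportive_lfc,n_supportive_de log2 fold-change and number of
#'   ligand genes planted as up-regulated in all supportive lines.
#' @param n_planted_lr_pairs Number of true ligand-receptor pairs
#'   (Lig_i, Rcp_i) planted in the toy database.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_cells_per_type = 125L,
                       nb_dispersion = 10,
                       size_factor_sigma = 0.3,
                       cell_types = NULL,
                       n_markers_per_type = 10L,
                       marker_mean = 8,
                       marker_offtype_mean = 0.005,
                       baseline_mean = 0.5,
                       n_trajectory_genes_up = 20L,
                       n_trajectory_genes_down = 20L,
                       trajectory_fold = 30,
                       trajectory_peak_mean = 6,
                       n_receptors = 20L,
                       receptor_mean = 1.5,
                       n_ligands = 20L,
                       ligand_mean = 2,
                       n_silent_ligands = 5L,
                       n_pan_ec = 5L,
                       pan_ec_mean = 8,
                       niche_n_cells = 300L,
                       n_supportive = 3L,
                       supportive_lfc = 2,
                       n_supportive_de = 5L,
                       n_planted_lr_pairs = 8L) {
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (size_factor_sigma < 0) stop("size_factor_sigma must be non-negative")
  if (n_supportive < 1) stop("need at least one supportive population")
  if (is.null(cell_types))
    cell_types <- trajectory_cell_types(n_cells_per_type, receptor_mean)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              nb_dispersion = nb_dispersion,
              size_factor_sigma = size_factor_sigma,
              cell_types = cell_types,
              n_markers_per_type = as.integer(n_markers_per_type),
              marker_mean = marker_mean,
              marker_offtype_mean = marker_offtype_mean,
              baseline_mean = baseline_mean,
              n_trajectory_genes_up = as.integer(n_trajectory_genes_up),
              n_trajectory_genes_down = as.integer(n_trajectory_genes_down),
              trajectory_fold = trajectory_fold,
              trajectory_peak_mean = trajectory_peak_mean,
              n_receptors = as.integer(n_receptors),
              receptor_mean = receptor_mean,
              n_ligands = as.integer(n_ligands), ligand_mean = ligand_mean,
              n_silent_ligands = as.integer(n_silent_ligands),
              n_pan_ec = as.integer(n_pan_ec), pan_ec_mean = pan_ec_mean,
              niche_n_cells = as.integer(niche_n_cells),
              n_supportive = as.integer(n_supportive),
              supportive_lfc = supportive_lfc,
              n_supportive_de = as.integer(n_supportive_de),
              n_planted_lr_pairs = as.integer(n_planted_lr_pairs))
  cfg$genes <- build_gene_universe(cfg)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default trajectory cell types
#'
#' Arterial EC, hemogenic endothelium (HE), pre-HSC and progenitor occupy
#' contiguous quarters of the latent maturation time; HE and pre-HSC (the
#' HSC-precursor populations) express the receptor block.
#'
#' @param n_cells_per_type Cells per population.
#' @param receptor_mean NB mean of receptor genes in receptor-bearing types.
#' @export
trajectory_cell_types <- function(n_cells_per_type = 125L,
                                  receptor_mean = 1.5) {
  list(
    list(name = "arterial_EC", n_cells = n_cells_per_type,
         t_interval = c(0, 0.25), receptor_mean = 0.01,
         endothelial = TRUE),
    list(name = "HE", n_cells = n_cells_per_type,
         t_interval = c(0.25, 0.5), receptor_mean = receptor_mean),
    list(name = "pre_HSC", n_cells = n_cells_per_type,
         t_interval = c(0.5, 0.75), receptor_mean = receptor_mean),
    list(name = "progenitor", n_cells = n_cells_per_type,
         t_interval = c(0.75, 1), receptor_mean = 0.01))
}

#' In vitro colony cell types (HSC differentiating to HPC)
#'
#' Two populations along a differentiation pseudotime; receptors are
#' detectable in the HSC population (>= 20\% of cells), mirroring the
#' co-culture colony data used for the in vitro arm of the interactome.
#'
#' @param n_cells_per_type Cells per population.
#' @param receptor_mean NB mean of receptor genes in the HSC population.
#' @export
colony_cell_types <- function(n_cells_per_type = 125L, receptor_mean = 2) {
  list(
    list(name = "HSC", n_cells = n_cells_per_type,
         t_interval = c(0, 0.5), receptor_mean = receptor_mean),
    list(name = "HPC", n_cells = n_cells_per_type,
         t_interval = c(0.5, 1), receptor_mean = 0.05))
}

build_gene_universe <- function(cfg) {
  types <- vapply(cfg$cell_types, `[[`, character(1), "name")
  markers <- lapply(types, function(ty)
    sprintf("Mk%s%02d", gsub("[^A-Za-z]", "", tolower(ty)),
            seq_len(cfg$n_markers_per_type)))
  names(markers) <- types
  up <- sprintf("Tup%02d", seq_len(cfg$n_trajectory_genes_up))
  dn <- sprintf("Tdn%02d", seq_len(cfg$n_trajectory_genes_down))
  rcp <- sprintf("Rcp%02d", seq_len(cfg$n_receptors))
  lig <- sprintf("Lig%02d", seq_len(cfg$n_ligands))
  pan <- sprintf("Panec%02d", seq_len(cfg$n_pan_ec))
  n_struct <- length(unlist(markers)) + length(up) + length(dn) +
    length(rcp) + length(lig) + length(pan)
  if (cfg$n_genes < n_struct + 10)
    stop("n_genes too small for the structured gene blocks (need >= ",
         n_struct + 10, ")")
  bgd <- sprintf("Bgd%03d", seq_len(cfg$n_genes - n_struct))
  list(markers = markers, traj_up = up, traj_down = dn, receptors = rcp,
       ligands = lig, pan_ec = pan, background = bgd,
       all = c(unlist(markers, use.names = FALSE), up, dn, rcp, lig, pan, bgd))
}

validate_sim_config <- function(cfg) {
  for (ty in cfg$cell_types) {
    own <- cfg$genes$markers[[ty$name]]
    other <- setdiff(unlist(cfg$genes$markers, use.names = FALSE), own)
    if (length(intersect(own, other)))
      stop("config error: marker and forbidden sets overlap for type ",
           ty$name)
  }
  if (cfg$n_silent_ligands >= cfg$n_ligands)
    stop("config error: all ligands silent")
  if (cfg$n_planted_lr_pairs >
      min(cfg$n_ligands - cfg$n_silent_ligands, cfg$n_receptors))
    stop("config error: not enough expressed ligands/receptors for planted pairs")
  invisible(cfg)
}

# Per-gene NB mean for one cell of a given type at latent time t (NA for
# types without a time interval).
mean_profile <- function(cfg, type_spec, t, base_bgd) {
  g <- cfg$genes
  mu <- stats::setNames(rep(cfg$marker_offtype_mean, length(g$all)), g$all)
  mu[g$background] <- base_bgd
  mu[g$markers[[type_spec$name]]] <- cfg$marker_mean
  tt <- if (is.na(t)) 0.5 else t
  mu[g$traj_up] <- cfg$trajectory_peak_mean * cfg$trajectory_fold^(tt - 1)
  mu[g$traj_down] <- cfg$trajectory_peak_mean * cfg$trajectory_fold^(-tt)
  mu[g$receptors] <- type_spec$receptor_mean
  # niche ligands and pan-EC genes: silent in hematopoietic cells, expressed
  # in endothelial types (primary arterial EC is itself a ligand source)
  mu[g$ligands] <- 0.01
  mu[g$pan_ec] <- 0.01
  if (isTRUE(type_spec$endothelial)) {
    expressed <- g$ligands[seq_len(cfg$n_ligands - cfg$n_silent_ligands)]
    mu[expressed] <- cfg$ligand_mean
    mu[g$pan_ec] <- cfg$pan_ec_mean
  }
  mu
}

#' Simulate a UMI count matrix with planted ground truth
#'
#' Draws `counts ~ NB(mean = size_factor(c) * mu(g, type(c), t(c)),
#' dispersion = theta)`. Marker genes are detected in >= 90\% of own-type
#' cells and <= 2\% elsewhere in expectation; trajectory genes have means
#' monotone in the latent time t.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a `CountMatrix`) and `truth` (per-cell type,
#'   latent time and size factor; per-gene role, trajectory sign and marker
#'   assignment; planted LR pairs; supportive-enriched ligand list).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$genes
  base_bgd <- stats::setNames(
    config$baseline_mean * exp(stats::rnorm(length(g$background), 0, 0.3)),
    g$background)
  cells <- do.call(rbind, lapply(config$cell_types, function(ty) {
    t <- if (is.null(ty$t_interval)) rep(NA_real_, ty$n_cells) else
      stats::runif(ty$n_cells, ty$t_interval[1], ty$t_interval[2])
    data.frame(cell_type = ty$name, latent_time = t,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(cells)
  cells$barcode <- sprintf("cell%04d", seq_len(n))
  cells$size_factor <- exp(stats::rnorm(n, 0, config$size_factor_sigma))
  type_specs <- stats::setNames(config$cell_types,
                                vapply(config$cell_types, `[[`,
                                       character(1), "name"))
  counts <- matrix(0L, nrow = length(g$all), ncol = n,
                   dimnames = list(g$all, cells$barcode))
  for (i in seq_len(n)) {
    mu <- mean_profile(config, type_specs[[cells$cell_type[i]]],
                       cells$latent_time[i], base_bgd)
    counts[, i] <- stats::rnbinom(length(mu),
                                  mu = cells$size_factor[i] * mu,
                                  size = config$nb_dispersion)
  }
  expressed_lig <- g$ligands[seq_len(config$n_ligands - config$n_silent_ligands)]
  planted <- data.frame(
    ligand = expressed_lig[seq_len(config$n_planted_lr_pairs)],
    receptor = g$receptors[seq_len(config$n_planted_lr_pairs)],
    stringsAsFactors = FALSE)
  genes <- data.frame(gene = g$all, stringsAsFactors = FALSE)
  genes$role <- "background"
  genes$role[genes$gene %in% unlist(g$markers)] <- "marker"
  genes$role[genes$gene %in% g$traj_up] <- "trajectory"
  genes$role[genes$gene %in% g$traj_down] <- "trajectory"
  genes$role[genes$gene %in% g$receptors] <- "receptor"
  genes$role[genes$gene %in% g$ligands] <- "ligand"
  genes$role[genes$gene %in% g$pan_ec] <- "pan_EC"
  genes$trajectory_sign <- ifelse(genes$gene %in% g$traj_up, 1L,
                                  ifelse(genes$gene %in% g$traj_down, -1L, 0L))
  genes$marker_of <- NA_character_
  for (ty in names(g$markers))
    genes$marker_of[genes$gene %in% g$markers[[ty]]] <- ty
  truth <- list(cells = cells[c("barcode", "cell_type", "latent_time",
                                "size_factor")],
                genes = genes,
                lr_pairs = planted,
                supportive_ligands =
                  g$ligands[seq_len(config$n_supportive_de)])
  cm <- count_matrix(counts, sample_labels = cells$cell_type)
  list(counts = cm, truth = truth)
}

#' Simulate the niche endothelial-cell panel
#'
#' Generates `n_supportive` HSC-supportive AGM-EC populations plus one
#' non-supportive line over the same gene universe as [simulate_counts()].
#' All populations express the pan-EC marker block and the ligand block; the
#' planted supportive-enriched ligands are up-regulated (configured log2
#' fold-change) in every supportive line.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a `CountMatrix` whose `sample_labels` are the
#'   population names), `supportive` (logical per cell) and `truth` (planted
#'   DE ligand table with log2 fold-changes).
#' @export
simulate_niche_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  g <- config$genes
  pops <- c(paste0("AGM_EC_", seq_len(config$n_supportive)),
            "non_supportive_EC")
  supportive_pop <- c(rep(TRUE, config$n_supportive), FALSE)
  de_lig <- g$ligands[seq_len(config$n_supportive_de)]
  expressed_lig <- g$ligands[seq_len(config$n_ligands - config$n_silent_ligands)]
  base_bgd <- stats::setNames(
    config$baseline_mean * exp(stats::rnorm(length(g$background), 0, 0.3)),
    g$background)
  mu0 <- stats::setNames(rep(0.01, length(g$all)), g$all)
  mu0[g$background] <- base_bgd
  mu0[g$pan_ec] <- config$pan_ec_mean
  mu0[expressed_lig] <- config$ligand_mean
  counts <- NULL
  labels <- character()
  for (p in seq_along(pops)) {
    mu <- mu0
    if (supportive_pop[p]) mu[de_lig] <- mu[de_lig] * 2^config$supportive_lfc
    sf <- exp(stats::rnorm(config$niche_n_cells, 0, config$size_factor_sigma))
    block <- vapply(sf, function(s)
      stats::rnbinom(length(mu), mu = s * mu, size = config$nb_dispersion),
      numeric(length(mu)))
    counts <- cbind(counts, block)
    labels <- c(labels, rep(pops[p], config$niche_n_cells))
  }
  rownames(counts) <- g$all
  colnames(counts) <- sprintf("ec%04d", seq_len(ncol(counts)))
  cm <- count_matrix(counts, sample_labels = labels)
  list(counts = cm,
       supportive = labels %in% pops[supportive_pop],
       truth = data.frame(gene = de_lig,
                          log2_fold_change = rep(config$supportive_lfc,
                                                 length(de_lig)),
                          stringsAsFactors = FALSE))
}

#' Simulate a clonal index-sort outcome table
#'
#' Each well holds one sorted cell whose outcome is multinomial over
#' HSC_CFC / non_HSC_CFC / no_colony.
#'
#' @param n_wells Number of wells (sorted single cells).
#' @param p_hsc_cfc,p_non_hsc_cfc Outcome probabilities (sum <= 1).
#' @param embryo_equivalents Embryo equivalents sorted across the experiment.
#' @param fraction_sorted Fraction of gated cells actually index-sorted,
#'   in (0, 1].
#' @param seed Integer RNG seed.
#' @param stage Somite-pair range tag (default "E10-E11").
#' @return data.frame (well_id, stage, outcome) with attributes
#'   `embryo_equivalents` and `fraction_sorted`.
#' @export
simulate_clone_table <- function(n_wells, p_hsc_cfc, p_non_hsc_cfc,
                                 embryo_equivalents, fraction_sorted,
                                 seed = 1L, stage = "E10-E11") {
  if (p_hsc_cfc < 0 || p_non_hsc_cfc < 0 || p_hsc_cfc + p_non_hsc_cfc > 1)
    stop("invalid outcome probabilities")
  if (fraction_sorted <= 0 || fraction_sorted > 1)
    stop("fraction_sorted must be in (0, 1]")
  if (embryo_equivalents <= 0) stop("embryo_equivalents must be positive")
  set.seed(seed)
  outcome <- sample(c("HSC_CFC", "non_HSC_CFC", "no_colony"), n_wells,
                    replace = TRUE,
                    prob = c(p_hsc_cfc, p_non_hsc_cfc,
                             1 - p_hsc_cfc - p_non_hsc_cfc))
  structure(data.frame(well_id = sprintf("well%05d", seq_len(n_wells)),
                       stage = stage, outcome = outcome,
                       stringsAsFactors = FALSE),
            embryo_equivalents = embryo_equivalents,
            fraction_sorted = fraction_sorted)
}

#' Build a toy ligand-receptor database with known truth
#'
#' True pairs are the planted (ligand, receptor) pairs of the simulation,
#' uppercased to human-style symbols so the human-to-mouse mapping step is
#' exercised; decoy pairs use symbols absent from the gene universe.
#'
#' @param config A [sim_config()].
#' @param n_decoy_pairs Number of decoy pairs.
#' @return List with `db` (data.frame ligand_human / receptor_human /
#'   provenance) and `truth` (the planted mouse-symbol pairs).
#' @export
make_toy_lr_db <- function(config, n_decoy_pairs = 5L) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_counts_truth_only(config)
  planted <- sim$lr_pairs
  decoys <- data.frame(
    ligand_human = sprintf("DECOYLIG%d", seq_len(n_decoy_pairs)),
    receptor_human = sprintf("DECOYREC%d", seq_len(n_decoy_pairs)),
    stringsAsFactors = FALSE)
  db <- rbind(data.frame(ligand_human = toupper(planted$ligand),
                         receptor_human = toupper(planted$receptor),
                         stringsAsFactors = FALSE),
              decoys)
  db$provenance <- c(rep("planted", nrow(planted)),
                     rep("decoy", n_decoy_pairs))
  list(db = db, truth = planted)
}

# Ground-truth tables that do not require drawing counts.
simulate_counts_truth_only <- function(config) {
  g <- config$genes
  expressed_lig <- g$ligands[seq_len(config$n_ligands - config$n_silent_ligands)]
  list(lr_pairs = data.frame(
    ligand = expressed_lig[seq_len(config$n_planted_lr_pairs)],
    receptor = g$receptors[seq_len(config$n_planted_lr_pairs)],
    stringsAsFactors = FALSE),
    supportive_ligands = g$ligands[seq_len(config$n_supportive_de)])
}

#' Marker rules matching the simulated ground truth
#'
#' For each simulated cell type: two own markers required, the first marker
#' of every other type forbidden. Used by the end-to-end recovery harness.
#'
#' @param config A [sim_config()].
#' @param n_required Number of own markers in `required_all`.
#' @return List of [marker_rule()] objects.
#' @export
sim_marker_rules <- function(config, n_required = 2L) {
  g <- config$genes$markers
  lapply(names(g), function(ty) {
    marker_rule(ty,
                required_all = g[[ty]][seq_len(n_required)],
                forbidden = vapply(g[setdiff(names(g), ty)], `[`,
                                   character(1), 1))
  })
}
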