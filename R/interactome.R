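# The ligand-receptor atlas: detection-fraction expression calling per
# population, human-to-mouse symbol mapping, cross-reference against a
# ligand-receptor pair database, and categorical annotation of every called
# interaction (ligand sources, receptor population, pseudotime enrichment,
# supportive-niche enrichment).

#' Call expressed genes by detection fraction
#'
#' `detection_fraction = (# masked cells with UMI >= 1) / |mask|`; a gene is
#' called iff its fraction is >= `threshold` ("at least 10\%" and kin are
#' read as inclusive).
#'
#' @param counts A `CountMatrix`.
#' @param cell_mask Logical/index/character mask of cells (non-empty).
#' @param threshold Detection-fraction threshold in [0, 1].
#' @return data.frame: gene, detection_fraction, threshold, called.
#' @export
call_expressed <- function(counts, cell_mask, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  sub <- counts[, cell_mask, drop = FALSE]
  if (ncol(sub) == 0) stop("empty cell mask")
  frac <- as.numeric(Matrix::rowMeans(sub >= 1))
  data.frame(gene = rownames(counts), detection_fraction = frac,
             threshold = threshold,
             called = frac >= threshold & frac > 0,
             stringsAsFactors = FALSE)
}

#' Map human gene symbols to mouse
#'
#' Default rule: title case (first letter upper, rest lower), the implicit
#' correspondence used when crossing mouse expression data with a
#' human-symbol ligand-receptor database. Explicit overrides win; ambiguous
#' orthologs must be listed in the override table, never guessed.
#'
#' @param human_symbols Character vector.
#' @param override_table Optional data.frame with columns `human`, `mouse`.
#' @return data.frame: human, mouse, overridden.
#' @export
map_symbols <- function(human_symbols, override_table = NULL) {
  human_symbols <- as.character(human_symbols)
  mouse <- paste0(toupper(substr(human_symbols, 1, 1)),
                  tolower(substr(human_symbols, 2, nchar(human_symbols))))
  overridden <- rep(FALSE, length(mouse))
  if (!is.null(override_table)) {
    if (!all(c("human", "mouse") %in% names(override_table)))
      stop("override table needs 'human' and 'mouse' columns")
    hit <- match(human_symbols, override_table$human)
    overridden <- !is.na(hit)
    mouse[overridden] <- override_table$mouse[hit[overridden]]
  }
  data.frame(human = human_symbols, mouse = mouse, overridden = overridden,
             stringsAsFactors = FALSE)
}

#' Build the ligand-receptor interactome atlas
#'
#' A record exists for database pair (L, R), receptor population P, iff the
#' ligand is called in at least one ligand source (or is an exogenously
#' supplied cytokine) and the receptor is called in P. Ligand sources list
#' every qualifying source; a source given as a list of call tables (the
#' supportive AGM-EC lines) qualifies only when the ligand is called in all
#' of them (`supportive_rule = "all"`; "any" is the config switch).
#' Exogenous cytokines are flagged as source `exogenous_cytokine`,
#' exclusive of detection-based sources.
#'
#' @param ligand_calls_by_source Named list; each element a
#'   [call_expressed()] table or a list of such tables (all-of conjunction).
#'   Canonical names: `primary_arterial_EC`, `cultured_AGM_EC`.
#' @param receptor_calls_by_population Named list of [call_expressed()]
#'   tables; canonical names: `HSC_precursor`, `HSC`.
#' @param db Ligand-receptor database ([read_lr_database()]).
#' @param exogenous Mouse symbols of cytokines supplied in culture
#'   (default Il3, Kitl [SCF], Thpo [TPO]).
#' @param supportive_de_genes Mouse ligand symbols enriched in supportive vs
#'   non-supportive niche EC ([supportive_de_ligands()]).
#' @param pseudotime_categories Named list per receptor population of named
#'   character vectors gene -> "early"/"late"/"ns"; absent genes are
#'   "not_tested".
#' @param override_table Human-to-mouse overrides for [map_symbols()].
#' @param supportive_rule "all" (a multi-line source requires the ligand
#'   called in every line) or "any".
#' @return data.frame of interactome records: ligand_mouse, receptor_mouse,
#'   ligand_sources (semicolon list), receptor_population,
#'   receptor_pseudotime, supportive_enriched.
#' @export
build_interactome <- function(ligand_calls_by_source,
                              receptor_calls_by_population,
                              db,
                              exogenous = c("Il3", "Kitl", "Thpo"),
                              supportive_de_genes = character(),
                              pseudotime_categories = list(),
                              override_table = NULL,
                              supportive_rule = c("all", "any")) {
  supportive_rule <- match.arg(supportive_rule)
  known_pops <- c("HSC_precursor", "HSC")
  unknown <- setdiff(names(receptor_calls_by_population), known_pops)
  if (length(unknown))
    stop("unknown receptor population: ", paste(unknown, collapse = ", "))
  map <- map_symbols(unique(c(db$ligand_human, db$receptor_human)),
                     override_table)
  to_mouse <- stats::setNames(map$mouse, map$human)
  pairs <- data.frame(ligand_mouse = unname(to_mouse[db$ligand_human]),
                      receptor_mouse = unname(to_mouse[db$receptor_human]),
                      stringsAsFactors = FALSE)
  called_set <- function(tbl) tbl$gene[tbl$called]
  ligand_called <- lapply(ligand_calls_by_source, function(src) {
    if (is.data.frame(src)) return(called_set(src))
    sets <- lapply(src, called_set)
    if (supportive_rule == "all") Reduce(intersect, sets)
    else Reduce(union, sets)
  })
  receptor_called <- lapply(receptor_calls_by_population, called_set)
  records <- list()
  for (pop in names(receptor_called)) {
    rc <- receptor_called[[pop]]
    ptcat <- pseudotime_categories[[pop]]
    for (i in seq_len(nrow(pairs))) {
      lig <- pairs$ligand_mouse[i]; rec <- pairs$receptor_mouse[i]
      if (!rec %in% rc) next
      if (lig %in% exogenous) {
        sources <- "exogenous_cytokine"
      } else {
        sources <- names(ligand_called)[vapply(ligand_called, function(s)
          lig %in% s, logical(1))]
      }
      if (!length(sources)) next
      pt <- if (!is.null(ptcat) && rec %in% names(ptcat)) ptcat[[rec]]
            else "not_tested"
      records[[length(records) + 1]] <- data.frame(
        ligand_mouse = lig, receptor_mouse = rec,
        ligand_sources = paste(sources, collapse = ";"),
        receptor_population = pop,
        receptor_pseudotime = pt,
        supportive_enriched = lig %in% supportive_de_genes,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(ligand_mouse = character(), receptor_mouse = character(),
               ligand_sources = character(), receptor_population = character(),
               receptor_pseudotime = character(),
               supportive_enriched = logical(), stringsAsFactors = FALSE)
  # invariant: every output pair exists in the database (mouse namespace)
  if (nrow(out)) {
    key <- paste(out$ligand_mouse, out$receptor_mouse)
    dbkey <- paste(pairs$ligand_mouse, pairs$receptor_mouse)
    stopifnot(all(key %in% dbkey))
  }
  rownames(out) <- NULL
  out
}

#' Ligands enriched in HSC-supportive vs non-supportive niche EC
#'
#' Per-gene unpaired two-sided rank-sum test of pooled supportive cells
#' against non-supportive cells on size-factor-normalized expression, with a
#' log2 fold-change of means; a gene is flagged enriched iff its BH q-value
#' is < `q_max` and the fold-change is > 1 (supportive higher; genes higher
#' in non-supportive EC are never flagged).
#'
#' @param counts Niche-panel `CountMatrix`.
#' @param supportive Logical per cell (>= 1 TRUE and >= 1 FALSE).
#' @param norm Optional matching `NormalizedMatrix`.
#' @param q_max BH q-value cutoff (default 0.05).
#' @return data.frame: gene, log2_fold_change, p_value, q_value, enriched.
#' @export
supportive_de_ligands <- function(counts, supportive, norm = NULL,
                                  q_max = 0.05) {
  if (length(supportive) != ncol(counts))
    stop("need one supportive flag per cell")
  if (!any(supportive) || !any(!supportive))
    stop("need at least one supportive and one non-supportive cell")
  if (is.null(norm)) norm <- normalize_counts(counts)
  X <- as.matrix(norm)
  n1 <- sum(supportive); n2 <- sum(!supportive)
  res <- apply(X, 1, function(x) {
    if (stats::var(x) == 0) return(c(lfc = 0, p = 1))
    cmp <- compare_scores(x[supportive], x[!supportive])
    m1 <- mean(x[supportive]); m2 <- mean(x[!supportive])
    c(lfc = log2((m1 + 1e-9) / (m2 + 1e-9)), p = cmp$p_value)
  })
  lfc <- res["lfc", ]; p <- res["p", ]
  q <- bh_adjust(p)
  data.frame(gene = rownames(counts), log2_fold_change = as.numeric(lfc),
             p_value = as.numeric(p), q_value = as.numeric(q),
             enriched = q < q_max & lfc > 0,
             stringsAsFactors = FALSE)
}
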