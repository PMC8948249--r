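# Signature gene-set scoring and strict marker-logic cell-type
# classification. A cell is scored as the log-transformed sum of its
# size-factor-normalized expression over a signature gene set; it is
# classified as a type only by strict detection of the indicated marker
# genes (all required detected, at least one of any required-any group,
# none of the forbidden), leaving non-matching cells unclassified rather
# than imputing a type.

#' Per-cell gene-set score
#'
#' `score(c) = log(1 + sum over set members of normalized(g, c))`, natural
#' log by default. Members absent from the matrix are dropped with a
#' warning; an empty intersection yields all-zero scores (with a warning),
#' not an error.
#'
#' @param norm A `NormalizedMatrix`.
#' @param members Character vector of gene symbols (or one element of
#'   [read_gene_sets()]).
#' @param base Log base (default natural log).
#' @param pseudocount Added before the log (default 1).
#' @return Named numeric vector of per-cell scores.
#' @export
geneset_score <- function(norm, members, base = exp(1), pseudocount = 1) {
  members <- unique(as.character(members))
  present <- intersect(members, rownames(norm))
  if (!length(present)) {
    warning("no gene-set member found in the matrix; scores are all zero")
    return(stats::setNames(rep(log(pseudocount, base = base), ncol(norm)),
                           colnames(norm)))
  }
  if (length(present) < length(members))
    warning("gene-set members missing from the matrix: ",
            paste(setdiff(members, present), collapse = ", "))
  total <- Matrix::colSums(norm[present, , drop = FALSE])
  stats::setNames(log(pseudocount + as.numeric(total), base = base),
                  colnames(norm))
}

#' Score every gene set for every cell
#'
#' @param norm A `NormalizedMatrix`.
#' @param gene_sets Named list of character vectors ([read_gene_sets()]).
#' @inheritParams geneset_score
#' @return data.frame: barcode plus one `score_<name>` column per set.
#' @export
score_table <- function(norm, gene_sets, base = exp(1), pseudocount = 1) {
  out <- data.frame(barcode = colnames(norm), stringsAsFactors = FALSE)
  for (n in names(gene_sets))
    out[[paste0("score_", n)]] <- as.numeric(
      geneset_score(norm, gene_sets[[n]], base = base,
                    pseudocount = pseudocount))
  out
}

#' Unpaired two-sided Wilcoxon rank-sum comparison of two score groups
#'
#' Mann-Whitney U with the normal approximation (tie-corrected, with
#' continuity correction); when both groups have at most `exact_max`
#' observations the two-sided p-value is computed by exact enumeration of
#' all group assignments of the pooled values (valid under ties).
#'
#' @param x,y Numeric score vectors (both non-empty).
#' @param exact_max Enumerate exactly when both sizes are <= this (default 8).
#' @return List with `statistic` (U for the first group) and `p_value`.
#' @export
compare_scores <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    pooled <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    rr <- rank(pooled)
    us <- colSums(matrix(rr[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    # two-sided: total probability of assignments at least as far from the
    # null mean n1*n2/2 as the observed U
    dev <- abs(us - n1 * n2 / 2)
    p <- mean(dev >= abs(u - n1 * n2 / 2) - 1e-12)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = u, p_value = p)
}

#' Define a marker rule
#'
#' A cell is of the given type iff every `required_all` gene is detected,
#' at least one `required_any` gene is detected (when the group is
#' non-empty), and no `forbidden` gene is detected.
#'
#' @param type_name Cell-type label.
#' @param required_all,required_any,forbidden Character vectors of gene
#'   symbols; `required_any` and `forbidden` may be empty.
#' @return Object of class `marker_rule`.
#' @export
marker_rule <- function(type_name, required_all = character(),
                        required_any = character(),
                        forbidden = character()) {
  required_all <- unique(as.character(required_all))
  required_any <- unique(as.character(required_any))
  forbidden <- unique(as.character(forbidden))
  if (length(intersect(required_all, forbidden)) ||
      length(intersect(required_any, forbidden)))
    stop("rule '", type_name, "': required and forbidden genes overlap")
  if (!length(required_all) && !length(required_any))
    stop("rule '", type_name, "' requires at least one marker gene")
  structure(list(type_name = type_name, required_all = required_all,
                 required_any = required_any, forbidden = forbidden),
            class = "marker_rule")
}

rule_genes <- function(rule)
  unique(c(rule$required_all, rule$required_any, rule$forbidden))

#' Strict marker-logic cell-type classification
#'
#' Detection means raw UMI >= `detect_min` (default 1; the strictest reading
#' of classification by strict marker expression). Cells matching no rule
#' are "unclassified"; cells matching more than one rule are "ambiguous",
#' with all matched labels reported rather than silently tie-broken.
#'
#' @param counts A `CountMatrix`.
#' @param rules List of [marker_rule()] objects.
#' @param detect_min Minimum UMI count that counts as detection.
#' @return data.frame: barcode, cell_type (type label, "unclassified" or
#'   "ambiguous"), matched_types (semicolon-separated labels).
#' @export
classify_cells <- function(counts, rules, detect_min = 1) {
  if (inherits(rules, "marker_rule")) rules <- list(rules)
  genes <- unique(unlist(lapply(rules, rule_genes)))
  missing <- setdiff(genes, rownames(counts))
  if (length(missing))
    stop("rule genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  det <- as.matrix(counts[genes, , drop = FALSE] >= detect_min)
  hit <- vapply(rules, function(r) {
    ok <- rep(TRUE, ncol(det))
    if (length(r$required_all))
      ok <- ok & colSums(!det[r$required_all, , drop = FALSE]) == 0
    if (length(r$required_any))
      ok <- ok & colSums(det[r$required_any, , drop = FALSE]) > 0
    if (length(r$forbidden))
      ok <- ok & colSums(det[r$forbidden, , drop = FALSE]) == 0
    ok
  }, logical(ncol(counts)))
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = 1)
  labels <- vapply(rules, `[[`, character(1), "type_name")
  matched <- apply(hit, 1, function(h) paste(labels[h], collapse = ";"))
  n_hit <- rowSums(hit)
  cell_type <- ifelse(n_hit == 0, "unclassified",
                      ifelse(n_hit > 1, "ambiguous", matched))
  data.frame(barcode = colnames(counts), cell_type = cell_type,
             matched_types = matched, stringsAsFactors = FALSE)
}

#' Hemogenic-endothelium subset of HSC-precursor cells
#'
#' Within cells classified as HSC precursor, flags the transcriptionally
#' defined HE subset: cells lacking detection of Itga2b (CD41), Spn (CD43)
#' and Ptprc (CD45).
#'
#' @param counts A `CountMatrix` restricted to precursor cells (columns).
#' @param cell_types Character vector of the cells' type labels; all must be
#'   the precursor label.
#' @param precursor_label Expected label (default "HSC_precursor").
#' @param he_forbidden The three surface-marker genes (default
#'   Itga2b/Spn/Ptprc).
#' @param detect_min Detection threshold (UMI >= detect_min).
#' @return Named logical vector: TRUE for HE cells.
#' @export
he_subset <- function(counts, cell_types,
                      precursor_label = "HSC_precursor",
                      he_forbidden = c("Itga2b", "Spn", "Ptprc"),
                      detect_min = 1) {
  if (length(cell_types) != ncol(counts))
    stop("need one cell-type label per cell")
  if (any(cell_types != precursor_label))
    stop("he_subset is defined only for cells labeled '", precursor_label,
         "'")
  missing <- setdiff(he_forbidden, rownames(counts))
  if (length(missing))
    stop("rule genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  det <- counts[he_forbidden, , drop = FALSE] >= detect_min
  stats::setNames(Matrix::colSums(det) == 0, colnames(counts))
}

#' The packaged classification rules for AGM and colony data
#'
#' Marker logic as used for the in vivo V+61+E+ data (arterial EC, HSC
#' precursor, progenitor) and the in vitro colony data (HSC type, HPC type):
#' \itemize{
#'   \item arterial_EC: all of Cdh5, Dll4, Efnb2, Hey1; none of Runx1, Gfi1,
#'     Nr2f2, Nrp2.
#'   \item HSC_precursor: all of Gfi1, Mycn, Pdzk1ip1, Procr, Dll4, Vwf,
#'     Cdkn1c, Pbx1, Mllt3; none of Flt3, Il7r, Fcgr3, Csf3r.
#'   \item progenitor: Runx1 plus at least one of Flt3, Il7r, Fcgr3, Csf3r.
#'   \item HSC_type: all of Runx1, Pdzk1ip1, Vwf; none of Cd48, Itgal.
#'   \item HPC_type: at least one of Cd48, Itgal.
#' }
#'
#' @param which "agm" (first three), "colony" (last two) or "all".
#' @return List of [marker_rule()] objects.
#' @export
default_marker_rules <- function(which = c("agm", "colony", "all")) {
  which <- match.arg(which)
  agm <- list(
    marker_rule("arterial_EC",
                required_all = c("Cdh5", "Dll4", "Efnb2", "Hey1"),
                forbidden = c("Runx1", "Gfi1", "Nr2f2", "Nrp2")),
    marker_rule("HSC_precursor",
                required_all = c("Gfi1", "Mycn", "Pdzk1ip1", "Procr", "Dll4",
                                 "Vwf", "Cdkn1c", "Pbx1", "Mllt3"),
                forbidden = c("Flt3", "Il7r", "Fcgr3", "Csf3r")),
    marker_rule("progenitor",
                required_all = "Runx1",
                required_any = c("Flt3", "Il7r", "Fcgr3", "Csf3r")))
  colony <- list(
    marker_rule("HSC_type",
                required_all = c("Runx1", "Pdzk1ip1", "Vwf"),
                forbidden = c("Cd48", "Itgal")),
    marker_rule("HPC_type",
                required_any = c("Cd48", "Itgal")))
  switch(which, agm = agm, colony = colony, all = c(agm, colony))
}

#' Read marker rules from a delimited file
#'
#' Tab-separated with header `type_name, required_all, required_any,
#' forbidden`; gene lists are semicolon-separated, empty fields allowed.
#'
#' @param path Path to the TSV.
#' @return List of [marker_rule()] objects.
#' @export
read_marker_rules <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = NULL)
  split_genes <- function(x)
    if (is.na(x) || !nzchar(x)) character() else
      strsplit(x, ";", fixed = TRUE)[[1]]
  lapply(seq_len(nrow(df)), function(i)
    marker_rule(df$type_name[i],
                required_all = split_genes(df$required_all[i]),
                required_any = split_genes(df$required_any[i]),
                forbidden = split_genes(df$forbidden[i])))
}

#' Write marker rules to a delimited file
#' @param rules List of [marker_rule()] objects.
#' @param path Output path.
#' @export
write_marker_rules <- function(rules, path) {
  df <- data.frame(
    type_name = vapply(rules, `[[`, character(1), "type_name"),
    required_all = vapply(rules, function(r)
      paste(r$required_all, collapse = ";"), character(1)),
    required_any = vapply(rules, function(r)
      paste(r$required_any, collapse = ";"), character(1)),
    forbidden = vapply(rules, function(r)
      paste(r$forbidden, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
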