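# Clonal HSC colony-forming-cell quantification: per-well outcome
# frequencies with exact binomial confidence intervals, per-AGM abundance,
# multilineage engraftment classification, and comparison of
# transcriptionally defined precursor counts against the functional range.

#' HSC / non-HSC colony-forming-cell frequencies
#'
#' Percentages of wells (index-sorted single cells) whose outcome was
#' HSC_CFC / non_HSC_CFC, with exact Clopper-Pearson 95\% confidence
#' intervals (appropriate for the small well counts of clonal assays).
#'
#' @param clone_table data.frame with an `outcome` column over
#'   \{"HSC_CFC", "non_HSC_CFC", "no_colony"\}; see [simulate_clone_table()].
#' @param conf_level Confidence level (default 0.95).
#' @return List: n_wells, pct_hsc_cfc, pct_non_hsc_cfc, and per-outcome CI
#'   bounds (percent scale).
#' @export
cfc_frequencies <- function(clone_table, conf_level = 0.95) {
  if (!nrow(clone_table)) stop("empty clone table")
  bad <- setdiff(unique(clone_table$outcome),
                 c("HSC_CFC", "non_HSC_CFC", "no_colony"))
  if (length(bad))
    stop("unknown outcome: ", paste(bad, collapse = ", "))
  n <- nrow(clone_table)
  k_hsc <- sum(clone_table$outcome == "HSC_CFC")
  k_non <- sum(clone_table$outcome == "non_HSC_CFC")
  ci_hsc <- clopper_pearson(k_hsc, n, conf_level)
  ci_non <- clopper_pearson(k_non, n, conf_level)
  list(n_wells = n,
       pct_hsc_cfc = 100 * k_hsc / n,
       pct_non_hsc_cfc = 100 * k_non / n,
       ci_hsc_cfc = 100 * ci_hsc,
       ci_non_hsc_cfc = 100 * ci_non)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#' @param k Successes.
#' @param n Trials.
#' @param conf_level Confidence level.
#' @return c(lower, upper) on the proportion scale.
#' @export
clopper_pearson <- function(k, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' CFC frequencies pooled per embryonic stage
#'
#' Rows are pooled across experiments within each stage tag before the
#' frequencies are computed.
#'
#' @param clone_table data.frame with `stage` and `outcome` columns.
#' @param conf_level Confidence level.
#' @return data.frame, one row per stage.
#' @export
cfc_frequencies_by_stage <- function(clone_table, conf_level = 0.95) {
  do.call(rbind, lapply(split(clone_table, clone_table$stage), function(d) {
    f <- cfc_frequencies(d, conf_level)
    data.frame(stage = d$stage[1], n_wells = f$n_wells,
               pct_hsc_cfc = f$pct_hsc_cfc,
               pct_non_hsc_cfc = f$pct_non_hsc_cfc,
               hsc_ci_lower = f$ci_hsc_cfc[1], hsc_ci_upper = f$ci_hsc_cfc[2],
               stringsAsFactors = FALSE)
  }))
}

#' HSC colony-forming cells per AGM
#'
#' `n_hsc_cfc / (embryo_equivalents * fraction_sorted)`: the number of
#' detected HSC CFC scaled by how many embryo equivalents were sorted and
#' what fraction of gated cells was actually index-sorted.
#'
#' @param n_hsc_cfc Number of HSC CFC detected (>= 0).
#' @param embryo_equivalents Positive real.
#' @param fraction_sorted In (0, 1].
#' @return HSC CFC per AGM (real).
#' @export
cfc_per_agm <- function(n_hsc_cfc, embryo_equivalents, fraction_sorted) {
  if (embryo_equivalents <= 0) stop("embryo_equivalents must be positive")
  if (fraction_sorted <= 0 || fraction_sorted > 1)
    stop("fraction_sorted must be in (0, 1]")
  if (n_hsc_cfc < 0) stop("n_hsc_cfc must be non-negative")
  n_hsc_cfc / (embryo_equivalents * fraction_sorted)
}

#' Classify multilineage engraftment
#'
#' Multilineage engraftment requires donor chimerism strictly above
#' `donor_min` percent, each lineage (myeloid, B, T) detected at >=
#' `lineage_min` percent, and follow-up of at least `weeks_min` weeks.
#'
#' @param records data.frame with columns donor_pct, myeloid_pct, b_pct,
#'   t_pct, weeks (a single record may be given as a list).
#' @param donor_min Donor threshold, strict > (default 5).
#' @param lineage_min Per-lineage threshold, inclusive >= (default 0.5).
#' @param weeks_min Minimum follow-up in weeks, inclusive (default 16).
#' @return Logical vector, one per record.
#' @export
classify_engraftment <- function(records, donor_min = 5.0,
                                 lineage_min = 0.5, weeks_min = 16) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  need <- c("donor_pct", "myeloid_pct", "b_pct", "t_pct", "weeks")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("missing engraftment fields: ", paste(missing, collapse = ", "))
  for (f in need)
    if (anyNA(records[[f]])) stop("missing values in field ", f)
  pcts <- c("donor_pct", "myeloid_pct", "b_pct", "t_pct")
  for (f in pcts)
    if (any(records[[f]] < 0 | records[[f]] > 100))
      stop("percentages must be in [0, 100]: ", f)
  records$donor_pct > donor_min &
    records$myeloid_pct >= lineage_min &
    records$b_pct >= lineage_min &
    records$t_pct >= lineage_min &
    records$weeks >= weeks_min
}

#' Compare a transcriptional precursor count with the functional CFC range
#'
#' @param transcriptional_count Number of cells classified as HSC precursor
#'   in the scRNA-seq data at a stage.
#' @param cfc_range_low,cfc_range_high Predicted precursor range from the
#'   HSC CFC assay (low <= high).
#' @param stage Optional stage tag for the report.
#' @return List: within_range (logical) and a one-row report data.frame.
#' @export
compare_precursor_counts <- function(transcriptional_count, cfc_range_low,
                                     cfc_range_high, stage = NA_character_) {
  if (cfc_range_low > cfc_range_high)
    stop("inverted range: low > high")
  within <- transcriptional_count >= cfc_range_low &
    transcriptional_count <= cfc_range_high
  list(within_range = within,
       report = data.frame(stage = stage,
                           transcriptional_count = transcriptional_count,
                           cfc_range_low = cfc_range_low,
                           cfc_range_high = cfc_range_high,
                           within_range = within,
                           stringsAsFactors = FALSE))
}
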