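#' Classify protein abundance change
#'
#' Applies the abundance thresholds used for nuclear proteome comparisons:
#' a protein is `enriched` when `logfc > 1.5` with `fdr < 0.05`, `depleted`
#' when `logfc < -1.5` with `fdr < 0.05`, otherwise `unchanged`. Vectorized;
#' symmetric in the sign of `logfc`.
#'
#' @param logfc Log fold-change(s), treated vs untreated.
#' @param fdr Differential-abundance FDR value(s) in `[0, 1]`.
#' @param logfc_cut,fdr_cut Thresholds (defaults 1.5 and 0.05).
#' @return Character vector: `"enriched"`, `"depleted"`, or `"unchanged"`.
#' @export
classify_abundance <- function(logfc, fdr, logfc_cut = 1.5, fdr_cut = 0.05) {
  stopifnot(length(logfc) == length(fdr))
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) stopf("`fdr` must lie in [0, 1]")
  out <- rep("unchanged", length(logfc))
  out[logfc > logfc_cut & fdr < fdr_cut] <- "enriched"
  out[logfc < -logfc_cut & fdr < fdr_cut] <- "depleted"
  out
}

#' Spectral-count ratio with zero replacement
#'
#' Ratio of untreated to drug-treated phosphopeptide spectral counts. A zero
#' count on either side is replaced by `zero_replace` (0.1) to avoid division
#' by zero, applied symmetrically. Records where both totals are zero are
#' undefined (`NA`) and should be dropped by the caller with notice.
#'
#' @param untreated_total,treated_total Non-negative spectral-count totals.
#' @param zero_replace Replacement for zero counts (default 0.1).
#' @return Numeric ratio(s); `NA` where both operands are zero.
#' @export
spectra_ratio <- function(untreated_total, treated_total, zero_replace = 0.1) {
  stopifnot(length(untreated_total) == length(treated_total))
  if (any(untreated_total < 0 | treated_total < 0, na.rm = TRUE))
    stopf("spectral counts must be >= 0")
  u <- ifelse(untreated_total == 0, zero_replace, untreated_total)
  tr <- ifelse(treated_total == 0, zero_replace, treated_total)
  r <- u / tr
  r[untreated_total == 0 & treated_total == 0] <- NA_real_
  r
}

#' Filter phosphosites for decreased phosphorylation
#'
#' Applies the tabular rules used to nominate sites whose phosphorylation
#' drops under kinase inhibition:
#' \enumerate{
#'   \item drop sites on proteins whose abundance significantly decreased
#'     under treatment (`fdr < fdr_cut` with negative `logfc`) -- in any
#'     listed drug by default, since both drugs share the plotted axes;
#'   \item drop sites with insufficient untreated evidence: by default each
#'     untreated replicate must have at least `min_untreated` (2) spectra
#'     (the stricter per-replicate reading); `count_rule = "total"` applies
#'     the threshold to the replicate sum instead;
#'   \item drop sites with zero spectra in every untreated and treated
#'     column (no usable ratio).
#' }
#' Surviving sites get per-drug untreated/treated spectral-count ratios (with
#' the 0 -> 0.1 replacement) and a `decreased_in_all` flag (`ratio > 1` for
#' every drug).
#'
#' @param records Data frame with columns `protein_id`, `site`, untreated
#'   replicate counts `untreated_1`, `untreated_2`, and per drug `d`:
#'   `treated_<d>` (total counts), `logfc_<d>`, `fdr_<d>`. An `is_nucleolar`
#'   column is carried through if present.
#' @param drugs Character vector of drug names matching the column suffixes.
#' @param count_rule `"per_replicate"` (default) or `"total"`.
#' @param decrease_rule `"any_drug"` (default) or `"per_drug"`; under
#'   `"per_drug"` a site is only dropped if significantly decreased in every
#'   listed drug.
#' @param fdr_cut Abundance-decrease FDR cutoff (default 1e-4).
#' @param min_untreated Minimum untreated spectral count (default 2).
#' @param zero_replace Passed to [spectra_ratio()].
#' @return The surviving records with `ratio_<drug>` columns and
#'   `decreased_in_all`; attributes `n_dropped_abundance`,
#'   `n_dropped_counts`, `n_dropped_empty` record exclusions.
#' @export
filter_decreased_sites <- function(records, drugs,
                                   count_rule = c("per_replicate", "total"),
                                   decrease_rule = c("any_drug", "per_drug"),
                                   fdr_cut = 1e-4, min_untreated = 2,
                                   zero_replace = 0.1) {
  count_rule <- match.arg(count_rule)
  decrease_rule <- match.arg(decrease_rule)
  need <- c("protein_id", "site", "untreated_1", "untreated_2",
            paste0("treated_", drugs), paste0("logfc_", drugs),
            paste0("fdr_", drugs))
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))

  dec <- sapply(drugs, function(d)
    records[[paste0("fdr_", d)]] < fdr_cut & records[[paste0("logfc_", d)]] < 0)
  dec <- matrix(dec, nrow = nrow(records))
  drop_abund <- if (decrease_rule == "any_drug") apply(dec, 1L, any)
                else apply(dec, 1L, all)

  u1 <- records$untreated_1; u2 <- records$untreated_2
  drop_counts <- if (count_rule == "per_replicate")
    (u1 < min_untreated | u2 < min_untreated)
  else (u1 + u2) < min_untreated

  u_tot <- u1 + u2
  t_tot <- Reduce(`+`, lapply(drugs, function(d) records[[paste0("treated_", d)]]))
  drop_empty <- u_tot == 0 & t_tot == 0

  keep <- !(drop_abund | drop_counts | drop_empty)
  out <- records[keep, , drop = FALSE]
  for (d in drugs)
    out[[paste0("ratio_", d)]] <-
      spectra_ratio(out$untreated_1 + out$untreated_2,
                    out[[paste0("treated_", d)]], zero_replace)
  rat <- sapply(drugs, function(d) out[[paste0("ratio_", d)]] > 1)
  rat <- matrix(rat, nrow = nrow(out))
  out$decreased_in_all <- apply(rat, 1L, all)
  rownames(out) <- NULL
  attr(out, "n_dropped_abundance") <- sum(drop_abund)
  attr(out, "n_dropped_counts") <- sum(drop_counts & !drop_abund)
  attr(out, "n_dropped_empty") <- sum(drop_empty & !drop_abund & !drop_counts)
  out
}

#' Read/write phosphosite tables
#'
#' Tab-separated tables with the column layout documented in
#' [filter_decreased_sites()].
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_phospho_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_phospho_table
#' @param records Data frame to write.
#' @export
write_phospho_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
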